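# Shared fixtures, built in code and cached for the session.

# Tiny geno_matrix from a character matrix of "AA"/"Aa"/"aa"/NA calls.
toy_geno <- function(strings, chrom = NULL, pos = NULL, a1 = "A", a2 = "B") {
  s <- as.matrix(strings)
  calls <- matrix(NA_integer_, nrow(s), ncol(s), dimnames = dimnames(s))
  calls[s == "AA"] <- 2L; calls[s == "Aa"] <- 1L; calls[s == "aa"] <- 0L
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("L", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("m", seq_len(ncol(calls)))
  geno_matrix(calls, data.frame(
    marker = colnames(calls),
    chrom = chrom %||% rep(1L, ncol(calls)),
    pos = pos %||% seq_len(ncol(calls)) * 10,
    a1 = a1, a2 = a2, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One small shared study, reused across test files (built once).
.fixture_env <- new.env()
small_study <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- sim_config(genome = genome_map(n_markers = 300),
                      pop_sizes = c(bc1f3 = 60, dh = 30, f45 = 30,
                                    unrelated = 30),
                      n_qtl = 50, seed = 42)
    .fixture_env$study <- simulate_study(cfg)
  }
  .fixture_env$study
}

# Independent restricted log-likelihood, dense algebra only (oracle).
oracle_restricted_ll <- function(y, X, V) {
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            t(r) %*% Vi %*% r)[1]
}

# Mixed-model-equation GBLUP oracle: given variances, solve
#  [X'X   X'Z          ] [b]   [X'y]
#  [Z'X   Z'Z + lam*Ki ] [u] = [Z'y],  lam = s2e/s2a, Ki = K^-1 (train)
# and predict target lines via u_target = K[t, train] K_tt^-1 u_train.
oracle_mme_predict <- function(y_train, K, train_ids, target_ids, s2a, s2e) {
  Kt <- K[train_ids, train_ids]
  n <- length(train_ids)
  X <- matrix(1, n, 1)
  Ki <- solve(Kt)
  lhs <- rbind(cbind(crossprod(X), t(X)),
               cbind(X, diag(n) + (s2e / s2a) * Ki))
  rhs <- c(sum(y_train), y_train)
  sol <- solve(lhs, rhs)
  b <- sol[1]; u <- sol[-1]
  u_t <- K[target_ids, train_ids, drop = FALSE] %*% Ki %*% u
  setNames(b + drop(u_t), target_ids)
}
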