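#' Fit a GBLUP model (additive, or additive + dominance)
#'
#' Model: `y = mu + xi_a (+ xi_d) + eps` with
#' `xi_a ~ N(0, Ka sigma_a^2)`, `xi_d ~ N(0, Kd sigma_d^2)`,
#' `eps ~ N(0, I sigma_e^2)`.  Variance components are estimated on the
#' training lines by REML (default; eigendecomposition-based for a
#' single kernel, quasi-Newton with analytic gradients for two) or by a
#' conjugate Gibbs sampler; genetic effects for all lines in the kinship
#' (phenotyped or not) are obtained from the kinship cross-blocks:
#' `xi_hat = sigma^2 K[ , train] V^-1 (y - mu_hat)`.
#'
#' @param y named numeric vector of phenotypes (e.g. BLUEs), or a
#'   data.frame with columns `line` and `blue`
#' @param Ka additive kinship over all lines (train and target)
#' @param Kd optional dominance kinship (adds the dominance term)
#' @param train_ids lines used for training (default: all lines with
#'   phenotypes)
#' @param solver `"reml"` (default) or `"gibbs"`
#' @param seed required for `"gibbs"`
#' @param n_iter,burn_in Gibbs chain length and burn-in
#' @return a `gp_fit`: list with `mu`, `xi_a`, `xi_d`, `var_a`, `var_d`,
#'   `var_e`, `loglik`, `solver`, `train_ids`
#' @export
fit_gblup <- function(y, Ka, Kd = NULL, train_ids = NULL,
                      solver = c("reml", "gibbs"), seed = NULL,
                      n_iter = 15000, burn_in = 1000) {
  solver <- match.arg(solver)
  if (is.data.frame(y)) y <- setNames(y$blue, y$line)
  ids <- rownames(Ka)
  if (is.null(ids)) stop("Ka must have line ids as dimnames")
  train_ids <- train_ids %||% intersect(ids, names(y))
  if (!all(train_ids %in% ids)) stop("train_ids not all present in kinship")
  if (!all(train_ids %in% names(y))) stop("phenotypes missing for some train_ids")
  yt <- y[train_ids]
  Kt <- unclass(Ka)[train_ids, train_ids]
  X <- matrix(1, length(yt), 1)
  has_d <- !is.null(Kd)
  if (has_d && !identical(rownames(Kd), ids))
    Kd <- unclass(Kd)[ids, ids]
  if (solver == "reml") {
    Ks <- c(list(Kt), if (has_d) list(unclass(Kd)[train_ids, train_ids]))
    fit <- reml_fit(yt, X, Ks)
    mu <- fit$beta[1]
    Py <- fit$Py
    xi_a <- drop(unclass(Ka)[, train_ids] %*% Py) * fit$sigma2[1]
    xi_d <- if (has_d) drop(unclass(Kd)[, train_ids] %*% Py) * fit$sigma2[2]
            else NULL
    out <- list(mu = mu, xi_a = setNames(xi_a, ids),
                xi_d = if (has_d) setNames(xi_d, ids),
                var_a = fit$sigma2[1],
                var_d = if (has_d) fit$sigma2[2] else 0,
                var_e = fit$sigma2[length(fit$sigma2)],
                loglik = fit$loglik, solver = "reml", train_ids = train_ids)
  } else {
    if (is.null(seed)) stop("fit_gblup: gibbs solver requires a seed")
    out <- gblup_gibbs(yt, Ka, Kd, train_ids, seed, n_iter, burn_in)
  }
  class(out) <- "gp_fit"
  out
}

# Conjugate Gibbs sampler over (mu, u_a[, u_d], variances) with
# scaled-inverse-chi-squared priors (df0 = 5; scales set from an equal
# partition of the phenotypic variance).  Effects are sampled for all
# lines jointly; lines without data contribute only through the kernel.
gblup_gibbs <- function(yt, Ka, Kd, train_ids, seed, n_iter, burn_in) {
  set.seed(seed)
  ids <- rownames(Ka)
  n <- length(ids); nt <- length(yt)
  obs <- ids %in% train_ids
  yfull <- setNames(rep(0, n), ids); yfull[train_ids] <- yt
  has_d <- !is.null(Kd)
  ridge_inv <- function(K) {
    K <- unclass(K)
    ch <- tryCatch(chol(K), error = function(e) chol(K + diag(1e-6, n)))
    chol2inv(ch)
  }
  Kai <- ridge_inv(Ka)
  Kdi <- if (has_d) ridge_inv(Kd)
  df0 <- 5
  vy <- var(yt)
  ncmp <- 2 + has_d
  S0 <- vy / ncmp * (df0 + 2) / df0      # prior mode = vy / ncmp
  mu <- mean(yt); ua <- rep(0, n); ud <- rep(0, n)
  s2a <- vy / ncmp; s2e <- vy / ncmp; s2d <- if (has_d) vy / ncmp else 0
  D <- as.numeric(obs)
  keep <- 0; acc <- list(mu = 0, ua = rep(0, n), ud = rep(0, n),
                         s2a = 0, s2d = 0, s2e = 0)
  draw_u <- function(Kinv, s2u, resid_obs) {
    M <- Kinv / s2u + diag(D / s2e)
    ch <- chol(M)
    rhs <- D * resid_obs / s2e
    mean_u <- backsolve(ch, forwardsolve(t(ch), rhs))
    drop(mean_u + backsolve(ch, rnorm(n)))
  }
  for (it in seq_len(n_iter)) {
    resid <- yfull - mu - ua - ud
    # mu | rest
    mu <- rnorm(1, mean((yfull - ua - ud)[obs]), sqrt(s2e / nt))
    ua <- draw_u(Kai, s2a, yfull - mu - ud)
    if (has_d) ud <- draw_u(Kdi, s2d, yfull - mu - ua)
    s2a <- (sum(ua * (Kai %*% ua)) + df0 * S0) / rchisq(1, n + df0)
    if (has_d) s2d <- (sum(ud * (Kdi %*% ud)) + df0 * S0) / rchisq(1, n + df0)
    ee <- (yfull - mu - ua - ud)[obs]
    s2e <- (sum(ee^2) + df0 * S0) / rchisq(1, nt + df0)
    if (it > burn_in) {
      keep <- keep + 1
      acc$mu <- acc$mu + mu; acc$ua <- acc$ua + ua; acc$ud <- acc$ud + ud
      acc$s2a <- acc$s2a + s2a; acc$s2d <- acc$s2d + s2d; acc$s2e <- acc$s2e + s2e
    }
  }
  list(mu = acc$mu / keep,
       xi_a = setNames(acc$ua / keep, ids),
       xi_d = if (has_d) setNames(acc$ud / keep, ids),
       var_a = acc$s2a / keep,
       var_d = if (has_d) acc$s2d / keep else 0,
       var_e = acc$s2e / keep,
       loglik = NA_real_, solver = "gibbs", train_ids = train_ids)
}

#' Predict phenotypes from a fitted GBLUP model
#'
#' @param object a `gp_fit` from [fit_gblup()]
#' @param target_ids line ids to predict (default: all lines in the fit)
#' @param ... unused
#' @return named numeric vector `mu + xi_a (+ xi_d)` per target line
#' @export
predict.gp_fit <- function(object, target_ids = NULL, ...) {
  ids <- names(object$xi_a)
  target_ids <- target_ids %||% ids
  if (!all(target_ids %in% ids))
    stop("predict.gp_fit: unknown line id(s): ",
         paste(setdiff(target_ids, ids), collapse = ", "))
  p <- object$mu + object$xi_a[target_ids]
  if (!is.null(object$xi_d)) p <- p + object$xi_d[target_ids]
  p
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("gp_fit (%s): n_train = %d, var_a = %.4g, var_d = %.4g, var_e = %.4g\n",
              x$solver, length(x$train_ids), x$var_a, x$var_d, x$var_e))
  invisible(x)
}
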