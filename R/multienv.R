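#' Stack per-environment phenotypes
#'
#' @param blues data.frame with columns `line`, `env`, `blue` (e.g. from
#'   `fit_blue(..., scope = "per_env")`), or a named list of per-env
#'   vectors
#' @return a `stacked_phenotypes` data.frame (line, env, y)
#' @export
stack_phenotypes <- function(blues) {
  if (is.list(blues) && !is.data.frame(blues)) {
    blues <- do.call(rbind, lapply(names(blues), function(ev)
      data.frame(line = names(blues[[ev]]), env = ev,
                 blue = unname(blues[[ev]]), stringsAsFactors = FALSE)))
  }
  out <- data.frame(line = as.character(blues$line),
                    env = as.character(blues$env),
                    y = blues$blue %||% blues$y, stringsAsFactors = FALSE)
  if (anyNA(out$y)) stop("stack_phenotypes: missing phenotype values")
  class(out) <- c("stacked_phenotypes", "data.frame")
  out
}

#' Covariance structures for across-environment GBLUP
#'
#' For cells (line, env) listed in `cells`, the main-effect covariance
#' `G0` has block (j, j') equal to the additive kinship restricted to
#' the lines present in environments j and j' (main genetic effect
#' perfectly correlated across environments).  The interaction template
#' `G1` is block-diagonal by environment: `G1[[j]]` equals the kinship
#' block within environment j (each block is scaled by its own
#' environment-specific variance at fit time) and zero between
#' environments.
#'
#' @param Ka additive kinship over the union of lines
#' @param cells data.frame with columns `line`, `env` giving the stacked
#'   cell order
#' @return list with `G0` (n_cells x n_cells) and `G1` (named list of
#'   per-environment n_cells x n_cells blocks)
#' @export
build_covariances <- function(Ka, cells) {
  envs <- unique(cells$env)
  for (ev in envs) if (!any(cells$env == ev))
    stop("build_covariances: environment '", ev, "' has no lines")
  miss <- setdiff(unique(cells$line), rownames(Ka))
  if (length(miss))
    stop("build_covariances: lines missing from kinship: ",
         paste(utils::head(miss, 5), collapse = ", "))
  K <- unclass(Ka)
  G0 <- K[cells$line, cells$line]
  G1 <- lapply(envs, function(ev) {
    idx <- cells$env == ev
    B <- matrix(0, nrow(cells), nrow(cells))
    B[idx, idx] <- K[cells$line[idx], cells$line[idx]]
    B
  })
  names(G1) <- envs
  list(G0 = G0, G1 = G1)
}

#' Single-environment GBLUP
#'
#' The per-environment model: additive-only GBLUP on one environment's
#' BLUEs (delegates to [fit_gblup()]).
#'
#' @param y_env named phenotype vector for one environment
#' @param Ka additive kinship
#' @param train_ids training lines
#' @param ... passed to [fit_gblup()]
#' @return a `gp_fit`
#' @export
fit_se <- function(y_env, Ka, train_ids = NULL, ...) {
  fit_gblup(y_env, Ka, Kd = NULL, train_ids = train_ids, ...)
}

#' Across-environment and G-by-E GBLUP on stacked phenotypes
#'
#' AE model: `y = mu_j + xi + eps`, one additive genetic main effect
#' shared by all environments, `xi ~ N(0, G0 sigma_u^2)`.
#' G-by-E model: `y = mu_j + xi + xi_js + eps`, adding
#' environment-specific effects with block-diagonal covariance `G1`;
#' by default each environment block carries its own variance
#' `sigma_js^2` (`het_gxe = TRUE`).  Residuals are homogeneous across
#' environments.  Training uses all cells not listed in `masked_cells`;
#' predictions for masked cells come from the covariance cross-blocks:
#' AE uses `mu_j + xi`, G-by-E uses `mu_j + xi + xi_js`.
#'
#' @param stacked a [stack_phenotypes()] data.frame
#' @param Ka additive kinship over all lines involved
#' @param model `"AE"` or `"GxE"`
#' @param masked_cells optional data.frame (line, env) of cells to hold
#'   out of training and predict
#' @param het_gxe environment-specific interaction variances (default)
#'   or a single shared interaction variance
#' @return a `multienv_fit`: list with `mu` (per env), `var_u`, `var_s`
#'   (per env, G-by-E only), `var_e`, `predictions` (data.frame line,
#'   env, y_pred for masked cells; all cells when none masked), `model`
#' @export
fit_multienv <- function(stacked, Ka, model = c("AE", "GxE"),
                         masked_cells = NULL, het_gxe = TRUE) {
  model <- match.arg(model)
  st <- as.data.frame(stacked)
  envs <- unique(st$env)
  if (length(envs) < 2L)
    stop("fit_multienv: AE/GxE models need at least 2 environments")
  masked <- rep(FALSE, nrow(st))
  if (!is.null(masked_cells) && nrow(masked_cells)) {
    key <- paste(st$line, st$env)
    masked <- key %in% paste(masked_cells$line, masked_cells$env)
  }
  for (ev in envs) if (all(masked[st$env == ev]))
    stop("fit_multienv: all cells of environment '", ev, "' are masked")
  tr <- st[!masked, , drop = FALSE]
  cov_tr <- build_covariances(Ka, tr)
  X <- stats::model.matrix(~ 0 + factor(env, levels = envs), tr)
  colnames(X) <- envs
  Ks <- list(G0 = cov_tr$G0)
  if (model == "GxE") {
    if (het_gxe) Ks <- c(Ks, cov_tr$G1)
    else Ks <- c(Ks, list(gxe = Reduce(`+`, cov_tr$G1)))
  }
  fit <- reml_fit(tr$y, X, Ks)
  mu <- setNames(fit$beta, envs)
  s2 <- fit$sigma2
  var_u <- s2[1]
  var_e <- s2[length(s2)]
  var_s <- if (model == "GxE") {
    if (het_gxe) setNames(s2[2:(1 + length(envs))], envs)
    else setNames(rep(s2[2], length(envs)), envs)
  } else setNames(rep(0, length(envs)), envs)
  # predictions for target cells via covariance cross blocks
  tgt <- if (any(masked)) st[masked, , drop = FALSE] else st
  K <- unclass(Ka)
  Cmain <- K[tgt$line, tr$line, drop = FALSE] * var_u
  Cint <- matrix(0, nrow(tgt), nrow(tr))
  if (model == "GxE") {
    for (ev in envs) {
      it <- tgt$env == ev; io <- tr$env == ev
      if (any(it) && any(io))
        Cint[it, io] <- K[tgt$line[it], tr$line[io], drop = FALSE] * var_s[ev]
    }
  }
  g_hat <- drop((Cmain + Cint) %*% fit$Py)
  preds <- data.frame(line = tgt$line, env = tgt$env,
                      y_pred = unname(mu[tgt$env]) + g_hat,
                      stringsAsFactors = FALSE)
  structure(list(mu = mu, var_u = unname(var_u), var_s = var_s,
                 var_e = unname(var_e), predictions = preds, model = model,
                 loglik = fit$loglik, envs = envs, het_gxe = het_gxe),
            class = "multienv_fit")
}

#' @export
print.multienv_fit <- function(x, ...) {
  cat(sprintf("multienv_fit (%s): var_u = %.4g, var_e = %.4g\n",
              x$model, x$var_u, x$var_e))
  if (x$model == "GxE")
    cat("  var_s:", paste(sprintf("%s = %.4g", names(x$var_s), x$var_s),
                          collapse = ", "), "\n")
  invisible(x)
}
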