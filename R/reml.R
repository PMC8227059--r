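# Internal REML machinery for Gaussian mixed models of the form
#   y = X beta + sum_i u_i + eps,  u_i ~ N(0, K_i s2_i),  eps ~ N(0, I s2_e)
# All solvers maximize the restricted log-likelihood
#   lR = -1/2 [ log|V| + log|X' V^-1 X| + y' P y ]
# with V = sum_i s2_i K_i + s2_e I and P = V^-1 - V^-1 X (X'V^-1X)^-1 X'V^-1.

# Single-kernel fast path: eigendecompose K once, then the likelihood is
# a cheap 1-D function of the ratio lambda = s2_g / s2_e (EMMA-style).
reml_single <- function(y, X, K, tol = 1e-10) {
  n <- length(y); p <- ncol(X)
  eg <- eigen(K, symmetric = TRUE)
  U <- eg$vectors; d <- pmax(eg$values, 0)
  yt <- drop(crossprod(U, y)); Xt <- crossprod(U, X)
  negll <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    XtWX <- crossprod(Xt, Xt * w)
    cx <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(cx)) return(1e10)
    beta <- backsolve(cx, forwardsolve(t(cx), crossprod(Xt, yt * w)))
    rt <- yt - drop(Xt %*% beta)
    rss <- sum(rt^2 * w)
    s2e <- rss / (n - p)
    0.5 * ((n - p) * log(s2e) + sum(log(lam * d + 1)) +
             2 * sum(log(diag(cx))) + (n - p))
  }
  opt <- optimize(negll, c(-15, 15))
  # guard the boundaries
  for (b in c(-15, 15)) if (negll(b) < opt$objective - 1e-9)
    opt <- list(minimum = b, objective = negll(b))
  lam <- exp(opt$minimum)
  w <- 1 / (lam * d + 1)
  XtWX <- crossprod(Xt, Xt * w)
  beta <- solve(XtWX, crossprod(Xt, yt * w))
  rt <- yt - drop(Xt %*% beta)
  s2e <- sum(rt^2 * w) / (n - p)
  s2g <- max(lam * s2e, tol)
  Vi <- U %*% (t(U) * (1 / (s2g * d + s2e)))
  r <- y - drop(X %*% beta)
  list(sigma2 = c(s2g, s2e), beta = drop(beta), Vinv = Vi,
       Py = drop(Vi %*% r), loglik = -opt$objective, converged = TRUE)
}

# General multi-kernel REML: quasi-Newton (L-BFGS-B) on log-variances
# with the analytic gradient
#   d lR / d s2_i = -1/2 [ tr(P K_i) - (Py)' K_i (Py) ].
reml_multi <- function(y, X, Ks, init = NULL, maxit = 200, tol = 1e-10) {
  n <- length(y); q <- length(Ks)
  vy <- var(y)
  theta0 <- log(init %||% rep(vy / (q + 1), q + 1))
  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta) {
    key <- paste(signif(theta, 15), collapse = ",")
    if (identical(cache$key, key)) return(cache$val)
    s2 <- exp(theta)
    V <- diag(s2[q + 1], n)
    for (i in seq_len(q)) V <- V + s2[i] * Ks[[i]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      ch <- chol(V + diag(1e-6 * mean(diag(V)), n))
    }
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    XtViX <- XtVi %*% X
    cx <- chol(XtViX)
    beta <- backsolve(cx, forwardsolve(t(cx), XtVi %*% y))
    r <- y - drop(X %*% beta)
    Py <- drop(Vi %*% r)
    ld_v <- 2 * sum(log(diag(ch)))
    ld_x <- 2 * sum(log(diag(cx)))
    nll <- 0.5 * (ld_v + ld_x + sum(y * Py))
    # P = Vi - Vi X (X'ViX)^-1 X'Vi ; only elementwise products needed
    B <- backsolve(cx, forwardsolve(t(cx), XtVi))
    P <- Vi - crossprod(XtVi, B)
    gr <- numeric(q + 1)
    for (i in seq_len(q))
      gr[i] <- 0.5 * (sum(P * Ks[[i]]) - sum(Py * (Ks[[i]] %*% Py))) * s2[i]
    gr[q + 1] <- 0.5 * (sum(diag(P)) - sum(Py^2)) * s2[q + 1]
    val <- list(nll = nll, gr = gr, beta = drop(beta), Vinv = Vi, Py = Py)
    cache$key <- key; cache$val <- val
    val
  }
  opt <- optim(theta0, fn = function(th) evaluate(th)$nll,
               gr = function(th) evaluate(th)$gr,
               method = "L-BFGS-B", lower = log(tol), upper = log(1e8 * vy),
               control = list(maxit = maxit, factr = 1e7))
  fin <- evaluate(opt$par)
  list(sigma2 = pmax(exp(opt$par), tol), beta = fin$beta, Vinv = fin$Vinv,
       Py = fin$Py, loglik = -fin$nll, converged = opt$convergence == 0)
}

# Dispatch: eigen path for one kernel, quasi-Newton otherwise.
reml_fit <- function(y, X, Ks, ...) {
  if (length(Ks) == 1L) reml_single(y, X, Ks[[1]])
  else reml_multi(y, X, Ks, ...)
}
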