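# GBLUP: REML variance components, BLUP effects, predictions, Gibbs.

make_instance <- function(n = 12, m = 40, h2 = 0.6, seed = 3) {
  set.seed(seed)
  Z <- matrix(sample(c(-1, 0, 1), n * m, TRUE), n, m,
              dimnames = list(sprintf("L%02d", 1:n), NULL))
  K <- additive_kinship(Z)
  u <- drop(chol(unclass(K) + diag(1e-8, n))) # upper chol
  g <- drop(t(u) %*% rnorm(n))
  g <- g / sd(g) * sqrt(h2)
  y <- setNames(10 + g + rnorm(n, 0, sqrt(1 - h2)), rownames(Z))
  list(y = y, K = K, g = g)
}

test_that("REML matches a direct grid search of the restricted likelihood", {
  inst <- make_instance()
  fit <- fit_gblup(inst$y, inst$K)
  # oracle: dense-algebra restricted likelihood on a refining 2-D grid
  X <- matrix(1, length(inst$y), 1)
  ll <- function(s2a, s2e)
    oracle_restricted_ll(inst$y, X, s2a * unclass(inst$K) +
                           diag(s2e, length(inst$y)))
  ctr <- c(fit$var_a, fit$var_e); width <- 4
  for (pass in 1:6) {
    grid <- expand.grid(a = exp(log(ctr[1]) + seq(-width, width, length.out = 9)),
                        e = exp(log(ctr[2]) + seq(-width, width, length.out = 9)))
    vals <- mapply(ll, grid$a, grid$e)
    ctr <- unlist(grid[which.max(vals), ]); width <- width / 3.5
  }
  expect_equal(log(fit$var_a), log(unname(ctr[1])), tolerance = 1e-3)
  expect_equal(log(fit$var_e), log(unname(ctr[2])), tolerance = 1e-3)
  # and the package's optimum is at least as good as the grid's
  expect_gte(ll(fit$var_a, fit$var_e) + 1e-6, max(vals))
})

test_that("predictions equal the mixed-model-equation oracle", {
  inst <- make_instance(n = 10)
  train <- names(inst$y)[1:7]; target <- names(inst$y)[8:10]
  fit <- fit_gblup(inst$y, inst$K, train_ids = train)
  mme <- oracle_mme_predict(inst$y[train], unclass(inst$K) + diag(1e-9, 10),
                            train, target, fit$var_a, fit$var_e)
  expect_equal(predict(fit, target), mme, tolerance = 1e-6)
})

test_that("prediction contracts and invariances", {
  inst <- make_instance(n = 15)
  # identity kinship: no information flows to unphenotyped lines
  ids <- names(inst$y)
  KI <- diag(15); dimnames(KI) <- list(ids, ids)
  fitI <- fit_gblup(inst$y, KI, train_ids = ids[1:10])
  expect_equal(unname(predict(fitI, ids[11:15])), rep(fitI$mu, 5),
               tolerance = 1e-8)
  # shift invariance: y + c shifts predictions by c
  f1 <- fit_gblup(inst$y, inst$K)
  f2 <- fit_gblup(inst$y + 100, inst$K)
  expect_equal(predict(f2), predict(f1) + 100, tolerance = 1e-5)
  # identical kinship rows give identical predictions
  Z <- matrix(sample(c(-1, 0, 1), 8 * 30, TRUE), 8, 30,
              dimnames = list(paste0("L", 1:8), NULL))
  Z[8, ] <- Z[7, ]
  Kdup <- additive_kinship(Z)
  y <- setNames(rnorm(6, 10), paste0("L", 1:6))
  fdup <- fit_gblup(y, Kdup, train_ids = paste0("L", 1:6))
  expect_equal(unname(predict(fdup, "L7")), unname(predict(fdup, "L8")),
               tolerance = 1e-10)
  expect_error(predict(f1, "nope"), "unknown line")
  expect_error(fit_gblup(inst$y, inst$K, solver = "gibbs"), "seed")
})

test_that("REML and Gibbs posterior means agree on a 50-line instance", {
  # structured kinship (related backcross lines), centred so the genetic
  # variance is identified apart from the intercept
  st <- small_study()
  ids <- names(st$pop_of)[st$pop_of == "pop1"][1:50]
  Ka <- additive_kinship(st$hybrids$Z[ids, ], center = TRUE)
  set.seed(9)
  u <- chol(unclass(Ka) + diag(1e-6, 50))
  g <- drop(t(u) %*% rnorm(50)); g <- g / sd(g)
  y <- setNames(10 + g + rnorm(50, 0, 0.6), ids)
  train <- ids[1:40]
  fr <- fit_gblup(y, Ka, train_ids = train)
  fg <- fit_gblup(y, Ka, train_ids = train, solver = "gibbs",
                  seed = 77, n_iter = 4000, burn_in = 500)
  # posterior-mean predictions track the REML BLUPs
  expect_gt(cor(predict(fr), predict(fg)), 0.95)
  expect_lt(sd(predict(fr) - predict(fg)) / sd(y), 0.15)
  # gibbs is seed-reproducible
  fg2 <- fit_gblup(y, Ka, train_ids = train, solver = "gibbs",
                   seed = 77, n_iter = 4000, burn_in = 500)
  expect_identical(fg$xi_a, fg2$xi_a)
})

test_that("AD model does not beat A when dominance variance is absent", {
  set.seed(41)
  n <- 120; m <- 200
  Z <- matrix(sample(c(-1, -0.5, 0, 0.5, 1), n * m, TRUE), n, m,
              dimnames = list(sprintf("L%03d", 1:n), NULL))
  W <- matrix(sample(c(0, 0.5, 1), n * m, TRUE), n, m, dimnames = dimnames(Z))
  Ka <- additive_kinship(Z); Kd <- dominance_kinship(W)
  g <- drop(Z[, 1:50] %*% rnorm(50, 0, 0.2))
  y <- setNames(g + rnorm(n, 0, sd(g) * 0.7), rownames(Z))
  pa <- function(Kd_arg, model) {
    r <- run_within(y, Ka, Kd = Kd_arg, model = model, n_repeats = 5, seed = 6)
    r$mean["PA"]
  }
  pa_a <- pa(NULL, "A"); pa_ad <- pa(Kd, "AD")
  expect_lt(pa_ad - pa_a, 0.05)   # no systematic AD advantage
})
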