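#' Prediction accuracy
#'
#' Pearson correlation between predicted and observed values.
#'
#' @param predicted,observed numeric vectors of equal length (>= 3
#'   pairs, neither constant)
#' @return correlation coefficient in `[-1, 1]`
#' @export
prediction_accuracy <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("prediction_accuracy: length mismatch")
  if (length(predicted) < 3L) stop("prediction_accuracy: need >= 3 pairs")
  if (sd(predicted) == 0 || sd(observed) == 0)
    stop("prediction_accuracy: constant vector")
  cor(predicted, observed)
}

#' Seeded k-fold partition
#'
#' @param ids character vector of line ids
#' @param k number of folds
#' @param seed integer seed
#' @return integer vector of fold labels (1..k) named by id; fold sizes
#'   differ by at most one
#' @export
make_folds <- function(ids, k, seed) {
  if (length(ids) < k) stop("make_folds: fewer ids than folds")
  set.seed(seed)
  f <- rep(seq_len(k), length.out = length(ids))
  setNames(sample(f), ids)
}

cv_result <- function(pa_matrix, scheme, model) {
  # pa_matrix: repeats x groups (groups = populations or environments)
  structure(list(per_repeat = pa_matrix,
                 mean = colMeans(pa_matrix),
                 sd = apply(pa_matrix, 2, sd),
                 scheme = scheme, model = model),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%s, %s), %d repeats\n", x$scheme, x$model,
              nrow(x$per_repeat)))
  print(round(rbind(mean = x$mean, sd = x$sd), 3))
  invisible(x)
}

#' Within-population cross-validated genomic prediction
#'
#' Repeated 5-fold cross-validation inside one population (or a pooled
#' set of populations): per repeat, lines are partitioned into
#' `k_folds` folds, each fold is predicted from the remaining folds,
#' and the PA of the repeat is the correlation over all held-out lines
#' pooled across folds (a per-fold variant is available).
#'
#' @param y named phenotype vector (BLUEs) for the population
#' @param Ka additive kinship covering the population
#' @param Kd dominance kinship (used when `model = "AD"`)
#' @param model `"A"` (additive) or `"AD"` (additive + dominance)
#' @param k_folds folds per repeat (default 5)
#' @param n_repeats repeats (default 100)
#' @param seed master seed; fold seeds derive from it per repeat
#' @param pool_folds correlate all held-out lines of a repeat together
#'   (default) or average per-fold correlations
#' @return a `cv_result` with one PA column `"PA"`
#' @export
run_within <- function(y, Ka, Kd = NULL, model = c("A", "AD"), k_folds = 5,
                       n_repeats = 100, seed = 1L, pool_folds = TRUE) {
  model <- match.arg(model)
  ids <- intersect(rownames(Ka), names(y))
  if (length(ids) < k_folds) stop("run_within: population smaller than k_folds")
  Kd_use <- if (model == "AD") {
    if (is.null(Kd)) stop("run_within: model AD requires Kd")
    Kd
  }
  pa <- matrix(NA_real_, n_repeats, 1, dimnames = list(NULL, "PA"))
  for (rp in seq_len(n_repeats)) {
    folds <- make_folds(ids, k_folds, sub_seed(seed, rp))
    pred <- setNames(numeric(length(ids)), ids)
    fold_pa <- numeric(k_folds)
    for (f in seq_len(k_folds)) {
      hold <- ids[folds == f]
      fit <- fit_gblup(y[ids], Ka, Kd = Kd_use,
                       train_ids = setdiff(ids, hold))
      pred[hold] <- predict(fit, hold)
      if (!pool_folds) fold_pa[f] <- prediction_accuracy(pred[hold], y[hold])
    }
    pa[rp, 1] <- if (pool_folds) prediction_accuracy(pred, y[ids])
                 else mean(fold_pa)
  }
  cv_result(pa, "within", model)
}

#' One-to-one / three-to-one transfer prediction
#'
#' A single fit on all training-population lines, evaluated on the full
#' validation population (no folds).  With one training population this
#' is the one-to-one scheme; with several, the pooled (e.g.
#' three-to-one) scheme.
#'
#' @param y named phenotype vector covering training and validation lines
#' @param Ka additive kinship over all lines
#' @param train_ids,valid_ids disjoint line id sets
#' @param Kd dominance kinship (for `model = "AD"`)
#' @param model `"A"` or `"AD"`
#' @return list with `pa`, `predictions`, `fit`
#' @export
run_transfer <- function(y, Ka, train_ids, valid_ids, Kd = NULL,
                         model = c("A", "AD")) {
  model <- match.arg(model)
  if (length(intersect(train_ids, valid_ids)))
    stop("run_transfer: training and validation populations overlap")
  Kd_use <- if (model == "AD") {
    if (is.null(Kd)) stop("run_transfer: model AD requires Kd")
    Kd
  }
  fit <- fit_gblup(y, Ka, Kd = Kd_use, train_ids = train_ids)
  pred <- predict(fit, valid_ids)
  list(pa = prediction_accuracy(pred, y[valid_ids]),
       predictions = pred, fit = fit)
}

#' Multi-environment cross-validation (CV1 / CV2)
#'
#' Per repeat, lines are split into `k_folds` folds.  Under CV1 a
#' fold's phenotypes are masked in every environment (fully untested
#' lines); under CV2 they are masked only in the target environment
#' (lines tested elsewhere).  The model (`"SE"`, `"AE"` or `"GxE"`) is
#' fitted on the unmasked cells and the PA is computed per environment
#' over all masked cells of the repeat, pooled across folds.  For CV2
#' each environment is evaluated in turn as the masked one (restrict
#' with `target_envs`).  The SE model uses only the target environment's
#' data, so its CV1 and CV2 variants coincide.
#'
#' @param stacked a [stack_phenotypes()] data.frame
#' @param Ka additive kinship
#' @param model `"SE"`, `"AE"` or `"GxE"`
#' @param scheme `"cv1"` or `"cv2"`
#' @param k_folds folds (default 5)
#' @param n_repeats repeats (default 100)
#' @param seed master seed
#' @param envs_train optional subset of environments to use (e.g. a
#'   pair); default all
#' @param target_envs environments evaluated as validation (default all
#'   in `envs_train`)
#' @return a `cv_result`, one PA column per evaluated environment
#' @export
run_cv_multienv <- function(stacked, Ka, model = c("SE", "AE", "GxE"),
                            scheme = c("cv1", "cv2"), k_folds = 5,
                            n_repeats = 100, seed = 1L,
                            envs_train = NULL, target_envs = NULL) {
  model <- match.arg(model)
  scheme <- match.arg(scheme)
  st <- as.data.frame(stacked)
  envs_train <- envs_train %||% unique(st$env)
  st <- st[st$env %in% envs_train, , drop = FALSE]
  if (scheme == "cv2" && length(envs_train) < 2L)
    stop("run_cv_multienv: CV2 requires >= 2 environments")
  if (model %in% c("AE", "GxE") && length(envs_train) < 2L)
    stop("run_cv_multienv: AE/GxE require >= 2 environments")
  target_envs <- target_envs %||% envs_train
  ids <- unique(st$line)
  pa <- matrix(NA_real_, n_repeats, length(target_envs),
               dimnames = list(NULL, target_envs))
  key <- function(l, e) paste(l, e, sep = "\r")
  obs_y <- setNames(st$y, key(st$line, st$env))
  for (rp in seq_len(n_repeats)) {
    folds <- make_folds(ids, k_folds, sub_seed(seed, rp))
    pred <- setNames(rep(NA_real_, nrow(st)), key(st$line, st$env))
    for (f in seq_len(k_folds)) {
      hold <- ids[folds == f]
      if (model == "SE") {
        # SE trains within one environment; CV1/CV2 coincide
        for (ev in target_envs) {
          obs_ev <- st[st$env == ev, ]
          hold_ev <- intersect(hold, obs_ev$line)
          if (!length(hold_ev)) next
          yv <- setNames(obs_ev$y, obs_ev$line)
          fit <- fit_gblup(yv, Ka, train_ids = setdiff(names(yv), hold))
          pred[key(hold_ev, ev)] <- predict(fit, hold_ev)
        }
      } else if (scheme == "cv1") {
        mask <- st[st$line %in% hold, c("line", "env")]
        fit <- fit_multienv(st, Ka, model = model, masked_cells = mask)
        pr <- fit$predictions
        pred[key(pr$line, pr$env)] <- pr$y_pred
      } else {
        for (ev in target_envs) {
          hold_ev <- intersect(hold, st$line[st$env == ev])
          if (!length(hold_ev)) next
          mask <- data.frame(line = hold_ev, env = ev)
          fit <- fit_multienv(st, Ka, model = model, masked_cells = mask)
          pr <- fit$predictions
          pred[key(pr$line, pr$env)] <- pr$y_pred
        }
      }
    }
    for (ev in target_envs) {
      sel <- st$env == ev & !is.na(pred[key(st$line, st$env)])
      kk <- key(st$line[sel], ev)
      pa[rp, ev] <- prediction_accuracy(pred[kk], obs_y[kk])
    }
  }
  cv_result(pa, scheme, model)
}

#' Tidy per-repeat results of a `cv_result`
#' @param x a `cv_result`
#' @return data.frame (scheme, model, group, repeat, PA)
#' @export
as_tidy_cv <- function(x) {
  m <- x$per_repeat
  data.frame(scheme = x$scheme, model = x$model,
             group = rep(colnames(m), each = nrow(m)),
             rep = rep(seq_len(nrow(m)), times = ncol(m)),
             PA = as.vector(m), stringsAsFactors = FALSE)
}
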