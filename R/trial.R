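#' Per-line BLUEs from a multi-environment trial
#'
#' Fits the trial model
#' `y_ijk = mu + g_i + e_j + ge_ij + rep_(j)k (+ block) + eps_ijk` with
#' genotype fixed and all other terms random (REML via \pkg{lme4}), and
#' returns the fixed-effect estimate `mu + g_i` per line.
#'
#' Scope `"across_env"` uses environment, G-by-E and
#' replicate-within-environment random terms (plus
#' block-within-replicate when more than one block label is present);
#' `"per_env"` fits each environment separately with a random replicate
#' term, falling back to raw line means (with a warning) when the data
#' are unreplicated or the fit fails.
#'
#' @param records `trial_records` data.frame (line, env, rep, block, yield)
#' @param scope `"across_env"` (default) or `"per_env"`
#' @return `"across_env"`: data.frame (line, blue);
#'   `"per_env"`: data.frame (line, env, blue)
#' @export
fit_blue <- function(records, scope = c("across_env", "per_env")) {
  scope <- match.arg(scope)
  rec <- as.data.frame(records)
  if (!all(is.finite(rec$yield))) stop("fit_blue: non-finite yields")
  rec$line <- factor(rec$line)
  rec$env <- factor(rec$env)
  rec$rep <- factor(rec$rep)
  rec$block <- factor(rec$block %||% 1L)
  if (scope == "across_env") {
    form <- yield ~ 0 + line + (1 | env) + (1 | env:rep) + (1 | line:env)
    if (nlevels(rec$block) > 1L)
      form <- update(form, . ~ . + (1 | env:rep:block))
    fit <- suppressMessages(lme4::lmer(form, data = rec,
                                       control = lme4::lmerControl(
                                         check.conv.singular = "ignore")))
    b <- lme4::fixef(fit)
    data.frame(line = sub("^line", "", names(b)), blue = unname(b),
               stringsAsFactors = FALSE)
  } else {
    out <- lapply(levels(rec$env), function(ev) {
      d <- rec[rec$env == ev, , drop = FALSE]
      d$line <- droplevels(d$line)
      blue <- if (nlevels(d$rep) < 2L) {
        warning("fit_blue: environment '", ev,
                "' unreplicated; using raw means")
        tapply(d$yield, d$line, mean)
      } else {
        fit <- tryCatch(
          suppressMessages(lme4::lmer(yield ~ 0 + line + (1 | rep), data = d,
                                      control = lme4::lmerControl(
                                        check.conv.singular = "ignore"))),
          error = function(e) NULL)
        if (is.null(fit)) {
          warning("fit_blue: mixed model failed in '", ev,
                  "'; using raw means")
          tapply(d$yield, d$line, mean)
        } else {
          b <- lme4::fixef(fit)
          setNames(unname(b), sub("^line", "", names(b)))
        }
      }
      data.frame(line = names(blue), env = ev, blue = unname(blue),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
}

#' Balanced ANOVA of a multi-environment trial
#'
#' Classical two-factor (genotype x environment) decomposition with
#' replicates nested in environments, for balanced data (every line in
#' every environment x replicate exactly once).  Sources:
#' replicate-within-environment, genotype, environment, G-by-E, error;
#' F tests are against the error mean square.  Variance components are
#' then extracted (see [anova_from_ms()] for the convention).
#'
#' @param records `trial_records` data.frame
#' @param convention component-extraction convention, see
#'   [anova_from_ms()]
#' @return an `anova_result`
#' @export
anova_ms <- function(records, convention = c("error_ms", "classical")) {
  convention <- match.arg(convention)
  rec <- as.data.frame(records)
  rec$line <- factor(rec$line); rec$env <- factor(rec$env)
  rec$rep <- factor(rec$rep)
  n <- nlevels(rec$line); e <- nlevels(rec$env); r <- nlevels(rec$rep)
  cnt <- table(rec$line, rec$env, rec$rep)
  if (any(cnt != 1L))
    stop("anova_ms: unbalanced data (each line must appear once per ",
         "environment x replicate); use fit_blue for unbalanced trials")
  y <- rec$yield
  gm <- mean(y)
  mi <- tapply(y, rec$line, mean)
  mj <- tapply(y, rec$env, mean)
  mij <- tapply(y, list(rec$line, rec$env), mean)
  mjk <- tapply(y, list(rec$env, rec$rep), mean)
  ss_g <- e * r * sum((mi - gm)^2)
  ss_e <- n * r * sum((mj - gm)^2)
  ss_ge <- r * sum((mij - outer(mi - gm, mj, `+`))^2)
  ss_rep <- n * sum(sweep(mjk, 1, mj)^2)   # rep-within-env deviations
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_g - ss_e - ss_ge - ss_rep
  df <- c(rep_env = e * (r - 1), genotype = n - 1, environment = e - 1,
          gxe = (n - 1) * (e - 1), error = e * (r - 1) * (n - 1))
  ss <- c(ss_rep, ss_g, ss_e, ss_ge, ss_err)
  ms <- ss / df
  f <- c(ms[1:4] / ms[5], NA)
  p <- c(pf(f[1:4], df[1:4], df[5], lower.tail = FALSE), NA)
  tab <- data.frame(source = c("Rep/Env", "Genotype", "Environment",
                               "G by E", "Error"),
                    DF = as.integer(df), SS = ss, MS = ms, F = f, p = p,
                    row.names = NULL)
  res <- anova_from_ms(ms_genotype = ms[2], ms_gxe = ms[4], ms_error = ms[5],
                       e = e, r = r, convention = convention)
  res$table <- tab
  res$r_squared <- 1 - ss_err / ss_tot     # fit of the full fixed model
  res
}

#' Variance components from ANOVA mean squares
#'
#' Extracts genotype, G-by-E and error variance components from the
#' mean squares of a balanced multi-environment trial.  Two conventions
#' are offered:
#' \describe{
#'   \item{`"error_ms"` (default)}{`sigma_g^2 = (MS_G - MS_err)/(e r)`,
#'     `sigma_ge^2 = (MS_GxE - MS_err)/r`, `sigma_e^2 = MS_err`.  This is
#'     the convention used by common QTL-mapping trial-analysis software
#'     and is the package default.}
#'   \item{`"classical"`}{the expected-mean-squares rule
#'     `sigma_g^2 = (MS_G - MS_GxE)/(e r)`, with `sigma_ge^2` and
#'     `sigma_e^2` as above.}
#' }
#' Negative estimates are truncated at zero.
#'
#' @param ms_genotype,ms_gxe,ms_error mean squares
#' @param e,r number of environments and replicates
#' @param convention `"error_ms"` or `"classical"`
#' @return an `anova_result`: list with `components`
#'   (`sigma_g2`, `sigma_ge2`, `sigma_e2`), `e`, `r`, `convention`, and
#'   (when produced by [anova_ms()]) the full `table`
#' @export
anova_from_ms <- function(ms_genotype, ms_gxe, ms_error, e, r,
                          convention = c("error_ms", "classical")) {
  convention <- match.arg(convention)
  if (any(c(ms_genotype, ms_gxe, ms_error) < 0)) stop("mean squares must be >= 0")
  sig_e2 <- ms_error
  sig_ge2 <- max(0, (ms_gxe - ms_error) / r)
  sig_g2 <- if (convention == "error_ms")
    max(0, (ms_genotype - ms_error) / (e * r))
  else
    max(0, (ms_genotype - ms_gxe) / (e * r))
  structure(list(components = c(sigma_g2 = unname(sig_g2),
                                sigma_ge2 = unname(sig_ge2),
                                sigma_e2 = unname(sig_e2)),
                 e = e, r = r, convention = convention, table = NULL),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  if (!is.null(x$table)) {
    tab <- x$table
    tab$SS <- round(tab$SS, 2); tab$MS <- round(tab$MS, 2)
    tab$F <- round(tab$F, 2); tab$p <- round(tab$p, 2)
    print(tab)
  }
  cat(sprintf("components (%s): sigma_g2 = %.2f, sigma_ge2 = %.2f, sigma_e2 = %.2f\n",
              x$convention, x$components["sigma_g2"],
              x$components["sigma_ge2"], x$components["sigma_e2"]))
  invisible(x)
}

#' Entry-mean broad-sense heritability
#'
#' `H^2 = sigma_g^2 / (sigma_g^2 + sigma_ge^2 / e + sigma_e^2 / (e r))`,
#' the fraction of entry-mean variance that is genetic in a trial with
#' `e` environments and `r` replicates.
#'
#' @param a an `anova_result` from [anova_ms()] or [anova_from_ms()]
#' @return H^2 in `[0, 1]` (unrounded; round to 2 decimals for
#'   reporting)
#' @export
heritability <- function(a) {
  cmp <- a$components
  denom <- cmp["sigma_g2"] + cmp["sigma_ge2"] / a$e +
    cmp["sigma_e2"] / (a$e * a$r)
  if (denom <= 0) stop("heritability: all variance components are zero")
  unname(cmp["sigma_g2"] / denom)
}
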