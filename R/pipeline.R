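#' Run the end-to-end study pipeline from a config
#'
#' Executes the requested stages in dependency order —
#' `simulate -> qc -> structure -> trial -> kinship -> evaluate` —
#' writing every intermediate to `out_dir` in plain-text formats and
#' returning a manifest of outputs with checksums.  Stages read their
#' inputs from the outputs of earlier stages on disk, so a stage whose
#' upstream artifact is missing fails with an error naming the stage to
#' run first.
#'
#' The config is a YAML (or JSON) file, or an equivalent named list,
#' with keys: `version` (must be 1), `out_dir`, `seed`, `stages`
#' (subset of the five stage names), and optional per-stage parameter
#' blocks `simulate`, `qc`, `evaluate`.  Unknown top-level keys are
#' rejected.
#'
#' @param config path to a YAML/JSON config file, or a named list
#' @return a `run_manifest`: list with `config_hash`, `seed`,
#'   `stages` (per-stage output paths and md5 checksums), `version`
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config,
                                                                 simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  known <- c("version", "out_dir", "seed", "stages", "simulate", "qc",
             "evaluate")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("run_pipeline: unknown config key(s): ", paste(extra, collapse = ", "))
  if (!identical(as.integer(config$version %||% 1L), 1L))
    stop("run_pipeline: unsupported config version")
  out <- config$out_dir %||% stop("run_pipeline: out_dir required")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  all_stages <- c("simulate", "qc", "structure", "trial", "kinship", "evaluate")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("run_pipeline: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  stages <- all_stages[all_stages %in% stages]   # dependency order
  need <- function(path, stage) {
    if (!file.exists(path))
      stop("run_pipeline: missing artifact '", basename(path),
           "'; run stage '", stage, "' first")
    path
  }
  manifest <- list()
  log_stage <- function(name, files) {
    manifest[[name]] <<- list(outputs = files,
                              md5 = unname(tools::md5sum(files)))
    message(sprintf("[%s] %s: %d output(s)", format(Sys.time(), "%H:%M:%S"),
                    name, length(files)))
  }
  p <- function(...) file.path(out, ...)

  if ("simulate" %in% stages) {
    sp <- config$simulate %||% list()
    cfg <- sim_config(
      genome = genome_map(n_markers = sp$n_markers %||% 500),
      pop_sizes = unlist(sp$pop_sizes %||%
                           c(bc1f3 = 60, dh = 30, f45 = 30, unrelated = 30)),
      n_qtl = sp$n_qtl %||% 50,
      var_g = sp$var_g %||% 1600, var_ge = sp$var_ge %||% 600,
      var_rep = sp$var_rep %||% 50, var_error = sp$var_error %||% 3500,
      seed = seed)
    study <- simulate_study(cfg)
    write_geno_tsv(study$founders, p("founders.tsv"))
    all_lines <- geno_matrix(do.call(rbind, lapply(study$populations,
                                                   function(x) x$calls)),
                             study$founders$map)
    write_geno_tsv(all_lines, p("lines.tsv"))
    write.table(data.frame(line = names(study$pop_of),
                           population = as.character(study$pop_of)),
                p("populations.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_trial_csv(study$records, p("phenotypes.csv"))
    log_stage("simulate", c(p("founders.tsv"), p("lines.tsv"),
                            p("populations.tsv"), p("phenotypes.csv")))
  }

  if ("qc" %in% stages) {
    qp <- config$qc %||% list()
    lines <- read_geno_tsv(need(p("lines.tsv"), "simulate"))
    founders <- read_geno_tsv(need(p("founders.tsv"), "simulate"))
    filt <- filter_snps(lines,
                        call_rate_min = qp$call_rate_min %||% 0.97,
                        missing_rate_max = qp$missing_rate_max %||% 0.01,
                        maf_min = qp$maf_min %||% 0.05)
    filt <- impute_missing(filt, seed = sub_seed(seed, 101))
    coded <- code_alleles(filt)
    tester_full <- founders$calls["tester", ]
    tester <- tester_full[coded$map$marker]
    # orient tester dosages to the per-marker minor allele
    flip <- coded$map$a1 != founders$map$a1[match(coded$map$marker,
                                                  founders$map$marker)]
    tester[flip] <- 2L - tester[flip]
    hyb <- infer_hybrid_genotypes(coded, tester)
    write_hybrid_tsv(hyb, out)
    rem <- attr(filt, "removed")
    write.table(data.frame(rule = names(rem), removed = as.integer(rem)),
                p("qc_report.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("qc", c(p("Z.tsv"), p("W.tsv"), p("qc_report.tsv")))
  }

  if ("structure" %in% stages) {
    hyb <- read_hybrid_tsv(dirname(need(p("Z.tsv"), "qc")))
    pc <- pca_genotypes(hyb$Z)
    write.table(data.frame(line = rownames(pc$scores), pc$scores),
                p("pc_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(component = seq_along(pc$variance_explained),
                           variance_explained = pc$variance_explained),
                p("pc_variance.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write_kinship_tsv(similarity_matrix(hyb$Z), p("similarity.tsv"))
    log_stage("structure", c(p("pc_scores.tsv"), p("pc_variance.tsv"),
                             p("similarity.tsv")))
  }

  if ("trial" %in% stages) {
    rec <- read_trial_csv(need(p("phenotypes.csv"), "simulate"))
    blues <- fit_blue(rec, "across_env")
    write.table(blues, p("blues.csv"), sep = ",", quote = FALSE,
                row.names = FALSE)
    blues_env <- fit_blue(rec, "per_env")
    write.table(blues_env, p("blues_per_env.csv"), sep = ",", quote = FALSE,
                row.names = FALSE)
    an <- anova_ms(rec)
    write.table(an$table, p("anova.csv"), sep = ",", quote = FALSE,
                row.names = FALSE)
    writeLines(sprintf("H2,%.4f", heritability(an)), p("heritability.csv"))
    log_stage("trial", c(p("blues.csv"), p("blues_per_env.csv"),
                         p("anova.csv"), p("heritability.csv")))
  }

  if ("kinship" %in% stages) {
    hyb <- read_hybrid_tsv(dirname(need(p("Z.tsv"), "qc")))
    write_kinship_tsv(additive_kinship(hyb$Z), p("Ka.tsv"))
    kd_ok <- !inherits(try(dominance_kinship(hyb$W), silent = TRUE), "try-error")
    files <- p("Ka.tsv")
    if (kd_ok) {
      write_kinship_tsv(dominance_kinship(hyb$W), p("Kd.tsv"))
      files <- c(files, p("Kd.tsv"))
    }
    log_stage("kinship", files)
  }

  if ("evaluate" %in% stages) {
    ep <- config$evaluate %||% list()
    blues <- read.table(need(p("blues.csv"), "trial"), sep = ",", header = TRUE,
                        stringsAsFactors = FALSE)
    Ka <- read_kinship_tsv(need(p("Ka.tsv"), "kinship"))
    res <- run_within(setNames(blues$blue, blues$line), Ka,
                      model = ep$model %||% "A",
                      k_folds = ep$k_folds %||% 5,
                      n_repeats = ep$n_repeats %||% 5,
                      seed = sub_seed(seed, 201))
    write.table(as_tidy_cv(res), p("cv_results.csv"), sep = ",", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(group = names(res$mean), mean_PA = res$mean,
                           sd_PA = res$sd),
                p("cv_summary.csv"), sep = ",", quote = FALSE, row.names = FALSE)
    log_stage("evaluate", c(p("cv_results.csv"), p("cv_summary.csv")))
  }

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE)
  man <- structure(list(
    config_hash = unname(tools::md5sum(
      local({ f <- p("config.echo.json"); writeLines(cfg_json, f); f }))),
    seed = seed,
    version = as.character(packageVersion("hybridgp")),
    stages = manifest,
    absent = setdiff(all_stages, stages)), class = "run_manifest")
  writeLines(jsonlite::toJSON(unclass(man), auto_unbox = TRUE, pretty = TRUE),
             p("manifest.json"))
  man
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest (hybridgp", x$version, ")\n")
  cat("  stages run:", paste(names(x$stages), collapse = ", "), "\n")
  if (length(x$absent)) cat("  absent:", paste(x$absent, collapse = ", "), "\n")
  invisible(x)
}
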