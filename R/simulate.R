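#' Genetic map for the simulator
#'
#' Maize-style default: 10 chromosomes of 160 cM each with markers
#' evenly spaced.
#'
#' @param n_chromosomes number of chromosomes
#' @param chr_length_cM chromosome length(s) in centimorgan (recycled)
#' @param n_markers total marker count, split as evenly as possible
#'   across chromosomes
#' @return a `genome_map`: data.frame with columns `marker`, `chrom`,
#'   `pos` (cM, strictly increasing within chromosome)
#' @export
genome_map <- function(n_chromosomes = 10, chr_length_cM = 160, n_markers = 1000) {
  if (n_markers < n_chromosomes) stop("need at least one marker per chromosome")
  len <- rep_len(chr_length_cM, n_chromosomes)
  per <- rep(n_markers %/% n_chromosomes, n_chromosomes)
  extra <- n_markers %% n_chromosomes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  maps <- lapply(seq_len(n_chromosomes), function(c) {
    pos <- seq(0, len[c], length.out = per[c] + 1L)[-1L]  # avoid pos 0 ties
    data.frame(chrom = c, pos = pos)
  })
  map <- do.call(rbind, maps)
  map <- data.frame(marker = sprintf("m%05d", seq_len(nrow(map))), map,
                    stringsAsFactors = FALSE)
  class(map) <- c("genome_map", "data.frame")
  map
}

#' Simulation configuration
#'
#' Collects the stated world of the synthetic study: genome, population
#' sizes, trial design and variance components of the phenotype model
#' `y_ijk = mu + g_i + e_j + ge_ij + rep_(j)k + eps_ijk`.
#'
#' Default variance components (`var_g` 1600, `var_ge` 600, `var_rep` 50,
#' `var_error` 3500, kg^2 on a per-mu yield scale around `mu` = 750 kg)
#' give an entry-mean heritability of about 0.67 with 3 environments and
#' 2 replicates, inside the 0.58-0.74 band typical of multi-environment
#' maize yield trials.
#'
#' @param genome a [genome_map()]
#' @param pop_sizes named counts for the four population types
#' @param n_environments,n_replicates trial design
#' @param n_qtl number of causal markers sampled from the map
#' @param additive_effect_sd,dominance_effect_sd QTL effect scales
#'   (dominance off by default)
#' @param mu overall mean yield (kg per mu)
#' @param env_means per-environment offsets (kg); length
#'   `n_environments`
#' @param var_g,var_ge,var_rep,var_error variance components (kg^2);
#'   `var_error` may be a vector of length `n_environments` for
#'   heterogeneous residual variances (hence per-environment
#'   heritabilities)
#' @param maf_range founder minor-allele-frequency range
#' @param seed master seed; all operation-level seeds derive from it
#' @return a `sim_config` list
#' @export
sim_config <- function(genome = genome_map(),
                       pop_sizes = c(bc1f3 = 475, dh = 72, f45 = 60, unrelated = 68),
                       n_environments = 3, n_replicates = 2,
                       n_qtl = 100,
                       additive_effect_sd = 1, dominance_effect_sd = 0,
                       mu = 750,
                       env_means = c(0, 80, -60),
                       var_g = 1600, var_ge = 600, var_rep = 50, var_error = 3500,
                       maf_range = c(0.05, 0.5),
                       seed = 1L) {
  stopifnot(n_environments >= 1, n_replicates >= 1)
  if (any(c(var_g, var_ge, var_rep, var_error) < 0))
    stop("variance components must be non-negative")
  if (n_qtl > nrow(genome)) stop("n_qtl exceeds marker count")
  if (length(env_means) != n_environments)
    env_means <- rep_len(env_means, n_environments)
  structure(list(genome = genome, pop_sizes = pop_sizes,
                 n_environments = n_environments, n_replicates = n_replicates,
                 n_qtl = n_qtl,
                 additive_effect_sd = additive_effect_sd,
                 dominance_effect_sd = dominance_effect_sd,
                 mu = mu, env_means = env_means,
                 var_g = var_g, var_ge = var_ge, var_rep = var_rep,
                 var_error = var_error,
                 maf_range = maf_range, seed = as.integer(seed)),
            class = "sim_config")
}

#' Pedigree specification for one population
#'
#' @param population_type one of `"bc1f3"`, `"dh"`, `"f45"`,
#'   `"unrelated"` (all understood as testcross populations)
#' @param n_lines number of lines to derive
#' @param parents named character vector of founder ids; `donor` and
#'   `recurrent` for backcross-derived types (`bc1f3`, `dh`), `p1`/`p2`
#'   for `f45`; ignored for `unrelated`
#' @param tester tester founder id (must be fully homozygous)
#' @return a `pedigree_spec` list
#' @export
pedigree_spec <- function(population_type, n_lines, parents = character(), tester) {
  types <- c("bc1f3", "dh", "f45", "unrelated")
  if (!population_type %in% types)
    stop("unknown population_type '", population_type, "'; use one of: ",
         paste(types, collapse = ", "))
  if (n_lines < 1) stop("n_lines must be >= 1")
  structure(list(population_type = population_type, n_lines = as.integer(n_lines),
                 parents = parents, tester = tester),
            class = "pedigree_spec")
}

#' Simulate fully homozygous founder inbreds
#'
#' Per-marker allele frequencies are drawn uniformly from
#' `config$maf_range` and each founder carries the minor-frequency
#' allele with that probability, homozygous at every locus.
#'
#' @param config a [sim_config()]
#' @param n_founders number of founders
#' @param founder_ids optional ids (default `fnd001`, ...)
#' @param seed seed (defaults to a sub-seed of `config$seed`)
#' @return a [geno_matrix()] of homozygous founders; per-marker sampling
#'   frequencies are stored in the map column `sim_freq`
#' @export
simulate_founders <- function(config, n_founders = 72, founder_ids = NULL,
                              seed = sub_seed(config$seed, 1)) {
  map <- config$genome
  if (nrow(map) == 0L) stop("simulate_founders: zero markers in genome map")
  set.seed(seed)
  m <- nrow(map)
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  allele <- matrix(rbinom(n_founders * m, 1L, rep(p, each = n_founders)),
                   nrow = n_founders)
  calls <- 2L * allele
  rownames(calls) <- founder_ids %||% sprintf("fnd%03d", seq_len(n_founders))
  colnames(calls) <- map$marker
  map2 <- data.frame(map, a1 = "A", a2 = "B", sim_freq = p,
                     stringsAsFactors = FALSE)
  geno_matrix(calls, map2)
}

# ---- meiosis -------------------------------------------------------------

# Sample one gamete per individual from paired haplotype matrices
# (n x m, entries 0/1) under the Haldane no-interference model:
# recombination fraction between adjacent markers r = (1 - exp(-2d))/2
# with d the map distance in Morgans; the chromosome start picks either
# parental haplotype with probability 1/2.
sample_gametes <- function(hapA, hapB, map) {
  n <- nrow(hapA); m <- ncol(hapA)
  pick <- matrix(0L, n, m)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    d <- diff(map$pos[idx]) / 100
    r <- 0.5 * (1 - exp(-2 * d))
    k <- length(idx)
    sw <- matrix(0L, n, k)
    sw[, 1] <- rbinom(n, 1L, 0.5)
    if (k > 1)
      sw[, -1] <- matrix(rbinom(n * (k - 1), 1L, rep(r, each = n)), n)
    pick[, idx] <- t(apply(sw, 1, cumsum)) %% 2L
  }
  ifelse(pick == 1L, hapB, hapA)
}

hap_pair <- function(h1, h2) list(h1 = h1, h2 = h2)

# replicate a single genotype's haplotypes n times
rep_hap <- function(hap_vec, n) matrix(rep(hap_vec, each = n), nrow = n)

#' Derive a population from founders by explicit meiosis
#'
#' Population types:
#' \describe{
#'   \item{bc1f3}{donor x recurrent F1, backcrossed once to the
#'     recurrent parent, BC1F1 plants intercrossed at random (a stand-in
#'     for bulked-pollen pollination), then one generation of selfing.}
#'   \item{dh}{doubled haploid from a gamete of a BC1F2 plant.}
#'   \item{f45}{biparental F1 selfed to the F4 generation; the line is
#'     the F4 plant genotype (families are represented by their F4
#'     parent, ignoring residual within-family segregation).}
#'   \item{unrelated}{independent homozygous draws at the founder allele
#'     frequencies.}
#' }
#' Crossovers follow a no-interference (Haldane) model on the cM map.
#'
#' @param spec a [pedigree_spec()]
#' @param founders founder [geno_matrix()] (fully homozygous)
#' @param genome a [genome_map()] (defaults to the founder map)
#' @param seed integer seed
#' @return a [geno_matrix()] of derived lines (may be heterozygous)
#' @export
derive_population <- function(spec, founders, genome = NULL, seed = 1L) {
  map <- genome %||% founders$map
  set.seed(seed)
  n <- spec$n_lines
  get_hap <- function(id) {
    if (!id %in% rownames(founders$calls))
      stop("founder '", id, "' not found")
    cal <- founders$calls[id, ]
    if (any(cal == 1L, na.rm = TRUE)) stop("founder '", id, "' is not homozygous")
    as.integer(cal / 2L)
  }
  finish <- function(h, prefix) {
    calls <- h$h1 + h$h2
    rownames(calls) <- sprintf("%s%04d", prefix, seq_len(nrow(calls)))
    colnames(calls) <- map$marker
    geno_matrix(calls, founders$map)
  }
  bc1f2 <- function() {
    don <- get_hap(spec$parents[["donor"]])
    rec <- get_hap(spec$parents[["recurrent"]])
    f1 <- hap_pair(rep_hap(don, n), rep_hap(rec, n))
    bc1f1 <- hap_pair(sample_gametes(f1$h1, f1$h2, map), rep_hap(rec, n))
    # random intercross of BC1F1 plants (bulk-pollen approximation)
    mate <- sample.int(n, n, replace = TRUE)
    pollen <- sample_gametes(bc1f1$h1[mate, , drop = FALSE],
                             bc1f1$h2[mate, , drop = FALSE], map)
    egg <- sample_gametes(bc1f1$h1, bc1f1$h2, map)
    hap_pair(egg, pollen)
  }
  self_once <- function(h)
    hap_pair(sample_gametes(h$h1, h$h2, map), sample_gametes(h$h1, h$h2, map))
  switch(spec$population_type,
    bc1f3 = finish(self_once(bc1f2()), "bc"),
    dh = {
      b <- bc1f2()
      g <- sample_gametes(b$h1, b$h2, map)
      finish(hap_pair(g, g), "dh")
    },
    f45 = {
      p1 <- get_hap(spec$parents[["p1"]])
      p2 <- get_hap(spec$parents[["p2"]])
      h <- hap_pair(rep_hap(p1, n), rep_hap(p2, n))
      for (i in 1:3) h <- self_once(h)     # F1 -> F2 -> F3 -> F4
      finish(h, "f4")
    },
    unrelated = {
      p <- founders$map$sim_freq %||% (colMeans(founders$calls) / 2)
      al <- matrix(rbinom(n * length(p), 1L, rep(p, each = n)), nrow = n)
      finish(hap_pair(al, al), "ur")
    },
    stop("unknown population_type"))
}

#' Testcross a population to a common tester
#'
#' Returns the expected additive/dominance genotype codes of the
#' testcross hybrids (delegates to [infer_hybrid_genotypes()]).
#'
#' @param lines a [geno_matrix()] of candidate lines
#' @param tester a single-line [geno_matrix()], a named line in
#'   `lines`, or a dosage vector; must be homozygous at every locus
#' @param seed unused for the expected-code representation; kept for
#'   interface stability
#' @return a [hybrid_set()] of additive (Z) and dominance (W) codes
#' @export
testcross <- function(lines, tester, seed = NULL) {
  infer_hybrid_genotypes(lines, tester)
}

#' Simulate multi-environment plot-level phenotypes
#'
#' The generative model mirrors the trial model
#' `y_ijk = mu + g_i + e_j + ge_ij + rep_(j)k + eps_ijk`.  Genetic
#' values are built from `n_qtl` markers sampled from the hybrid code
#' matrices (additive codes times Normal effects, plus dominance when
#' `dominance_effect_sd > 0`), then centred and rescaled so their sample
#' variance equals `var_g` exactly; G-by-E, replicate-within-environment
#' and residual deviations are iid Normal with the configured variances.
#'
#' @param hybrids a [hybrid_set()]
#' @param config a [sim_config()]
#' @param seed seed (defaults to a sub-seed of `config$seed`)
#' @return `trial_records` data.frame (line, env, rep, block, yield)
#'   with the true genetic values in `attr(, "genetic_values")` and the
#'   QTL in `attr(, "qtl")`
#' @export
simulate_phenotypes <- function(hybrids, config,
                                seed = sub_seed(config$seed, 4)) {
  if (any(c(config$var_g, config$var_ge, config$var_rep, config$var_error) < 0))
    stop("variance components must be non-negative")
  set.seed(seed)
  Z <- hybrids$Z; W <- hybrids$W
  n <- nrow(Z); e <- config$n_environments; r <- config$n_replicates
  qtl <- sort(sample.int(ncol(Z), config$n_qtl))
  a_eff <- rnorm(config$n_qtl, 0, config$additive_effect_sd)
  g <- drop(Z[, qtl, drop = FALSE] %*% a_eff)
  if (config$dominance_effect_sd > 0) {
    d_eff <- rnorm(config$n_qtl, 0, config$dominance_effect_sd)
    g <- g + drop(W[, qtl, drop = FALSE] %*% d_eff)
  }
  g <- g - mean(g)
  sdg <- sd(g)
  g <- if (sdg > 0) g * sqrt(config$var_g) / sdg else g
  names(g) <- rownames(Z)
  envs <- sprintf("env%d", seq_len(e))
  ge <- matrix(rnorm(n * e, 0, sqrt(config$var_ge)), n, e,
               dimnames = list(rownames(Z), envs))
  repf <- matrix(rnorm(e * r, 0, sqrt(config$var_rep)), e, r)
  rec <- expand.grid(line = rownames(Z), env = envs, rep = seq_len(r),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(rec$line, rownames(Z)); j <- match(rec$env, envs)
  rec$block <- 1L
  verr <- rep_len(config$var_error, e)
  rec$yield <- config$mu + g[i] + config$env_means[j] + ge[cbind(i, j)] +
    repf[cbind(j, rec$rep)] + rnorm(nrow(rec), 0, sqrt(verr[j]))
  rec <- rec[order(i, j, rec$rep), ]
  rownames(rec) <- NULL
  class(rec) <- c("trial_records", "data.frame")
  attr(rec, "genetic_values") <- g
  attr(rec, "qtl") <- colnames(Z)[qtl]
  rec
}

#' Simulate the complete four-population testcross study
#'
#' Builds founders (a donor, a recurrent parent, a second biparental
#' parent, a homozygous tester), derives the four populations
#' (backcross BC1F3, doubled haploids from the same backcross, an F4:5
#' biparental family set sharing the donor parent, and unrelated
#' homozygous materials), testcrosses all lines to the tester, and
#' simulates the multi-environment trial.
#'
#' @param config a [sim_config()]
#' @return list with elements `founders`, `populations` (named list of
#'   [geno_matrix()]), `pop_of` (named factor line -> population),
#'   `hybrids` ([hybrid_set()] over all lines), `records`
#'   (`trial_records`), and `config`
#' @export
simulate_study <- function(config = sim_config()) {
  founders <- simulate_founders(config, n_founders = 4,
                                founder_ids = c("donor", "recurrent", "p2", "tester"),
                                seed = sub_seed(config$seed, 1))
  ps <- config$pop_sizes
  specs <- list(
    pop1 = pedigree_spec("bc1f3", ps[["bc1f3"]],
                         c(donor = "donor", recurrent = "recurrent"), "tester"),
    pop2 = pedigree_spec("dh", ps[["dh"]],
                         c(donor = "donor", recurrent = "recurrent"), "tester"),
    pop3 = pedigree_spec("f45", ps[["f45"]],
                         c(p1 = "donor", p2 = "p2"), "tester"),
    pop4 = pedigree_spec("unrelated", ps[["unrelated"]], character(), "tester"))
  pops <- lapply(seq_along(specs), function(i)
    derive_population(specs[[i]], founders, seed = sub_seed(config$seed, 10 + i)))
  names(pops) <- names(specs)
  # unique line ids across populations
  for (nm in names(pops)) {
    rownames(pops[[nm]]$calls) <- paste0(nm, "_", rownames(pops[[nm]]$calls))
  }
  all_calls <- do.call(rbind, lapply(pops, function(p) p$calls))
  all_lines <- geno_matrix(all_calls, founders$map)
  pop_of <- factor(rep(names(pops), vapply(pops, function(p) nrow(p$calls),
                                           integer(1))),
                   levels = names(pops))
  names(pop_of) <- rownames(all_calls)
  tester <- founders$calls["tester", ]
  hybrids <- infer_hybrid_genotypes(all_lines, tester)
  records <- simulate_phenotypes(hybrids, config)
  list(founders = founders, populations = pops, pop_of = pop_of,
       hybrids = hybrids, records = records, config = config)
}

#' Write trial records as long-format CSV
#' @param records `trial_records`
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_trial_csv <- function(records, path) {
  write.table(as.data.frame(records), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  rec <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  need <- c("line", "env", "rep", "yield")
  if (!all(need %in% names(rec)))
    stop("trial CSV must have columns: ", paste(need, collapse = ", "))
  if (is.null(rec$block)) rec$block <- 1L
  class(rec) <- c("trial_records", "data.frame")
  rec
}
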