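#' SNP quality control
#'
#' Filters markers in the fixed order: (1) assay call rate below
#' `call_rate_min`, (2) missing position metadata (when
#' `require_position`), (3) missing-call rate above `missing_rate_max`,
#' (4) minor allele frequency (computed after the earlier filters)
#' below `maf_min`.  A marker must pass all rules to be retained.
#'
#' @param raw a [geno_matrix()]
#' @param call_rate_min minimum assay call rate (default 0.97)
#' @param missing_rate_max maximum missing-call fraction (default 0.01)
#' @param maf_min minimum minor allele frequency (default 0.05)
#' @param require_position drop markers lacking chrom/pos metadata
#' @return filtered [geno_matrix()]; per-rule removal counts in
#'   `attr(, "removed")`
#' @export
filter_snps <- function(raw, call_rate_min = 0.97, missing_rate_max = 0.01,
                        maf_min = 0.05, require_position = TRUE) {
  if (ncol(raw$calls) == 0L) stop("filter_snps: empty genotype matrix")
  removed <- c(call_rate = 0L, position = 0L, missing = 0L, maf = 0L)
  g <- raw
  keep <- marker_call_rate(g) >= call_rate_min
  removed["call_rate"] <- sum(!keep)
  g <- subset_markers(g, keep)
  if (require_position) {
    keep <- !(is.na(g$map$chrom) | is.na(g$map$pos))
    removed["position"] <- sum(!keep)
    g <- subset_markers(g, keep)
  }
  if (ncol(g$calls)) {
    keep <- marker_missing_rate(g) <= missing_rate_max
    removed["missing"] <- sum(!keep)
    g <- subset_markers(g, keep)
  }
  if (ncol(g$calls)) {
    keep <- marker_maf(g) >= maf_min & !is.nan(marker_maf(g))
    removed["maf"] <- sum(!keep)
    g <- subset_markers(g, keep)
  }
  if (ncol(g$calls) == 0L)
    stop("filter_snps: no markers survive QC (removed: ",
         paste(names(removed), removed, sep = "=", collapse = ", "), ")")
  attr(g, "removed") <- removed
  g
}

#' Impute residual missing calls
#'
#' A deliberately simple stand-in for haplotype-based imputation,
#' adequate when the post-QC missing rate is at most ~1%:
#' `"major_allele"` fills each missing call with the marker's most
#' frequent observed call; `"freq_sample"` draws from the observed call
#' frequencies.
#'
#' @param g a [geno_matrix()]
#' @param method `"major_allele"` (default) or `"freq_sample"`
#' @param seed seed for `"freq_sample"`
#' @return a [geno_matrix()] with no missing calls
#' @export
impute_missing <- function(g, method = c("major_allele", "freq_sample"),
                           seed = 1L) {
  method <- match.arg(method)
  calls <- g$calls
  miss_cols <- which(colSums(is.na(calls)) > 0L)
  if (!length(miss_cols)) return(g)
  set.seed(seed)
  for (j in miss_cols) {
    obs <- calls[, j][!is.na(calls[, j])]
    if (!length(obs))
      stop("impute_missing: marker '", colnames(calls)[j], "' has no observed calls")
    tab <- table(obs)
    na_i <- which(is.na(calls[, j]))
    calls[na_i, j] <- if (method == "major_allele") {
      as.integer(names(tab)[which.max(tab)])
    } else {
      as.integer(sample(names(tab), length(na_i), replace = TRUE,
                        prob = as.numeric(tab)))
    }
  }
  geno_matrix(calls, g$map)
}

#' Orient markers so that A is the minor allele
#'
#' Re-labels alleles per marker so the minor allele is `A` (code:
#' AA = 1, Aa = 0, aa = -1) and the major allele is `a`.  At an exact
#' frequency tie the lexicographically smaller allele label is
#' designated minor.  Dosages are flipped where the current `a1` allele
#' is the major one.
#'
#' @param g a [geno_matrix()] without missing calls
#' @return a [geno_matrix()] whose `a1` is the minor allele everywhere;
#'   monomorphic markers trigger a warning
#' @export
code_alleles <- function(g) {
  p1 <- colMeans(g$calls, na.rm = TRUE) / 2   # freq of current a1
  if (any(p1 == 0 | p1 == 1))
    warning("code_alleles: ", sum(p1 == 0 | p1 == 1),
            " monomorphic marker(s); MAF filtering should precede coding")
  flip <- p1 > 0.5 | (p1 == 0.5 & g$map$a2 < g$map$a1)
  calls <- g$calls
  calls[, flip] <- 2L - calls[, flip, drop = FALSE]
  map <- g$map
  tmp <- map$a1[flip]; map$a1[flip] <- map$a2[flip]; map$a2[flip] <- tmp
  geno_matrix(calls, map)
}

#' Additive codes of inbred/parent lines
#'
#' @param g a [geno_matrix()] oriented by [code_alleles()]
#' @return numeric matrix lines x markers with AA = 1, Aa = 0, aa = -1
#' @export
additive_codes <- function(g) {
  z <- g$calls - 1
  storage.mode(z) <- "double"
  z
}

#' Hybrid genotype code container
#'
#' @param Z additive codes, lines x markers, entries in `[-1, 1]`
#' @param W dominance codes, lines x markers, entries in `[0, 1]`
#' @return a `hybrid_set`
#' @export
hybrid_set <- function(Z, W) {
  stopifnot(identical(dim(Z), dim(W)))
  if (any(Z < -1 | Z > 1, na.rm = TRUE)) stop("Z codes outside [-1, 1]")
  if (any(W < 0 | W > 1, na.rm = TRUE)) stop("W codes outside [0, 1]")
  structure(list(Z = Z, W = W), class = "hybrid_set")
}

#' @export
print.hybrid_set <- function(x, ...) {
  cat(sprintf("hybrid_set: %d hybrids x %d markers\n", nrow(x$Z), ncol(x$Z)))
  invisible(x)
}

#' Infer hybrid additive/dominance codes from parent lines and a tester
#'
#' The hybrid additive code at a locus is the mean of the two parental
#' additive codes (AA = 1, Aa = 0, aa = -1), e.g. Aa x AA -> (0 + 1)/2 =
#' 0.5 and Aa x aa -> (0 - 1)/2 = -0.5.  The dominance code is the
#' expected heterozygosity of the hybrid: 1 for AA x aa, 0.5 for a
#' segregating line crossed to either homozygote, 0 when both parents
#' are homozygous for the same allele.
#'
#' @param lines a [geno_matrix()] of candidate lines (no missing calls)
#' @param tester a homozygous tester: a line id in `lines`, a
#'   single-line [geno_matrix()], or a dosage vector (0/2 per marker)
#' @return a [hybrid_set()]
#' @export
infer_hybrid_genotypes <- function(lines, tester) {
  td <- if (is.character(tester) && length(tester) == 1L) {
    if (!tester %in% rownames(lines$calls)) stop("tester '", tester, "' not found")
    lines$calls[tester, ]
  } else if (inherits(tester, "geno_matrix")) {
    if (nrow(tester$calls) != 1L) stop("tester geno_matrix must have one line")
    tester$calls[1L, ]
  } else as.integer(tester)
  if (length(td) != ncol(lines$calls))
    stop("tester length does not match marker count")
  if (any(is.na(td)) || any(td == 1L))
    stop("tester must be homozygous (and non-missing) at every locus")
  dl <- lines$calls
  if (any(is.na(dl))) stop("line genotypes contain missing calls; impute first")
  tz <- rep(td - 1L, each = nrow(dl))
  Z <- (dl - 1 + tz) / 2
  W <- abs(dl - rep(td, each = nrow(dl))) / 2
  storage.mode(Z) <- "double"; storage.mode(W) <- "double"
  dimnames(Z) <- dimnames(W) <- dimnames(dl)
  hybrid_set(Z, W)
}

#' Write / read hybrid code matrices as TSV
#' @param h a [hybrid_set()]
#' @param dir output directory (files `Z.tsv`, `W.tsv`)
#' @return invisibly, the file paths
#' @export
write_hybrid_tsv <- function(h, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pz <- file.path(dir, "Z.tsv"); pw <- file.path(dir, "W.tsv")
  write.table(data.frame(line = rownames(h$Z), h$Z, check.names = FALSE),
              pz, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(line = rownames(h$W), h$W, check.names = FALSE),
              pw, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pz, pw))
}

#' @rdname write_hybrid_tsv
#' @export
read_hybrid_tsv <- function(dir) {
  rd <- function(p) {
    df <- read.table(p, sep = "\t", header = TRUE, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE]); rownames(m) <- df$line; m
  }
  hybrid_set(rd(file.path(dir, "Z.tsv")), rd(file.path(dir, "W.tsv")))
}
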