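#' Genotype matrix container
#'
#' Stores biallelic SNP calls for a set of (possibly heterozygous) lines
#' together with per-marker metadata.  Calls are kept internally as the
#' dosage (0, 1, 2 or `NA`) of the marker's first allele (`a1`); helpers
#' convert to/from the conventional `"AA"/"Aa"/"aa"` strings, where `A`
#' is `a1` and `a` is `a2`.
#'
#' @param calls integer matrix, lines x markers, entries in
#'   `c(0L, 1L, 2L, NA)`: dosage of allele `a1`.  Rownames are line ids,
#'   colnames marker ids.
#' @param map data.frame with one row per marker: columns `marker`,
#'   `chrom`, `pos` (genetic position, cM) and allele labels `a1`, `a2`.
#'   `chrom`/`pos` may be `NA` for markers lacking position metadata.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, map) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(map$marker)) map$marker <- colnames(calls)
  if (is.null(colnames(calls))) colnames(calls) <- map$marker
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("line%04d", seq_len(nrow(calls)))
  if (nrow(map) != ncol(calls))
    stop("geno_matrix: map rows (", nrow(map), ") != markers (", ncol(calls), ")")
  if (is.null(map$a1)) map$a1 <- "A"
  if (is.null(map$a2)) map$a2 <- "B"
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("geno_matrix: calls must be dosages in 0..2 or NA")
  structure(list(calls = calls, map = as.data.frame(map, stringsAsFactors = FALSE)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d lines x %d markers (%.2f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Line identifiers of a genotype matrix
#' @param g a [geno_matrix()]
#' @return character vector of line ids
#' @export
line_ids <- function(g) rownames(g$calls)

#' Per-marker minor allele frequency
#'
#' Allele frequency of `a1` is computed from non-missing dosages; the
#' MAF is `min(p, 1 - p)`, hence always in `[0, 0.5]`.
#'
#' @param g a [geno_matrix()]
#' @return numeric vector, one MAF per marker
#' @export
marker_maf <- function(g) {
  p <- colMeans(g$calls, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Per-marker missing rate
#' @param g a [geno_matrix()]
#' @return numeric vector of missing-call fractions per marker
#' @export
marker_missing_rate <- function(g) colMeans(is.na(g$calls))

#' Per-marker call rate
#'
#' If the map carries an assay-level `call_rate` column (e.g. from a chip
#' manifest) that is used; otherwise the observed fraction of
#' non-missing calls.
#'
#' @param g a [geno_matrix()]
#' @return numeric vector of call rates per marker
#' @export
marker_call_rate <- function(g) {
  if (!is.null(g$map$call_rate)) g$map$call_rate else 1 - marker_missing_rate(g)
}

subset_markers <- function(g, keep) {
  geno_matrix(g$calls[, keep, drop = FALSE], g$map[keep, , drop = FALSE])
}

subset_lines <- function(g, ids) {
  geno_matrix(g$calls[ids, , drop = FALSE], g$map)
}

#' Convert dosage calls to genotype strings
#'
#' @param g a [geno_matrix()]
#' @return character matrix with entries `"AA"`, `"Aa"`, `"aa"` or `NA`
#'   (A = allele `a1`, a = allele `a2`)
#' @export
calls_as_strings <- function(g) {
  out <- matrix(NA_character_, nrow(g$calls), ncol(g$calls),
                dimnames = dimnames(g$calls))
  out[!is.na(g$calls) & g$calls == 2L] <- "AA"
  out[!is.na(g$calls) & g$calls == 1L] <- "Aa"
  out[!is.na(g$calls) & g$calls == 0L] <- "aa"
  out
}

#' Write / read a genotype matrix as TSV with a marker-map sidecar
#'
#' The genotype table holds lines x markers calls as `AA/Aa/aa` strings
#' (missing as empty); the sidecar (`<path>.map.tsv`) holds the marker
#' metadata.
#'
#' @param g a [geno_matrix()]
#' @param path output TSV path
#' @return `write_geno_tsv`: invisibly, the paths written.
#'   `read_geno_tsv`: a [geno_matrix()].
#' @export
write_geno_tsv <- function(g, path) {
  s <- calls_as_strings(g)
  df <- data.frame(line = rownames(s), s, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  map_path <- paste0(path, ".map.tsv")
  write.table(g$map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, map_path))
}

#' @rdname write_geno_tsv
#' @export
read_geno_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("", "NA"))
  map <- read.table(paste0(path, ".map.tsv"), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  s <- as.matrix(df[, -1, drop = FALSE])
  rownames(s) <- df$line
  calls <- matrix(NA_integer_, nrow(s), ncol(s), dimnames = dimnames(s))
  calls[s == "AA"] <- 2L
  calls[s == "Aa" | s == "aA"] <- 1L
  calls[s == "aa"] <- 0L
  geno_matrix(calls, map)
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Uses \pkg{VariantAnnotation} to parse the file, keeps biallelic SNP
#' records with a diploid GT field, and returns dosages of the ALT
#' allele (`a1` = ALT, `a2` = REF).  Positions are physical (bp); no
#' genetic map is attached.
#'
#' @param path VCF file path
#' @return a [geno_matrix()] (lines = VCF samples)
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf_genotypes requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  alt1 <- vapply(seq_along(altl), function(i) {
    a <- as.character(altl[[i]])
    if (length(a) == 1L) a else ""
  }, character(1))
  keep <- nchar(ref) == 1L & nchar(alt1) == 1L
  if (any(!keep))
    message("read_vcf_genotypes: dropped ", sum(!keep),
            " non-biallelic/non-SNP records")
  if (!any(keep)) stop("read_vcf_genotypes: no biallelic SNP records")
  vcf <- vcf[keep]
  gt <- VariantAnnotation::geno(vcf)$GT          # markers x samples
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  rr <- SummarizedExperiment::rowRanges(vcf)
  map <- data.frame(marker = names(vcf),
                    chrom = as.character(GenomeInfoDb::seqnames(rr)),
                    pos = BiocGenerics::start(rr),
                    a1 = alt1[keep], a2 = ref[keep],
                    stringsAsFactors = FALSE)
  geno_matrix(t(dos), map)
}
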