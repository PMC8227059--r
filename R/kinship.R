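#' Genomic relationship (kinship) matrices
#'
#' Additive: `Ka = Z Z' / mean(diag(Z Z'))`; dominance: the same with
#' the dominance code matrix `W`.  The cross-product is taken on the raw
#' code matrices (no column centring) so that the normalized matrix has
#' mean diagonal exactly 1; a centred variant is available via
#' `center = TRUE`.
#'
#' @param Z additive code matrix, lines x markers (entries in `[-1, 1]`)
#' @param W dominance code matrix, lines x markers (entries in `[0, 1]`)
#' @param center centre marker columns before the cross-product
#' @return a `kinship_matrix`: symmetric lines x lines matrix with
#'   `attr(, "kind")` and `attr(, "normalizer")` (the mean raw diagonal)
#' @export
additive_kinship <- function(Z, center = FALSE) {
  make_kinship(Z, "additive", center)
}

#' @rdname additive_kinship
#' @export
dominance_kinship <- function(W, center = FALSE) {
  make_kinship(W, "dominance", center)
}

make_kinship <- function(M, kind, center = FALSE) {
  if (anyNA(M)) stop("kinship: missing codes")
  if (ncol(M) < 1L) stop("kinship: need at least one marker")
  if (center) M <- scale(M, center = TRUE, scale = FALSE)
  K <- tcrossprod(M)
  nrm <- mean(diag(K))
  if (nrm <= 0)
    stop("kinship: zero diagonal (all-", if (kind == "dominance") "zero W"
         else "zero Z", "); no segregating information")
  K <- K / nrm
  structure(K, kind = kind, normalizer = nrm,
            class = c("kinship_matrix", class(K)))
}

#' Write / read a kinship matrix as TSV with line ids
#' @param K a `kinship_matrix` (or any square matrix with dimnames)
#' @param path TSV path
#' @return invisibly `path`; `read_kinship_tsv` returns the matrix
#' @export
write_kinship_tsv <- function(K, path) {
  write.table(data.frame(line = rownames(K), as.data.frame(unclass(K)),
                         check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship_tsv
#' @export
read_kinship_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df$line
  K
}
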