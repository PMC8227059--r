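#' Principal component analysis of genotype codes
#'
#' Columns (markers) are centred and scaled to unit variance;
#' zero-variance columns are dropped with a warning.  The scaled matrix
#' is decomposed by SVD and scores are the scaled matrix times the right
#' singular vectors; the variance explained by component k is the
#' squared singular value over the sum of squared singular values.
#'
#' @param Z numeric matrix, lines x markers (additive codes; no missing)
#' @param n_components number of components to return (default
#'   `min(dim)` capped at 10)
#' @return a `pc_result`: list with `scores` (lines x components) and
#'   `variance_explained` (fractions, non-increasing)
#' @export
pca_genotypes <- function(Z, n_components = min(10L, nrow(Z) - 1L, ncol(Z))) {
  if (nrow(Z) < 2L) stop("pca_genotypes: need at least 2 lines")
  if (anyNA(Z)) stop("pca_genotypes: missing codes; impute first")
  sds <- apply(Z, 2, sd)
  if (any(sds == 0)) {
    warning("pca_genotypes: dropping ", sum(sds == 0), " monomorphic column(s)")
    Z <- Z[, sds > 0, drop = FALSE]
  }
  Xs <- scale(Z)
  sv <- svd(Xs)
  k <- min(n_components, length(sv$d))
  scores <- Xs %*% sv$v[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  ve <- sv$d^2 / sum(sv$d^2)
  structure(list(scores = scores, variance_explained = ve[seq_len(k)]),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat("pc_result:", nrow(x$scores), "lines,", ncol(x$scores), "components\n")
  cat("variance explained (%):",
      paste(sprintf("%.2f", 100 * x$variance_explained), collapse = " "), "\n")
  invisible(x)
}

#' Pairwise genetic similarity (Pearson correlation of genotype codes)
#'
#' @param Z numeric matrix, lines x markers
#' @return symmetric `similarity_matrix` with unit diagonal
#' @export
similarity_matrix <- function(Z) {
  if (ncol(Z) < 2L) stop("similarity_matrix: need >= 2 markers per line")
  sds <- apply(Z, 1, sd)
  if (any(sds == 0))
    stop("similarity_matrix: constant genotype vector for line(s): ",
         paste(rownames(Z)[sds == 0], collapse = ", "))
  s <- cor(t(Z))
  structure(s, class = c("similarity_matrix", class(s)))
}

#' Mean between-population similarity summary
#'
#' @param sim a [similarity_matrix()]
#' @param pop_of factor of population labels, named by line id
#' @return matrix of mean similarities between (and within) populations
#' @export
population_similarity <- function(sim, pop_of) {
  pops <- levels(pop_of)
  out <- matrix(NA_real_, length(pops), length(pops),
                dimnames = list(pops, pops))
  ids <- rownames(sim)
  for (a in pops) for (b in pops) {
    ia <- ids[pop_of[ids] == a]; ib <- ids[pop_of[ids] == b]
    block <- sim[ia, ib, drop = FALSE]
    if (a == b) diag(block) <- NA
    out[a, b] <- mean(block, na.rm = TRUE)
  }
  out
}
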