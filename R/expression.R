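#' Spearman-correlation distance between two expression profiles
#'
#' One minus the Spearman rank correlation; ties receive average ranks.
#' Ranges over [0, 2]: 0 for identical rank orders, 2 for perfectly
#' reversed ones.
#'
#' @param profile_a,profile_b Equal-length numeric vectors, length >= 3.
#' @return Distance in [0, 2].
#' @export
spearman_distance <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b) || length(profile_a) < 3L) {
    stop("profiles must be equal-length numeric vectors of length >= 3")
  }
  if (sd(profile_a) == 0 || sd(profile_b) == 0) {
    stop("Spearman correlation undefined for a constant profile")
  }
  1 - cor(profile_a, profile_b, method = "spearman")
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of the gene rows of an RPKM matrix under the
#' one-minus-Spearman distance. Zero-variance profiles (for which the
#' correlation is undefined) are excluded with a warning rather than
#' assigned an arbitrary distance. Output is deterministic:
#' \code{stats::hclust} breaks merge ties by observation order.
#'
#' @param matrix Numeric matrix, genes in rows, tissues in columns
#'   (>= 3), with row names.
#' @param linkage Agglomeration method passed to \code{hclust}
#'   (default \code{"average"}).
#' @return An \code{hclust} object.
#' @export
hierarchical_cluster <- function(matrix, linkage = "average") {
  .check_expression(matrix)
  if (nrow(matrix) < 2L) stop("need at least 2 genes to cluster")
  constant <- apply(matrix, 1L, sd) == 0
  if (any(constant)) {
    warning("excluding ", sum(constant),
            " zero-variance profile(s) from clustering: ",
            paste(rownames(matrix)[constant], collapse = ", "))
    matrix <- matrix[!constant, , drop = FALSE]
    if (nrow(matrix) < 2L) stop("fewer than 2 variable profiles remain")
  }
  d <- as.dist(1 - cor(t(matrix), method = "spearman"))
  hclust(d, method = linkage)
}

.check_expression <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("expression input must be a numeric matrix (genes x tissues)")
  }
  if (anyNA(matrix) || any(!is.finite(matrix))) {
    stop("expression matrix contains non-finite values")
  }
  if (any(matrix < 0)) stop("RPKM values must be non-negative")
  if (is.null(rownames(matrix))) stop("expression matrix needs row names")
  invisible(matrix)
}

.expressed <- function(x, threshold) x >= threshold & x > 0

#' Genes expressed in exactly one tissue
#'
#' A gene is called expressed in a tissue when its RPKM is at least
#' \code{expressed_threshold} and strictly positive (so a threshold of 0
#' means any positive signal).
#'
#' @param matrix Numeric RPKM matrix, genes in rows.
#' @param expressed_threshold Expression call threshold (default 1 RPKM).
#' @return Character vector of tissue-specific gene IDs.
#' @export
tissue_specific_genes <- function(matrix, expressed_threshold = 1) {
  .check_expression(matrix)
  if (expressed_threshold < 0) stop("threshold must be >= 0")
  n_on <- rowSums(.expressed(matrix, expressed_threshold))
  rownames(matrix)[n_on == 1L]
}

#' Genes expressed throughout the fruit ripening stages
#'
#' Returns the genes called expressed (RPKM at least the threshold and
#' strictly positive) in every listed stage column.
#'
#' @param matrix Numeric RPKM matrix, genes in rows.
#' @param stages Column names of the ripening stages (e.g. mature green,
#'   breaker, red ripe).
#' @param expressed_threshold Expression call threshold (default 1 RPKM).
#' @return Character vector of gene IDs.
#' @export
fruit_expressed_genes <- function(matrix, stages, expressed_threshold = 1) {
  .check_expression(matrix)
  missing_cols <- setdiff(stages, colnames(matrix))
  if (length(missing_cols)) {
    stop("stage column(s) absent from matrix: ",
         paste(missing_cols, collapse = ", "))
  }
  on <- .expressed(matrix[, stages, drop = FALSE], expressed_threshold)
  rownames(matrix)[rowSums(on) == length(stages)]
}

#' Relative quantification by the comparative-CT method
#'
#' \code{ddCT = (CT_target - CT_reference) - (CT_target_calibrator -
#' CT_reference_calibrator)} and \code{RQ = 2^-ddCT}. RQ is 1 when the
#' sample equals the calibrator and \code{log2(RQ) = -ddCT} exactly.
#'
#' @param ct_target,ct_reference Target and reference-gene CT values in
#'   the sample.
#' @param ct_target_calibrator,ct_reference_calibrator The same two CTs in
#'   the calibrator sample.
#' @return Fold change(s) RQ > 0.
#' @export
relative_quantity <- function(ct_target, ct_reference,
                              ct_target_calibrator,
                              ct_reference_calibrator) {
  cts <- c(ct_target, ct_reference, ct_target_calibrator,
           ct_reference_calibrator)
  if (anyNA(cts) || any(!is.finite(cts))) {
    stop("CT values must be finite")
  }
  ddct <- (ct_target - ct_reference) -
    (ct_target_calibrator - ct_reference_calibrator)
  2^(-ddct)
}
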