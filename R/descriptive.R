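# Descriptive layer: log transform, PCA of samples, Spearman-correlation
# clustering, and delta-delta-Ct relative quantification for qPCR
# validation data.

#' Log2 transform with pseudocount
#'
#' @param mat non-negative matrix (e.g. GeTMM values).
#' @param pseudocount added before taking log2 (default 1, so 0 maps to 0).
#' @return transformed matrix.
#' @export
log_transform <- function(mat, pseudocount = 1) {
  if (inherits(mat, "getmm_matrix")) mat <- mat$values
  if (any(mat < 0)) abort_validation("log transform requires values >= 0")
  log2(mat + pseudocount)
}

#' PCA of samples
#'
#' Samples are rows, genes columns (a genes x samples matrix is transposed
#' automatically when sample names are on the columns). Columns are centred,
#' not scaled; scores are the centred data projected on the right singular
#' vectors.
#'
#' @param mat numeric matrix; samples x genes after any transposition.
#' @param transpose set `TRUE` if `mat` is genes x samples (default assumes
#'   genes x samples, the pipeline's native orientation).
#' @return object of class `pca_result`: `scores` (samples x components),
#'   `variance_explained` (fractions summing to 1), `sdev`.
#' @export
pca_samples <- function(mat, transpose = TRUE) {
  if (inherits(mat, "getmm_matrix")) mat <- mat$values
  x <- if (transpose) t(mat) else mat
  if (nrow(x) < 2) abort_validation("PCA needs at least 2 samples")
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = fit$x, variance_explained = ve, sdev = fit$sdev),
            class = "pca_result")
}

#' Spearman-correlation sample clustering
#'
#' Pairwise Spearman rank correlation between samples (average ranks for
#' ties), then agglomerative hierarchical clustering on distance `1 - rho`
#' (complete linkage by default).
#'
#' @param mat genes x samples matrix; columns are clustered.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return object of class `sample_clustering`: `correlation` (samples x
#'   samples Spearman matrix), `hclust`, `newick` (dendrogram as a Newick
#'   string with merge heights as branch lengths).
#' @export
cluster_samples <- function(mat, linkage = "complete") {
  if (inherits(mat, "getmm_matrix")) mat <- mat$values
  if (ncol(mat) < 2) abort_validation("clustering needs at least 2 samples")
  const <- apply(mat, 2, function(x) stats::var(x) == 0)
  if (any(const))
    abort_validation(paste("constant sample(s), Spearman undefined:",
                           paste(colnames(mat)[const], collapse = ", ")))
  rho <- stats::cor(mat, method = "spearman")
  hc <- stats::hclust(stats::as.dist(1 - rho), method = linkage)
  structure(list(correlation = rho, hclust = hc, newick = hclust_newick(hc)),
            class = "sample_clustering")
}

# Newick serialization of an hclust tree; branch lengths are differences in
# merge heights (leaves sit at height 0).
hclust_newick <- function(hc) {
  build <- function(node, parent_height) {
    if (node < 0) {
      sprintf("%s:%.10g", hc$labels[-node], parent_height)
    } else {
      h <- hc$height[node]
      sprintf("(%s,%s):%.10g",
              build(hc$merge[node, 1], h),
              build(hc$merge[node, 2], h),
              parent_height - h)
    }
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  paste0("(", build(hc$merge[root, 1], h), ",",
         build(hc$merge[root, 2], h), ");")
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,sample - Ct_ref,sample) -
#'         (Ct_target,calibrator - Ct_ref,calibrator)`; the relative
#' expression is `2^-ddCt`. The reference is a housekeeping gene (e.g.
#' GAPDH) and the calibrator a baseline sample.
#'
#' @param ct_target_sample,ct_ref_sample Ct values in the test sample.
#' @param ct_target_calibrator,ct_ref_calibrator Ct values in the
#'   calibrator.
#' @return relative expression (vectorized).
#' @export
ddct <- function(ct_target_sample, ct_ref_sample,
                 ct_target_calibrator, ct_ref_calibrator) {
  stopifnot(all(is.finite(c(ct_target_sample, ct_ref_sample,
                            ct_target_calibrator, ct_ref_calibrator))))
  d <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-d)
}
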