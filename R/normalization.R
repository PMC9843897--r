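# GeTMM: gene-length-corrected counts (RPK) scaled by trimmed-mean-of-M
# (TMM) factors, so that expression is comparable across genes of different
# lengths and across libraries of different depth and composition — the
# prerequisite for comparing orthologues between species.

#' TMM parameters
#'
#' Canonical TMM settings: 30% two-sided trim on the log-ratios (M), 5% trim
#' on the average log-expression (A), asymptotic-variance precision weights,
#' and automatic reference selection (the sample whose 75th-percentile
#' relative expression is closest to the mean of the per-sample 75th
#' percentiles).
#'
#' @param logratio_trim two-sided trim fraction on M values, in `[0, 0.5)`.
#' @param abs_trim two-sided trim fraction on A values, in `[0, 0.5)`.
#' @param reference_sample sample ID to use as reference, or `"auto"`.
#' @param weighting use inverse-asymptotic-variance weights for the mean M.
#' @return list of class `tmm_params`.
#' @export
tmm_params <- function(logratio_trim = 0.30, abs_trim = 0.05,
                       reference_sample = "auto", weighting = TRUE) {
  if (logratio_trim < 0 || logratio_trim >= 0.5 ||
      abs_trim < 0 || abs_trim >= 0.5)
    abort_validation("trim fractions must be in [0, 0.5)")
  structure(list(logratio_trim = logratio_trim, abs_trim = abs_trim,
                 reference_sample = reference_sample,
                 weighting = isTRUE(weighting)),
            class = "tmm_params")
}

#' Filter genes not expressed in every sample
#'
#' A row is retained iff, within every species, every sample has count > 0.
#' With the joined orthologue matrix this reduces to "positive everywhere",
#' which also guarantees finite M values in all pairwise TMM comparisons.
#'
#' @param mat joined counts on orthologue rows (genes x samples).
#' @param species_of named character vector mapping sample ID -> species;
#'   must cover every column.
#' @return the row-subset matrix.
#' @export
filter_low_expressed <- function(mat, species_of) {
  if (ncol(mat) == 0 || nrow(mat) == 0) return(mat)
  missing <- setdiff(colnames(mat), names(species_of))
  if (length(missing))
    abort_config(paste("samples without a species label:",
                       paste(missing, collapse = ", ")))
  keep <- rowSums(mat > 0) == ncol(mat)
  mat[keep, , drop = FALSE]
}

#' Reads per kilobase (RPK)
#'
#' @param counts genes x samples matrix.
#' @param gene_lengths per-row gene lengths in bp (recycled by name if
#'   named, else by position).
#' @return matrix of `counts / (length/1000)`.
#' @export
rpk <- function(counts, gene_lengths) {
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    gene_lengths <- gene_lengths[rownames(counts)]
    if (anyNA(gene_lengths))
      abort_validation("gene_lengths missing for some rows")
  }
  if (length(gene_lengths) != nrow(counts))
    abort_validation("one gene length per row required")
  if (any(gene_lengths <= 0))
    abort_validation("gene lengths must be > 0")
  counts / (gene_lengths / 1000)
}

# Single pairwise TMM factor of sample `obs` against reference `ref`
# (expression vectors; Ny, Nr their library sizes).
tmm_pair_factor <- function(obs, ref, Ny, Nr, params) {
  pos <- obs > 0 & ref > 0
  y <- obs[pos]; r <- ref[pos]
  if (length(y) == 0) return(1)
  M <- log2((y / Ny) / (r / Nr))
  A <- 0.5 * log2((y / Ny) * (r / Nr))
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * params$logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * params$abs_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) return(1)
  if (params$weighting) {
    # Asymptotic variance of M on the relative-proportion scale:
    # (1 - p)/p per sample with p = y/N. Identical (up to a constant) to
    # the count-scale form (N - y)/(N y) when library sizes are equal, but
    # exactly invariant to rescaling a sample's counts, which the GeTMM
    # contract requires.
    py <- y / Ny; pr <- r / Nr
    v <- (1 - py) / py + (1 - pr) / pr
    v <- pmax(v, 1e-12)
    f <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
  } else {
    f <- mean(M[keep])
  }
  2^f
}

#' TMM scaling factors
#'
#' One factor per sample, computed against a reference sample from doubly
#' trimmed, optionally precision-weighted log-ratios of relative expression;
#' genes with a zero in either sample are excluded from the comparison.
#' Factors are rescaled so their geometric mean is 1.
#'
#' @param mat non-negative genes x samples matrix (counts or RPK).
#' @param params a [tmm_params()] object.
#' @return named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(mat, params = tmm_params()) {
  if (ncol(mat) < 2) abort_validation("TMM needs at least 2 samples")
  libs <- colSums(mat)
  if (any(libs <= 0)) {
    bad <- colnames(mat)[libs <= 0]
    abort_validation(paste("sample(s) with all-zero counts:",
                           paste(bad, collapse = ", ")))
  }
  if (identical(params$reference_sample, "auto")) {
    q75 <- apply(sweep(mat, 2, libs, "/"), 2, stats::quantile, probs = 0.75)
    ref_idx <- which.min(abs(q75 - mean(q75)))
  } else {
    ref_idx <- match(params$reference_sample, colnames(mat))
    if (is.na(ref_idx))
      abort_config(paste("reference sample not found:",
                         params$reference_sample))
  }
  f <- vapply(seq_len(ncol(mat)), function(s) {
    if (s == ref_idx) return(1)
    tmm_pair_factor(mat[, s], mat[, ref_idx], libs[s], libs[ref_idx], params)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(mat))
}

#' GeTMM normalization
#'
#' TMM factors are computed on the RPK matrix and each sample's RPK values
#' are put on a per-million scale using its factor-adjusted RPK library
#' size: `value[g,s] = RPK[g,s] / (sum_g RPK[g,s] * f_s) * 1e6`. The result
#' is invariant to any positive rescaling of a sample's counts.
#'
#' @param counts filtered joined count matrix (genes x samples).
#' @param gene_lengths per-row lengths in bp (see [rpk()]).
#' @param params a [tmm_params()].
#' @return object of class `getmm_matrix`: list with `values` (normalized
#'   matrix), `scaling_factors`, `library_sizes` (RPK column sums) and
#'   `params`.
#' @export
getmm_normalize <- function(counts, gene_lengths, params = tmm_params()) {
  getmm_from_rpk(rpk(counts, gene_lengths), params)
}

#' GeTMM scaling of a pre-computed RPK matrix
#'
#' Used directly by the pipeline, where species-specific gene lengths mean
#' the RPK matrix is assembled per species before joint TMM.
#'
#' @param rpk_mat RPK matrix (genes x samples).
#' @inheritParams getmm_normalize
#' @return a `getmm_matrix` (see [getmm_normalize()]).
#' @export
getmm_from_rpk <- function(rpk_mat, params = tmm_params()) {
  f <- tmm_factors(rpk_mat, params)
  libs <- colSums(rpk_mat)
  values <- sweep(rpk_mat, 2, libs * f, "/") * 1e6
  structure(list(values = values, scaling_factors = f,
                 library_sizes = libs, params = params),
            class = "getmm_matrix")
}

#' @export
print.getmm_matrix <- function(x, ...) {
  cat(sprintf("<getmm_matrix> %d genes x %d samples; factor range [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values),
              min(x$scaling_factors), max(x$scaling_factors)))
  invisible(x)
}

#' Per-gene coefficient of variation
#'
#' `sd/mean` across samples (sample standard deviation, n-1 denominator).
#' Rows with zero mean are excluded with a warning.
#'
#' @param mat genes x samples matrix (raw counts or normalized values).
#' @return named numeric vector of CVs for rows with positive mean.
#' @export
coefficient_of_variation <- function(mat) {
  mu <- rowMeans(mat)
  if (any(mu == 0)) {
    warning(sprintf("%d zero-mean row(s) excluded from CV", sum(mu == 0)))
  }
  keep <- mu > 0
  sds <- apply(mat[keep, , drop = FALSE], 1, stats::sd)
  sds / mu[keep]
}
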