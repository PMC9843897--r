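# Promoter methylation from WGBS cytosine reports: strand-aware 1 kb
# promoter extraction, the pooled-read methylation level with coverage
# filters, and a per-promoter two-group Welch t-test.

#' Strand-aware 1 kb promoter regions
#'
#' One region per gene, upstream of the transcription start site: for a `+`
#' strand gene the promoter is `[TSS - span, TSS)` with `TSS = start`; for a
#' `-` strand gene the TSS is the last transcribed base (`end - 1` in
#' half-open coordinates) and the promoter is `[TSS + 1, TSS + 1 + span)`,
#' i.e. `[end, end + span)`. Regions are clipped at position 0.
#'
#' @param genes gene table with one representative row per gene (apply
#'   [select_longest_isoform()] first if needed).
#' @param span promoter length in bp (default 1000).
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
promoter_regions <- function(genes, span = 1000) {
  if (anyDuplicated(genes$gene_id))
    abort_validation("one representative record per gene required")
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0L, genes$start - span), genes$end)
  end <- ifelse(plus, genes$start, genes$end + span)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = start, end = end, strand = genes$strand,
             stringsAsFactors = FALSE)
}

#' Promoter methylation levels with coverage filters
#'
#' A CpG passes iff its depth `mC + C` exceeds `min_depth_exclusive`
#' (strictly more than five reads by default); a promoter is reported iff at
#' least `min_cpg` CpGs pass. The level is the pooled ratio
#' `sum(mC) / sum(mC + C)` over passing CpGs. CpG report positions are
#' 1-based and are matched to the 0-based half-open promoter intervals.
#'
#' @param cpgs cytosine report rows for one or more samples
#'   ([read_cpg_report()]).
#' @param promoters promoter table ([promoter_regions()]).
#' @param min_cpg minimum number of passing CpGs (default 2).
#' @param min_depth_exclusive depth must be strictly greater than this
#'   (default 5).
#' @return list with `levels`: data.frame `gene_id`, `sample_id`, `level`,
#'   `n_cpg_passing`, `total_mC`, `total_C`; and `excluded`: data.frame
#'   `gene_id`, `sample_id`, `reason` for promoters that failed the filter.
#' @export
promoter_methylation <- function(cpgs, promoters, min_cpg = 2,
                                 min_depth_exclusive = 5) {
  samples <- unique(cpgs$sample_id)
  lev_rows <- list(); exc_rows <- list()
  for (smp in samples) {
    sub <- cpgs[cpgs$sample_id == smp, , drop = FALSE]
    sub <- sub[sub$count_methylated + sub$count_unmethylated >
                 min_depth_exclusive, , drop = FALSE]
    for (chr in unique(promoters$chrom)) {
      pr <- promoters[promoters$chrom == chr, , drop = FALSE]
      sc <- sub[sub$chrom == chr, , drop = FALSE]
      pos0 <- sort(sc$position - 1L)  # to 0-based
      ord <- order(sc$position)
      mC <- sc$count_methylated[ord]
      uC <- sc$count_unmethylated[ord]
      for (i in seq_len(nrow(pr))) {
        lo <- findInterval(pr$start[i] - 0.5, pos0) + 1L
        hi <- findInterval(pr$end[i] - 0.5, pos0)
        npass <- if (hi >= lo) hi - lo + 1L else 0L
        if (npass >= min_cpg) {
          tm <- sum(mC[lo:hi]); tu <- sum(uC[lo:hi])
          lev_rows[[length(lev_rows) + 1L]] <- data.frame(
            gene_id = pr$gene_id[i], sample_id = smp,
            level = tm / (tm + tu), n_cpg_passing = npass,
            total_mC = tm, total_C = tu, stringsAsFactors = FALSE)
        } else {
          exc_rows[[length(exc_rows) + 1L]] <- data.frame(
            gene_id = pr$gene_id[i], sample_id = smp,
            reason = sprintf("only %d CpG(s) with depth > %d (need >= %d)",
                             npass, min_depth_exclusive, min_cpg),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  empty_lev <- data.frame(gene_id = character(), sample_id = character(),
                          level = numeric(), n_cpg_passing = integer(),
                          total_mC = numeric(), total_C = numeric(),
                          stringsAsFactors = FALSE)
  empty_exc <- data.frame(gene_id = character(), sample_id = character(),
                          reason = character(), stringsAsFactors = FALSE)
  list(levels = if (length(lev_rows)) do.call(rbind, lev_rows) else empty_lev,
       excluded = if (length(exc_rows)) do.call(rbind, exc_rows) else empty_exc)
}

# Welch two-sided t-test in closed form with explicit degenerate handling.
welch_t <- function(a, b, pooled = FALSE) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  delta <- mean(a) - mean(b)
  if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (!is.finite(se) || se == 0) {
    if (delta == 0) return(c(t = 0, df = NA_real_, p = 1))
    return(c(t = sign(delta) * Inf, df = NA_real_, p = 0))
  }
  t <- delta / se
  c(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Differential promoter methylation between two groups
#'
#' Per-promoter two-sided Welch t-test on per-sample methylation levels.
#' Promoters lacking at least 2 reported levels in each group are skipped
#' with a reason.
#'
#' @param levels_a,levels_b data.frames from
#'   `promoter_methylation()$levels` for the samples of each group (or any
#'   data.frame with `gene_id`, `sample_id`, `level`).
#' @param pooled use the pooled-variance (Student) t-test instead of Welch.
#' @return list with `tests`: data.frame `gene_id`, `mean_a`, `mean_b`,
#'   `t`, `p_value`; and `skipped`: data.frame `gene_id`, `reason`.
#' @export
differential_methylation <- function(levels_a, levels_b, pooled = FALSE) {
  genes <- union(levels_a$gene_id, levels_b$gene_id)
  rows <- list(); skipped <- list()
  for (g in genes) {
    a <- levels_a$level[levels_a$gene_id == g]
    b <- levels_b$level[levels_b$gene_id == g]
    if (length(a) < 2 || length(b) < 2) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        gene_id = g,
        reason = sprintf("need >= 2 levels per group (have %d and %d)",
                         length(a), length(b)),
        stringsAsFactors = FALSE)
      next
    }
    w <- welch_t(a, b, pooled = pooled)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, mean_a = mean(a), mean_b = mean(b),
      t = unname(w["t"]), p_value = unname(w["p"]),
      stringsAsFactors = FALSE)
  }
  empty_t <- data.frame(gene_id = character(), mean_a = numeric(),
                        mean_b = numeric(), t = numeric(),
                        p_value = numeric(), stringsAsFactors = FALSE)
  empty_s <- data.frame(gene_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  list(tests = if (length(rows)) do.call(rbind, rows) else empty_t,
       skipped = if (length(skipped)) do.call(rbind, skipped) else empty_s)
}
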