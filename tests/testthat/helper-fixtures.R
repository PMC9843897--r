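# Shared fixture builders. Everything is generated in code; tests write
# temporary files only through these helpers.

write_tmp_tsv <- function(df, ..., col.names = TRUE) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col.names)
  path
}

toy_counts_df <- function() {
  data.frame(gene_id = c("g1", "g2", "g3"),
             s1 = c(10L, 0L, 5L), s2 = c(3L, 7L, 2L))
}

toy_gene_table <- function() {
  data.frame(gene_id = c("g1", "g1", "g2"),
             isoform_id = c("g1.t1", "g1.t2", "g2.t1"),
             chrom = c("chr1", "chr1", "chr2"),
             start = c(100L, 100L, 5000L),
             end = c(600L, 450L, 9000L),
             strand = c("+", "+", "-"),
             protein_length = c(120L, 300L, 800L))
}

random_hit_table <- function(n_query, n_subject, prefix_q, prefix_s,
                             n_hits = 60) {
  data.frame(
    qseqid = sprintf("%s%02d", prefix_q, sample.int(n_query, n_hits, TRUE)),
    sseqid = sprintf("%s%02d", prefix_s, sample.int(n_subject, n_hits, TRUE)),
    pident = round(runif(n_hits, 30, 100), 1),
    length = sample.int(500, n_hits, TRUE),
    mismatch = sample.int(50, n_hits, TRUE),
    gapopen = sample.int(5, n_hits, TRUE),
    qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
    evalue = 10^runif(n_hits, -60, -6),
    bitscore = round(runif(n_hits, 50, 900), 1),
    stringsAsFactors = FALSE)
}

# Brute-force best-hit oracle: explicit loops, no sorting tricks.
oracle_best_hits <- function(hits) {
  out <- character(0)
  for (q in unique(hits$qseqid)) {
    h <- hits[hits$qseqid == q, ]
    best <- h[1, ]
    if (nrow(h) > 1) for (i in 2:nrow(h)) {
      cand <- h[i, ]
      better <- cand$evalue < best$evalue ||
        (cand$evalue == best$evalue && cand$bitscore > best$bitscore) ||
        (cand$evalue == best$evalue && cand$bitscore == best$bitscore &&
           cand$sseqid < best$sseqid)
      if (better) best <- cand
    }
    out[q] <- best$sseqid
  }
  out
}

oracle_rbh <- function(hits_ab, hits_ba) {
  ab <- oracle_best_hits(hits_ab)
  ba <- oracle_best_hits(hits_ba)
  pairs <- character(0)
  for (a in names(ab)) {
    b <- ab[[a]]
    if (!is.na(ba[b]) && identical(unname(ba[b]), a))
      pairs <- c(pairs, paste(a, b))
  }
  sort(pairs)
}

# Brute-force BH step-up straight from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Conditional NB exact-test oracle: builds each group-sum pmf by explicit
# convolution of per-sample NB pmfs (independent of the size-additivity
# shortcut in the implementation).
oracle_nb_exact_p <- function(sa, tot, na, nb, phi) {
  mu <- tot / (na + nb)
  pmf1 <- function(upper) {
    if (phi <= 0) stats::dpois(0:upper, mu)
    else stats::dnbinom(0:upper, size = 1 / phi, mu = mu)
  }
  conv_n <- function(n, upper) {
    acc <- pmf1(upper)
    if (n > 1) for (i in 2:n) {
      base <- pmf1(upper)
      new <- numeric(upper + 1)
      for (t in 0:upper) {
        new[t + 1] <- sum(acc[1:(t + 1)] * rev(base[1:(t + 1)]))
      }
      acc <- new
    }
    acc
  }
  pa <- conv_n(na, tot)
  pb <- conv_n(nb, tot)
  joint <- pa * rev(pb)
  joint <- joint / sum(joint)
  sum(joint[joint <= joint[sa + 1] * (1 + 1e-10)])
}

# Exhaustive hypergeometric ORA oracle for small universes.
oracle_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_term <- seq_len(K)  # term members are wlog 1..K
  overlaps <- apply(draws, 2, function(d) sum(d %in% in_term))
  mean(overlaps >= k)
}

small_sim_cfg <- function(seed = 11, methylation = list(), ...) {
  meth <- utils::modifyList(list(n_promoters = 40, n_differential = 10),
                            methylation)
  sim_config(n_species = 4, n_genes = 400, samples_per_species = 3,
             n_convergent_up = 10, n_convergent_down = 10,
             library_size_range = c(2e5, 5e5),
             methylation = meth, seed = seed, ...)
}
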