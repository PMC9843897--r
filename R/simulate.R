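# Synthetic multi-species world with planted convergent genes.
#
# The generator emulates the structure the analysis assumes: per-species NB
# counts whose expected value is library size x relative expression, where
# relative expression combines a shared per-gene baseline, gene length,
# species effects, and — for the planted genes — a direction-consistent
# convergent shift in the focal species. Species effects have two
# components: a small iid wobble on every gene, and strong lineage-specific
# divergence on a random subset of NON-planted genes. The strong component
# is what makes PCA separate species; it is kept off the planted genes so
# the planted truth labels remain the actual truth of the generative model
# (a planted "convergent" gene with a large confounding lineage shift would
# no longer be convergent). See the methods vignette for the calibration.

#' Synthetic-world configuration
#'
#' Defaults describe the package's reference world: 8 species (2 focal),
#' 4 replicates, 5,000 genes, 50 + 50 planted convergent genes shifted by
#' 2 log2 units, NB dispersion 0.1 (variance = mu + phi mu^2), unequal
#' library sizes, and binomial promoter methylation.
#'
#' @param n_species number of species; the first `n_focal` are focal.
#' @param n_focal number of focal (convergent) species.
#' @param samples_per_species biological replicates per species.
#' @param n_genes orthologous genes.
#' @param n_convergent_up,n_convergent_down planted convergent gene counts.
#' @param effect_log2fc planted shift magnitude in log2 units (> 0).
#' @param baseline_log_mean,baseline_log_sd natural-log normal parameters of
#'   the shared per-gene relative expression baseline.
#' @param species_effect_sd sd (log2) of the small iid species effect on
#'   every gene.
#' @param divergent_fraction fraction of non-planted genes that also carry
#'   strong lineage divergence.
#' @param divergent_effect_sd per-axis sd (log2) of the 2-D lineage loading
#'   drawn for divergent genes; per-species effect sd equals this value
#'   (species positions are on the unit circle).
#' @param dispersion NB dispersion phi.
#' @param library_size_range uniform range of expected library sizes.
#' @param gene_length_range uniform range of base gene lengths (bp); each
#'   species' copy is jittered by +/- 10%.
#' @param seed mandatory integer seed; all `simulate_*` functions derive
#'   their RNG streams from it.
#' @param methylation list: `n_promoters`, `cpgs_per_promoter`,
#'   `depth_mean`, `level_high`, `level_low`, `n_differential`,
#'   `samples_per_group`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_species = 8, n_focal = 2, samples_per_species = 4,
                       n_genes = 5000, n_convergent_up = 50,
                       n_convergent_down = 50, effect_log2fc = 2,
                       baseline_log_mean = 2, baseline_log_sd = 1,
                       species_effect_sd = 0.1, divergent_fraction = 0.25,
                       divergent_effect_sd = 1, dispersion = 0.1,
                       library_size_range = c(2e6, 5e6),
                       gene_length_range = c(300, 15000),
                       seed,
                       methylation = list()) {
  if (missing(seed)) abort_config("sim_config requires an explicit seed")
  if (effect_log2fc <= 0) abort_config("effect_log2fc must be > 0")
  if (n_focal < 1 || n_focal >= n_species)
    abort_config("need 1 <= n_focal < n_species")
  if (n_convergent_up + n_convergent_down > n_genes)
    abort_config("more planted genes than genes")
  meth_defaults <- list(n_promoters = 500, cpgs_per_promoter = 10,
                        depth_mean = 30, level_high = 0.8, level_low = 0.2,
                        n_differential = 100, samples_per_group = 4)
  meth <- utils::modifyList(meth_defaults, methylation)
  structure(list(
    n_species = n_species, n_focal = n_focal,
    samples_per_species = samples_per_species, n_genes = n_genes,
    n_convergent_up = n_convergent_up, n_convergent_down = n_convergent_down,
    effect_log2fc = effect_log2fc, baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd, species_effect_sd = species_effect_sd,
    divergent_fraction = divergent_fraction,
    divergent_effect_sd = divergent_effect_sd, dispersion = dispersion,
    library_size_range = library_size_range,
    gene_length_range = gene_length_range, seed = as.integer(seed),
    methylation = meth), class = "sim_config")
}

rnb <- function(n, mu, phi) {
  if (phi <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, size = 1 / phi, mu = mu)
}

#' Simulate per-species count matrices with planted convergent genes
#'
#' @param config a [sim_config()].
#' @return list with `counts` (list of [count_matrix()] per species),
#'   `gene_tables` (list of gene tables per species; a random 20% of genes
#'   get a second, shorter isoform so longest-isoform selection is
#'   exercised), `species`, `focal`, and `truth` (orthology table, planted
#'   `convergent_up` / `convergent_down` in the first focal species' gene
#'   IDs, expected per-species means, gene lengths).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- config$n_species; n <- config$n_genes
  species <- sprintf("sp%02d", seq_len(k))
  focal <- species[seq_len(config$n_focal)]
  gene_ids <- sapply(species, function(sp)
    sprintf("%s_g%05d", sp, seq_len(n)), simplify = FALSE)

  base_len <- round(stats::runif(n, config$gene_length_range[1],
                                 config$gene_length_range[2]))
  len <- sapply(species, function(sp)
    pmax(100L, as.integer(round(base_len * stats::runif(n, 0.9, 1.1)))),
    simplify = FALSE)

  base <- exp(stats::rnorm(n, config$baseline_log_mean,
                           config$baseline_log_sd))

  planted <- sample.int(n, config$n_convergent_up + config$n_convergent_down)
  up_idx <- planted[seq_len(config$n_convergent_up)]
  down_idx <- setdiff(planted, up_idx)

  eff <- matrix(stats::rnorm(n * k, 0, config$species_effect_sd), n, k)
  divergent <- rep(FALSE, n)
  nonplanted <- setdiff(seq_len(n), planted)
  divergent[nonplanted] <-
    stats::runif(length(nonplanted)) < config$divergent_fraction
  # Lineage divergence lives in a 2-D "lineage space": species sit on the
  # unit circle with the focal species maximally separated (they are
  # distant lineages that converged ecologically, not sister taxa), and
  # each divergent gene draws an isotropic 2-D loading. This concentrates
  # between-species variance in a plane (so PCA separates species) while
  # making lineage-driven false convergence geometrically impossible:
  # opposite positions imply opposite lineage effects in the two focals.
  pos <- integer(k)
  focal_pos <- round(seq(0, k - 1, length.out = config$n_focal + 1))[
    seq_len(config$n_focal)] + 1L
  pos[seq_len(config$n_focal)] <- focal_pos
  pos[(config$n_focal + 1):k] <- setdiff(seq_len(k), focal_pos)
  angles <- 2 * pi * (pos - 1) / k
  u <- rbind(cos(angles), sin(angles))          # 2 x k species positions
  lam <- matrix(stats::rnorm(n * 2, 0, config$divergent_effect_sd), n, 2)
  lam[!divergent, ] <- 0
  eff <- eff + lam %*% u
  shift <- matrix(0, n, k)
  shift[up_idx, seq_len(config$n_focal)] <- config$effect_log2fc
  shift[down_idx, seq_len(config$n_focal)] <- -config$effect_log2fc

  counts <- list(); expected <- list()
  for (s in seq_len(k)) {
    q <- base * (len[[s]] / 1000) * 2^(eff[, s] + shift[, s])
    p <- q / sum(q)
    nrep <- config$samples_per_species
    libs <- stats::runif(nrep, config$library_size_range[1],
                         config$library_size_range[2])
    m <- matrix(0L, n, nrep)
    for (j in seq_len(nrep)) {
      m[, j] <- rnb(n, libs[j] * p, config$dispersion)
    }
    dimnames(m) <- list(gene_ids[[s]],
                        sprintf("%s_r%d", species[s], seq_len(nrep)))
    counts[[species[s]]] <- count_matrix(m, species[s], "synthetic")
    expected[[species[s]]] <- p
  }

  gene_tables <- list()
  for (s in seq_len(k)) {
    ids <- gene_ids[[s]]
    chrom <- sprintf("chr%d", 1 + (seq_len(n) - 1) %% 10)
    # lay genes along each chromosome with 2 kb gaps
    start <- integer(n)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      start[i] <- cumsum(c(2000L, utils::head(len[[s]][i], -1) + 2000L))
    }
    strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
    tbl <- data.frame(gene_id = ids,
                      isoform_id = paste0(ids, ".t1"),
                      chrom = chrom, start = start,
                      end = start + len[[s]], strand = strand,
                      protein_length = pmax(1L, len[[s]] %/% 3),
                      stringsAsFactors = FALSE)
    extra <- which(stats::runif(n) < 0.2)
    if (length(extra)) {
      alt <- tbl[extra, ]
      alt$isoform_id <- paste0(alt$gene_id, ".t2")
      alt$protein_length <- pmax(1L, alt$protein_length - 10L)
      tbl <- rbind(tbl, alt)
    }
    gene_tables[[species[s]]] <- tbl
  }

  orthology <- as.data.frame(gene_ids, stringsAsFactors = FALSE)
  names(orthology) <- species
  proxy <- gene_ids[[1]]
  truth <- list(orthology = orthology,
                convergent_up = sort(proxy[up_idx]),
                convergent_down = sort(proxy[down_idx]),
                divergent = proxy[divergent],
                expected_fraction = expected,
                lengths = len)
  list(counts = counts, gene_tables = gene_tables, species = species,
       focal = focal, truth = truth)
}

#' Simulate pairwise protein hit tables consistent with an orthology truth
#'
#' True orthologue pairs get mutual best hits at E ~ 1e-50; a fraction of
#' genes also emit decoy hits to a wrong partner, at E-values between 1e-7
#' and 1e-4 and lower bit scores, so some decoys survive the E-value filter
#' but never displace a best hit. RBH over these tables reconstructs the
#' truth exactly.
#'
#' @param truth orthology truth (`simulate_counts()$truth`).
#' @param config the same [sim_config()].
#' @param decoy_fraction fraction of genes emitting a decoy hit.
#' @return named list of 12-column hit tables, one per ordered species pair
#'   (`"A|B"` has A queries and B subjects).
#' @export
simulate_hit_tables <- function(truth, config, decoy_fraction = 0.10) {
  set.seed(config$seed + 1L)
  orth <- truth$orthology
  species <- names(orth)
  n <- nrow(orth)
  out <- list()
  mk_row <- function(q, s, ev, bits) {
    data.frame(qseqid = q, sseqid = s, pident = 90, length = 300,
               mismatch = 30, gapopen = 1, qstart = 1, qend = 300,
               sstart = 1, send = 300, evalue = ev, bitscore = bits,
               stringsAsFactors = FALSE)
  }
  for (i in seq_along(species)) for (j in seq_along(species)) {
    if (i == j) next
    a <- orth[[species[i]]]; b <- orth[[species[j]]]
    tab <- mk_row(a, b, 1e-50, 500)
    dec <- which(stats::runif(n) < decoy_fraction)
    if (length(dec)) {
      wrong <- b[(dec %% n) + 1L]  # deterministic wrong partner
      ok <- wrong != b[dec]
      dec <- dec[ok]; wrong <- wrong[ok]
      if (length(dec)) {
        ev <- 10^stats::runif(length(dec), -7, -4)
        tab <- rbind(tab, mk_row(a[dec], wrong, ev,
                                 round(stats::runif(length(dec), 50, 200))))
      }
    }
    out[[paste(species[i], species[j], sep = "|")]] <- tab
  }
  out
}

#' Simulate per-sample CpG cytosine reports over promoters
#'
#' Two sample groups; per CpG the read depth is Poisson(`depth_mean`) and
#' the methylated count is Binomial(depth, pi) where pi is the promoter's
#' group-specific true level. `n_differential` promoters differ between
#' groups (`level_high` vs `level_low`, half in each orientation); the rest
#' share a common level drawn uniformly from (0.1, 0.9).
#'
#' @param config a [sim_config()] (its `methylation` block is used).
#' @param promoters optional promoter table ([promoter_regions()]); by
#'   default a synthetic promoter set on one contig is generated.
#' @return list with `cpgs` (data.frame in [read_cpg_report()] layout with
#'   `sample_id`), `groups` (named list of sample IDs per group),
#'   `promoters`, and `truth` (per-promoter true level per group).
#' @export
simulate_methylation <- function(config, promoters = NULL) {
  set.seed(config$seed + 2L)
  mc <- config$methylation
  if (is.null(promoters)) {
    np <- mc$n_promoters
    start <- seq(0L, by = 2000L, length.out = np)
    promoters <- data.frame(gene_id = sprintf("prom%05d", seq_len(np)),
                            chrom = "chrM1", start = start,
                            end = start + 1000L, strand = "+",
                            stringsAsFactors = FALSE)
  }
  np <- nrow(promoters)
  n_diff <- min(mc$n_differential, np)
  pi_a <- stats::runif(np, 0.1, 0.9)
  pi_b <- pi_a
  if (n_diff > 0) {
    d <- seq_len(n_diff)
    half <- d[seq_len(n_diff %/% 2)]
    pi_a[d] <- mc$level_low; pi_b[d] <- mc$level_high
    pi_a[half] <- mc$level_high; pi_b[half] <- mc$level_low
  }
  groups <- list(
    groupA = sprintf("methA_r%d", seq_len(mc$samples_per_group)),
    groupB = sprintf("methB_r%d", seq_len(mc$samples_per_group)))
  truth <- data.frame(gene_id = promoters$gene_id, level_groupA = pi_a,
                      level_groupB = pi_b,
                      differential = seq_len(np) <= n_diff,
                      stringsAsFactors = FALSE)
  rows <- list()
  for (grp in names(groups)) {
    pi <- if (grp == "groupA") pi_a else pi_b
    for (smp in groups[[grp]]) {
      for (i in seq_len(np)) {
        ncpg <- mc$cpgs_per_promoter
        # CpGs spread evenly inside the promoter (1-based report positions)
        pos1 <- promoters$start[i] +
          round(seq(50, 950, length.out = ncpg) / 1000 *
                  (promoters$end[i] - promoters$start[i])) + 1L
        depth <- stats::rpois(ncpg, mc$depth_mean)
        mC <- stats::rbinom(ncpg, depth, pi[i])
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = smp, chrom = promoters$chrom[i], position = pos1,
          strand = "+", count_methylated = mC,
          count_unmethylated = depth - mC, stringsAsFactors = FALSE)
      }
    }
  }
  list(cpgs = do.call(rbind, rows), groups = groups, promoters = promoters,
       truth = truth)
}

#' Simulate a GMT-like term map over the proxy gene universe
#'
#' Random terms plus two terms concentrated on the planted convergent sets,
#' so the enrichment stage has signal to find.
#'
#' @param truth orthology truth from [simulate_counts()].
#' @param config the same [sim_config()].
#' @param n_terms number of random background terms.
#' @param term_size size of each random term.
#' @return a `term_map`.
#' @export
simulate_term_map <- function(truth, config, n_terms = 30, term_size = 50) {
  set.seed(config$seed + 3L)
  universe <- truth$orthology[[1]]
  ids <- c(sprintf("TERM%03d", seq_len(n_terms)), "TERM_UP", "TERM_DOWN")
  nms <- c(sprintf("random term %d", seq_len(n_terms)),
           "planted up programme", "planted down programme")
  members <- lapply(seq_len(n_terms), function(i)
    sort(sample(universe, term_size)))
  members <- c(members,
               list(sort(c(truth$convergent_up,
                           sample(universe, 20))),
                    sort(c(truth$convergent_down,
                           sample(universe, 20)))))
  names(members) <- ids
  structure(list(term_id = ids, term_name = nms, members = members),
            class = "term_map")
}
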