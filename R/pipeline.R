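# End-to-end orchestration: simulate (or read) inputs, derive orthologues,
# normalize, describe, test, call convergence, enrich, score methylation,
# and emit a machine-readable run report with file checksums.

default_params <- function() {
  list(evalue_cutoff = 1e-5, logratio_trim = 0.30, abs_trim = 0.05,
       reference_sample = "auto", lfc_threshold = 1, fdr_threshold = 0.05,
       min_support = NULL, dispersion = "auto", pseudocount = 1,
       span = 1000, min_cpg = 2, min_depth_exclusive = 5,
       enrich_fdr = 0.05, linkage = "complete",
       include_other_focal = FALSE)
}

#' Load and validate a pipeline configuration
#'
#' @param config a list, or the path of a YAML file with the same structure:
#'   `seed`, `outdir`, `tissue`, either a `simulate` block of
#'   [sim_config()] fields or an `inputs` block of file paths
#'   (`counts`, `gene_tables`, `hit_tables` per species / species pair,
#'   optional `cpg_reports` + `cpg_groups`, optional `term_map`), a
#'   `species` block (`focal`, `background` label vectors; implied in
#'   simulate mode), and an optional `params` block overriding
#'   thresholds/trims.
#' @return validated config list (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) abort_config("config needs a seed")
  if (is.null(config$outdir)) abort_config("config needs an outdir")
  config$tissue <- config$tissue %||% "tissue"
  config$params <- utils::modifyList(default_params(),
                                     config$params %||% list())
  if (is.null(config$simulate)) {
    inp <- config$inputs
    if (is.null(inp)) abort_config("config needs `simulate` or `inputs`")
    sp <- c(config$species$focal, config$species$background)
    if (length(config$species$focal) < 1 ||
        length(config$species$background) < 1)
      abort_config("config needs focal and background species")
    for (s in sp) {
      if (is.null(inp$counts[[s]]))
        abort_config(paste("no count matrix configured for species", s))
      if (is.null(inp$gene_tables[[s]]))
        abort_config(paste("no gene table configured for species", s))
    }
    paths <- c(unlist(inp$counts), unlist(inp$gene_tables),
               unlist(inp$hit_tables), unlist(inp$cpg_reports),
               inp$term_map)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      abort_config(paste("configured input file(s) missing:",
                         paste(missing, collapse = ", ")))
  }
  class(config) <- c("pipeline_config", "list")
  config
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full convergence pipeline
#'
#' Stage order: inputs (simulated or read) -> longest isoform + RBH ->
#' 1:1 orthologues -> joined counts -> expression filter -> RPK + TMM
#' (GeTMM) -> log2/PCA/Spearman clustering -> per-pair NB exact tests ->
#' shared and convergent DEG sets -> over-representation -> promoter
#' methylation. Every stage output is written under `outdir`; the run
#' report (JSON) carries per-stage counts, DEG tallies per comparison,
#' convergence counts, planted-truth scores when simulating, and an md5
#' manifest of all artifacts. Deterministic given the config (seed
#' included).
#'
#' @param config see [pipeline_config()].
#' @return the run report, invisibly (also written to
#'   `outdir/report.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  p <- cfg$params
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(tissue = cfg$tissue, seed = cfg$seed, parameters = p,
                 stages = list())
  truth <- NULL; meth_sim <- NULL; term_map <- NULL

  ## ---- stage: inputs ------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_counts(scfg)
    hits <- simulate_hit_tables(sim$truth, scfg)
    meth_sim <- simulate_methylation(scfg)
    term_map <- simulate_term_map(sim$truth, scfg)
    truth <- sim$truth
    focal <- sim$focal
    background <- setdiff(sim$species, focal)
    species <- sim$species
    indir <- file.path(outdir, "inputs")
    dir.create(indir, showWarnings = FALSE)
    count_paths <- gene_paths <- stats::setNames(character(0), character(0))
    for (s in species) {
      cp <- file.path(indir, paste0("counts_", s, ".tsv"))
      write_count_matrix(sim$counts[[s]], cp)
      count_paths[s] <- cp
      gp <- file.path(indir, paste0("genes_", s, ".tsv"))
      write_gene_table(sim$gene_tables[[s]], gp)
      gene_paths[s] <- gp
    }
    hit_paths <- stats::setNames(character(0), character(0))
    for (key in names(hits)) {
      hp <- file.path(indir, paste0("hits_", gsub("\\|", "_", key), ".tsv"))
      write_hit_table(hits[[key]], hp)
      hit_paths[key] <- hp
    }
    cpg_paths <- stats::setNames(character(0), character(0))
    for (smp in unique(meth_sim$cpgs$sample_id)) {
      mp <- file.path(indir, paste0("cpg_", smp, ".tsv"))
      write_cpg_report(meth_sim$cpgs[meth_sim$cpgs$sample_id == smp, ], mp)
      cpg_paths[smp] <- mp
    }
    tm_path <- file.path(indir, "terms.gmt")
    write_term_map(term_map, tm_path)
    write_tsv(truth$orthology, file.path(indir, "truth_orthology.tsv"))
    writeLines(c(paste0("up\t", paste(truth$convergent_up, collapse = ",")),
                 paste0("down\t", paste(truth$convergent_down, collapse = ","))),
               file.path(indir, "truth_convergent.tsv"))
    cpg_groups <- meth_sim$groups
  } else {
    focal <- cfg$species$focal
    background <- cfg$species$background
    species <- c(focal, background)
    count_paths <- unlist(cfg$inputs$counts)[species]
    gene_paths <- unlist(cfg$inputs$gene_tables)[species]
    hit_paths <- unlist(cfg$inputs$hit_tables)
    cpg_paths <- unlist(cfg$inputs$cpg_reports %||% list())
    tm_path <- cfg$inputs$term_map
    cpg_groups <- cfg$inputs$cpg_groups %||% NULL
  }
  if (length(focal) < 2)
    abort_config("convergence needs at least 2 focal species")

  counts <- lapply(species, function(s)
    read_count_matrix(count_paths[[s]], s, cfg$tissue))
  names(counts) <- species
  gene_tables <- lapply(species, function(s) read_gene_table(gene_paths[[s]]))
  names(gene_tables) <- species
  report$stages$inputs <- list(
    species = as.list(stats::setNames(
      vapply(counts, function(x) ncol(x$counts), 0L), species)),
    genes = as.list(stats::setNames(
      vapply(counts, function(x) nrow(x$counts), 0L), species)))

  ## ---- stage: orthology --------------------------------------------
  rbh_sets <- list()
  for (i in seq_along(species)) for (j in seq_along(species)) {
    if (i >= j) next
    a <- species[i]; b <- species[j]
    key_ab <- paste(a, b, sep = "|"); key_ba <- paste(b, a, sep = "|")
    get_hits <- function(key) {
      if (is.null(hit_paths[[key]]))
        abort_config(paste("no hit table for pair", key))
      suppressMessages(read_hit_table(hit_paths[[key]], p$evalue_cutoff))
    }
    rbh_sets[[key_ab]] <- reciprocal_best_hits(get_hits(key_ab),
                                               get_hits(key_ba))
  }
  # gene-level hits assumed: map isoforms to genes would happen upstream;
  # representative isoform choice is still validated here
  reps <- lapply(gene_tables, select_longest_isoform)
  orth <- one_to_one_orthologues(rbh_sets, species, tissue = cfg$tissue)
  write_orthologue_map(orth, file.path(outdir, "orthologues.tsv"))
  report$stages$orthology <- list(
    n_orthogroups = nrow(orth),
    rbh_pairs = as.list(stats::setNames(
      vapply(rbh_sets, nrow, 0L), names(rbh_sets))))
  if (nrow(orth) == 0) abort_validation("no 1:1 orthogroups found")

  ## ---- stage: join + filter + normalize ----------------------------
  proxy <- orth[[species[1]]]
  joined <- do.call(cbind, lapply(species, function(s) {
    m <- counts[[s]]$counts[orth[[s]], , drop = FALSE]
    rownames(m) <- proxy
    m
  }))
  species_of <- stats::setNames(
    rep(species, vapply(counts, function(x) ncol(x$counts), 0L)),
    unlist(lapply(counts, function(x) colnames(x$counts))))
  filtered <- filter_low_expressed(joined, species_of)
  report$stages$filter <- list(genes_in = nrow(joined),
                               genes_kept = nrow(filtered))
  if (nrow(filtered) < 2) abort_validation("too few genes after filtering")

  # species-specific gene lengths on orthologue rows
  lengths_of <- lapply(species, function(s) {
    tbl <- gene_tables[[s]]
    rep_tbl <- tbl[tbl$isoform_id %in% reps[[s]], ]
    stats::setNames(rep_tbl$end - rep_tbl$start, rep_tbl$gene_id)
  })
  names(lengths_of) <- species
  kept_idx <- match(rownames(filtered), proxy)
  rpk_mat <- do.call(cbind, lapply(species, function(s) {
    g <- orth[[s]][kept_idx]
    cols <- names(species_of)[species_of == s]
    rpk(filtered[, cols, drop = FALSE], unname(lengths_of[[s]][g]))
  }))
  rpk_mat <- rpk_mat[, colnames(filtered), drop = FALSE]
  params_tmm <- tmm_params(p$logratio_trim, p$abs_trim, p$reference_sample)
  norm <- getmm_from_rpk(rpk_mat, params_tmm)
  write_tsv(data.frame(gene_id = rownames(norm$values), norm$values,
                       check.names = FALSE),
            file.path(outdir, "normalized.tsv"))
  jsonlite::write_json(
    list(scaling_factors = as.list(norm$scaling_factors),
         library_sizes = as.list(norm$library_sizes)),
    file.path(outdir, "factors.json"), auto_unbox = TRUE, digits = NA)
  report$stages$normalization <- list(
    factor_range = range(norm$scaling_factors))

  ## ---- stage: descriptive ------------------------------------------
  lg <- log_transform(norm, pseudocount = p$pseudocount)
  pca <- pca_samples(lg)
  clus <- cluster_samples(lg, linkage = p$linkage)
  write_tsv(data.frame(sample_id = rownames(pca$scores),
                       species = unname(species_of[rownames(pca$scores)]),
                       pca$scores[, seq_len(min(5, ncol(pca$scores)))],
                       check.names = FALSE),
            file.path(outdir, "pca_scores.tsv"))
  write_tsv(data.frame(sample_id = rownames(clus$correlation),
                       clus$correlation, check.names = FALSE),
            file.path(outdir, "correlation.tsv"))
  writeLines(clus$newick, file.path(outdir, "dendrogram.nwk"))
  report$stages$descriptive <- list(
    pc1_var = pca$variance_explained[1],
    pc2_var = pca$variance_explained[2])

  ## ---- stage: differential expression ------------------------------
  # Tests run on count-scale values: raw counts with the per-gene,
  # per-species length bias divided out (count * gm_length / length), so
  # cross-species fold changes are length-free but totals keep the full
  # counting information the exact test needs. Effective library sizes are
  # the adjusted column sums times the (RPK-based) TMM factors.
  len_mat <- do.call(cbind, lapply(species, function(s)
    unname(lengths_of[[s]][orth[[s]][kept_idx]])))
  gm_len <- exp(rowMeans(log(len_mat)))
  adj_counts <- do.call(cbind, lapply(seq_along(species), function(si) {
    cols <- names(species_of)[species_of == species[si]]
    filtered[, cols, drop = FALSE] * (gm_len / len_mat[, si])
  }))
  adj_counts <- adj_counts[, colnames(filtered), drop = FALSE]
  eff_libs <- colSums(adj_counts) * norm$scaling_factors[colnames(adj_counts)]
  de_dir <- file.path(outdir, "de")
  dir.create(de_dir, showWarnings = FALSE)
  de_counts <- list()
  deg_sets <- list()
  for (f in focal) {
    others <- if (isTRUE(p$include_other_focal))
      setdiff(species, f) else background
    deg_sets[[f]] <- list()
    for (b in others) {
      ca <- adj_counts[, names(species_of)[species_of == f], drop = FALSE]
      cb <- adj_counts[, names(species_of)[species_of == b], drop = FALSE]
      sfa <- eff_libs[colnames(ca)]; sfb <- eff_libs[colnames(cb)]
      phi <- if (identical(p$dispersion, "auto")) {
        estimate_common_dispersion(cbind(ca, cb),
                                   rep(c("a", "b"), c(ncol(ca), ncol(cb))),
                                   c(sfa, sfb))
      } else as.numeric(p$dispersion)
      de <- de_table(ca, cb, phi, sfa, sfb,
                     lfc_threshold = p$lfc_threshold,
                     fdr_threshold = p$fdr_threshold,
                     comparison = c(f, b, cfg$tissue))
      write_tsv(de, file.path(de_dir, sprintf("%s_vs_%s.tsv", f, b)))
      degs <- call_degs(de, p$lfc_threshold, p$fdr_threshold)
      deg_sets[[f]][[b]] <- degs
      de_counts[[sprintf("%s_vs_%s", f, b)]] <-
        list(up = length(degs$up), down = length(degs$down),
             dispersion = phi)
    }
  }
  report$stages$diffexp <- de_counts

  ## ---- stage: convergence ------------------------------------------
  min_support <- p$min_support %||% length(deg_sets[[focal[1]]])
  sh <- lapply(focal[1:2], function(f) {
    s <- list(up = shared_degs(deg_sets[[f]], "up", min_support),
              down = shared_degs(deg_sets[[f]], "down", min_support))
    attr(s, "background") <- names(deg_sets[[f]])
    s
  })
  conv <- convergent_genes(sh[[1]], sh[[2]], tissue = cfg$tissue)
  write_tsv(data.frame(gene_id = conv$convergent_up),
            file.path(outdir, "convergent_up.tsv"))
  write_tsv(data.frame(gene_id = conv$convergent_down),
            file.path(outdir, "convergent_down.tsv"))
  conv_summary <- list(
    shared = stats::setNames(list(
      list(up = length(conv$shared_up_focal1),
           down = length(conv$shared_down_focal1)),
      list(up = length(conv$shared_up_focal2),
           down = length(conv$shared_down_focal2))), focal[1:2]),
    convergent_up = length(conv$convergent_up),
    convergent_down = length(conv$convergent_down))
  if (!is.null(truth)) {
    sc <- score_convergence(
      list(up = conv$convergent_up, down = conv$convergent_down),
      list(up = truth$convergent_up, down = truth$convergent_down))
    conv_summary$truth_score <- sc
  }
  jsonlite::write_json(conv_summary, file.path(outdir, "convergence.json"),
                       auto_unbox = TRUE, digits = NA)
  report$stages$convergence <- conv_summary

  ## ---- stage: enrichment -------------------------------------------
  if (!is.null(tm_path) || !is.null(term_map)) {
    if (is.null(term_map)) term_map <- read_term_map(tm_path)
    universe <- rownames(counts[[species[1]]]$counts)
    enr <- list()
    for (dirn in c("up", "down")) {
      study <- conv[[paste0("convergent_", dirn)]]
      tab <- if (length(study) > 0)
        over_representation(study, term_map, universe)
      else over_representation(character(0), term_map, universe)
      write_tsv(tab, file.path(outdir, paste0("enrichment_", dirn, ".tsv")))
      enr[[dirn]] <- list(tested = nrow(tab),
                          significant = sum(tab$fdr < p$enrich_fdr))
    }
    report$stages$enrichment <- enr
  }

  ## ---- stage: methylation ------------------------------------------
  if (length(cpg_paths) > 0 && !is.null(cpg_groups)) {
    cpgs <- do.call(rbind, lapply(names(cpg_paths), function(smp)
      read_cpg_report(cpg_paths[[smp]], smp)))
    promoters <- if (!is.null(meth_sim)) meth_sim$promoters else {
      g1 <- gene_tables[[species[1]]]
      promoter_regions(
        g1[g1$isoform_id %in% reps[[species[1]]], ], span = p$span)
    }
    pm <- promoter_methylation(cpgs, promoters, p$min_cpg,
                               p$min_depth_exclusive)
    write_tsv(pm$levels, file.path(outdir, "methylation_levels.tsv"))
    ga <- cpg_groups[[1]]; gb <- cpg_groups[[2]]
    dm <- differential_methylation(
      pm$levels[pm$levels$sample_id %in% ga, ],
      pm$levels[pm$levels$sample_id %in% gb, ])
    write_tsv(dm$tests, file.path(outdir, "methylation_tests.tsv"))
    report$stages$methylation <- list(
      promoters_reported = length(unique(pm$levels$gene_id)),
      promoters_excluded = length(unique(pm$excluded$gene_id)),
      tested = nrow(dm$tests),
      significant = sum(dm$tests$p_value < 0.05))
  }

  ## ---- report -------------------------------------------------------
  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "report.json"]
  sums <- tools::md5sum(files)
  report$manifest <- as.list(stats::setNames(
    unname(sums), sub(paste0("^", outdir, "/?"), "", names(sums))))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
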