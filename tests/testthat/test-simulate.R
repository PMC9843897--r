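test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_counts(small_sim_cfg(seed = 13))
  b <- simulate_counts(small_sim_cfg(seed = 13))
  expect_identical(a, b)
  c <- simulate_counts(small_sim_cfg(seed = 14))
  expect_false(identical(a$counts[[1]]$counts, c$counts[[1]]$counts))

  cfg <- small_sim_cfg(seed = 13)
  expect_identical(simulate_hit_tables(a$truth, cfg),
                   simulate_hit_tables(b$truth, cfg))
  expect_identical(simulate_methylation(cfg), simulate_methylation(cfg))
})

test_that("config validation", {
  expect_error(sim_config(), class = "convexpr_config_error")  # seed mandatory
  expect_error(sim_config(seed = 1, effect_log2fc = 0),
               class = "convexpr_config_error")
  expect_error(sim_config(seed = 1, n_genes = 10, n_convergent_up = 8,
                          n_convergent_down = 8),
               class = "convexpr_config_error")
})

test_that("planted genes shift focal means by about the planted effect", {
  cfg <- sim_config(n_species = 4, n_genes = 500, samples_per_species = 4,
                    n_convergent_up = 25, n_convergent_down = 25,
                    effect_log2fc = 2, divergent_fraction = 0,
                    species_effect_sd = 0, seed = 15)
  sim <- simulate_counts(cfg)
  idx_up <- match(sim$truth$convergent_up, sim$truth$orthology[[1]])
  # relative expression within species: planted-up genes should sit ~2^2
  # higher in a focal species than in a background species
  cpm <- function(cm) sweep(cm$counts, 2, colSums(cm$counts), "/") * 1e6
  f <- rowMeans(cpm(sim$counts[[1]]))          # focal
  b <- rowMeans(cpm(sim$counts[[4]]))          # background
  # lengths differ per species; compare length-corrected abundances
  fr <- f / sim$truth$lengths[[1]]; br <- b / sim$truth$lengths[[4]]
  idx_down <- match(sim$truth$convergent_down, sim$truth$orthology[[1]])
  # normalize against the null-gene median ratio: planting 50/500 genes at
  # 4x shifts the per-million composition, which is exactly what the TMM
  # stage exists to absorb downstream
  med_null <- median((fr / br)[-c(idx_up, idx_down)])
  ratio <- (fr[idx_up] / br[idx_up]) / med_null
  expect_lt(abs(median(log2(ratio)) - 2), 0.2)
  expect_gt(mean(ratio > 4 * 0.6 & ratio < 4 * 1.6), 0.8)
  ratio_dn <- (fr[idx_down] / br[idx_down]) / med_null
  expect_lt(abs(median(log2(ratio_dn)) + 2), 0.2)
})

test_that("hit tables reconstruct the planted orthology exactly", {
  cfg <- small_sim_cfg(seed = 16)
  sim <- simulate_counts(cfg)
  hits <- simulate_hit_tables(sim$truth, cfg, decoy_fraction = 0.3)
  sp <- sim$species
  rbh <- list()
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    if (i >= j) next
    ab <- hits[[paste(sp[i], sp[j], sep = "|")]]
    ba <- hits[[paste(sp[j], sp[i], sep = "|")]]
    # decoys live at evalue >= 1e-7 > true hits at 1e-50; E filter at 1e-5
    # removes some, best-hit ranking removes the rest
    ab <- ab[ab$evalue <= 1e-5, ]; ba <- ba[ba$evalue <= 1e-5, ]
    rbh[[paste(sp[i], sp[j], sep = "|")]] <- reciprocal_best_hits(ab, ba)
  }
  m <- one_to_one_orthologues(rbh, sp)
  want <- sim$truth$orthology[order(sim$truth$orthology[[1]]), ]
  rownames(want) <- NULL
  attr(m, "tissue") <- NULL
  expect_identical(m, want)
})

test_that("methylation generator respects truth levels and depth filter", {
  cfg <- small_sim_cfg(seed = 17)
  ms <- simulate_methylation(cfg)
  pm <- promoter_methylation(ms$cpgs, ms$promoters)
  # estimated level close to truth per group (depth_mean 30 x 10 CpGs)
  lv <- pm$levels[pm$levels$sample_id == ms$groups$groupA[1], ]
  tr <- ms$truth$level_groupA[match(lv$gene_id, ms$truth$gene_id)]
  expect_lt(median(abs(lv$level - tr)), 0.05)

  # very shallow depth -> most promoters unreported
  cfg2 <- small_sim_cfg(seed = 18,
                        methylation = list(n_promoters = 40, depth_mean = 3))
  ms2 <- simulate_methylation(cfg2)
  pm2 <- promoter_methylation(ms2$cpgs, ms2$promoters)
  n_possible <- nrow(ms2$promoters) *
    length(unlist(ms2$groups, use.names = FALSE))
  expect_lt(nrow(pm2$levels), 0.5 * n_possible)
})

test_that("null world yields uniform DE p-values", {
  cfg <- sim_config(n_species = 2, n_focal = 1, samples_per_species = 4,
                    n_genes = 2000, n_convergent_up = 0,
                    n_convergent_down = 0, effect_log2fc = 1,
                    species_effect_sd = 0, divergent_fraction = 0,
                    dispersion = 0, seed = 19)
  sim <- simulate_counts(cfg)
  # counts scale with species-specific gene length; divide the length
  # factor out (as the pipeline does) so the two species are exchangeable
  la <- sim$truth$lengths[[1]]; lb <- sim$truth$lengths[[2]]
  gm <- sqrt(la * lb)
  a <- sim$counts[[1]]$counts * (gm / la)
  b <- sim$counts[[2]]$counts * (gm / lb)
  de <- exact_test_nb(a, b, phi = 0)
  ks <- suppressWarnings(ks.test(de$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})
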