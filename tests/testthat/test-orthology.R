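test_that("longest isoform selection is deterministic, ties break lexicographically", {
  tbl <- toy_gene_table()
  sel <- select_longest_isoform(tbl)
  expect_identical(sel[["g1"]], "g1.t2")  # 300 aa beats 120 aa
  expect_identical(sel[["g2"]], "g2.t1")  # single isoform

  tie <- data.frame(gene_id = "g", isoform_id = c("g.b", "g.a"),
                    chrom = "chr1", start = 0L, end = 10L, strand = "+",
                    protein_length = c(200L, 200L))
  expect_identical(unname(select_longest_isoform(tie)["g"]), "g.a")
  # invariant under row permutation
  set.seed(1)
  for (i in 1:5) {
    perm <- tbl[sample(nrow(tbl)), ]
    expect_identical(select_longest_isoform(perm), sel)
  }
})

test_that("reciprocal best hits match forced example and are symmetric", {
  ab <- data.frame(qseqid = c("a1", "a2"), sseqid = c("b1", "b1"),
                   pident = 90, length = 100, mismatch = 1, gapopen = 0,
                   qstart = 1, qend = 9, sstart = 1, send = 9,
                   evalue = c(1e-50, 1e-20), bitscore = c(500, 300))
  ba <- ab[1, ]; ba$qseqid <- "b1"; ba$sseqid <- "a1"
  r <- reciprocal_best_hits(ab, ba)
  expect_equal(r$gene_a, "a1")
  expect_equal(r$gene_b, "b1")

  empty <- ab[0, ]
  expect_equal(nrow(reciprocal_best_hits(empty, empty)), 0)
})

test_that("RBH equals the double-loop oracle on random tables", {
  set.seed(77)
  for (i in 1:15) {
    ab <- random_hit_table(20, 20, "a", "b")
    ba <- random_hit_table(20, 20, "b", "a")
    got <- reciprocal_best_hits(ab, ba)
    expect_identical(sort(paste(got$gene_a, got$gene_b)), oracle_rbh(ab, ba))
    # symmetry: swap directions, reverse pairs
    rev <- reciprocal_best_hits(ba, ab)
    expect_setequal(paste(got$gene_a, got$gene_b),
                    paste(rev$gene_b, rev$gene_a))
  }
})

test_that("1:1 orthologues require a full clique", {
  pair <- function(a, b) data.frame(gene_a = a, gene_b = b,
                                    stringsAsFactors = FALSE)
  # fully linked triple -> one row
  rbh <- list("A|B" = pair("a1", "b1"), "A|C" = pair("a1", "c1"),
              "B|C" = pair("b1", "c1"))
  m <- one_to_one_orthologues(rbh, c("A", "B", "C"))
  expect_equal(nrow(m), 1)
  expect_equal(unlist(m[1, ], use.names = FALSE), c("a1", "b1", "c1"))

  # missing A-C link -> no row (clique required, no transitive chaining)
  rbh2 <- list("A|B" = pair("a1", "b1"), "A|C" = pair("a1", "c9"),
               "B|C" = pair("b1", "c1"))
  expect_equal(nrow(one_to_one_orthologues(rbh2, c("A", "B", "C"))), 0)

  # missing species pair -> configuration error
  expect_error(one_to_one_orthologues(rbh[1:2], c("A", "B", "C")),
               class = "convexpr_config_error")
})

test_that("clique rule matches brute-force enumeration on random graphs", {
  set.seed(99)
  species <- c("A", "B", "C", "D")
  genes <- lapply(species, function(s) sprintf("%s%d", tolower(s), 1:6))
  names(genes) <- species
  for (rep in 1:10) {
    # random partial matchings per species pair
    rbh <- list()
    for (i in 1:3) for (j in (i + 1):4) {
      a <- species[i]; b <- species[j]
      n <- sample(3:6, 1)
      ga <- sample(genes[[a]], n); gb <- sample(genes[[b]], n)
      rbh[[paste(a, b, sep = "|")]] <-
        data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
    }
    got <- one_to_one_orthologues(rbh, species)
    # oracle: test all 6^4 tuples for the all-pairs-linked property
    linked <- function(sa, ga, sb, gb) {
      p <- rbh[[paste(sa, sb, sep = "|")]]
      any(p$gene_a == ga & p$gene_b == gb)
    }
    want <- list()
    for (g1 in genes$A) for (g2 in genes$B) for (g3 in genes$C)
      for (g4 in genes$D) {
        tup <- c(g1, g2, g3, g4)
        ok <- TRUE
        for (i in 1:3) for (j in (i + 1):4) {
          if (!linked(species[i], tup[i], species[j], tup[j])) ok <- FALSE
        }
        if (ok) want[[length(want) + 1]] <- tup
      }
    want <- if (length(want)) do.call(rbind, want) else
      matrix(character(0), 0, 4)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      got_m <- as.matrix(got)
      dimnames(got_m) <- NULL; dimnames(want) <- NULL
      expect_identical(got_m[order(got_m[, 1]), , drop = FALSE],
                       want[order(want[, 1]), , drop = FALSE])
    }
  }
})

test_that("orthologue rows shrink monotonically as species are added", {
  cfg <- small_sim_cfg(seed = 5)
  sim <- simulate_counts(cfg)
  hits <- simulate_hit_tables(sim$truth, cfg)
  rbh <- list()
  sp <- sim$species
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    if (i >= j) next
    key <- paste(sp[i], sp[j], sep = "|")
    rbh[[key]] <- reciprocal_best_hits(
      hits[[key]], hits[[paste(sp[j], sp[i], sep = "|")]])
  }
  sizes <- vapply(2:length(sp), function(k)
    nrow(one_to_one_orthologues(rbh, sp[1:k])), 0L)
  expect_true(all(diff(sizes) <= 0))
})
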