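# 1:1 single-copy orthology via reciprocal best hits (RBH).
#
# One representative protein (the longest isoform) is kept per gene; for
# every unordered species pair the best protein hit in each direction is
# computed and pairs that are mutually best become RBH pairs; genes whose
# pairwise links form a complete clique across all species (one gene per
# species) become orthogroup rows. The clique rule — rather than transitive
# chaining — is what guarantees strict 1:1 single-copy semantics.

#' Select the longest isoform per gene
#'
#' Exactly one isoform is retained per gene: the one with the greatest
#' `protein_length`. Ties are broken by the lexicographically smallest
#' `isoform_id`, so the result is invariant under input row order.
#'
#' @param records gene table data.frame ([read_gene_table()]).
#' @return named character vector: `gene_id` -> chosen `isoform_id`.
#' @export
select_longest_isoform <- function(records) {
  if (nrow(records) == 0) abort_validation("empty gene record list")
  ord <- order(records$gene_id,
               -records$protein_length,
               records$isoform_id,
               method = "radix")
  r <- records[ord, ]
  first <- !duplicated(r$gene_id)
  stats::setNames(r$isoform_id[first], r$gene_id[first])
}

# Best hit per query: lowest evalue, then highest bitscore, then
# lexicographically smallest subject.
best_hits <- function(hits) {
  if (nrow(hits) == 0)
    return(stats::setNames(character(0), character(0)))
  ord <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid,
               method = "radix")
  h <- hits[ord, ]
  first <- !duplicated(h$qseqid)
  stats::setNames(h$sseqid[first], h$qseqid[first])
}

#' Reciprocal best hits between two species
#'
#' @param hits_ab hit table with species-A queries and species-B subjects,
#'   already E-value filtered ([read_hit_table()]).
#' @param hits_ba the reverse-direction table.
#' @return data.frame with columns `gene_a`, `gene_b`, one row per RBH pair,
#'   sorted by `gene_a`. "Best" means lowest evalue, ties broken by highest
#'   bitscore then lexicographic subject ID, so the output is deterministic
#'   under permutation of the input rows.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  ab <- best_hits(hits_ab)   # a -> best b
  ba <- best_hits(hits_ba)   # b -> best a
  a <- names(ab)
  keep <- !is.na(ba[ab]) & ba[ab] == a
  out <- data.frame(gene_a = a[keep], gene_b = unname(ab[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect pairwise RBH sets into 1:1 single-copy orthogroups
#'
#' A row (one gene per species) is emitted iff every one of the
#' `choose(k, 2)` pairwise links inside the tuple is an RBH pair. Because a
#' gene can appear in at most one RBH pair per species pair (best hits are
#' unique), rows cannot conflict.
#'
#' @param rbh_sets named list of RBH data.frames from
#'   [reciprocal_best_hits()]; names are `"A|B"` for each unordered species
#'   pair, with `gene_a` from species `A` and `gene_b` from species `B`.
#' @param species_ids character vector of all species labels.
#' @param tissue optional tissue label stored as an attribute.
#' @return data.frame with one column per species (named by `species_ids`),
#'   one row per 1:1 orthogroup, sorted by the first species' gene IDs.
#' @export
one_to_one_orthologues <- function(rbh_sets, species_ids, tissue = NA) {
  k <- length(species_ids)
  if (k < 2) abort_config("need at least 2 species")
  pair_key <- function(a, b) paste(a, b, sep = "|")
  # normalize access: partner(sp_x, sp_y) as named lookup vectors
  lut <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- species_ids[i]; b <- species_ids[j]
    key <- pair_key(a, b); rev_key <- pair_key(b, a)
    if (!is.null(rbh_sets[[key]])) {
      p <- rbh_sets[[key]]
    } else if (!is.null(rbh_sets[[rev_key]])) {
      p <- rbh_sets[[rev_key]][, c("gene_b", "gene_a")]
      names(p) <- c("gene_a", "gene_b")
    } else {
      abort_config(sprintf("missing RBH set for species pair %s / %s", a, b))
    }
    lut[[key]] <- stats::setNames(p$gene_b, p$gene_a)
    lut[[rev_key]] <- stats::setNames(p$gene_a, p$gene_b)
  }
  anchor <- species_ids[1]
  seeds <- names(lut[[pair_key(anchor, species_ids[2])]])
  rows <- lapply(seeds, function(g1) {
    tuple <- character(k)
    tuple[1] <- g1
    for (j in 2:k) {
      partner <- lut[[pair_key(anchor, species_ids[j])]][g1]
      if (is.na(partner)) return(NULL)
      tuple[j] <- partner
    }
    # clique check on all non-anchor pairs
    if (k >= 3) for (i in 2:(k - 1)) for (j in (i + 1):k) {
      p <- lut[[pair_key(species_ids[i], species_ids[j])]][tuple[i]]
      if (is.na(p) || p != tuple[j]) return(NULL)
    }
    tuple
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), k), species_ids))
  } else {
    out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(out) <- species_ids
    out <- out[order(out[[1]]), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "tissue") <- tissue
  out
}

#' Write an orthologue map as TSV (one column per species)
#' @param map orthologue map data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orthologue_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
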