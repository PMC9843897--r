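# Readers and writers for the on-disk formats the pipeline touches.
# All coordinates are normalized at read time: gene tables are BED-like
# (0-based half-open), cytosine reports are 1-based per the bismark
# convention; downstream code never converts again.

#' Construct a per-species count matrix
#'
#' Container for one species' gene-level RNA-seq counts in one tissue.
#' Counts must be non-negative integers; gene and sample identifiers must be
#' unique; at least two biological replicates are required, matching the
#' study design the downstream differential tests assume.
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param species single species label.
#' @param tissue single tissue label.
#' @return An object of class `count_matrix` with fields `counts`, `species`,
#'   `tissue`.
#' @export
count_matrix <- function(counts, species, tissue) {
  if (!is.matrix(counts)) abort_validation("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort_validation("count matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    abort_validation("duplicate gene IDs in count matrix")
  if (anyDuplicated(colnames(counts)))
    abort_validation("duplicate sample IDs in count matrix")
  if (ncol(counts) < 2)
    abort_validation("a species needs at least 2 biological replicates")
  if (anyNA(counts)) abort_validation("missing values are not permitted in counts")
  if (any(counts < 0)) abort_validation("counts must be >= 0")
  if (any(counts != round(counts))) abort_validation("counts must be integral")
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts, species = as.character(species)[1],
         tissue = as.character(tissue)[1]),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %s / %s: %d genes x %d samples\n",
              x$species, x$tissue, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Read a per-species count matrix from TSV
#'
#' Expects a header row of sample IDs, first column of gene IDs, and integer
#' cells. Row and column order are preserved.
#'
#' @param path TSV file path.
#' @inheritParams count_matrix
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, species, tissue) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) abort_format("count matrix needs a gene column and samples")
  gene_ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(m), nrow = nrow(m)))
  if (anyNA(num)) abort_format("non-numeric cell in count matrix")
  if (any(num != round(num))) abort_format("non-integer cell in count matrix")
  dimnames(num) <- list(gene_ids, colnames(df)[-1])
  count_matrix(num, species, tissue)
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_count_matrix()]; round-trips exactly.
#'
#' @param x a `count_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED-like gene/isoform table
#'
#' Columns: `gene_id`, `isoform_id`, `chrom`, `start`, `end`, `strand`,
#' `protein_length`. Coordinates are 0-based half-open; `protein_length` is
#' in amino acids and drives longest-isoform selection.
#'
#' @param path TSV file path (with header).
#' @return data.frame of validated gene records, one row per isoform.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "isoform_id", "chrom", "start", "end", "strand",
            "protein_length")
  if (!all(need %in% names(df)))
    abort_format(paste("gene table must have columns:",
                       paste(need, collapse = ", ")))
  df <- df[, need]
  validate_gene_table(df)
  df
}

validate_gene_table <- function(df) {
  if (anyNA(df)) abort_validation("gene table has missing values")
  if (!all(df$strand %in% c("+", "-")))
    abort_validation("strand must be '+' or '-'")
  if (any(df$start >= df$end))
    abort_validation("gene table requires start < end (0-based half-open)")
  if (any(df$start < 0)) abort_validation("negative coordinate in gene table")
  if (any(df$protein_length < 1))
    abort_validation("protein_length must be >= 1")
  if (anyDuplicated(df$isoform_id))
    abort_validation("duplicate isoform_id in gene table")
  invisible(df)
}

#' Write a gene table (inverse of [read_gene_table()])
#' @param df gene table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Standard 12-column dialect: qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore — no header line.
#' Hits with E-value above `evalue_cutoff` are discarded at read time.
#'
#' @param path tab-separated file, no header.
#' @param evalue_cutoff retain hits with `evalue <= evalue_cutoff`
#'   (default `1e-5`).
#' @return data.frame of retained hits with the 12 standard columns; the
#'   number read and retained is reported via `message()`.
#' @export
read_hit_table <- function(path, evalue_cutoff = 1e-5) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    warning("empty hit table: ", path)
    df <- as.data.frame(stats::setNames(
      c(list(character(), character()), rep(list(numeric()), 10)), cols))
    return(df)
  }
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) != 12)
    abort_format(sprintf("hit table must have 12 columns (found %d)", ncol(df)))
  names(df) <- cols
  if (any(df$evalue < 0)) abort_validation("negative evalue in hit table")
  if (any(df$bitscore < 0)) abort_validation("negative bitscore in hit table")
  n_in <- nrow(df)
  df <- df[df$evalue <= evalue_cutoff, , drop = FALSE]
  rownames(df) <- NULL
  message(sprintf("hit table %s: retained %d / %d hits at E <= %g",
                  basename(path), nrow(df), n_in, evalue_cutoff))
  df
}

#' Write a 12-column hit table (no header)
#' @param df hit table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-sample CpG cytosine report
#'
#' Bismark-style subset with header: `chrom`, `position` (1-based),
#' `strand`, `count_methylated`, `count_unmethylated`. One line per
#' cytosine; duplicates of (chrom, position, strand) are rejected.
#'
#' @param path TSV file path.
#' @param sample_id label attached to every record.
#' @return data.frame with columns `sample_id`, `chrom`, `position`,
#'   `strand`, `count_methylated`, `count_unmethylated`.
#' @export
read_cpg_report <- function(path, sample_id) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "position", "strand", "count_methylated",
            "count_unmethylated")
  if (!all(need %in% names(df)))
    abort_format(paste("cytosine report must have columns:",
                       paste(need, collapse = ", ")))
  df <- df[, need]
  if (anyNA(df)) abort_validation("cytosine report has missing values")
  if (any(df$position < 1))
    abort_validation("cytosine positions are 1-based (>= 1)")
  if (any(df$count_methylated < 0) || any(df$count_unmethylated < 0))
    abort_validation("negative read count in cytosine report")
  key <- paste(df$chrom, df$position, df$strand)
  if (anyDuplicated(key))
    abort_validation("duplicate (chrom, position, strand) in cytosine report")
  cbind(sample_id = as.character(sample_id)[1], df,
        stringsAsFactors = FALSE)
}

#' Write a cytosine report (inverse of [read_cpg_report()])
#' @param df cytosine report data.frame (the `sample_id` column is dropped).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cpg_report <- function(df, path) {
  keep <- c("chrom", "position", "strand", "count_methylated",
            "count_unmethylated")
  utils::write.table(df[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT-like term map
#'
#' Tab-separated, no header: `term_id`, `term_name`, then one member gene
#' per remaining field. Terms must be unique and non-empty.
#'
#' @param path GMT-like file path.
#' @return A `term_map`: list with `term_id`, `term_name` (character
#'   vectors) and `members` (named list of gene-ID vectors).
#' @export
read_term_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3))
    abort_format("each term map line needs term_id, term_name and >= 1 member")
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) abort_validation("duplicate term_id in term map")
  nms <- vapply(parts, `[[`, character(1), 2L)
  members <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(members) <- ids
  structure(list(term_id = ids, term_name = nms, members = members),
            class = "term_map")
}

#' Write a term map in GMT-like format
#' @param tm a `term_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_term_map <- function(tm, path) {
  stopifnot(inherits(tm, "term_map"))
  lines <- vapply(seq_along(tm$term_id), function(i) {
    paste(c(tm$term_id[i], tm$term_name[i], tm$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
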