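# Over-representation analysis of a study gene set against a term map,
# with the focal species' full annotation as the default universe.

#' Hypergeometric over-representation analysis
#'
#' For each term with at least one study-set member, computes the upper-tail
#' hypergeometric probability `P[X >= k]` of drawing `k` term members in a
#' study set of size `n` from a universe of `N` genes containing `K` term
#' members (term membership intersected with the universe first), then
#' adjusts across tested terms with Benjamini-Hochberg.
#'
#' @param study_set character vector of study genes; must be a subset of
#'   `universe`.
#' @param term_map a `term_map` ([read_term_map()]).
#' @param universe character vector of background genes.
#' @param min_term_size,max_term_size optional term-size filters applied
#'   after intersection with the universe (defaults: no filtering).
#' @return data.frame with one row per tested term: `term_id`, `term_name`,
#'   `k` (overlap), `n` (study size), `K` (term size in universe),
#'   `N` (universe size), `p_value`, `fdr`; sorted by `p_value`.
#' @export
over_representation <- function(study_set, term_map, universe,
                                min_term_size = 1, max_term_size = Inf) {
  stopifnot(inherits(term_map, "term_map"))
  universe <- unique(universe)
  study_set <- unique(study_set)
  outside <- setdiff(study_set, universe)
  if (length(outside))
    abort_validation(paste("study genes outside the universe:",
                           paste(utils::head(outside, 10), collapse = ", ")))
  N <- length(universe)
  n <- length(study_set)
  rows <- lapply(seq_along(term_map$term_id), function(i) {
    members <- intersect(term_map$members[[i]], universe)
    K <- length(members)
    if (K < min_term_size || K > max_term_size) return(NULL)
    k <- length(intersect(study_set, members))
    if (k == 0) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term_map$term_id[i],
               term_name = term_map$term_name[i],
               k = k, n = n, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p_value = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
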