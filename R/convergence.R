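# Convergence calling: genes that shift in the same direction in each focal
# species against EVERY background species, intersected across the two
# focal species. This is the "shared DEG" logic behind the headline
# convergent gene sets in comparative diet-adaptation transcriptomics.

#' Direction-consistent DEGs shared across all comparisons of one focal species
#'
#' A gene qualifies iff it is a significant DEG with the requested direction
#' in at least `min_support` of the focal species' pairwise comparisons
#' (default: all of them).
#'
#' @param deg_sets list of DEG call lists ([call_degs()]), one per
#'   (focal, background) comparison, named by background species.
#' @param direction `"up"` or `"down"`.
#' @param min_support minimum number of supporting comparisons; default all.
#' @return character vector of shared gene IDs (sorted).
#' @export
shared_degs <- function(deg_sets, direction = c("up", "down"),
                        min_support = length(deg_sets)) {
  direction <- match.arg(direction)
  if (length(deg_sets) == 0) abort_config("no comparisons supplied")
  if (min_support < 1 || min_support > length(deg_sets))
    abort_config("min_support must be in [1, number of comparisons]")
  tallies <- table(unlist(lapply(deg_sets, `[[`, direction), use.names = FALSE))
  sort(names(tallies)[tallies >= min_support])
}

#' Convergent genes of two focal species
#'
#' Intersects the two focal species' shared up- and down-regulated sets.
#' Both shared sets must have been computed against the same background
#' species.
#'
#' @param shared_focal1,shared_focal2 lists with `up` and `down` character
#'   vectors ([shared_degs()] per direction), each carrying an optional
#'   `background` attribute used for the consistency check.
#' @param tissue optional tissue label.
#' @return object of class `convergence_result`: list with the per-focal
#'   shared sets, `convergent_up`, `convergent_down`, and `tissue`.
#' @export
convergent_genes <- function(shared_focal1, shared_focal2, tissue = NA) {
  b1 <- attr(shared_focal1, "background")
  b2 <- attr(shared_focal2, "background")
  if (!is.null(b1) && !is.null(b2) && !setequal(b1, b2))
    abort_config("focal species were compared against different backgrounds")
  res <- list(
    shared_up_focal1 = sort(shared_focal1$up),
    shared_down_focal1 = sort(shared_focal1$down),
    shared_up_focal2 = sort(shared_focal2$up),
    shared_down_focal2 = sort(shared_focal2$down),
    convergent_up = sort(intersect(shared_focal1$up, shared_focal2$up)),
    convergent_down = sort(intersect(shared_focal1$down, shared_focal2$down)),
    tissue = tissue
  )
  structure(res, class = "convergence_result")
}

#' @export
print.convergence_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<convergence_result>%s\n",
    "  focal 1 shared: %d up / %d down\n",
    "  focal 2 shared: %d up / %d down\n",
    "  convergent:     %d up / %d down\n"),
    if (is.na(x$tissue)) "" else paste0(" tissue=", x$tissue),
    length(x$shared_up_focal1), length(x$shared_down_focal1),
    length(x$shared_up_focal2), length(x$shared_down_focal2),
    length(x$convergent_up), length(x$convergent_down)))
  invisible(x)
}

#' Score convergence calls against a planted truth
#'
#' @param called list with `up`, `down` character vectors of called
#'   convergent genes.
#' @param truth list with `up`, `down` character vectors of planted genes.
#' @return list with `tp`, `fp`, `fn`, `sensitivity`, `fdr`. A call is a
#'   true positive only if gene and direction both match.
#' @export
score_convergence <- function(called, truth) {
  tp <- length(intersect(called$up, truth$up)) +
    length(intersect(called$down, truth$down))
  n_called <- length(called$up) + length(called$down)
  n_truth <- length(truth$up) + length(truth$down)
  fp <- n_called - tp
  fn <- n_truth - tp
  list(tp = tp, fp = fp, fn = fn,
       sensitivity = if (n_truth > 0) tp / n_truth else NA_real_,
       fdr = if (n_called > 0) fp / n_called else 0)
}
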