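# Tandem repeat finding inside individual reads -- the computational core
# that nominates ITD-bearing reads.

#' Find tandem repeats in a sequence
#'
#' For each period `p` between `min_period` and `max_period`, positions `j`
#' of `seq` are compared with positions `j + p`; every maximal run of such
#' comparisons containing at most `resolution` mismatches is a candidate.
#' Overlapping candidates of the same period are merged, and a merged run is
#' reported when its total span (run length + period) is at least `2p`,
#' i.e. the duplication is fully contained in the sequence (`copies >= 2`).
#' Runs that are exactly periodic at a proper divisor of the period
#' (homopolymers, microsatellites) are not reported at that period.
#'
#' @param seq A single DNA string.
#' @param min_period Smallest period reported, bp. Default 15 (the smallest
#'   ITD observed in practice; anchors the search to biologically plausible
#'   duplication sizes).
#' @param max_period Largest period reported, bp. Default 150.
#' @param resolution Mismatch budget per maximal run (tolerates a sequencing
#'   error or minor ITD impurity between the copies). Default 1; use 0 for
#'   exact mode. For merged overlapping runs the reported `mismatches` is
#'   counted over the union and can exceed `resolution`; each constituent
#'   maximal run respects the budget.
#'
#' @return A data frame sorted by (`start`, `period`) with columns `start`
#'   (0-based), `period`, `span`, `copies` (= span/period) and `mismatches`.
#'   A sequence shorter than `2 * min_period` yields zero rows.
#' @examples
#' find_tandem_repeats("ACGTACGT", min_period = 4)
#' @export
find_tandem_repeats <- function(seq, min_period = 15L, max_period = 150L,
                                resolution = 1L) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  stopifnot(min_period >= 1L, max_period >= min_period, resolution >= 0L)
  res <- find_repeats_cpp(toupper(seq), as.integer(min_period),
                          as.integer(max_period), as.integer(resolution))
  res$copies <- res$span / res$period
  res[, c("start", "period", "span", "copies", "mismatches")]
}

# Best qualifying repeat per read (largest span, ties by smaller start then
# smaller period) plus the longest exact-match core at the chosen period.
# Used by discover_clones(); returned as a data frame aligned with `seqs`.
best_repeats <- function(seqs, min_period = 15L, max_period = 150L,
                         resolution = 1L) {
  best_repeat_cpp(seqs, as.integer(min_period), as.integer(max_period),
                  as.integer(resolution))
}
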