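# Overlap-consensus merging of paired-end amplicon reads.

#' Merge read pairs into single amplicon-spanning reads
#'
#' Mate 2 is reverse-complemented, then, among overlaps of at least
#' `min_overlap` bases whose mismatch fraction is within
#' `max_mismatch_frac`, the overlap maximizing (matches - mismatches) is
#' chosen (ties go to the larger overlap). Overlaps over the budget never
#' compete: in ITD-bearing pairs the duplication's self-similarity at the
#' duplication lag can out-score the true overlap, and filtering first
#' keeps the true near-exact overlap ahead. At overlapped positions the
#' base with the higher Phred quality is kept (ties go to mate 1). A pair
#' with no acceptable overlap is left unmerged -- a normal, counted
#' outcome, not an error; unmerged pairs are excluded from all downstream
#' counting but appear in the QC tallies.
#'
#' @param pairs A `read_pairs` object.
#' @param min_overlap Minimum acceptable overlap, bases. Default 10.
#' @param max_mismatch_frac Maximum fraction of mismatching bases in the
#'   chosen overlap. Default 0.1.
#'
#' @return A `merged_reads` data frame with one row per input pair:
#'   `read_id`, `seq`, `qual`, `overlap_len`, `n_mismatch`, `merged`
#'   (logical; unmerged rows carry `NA` sequence).
#' @examples
#' s <- paste(sample(c("A","C","G","T"), 250, replace = TRUE), collapse = "")
#' p <- make_read_pairs("r1", substr(s, 1, 150),
#'                      as.character(itdseq:::revcomp_cpp(substr(s, 101, 250))))
#' merge_pairs(p)$overlap_len
#' @export
merge_pairs <- function(pairs, min_overlap = 10L, max_mismatch_frac = 0.1) {
  stopifnot(inherits(pairs, "read_pairs"))
  if (length(pairs) == 0L) {
    out <- data.frame(read_id = character(0), seq = character(0),
                      qual = character(0), overlap_len = integer(0),
                      n_mismatch = integer(0), merged = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("merged_reads", "data.frame")
    return(out)
  }
  res <- merge_pairs_cpp(pairs$seq1, pairs$seq2, pairs$qual1, pairs$qual2,
                         as.integer(min_overlap), max_mismatch_frac)
  out <- data.frame(read_id = pairs$read_id, seq = res$seq, qual = res$qual,
                    overlap_len = res$overlap_len,
                    n_mismatch = res$n_mismatch, merged = res$merged,
                    stringsAsFactors = FALSE)
  class(out) <- c("merged_reads", "data.frame")
  out
}

#' Merge a single read pair
#'
#' Convenience wrapper around [merge_pairs()] for one pair.
#'
#' @param seq1,seq2 Mate sequences (mate 2 in sequencing orientation).
#' @param qual1,qual2 Optional Phred-33 quality strings (default constant
#'   Q40).
#' @inheritParams merge_pairs
#' @return A one-row `merged_reads` data frame; `merged` is `FALSE` when the
#'   pair cannot be merged.
#' @export
merge_pair <- function(seq1, seq2, qual1 = NULL, qual2 = NULL,
                       min_overlap = 10L, max_mismatch_frac = 0.1) {
  p <- make_read_pairs("pair", seq1, seq2, qual1, qual2)
  merge_pairs(p, min_overlap = min_overlap,
              max_mismatch_frac = max_mismatch_frac)
}

#' Per-sample merge statistics
#'
#' @param merged A `merged_reads` data frame.
#' @return A list with `n_pairs`, `n_merged`, `merge_rate`.
#' @export
merge_stats <- function(merged) {
  list(n_pairs = nrow(merged), n_merged = sum(merged$merged),
       merge_rate = if (nrow(merged)) mean(merged$merged) else NA_real_)
}
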