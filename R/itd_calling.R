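# Reference-anchored ITD clone discovery and breakpoint counting.
#
# A clone is the unit of detection and tracking: (itd_length,
# insertion_site) plus a junction signature -- the 2*k_flank bases spanning
# the boundary where the second copy of the duplicated unit begins, present
# only on the mutant allele. All work is alignment-free: reads are anchored
# to the amplicon by exact substring matching.

# substring with 0-based half-open coordinates
sub0 <- function(s, from, to) substr(s, from + 1L, to)

#' Left-align an ITD insertion site
#'
#' The (site, unit) description of a tandem duplication is ambiguous: if
#' `ref[site-1] == ref[site-1-L]` the same mutant sequence is produced by
#' site - 1. All sites in the package are canonical, i.e. slid left until
#' that equality fails.
#'
#' @param reference An `amplicon_reference`.
#' @param insertion_site Candidate 0-based site (where the second copy
#'   begins).
#' @param itd_length Duplication length, bp.
#' @return The canonical (smallest equivalent) insertion site.
#' @export
canonical_site <- function(reference, insertion_site, itd_length) {
  s <- reference$sequence
  x <- as.integer(insertion_site)
  L <- as.integer(itd_length)
  while (x - 1L - L >= 0L &&
         substr(s, x, x) == substr(s, x - L, x - L)) {
    x <- x - 1L
  }
  x
}

#' Mutant amplicon sequence for an ITD
#'
#' Wild-type amplicon with the `itd_length` bases ending at `insertion_site`
#' duplicated, so the unit appears twice in tandem and the second copy
#' begins at `insertion_site`.
#'
#' @inheritParams canonical_site
#' @return The mutant DNA string (length = reference length + itd_length).
#' @export
mutant_sequence <- function(reference, insertion_site, itd_length) {
  s <- reference$sequence
  site <- as.integer(insertion_site)
  L <- as.integer(itd_length)
  stopifnot(site - L >= 0L, site <= nchar(s))
  paste0(sub0(s, 0L, site), sub0(s, site - L, site),
         sub0(s, site, nchar(s)))
}

#' Junction signature of an ITD clone
#'
#' The `k_flank` bases ending at the breakpoint plus the `k_flank` bases
#' starting at it, on the mutant allele: `ref[site-k, site)` followed by
#' `ref[site-L, site-L+k)`. Unique to the ITD allele; it must not occur in
#' the wild-type amplicon.
#'
#' @inheritParams canonical_site
#' @param k_flank Flank length on each side of the breakpoint. Default 12
#'   (24 matching bases: a chance match is ~4^-24).
#' @return The 2*k_flank-base signature string.
#' @export
junction_signature <- function(reference, insertion_site, itd_length,
                               k_flank = 12L) {
  s <- reference$sequence
  site <- as.integer(insertion_site)
  L <- as.integer(itd_length)
  k <- as.integer(k_flank)
  stopifnot(site - k >= 0L, site - L >= 0L, site - L + k <= nchar(s))
  paste0(sub0(s, site - k, site), sub0(s, site - L, site - L + k))
}

#' Wild-type breakpoint signature at a clone's insertion site
#'
#' The 2*k_flank wild-type bases centered on the insertion site; reads
#' containing it carry the uninterrupted wild-type allele at the site.
#'
#' @inheritParams junction_signature
#' @return The signature string; errors if it does not occur exactly once in
#'   the reference.
#' @export
wt_signature <- function(reference, insertion_site, k_flank = 12L) {
  s <- reference$sequence
  site <- as.integer(insertion_site)
  k <- as.integer(k_flank)
  stopifnot(site - k >= 0L, site + k <= nchar(s))
  sig <- sub0(s, site - k, site + k)
  n_occ <- length(gregexpr(sig, s, fixed = TRUE)[[1]])
  if (n_occ != 1L)
    stop("wild-type signature at site ", site, " occurs ", n_occ,
         " times in the reference", call. = FALSE)
  sig
}

empty_catalog <- function() {
  out <- data.frame(clone_id = character(0), itd_length = integer(0),
                    insertion_site = integer(0),
                    junction_signature = character(0),
                    wt_sig = character(0),
                    duplicated_seq = character(0), support = integer(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("itd_catalog", "data.frame")
  attr(out, "n_unanchored") <- 0L
  out
}

#' Discover ITD clones from merged reads
#'
#' Each merged read carrying a qualifying tandem repeat (fully contained
#' duplication, period within bounds) is anchored to the reference by exact
#' match of its first and last `anchor_len` bases; the two anchor offsets
#' must imply the same duplication length as the repeat period. The
#' insertion site is the anchor offset plus the repeat's exact-core start
#' plus the period, left-aligned with [canonical_site()]; the read's
#' observed duplicated unit must match the reference unit at that site
#' within one substitution. Reads are pooled by (itd_length,
#' insertion_site); keys supported by fewer than `min_support` reads are
#' dropped, and the catalog is sorted by descending support.
#'
#' Reads whose anchors do not match the reference (or disagree with the
#' repeat period) are skipped and tallied as unanchored, not guessed.
#'
#' @param merged A `merged_reads` data frame from [merge_pairs()].
#' @param reference An `amplicon_reference`.
#' @param min_period,max_period,resolution Repeat-finder parameters, see
#'   [find_tandem_repeats()].
#' @param k_flank Junction signature flank, see [junction_signature()].
#' @param anchor_len Anchor length for exact reference matching. Default 20.
#' @param min_support Minimum supporting reads for a clone at discovery
#'   (follow-up counting has no support floor; the Fisher test governs
#'   positivity). Default 5.
#' @param max_reads Optionally cap the number of merged reads scanned
#'   (deterministic head subsample); discovery needs support, not depth.
#'
#' @return An `itd_catalog` data frame: `clone_id`, `itd_length`,
#'   `insertion_site`, `junction_signature`, `wt_sig`, `duplicated_seq`,
#'   `support`; attribute `n_unanchored` counts skipped repeat-bearing
#'   reads.
#' @export
discover_clones <- function(merged, reference, min_period = 15L,
                            max_period = 150L, resolution = 1L,
                            k_flank = 12L, anchor_len = 20L,
                            min_support = 5L, max_reads = NULL) {
  stopifnot(inherits(merged, "merged_reads"),
            inherits(reference, "amplicon_reference"))
  refseq <- reference$sequence
  seqs <- merged$seq[merged$merged]
  if (!is.null(max_reads)) seqs <- head(seqs, max_reads)

  empty <- empty_catalog()
  if (length(seqs) == 0L) return(empty)

  br <- best_repeats(seqs, min_period, max_period, resolution)
  cand <- which(!is.na(br$period) & br$core_len >= br$period)
  n_unanchored <- 0L
  keys <- character(0)
  key_len <- integer(0); key_site <- integer(0)

  for (i in cand) {
    s <- seqs[i]
    m <- nchar(s)
    p <- br$period[i]
    if (m < 2L * anchor_len) { n_unanchored <- n_unanchored + 1L; next }
    a_head <- substr(s, 1L, anchor_len)
    a_tail <- substr(s, m - anchor_len + 1L, m)
    o1 <- as.integer(regexpr(a_head, refseq, fixed = TRUE)) - 1L
    o2 <- as.integer(regexpr(a_tail, refseq, fixed = TRUE)) - 1L
    if (o1 < 0L || o2 < 0L) { n_unanchored <- n_unanchored + 1L; next }
    # anchor-implied duplication length must equal the repeat period
    if ((o1 + m - anchor_len) - o2 != p) {
      n_unanchored <- n_unanchored + 1L; next
    }
    a0 <- br$core_start[i]
    site <- o1 + a0 + p
    if (site - p < 0L || site > nchar(refseq)) {
      n_unanchored <- n_unanchored + 1L; next
    }
    # observed duplicated unit must match the reference unit at this site
    unit_obs <- sub0(s, a0, a0 + p)
    unit_ref <- sub0(refseq, site - p, site)
    mm <- str_mismatches_cpp(unit_obs, unit_ref)
    if (is.na(mm) || mm > 1L) { n_unanchored <- n_unanchored + 1L; next }
    site <- canonical_site(reference, site, p)
    if (site < reference$itd_window[1] || site >= reference$itd_window[2])
      next
    keys <- c(keys, paste0(p, "@", site))
    key_len <- c(key_len, p); key_site <- c(key_site, site)
  }

  attr(empty, "n_unanchored") <- n_unanchored
  if (length(keys) == 0L) return(empty)

  tab <- table(keys)
  keep <- names(tab)[tab >= min_support]
  if (length(keep) == 0L) return(empty)

  idx <- match(keep, keys)
  out <- data.frame(
    itd_length = key_len[idx],
    insertion_site = key_site[idx],
    support = as.integer(tab[keep]),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$support, out$insertion_site, out$itd_length), ,
             drop = FALSE]
  out$clone_id <- sprintf("ITD%d@%d", out$itd_length, out$insertion_site)

  sig <- character(nrow(out)); wsig <- character(nrow(out))
  dup <- character(nrow(out)); ok <- logical(nrow(out))
  for (j in seq_len(nrow(out))) {
    js <- junction_signature(reference, out$insertion_site[j],
                             out$itd_length[j], k_flank)
    # the junction must be unique to the mutant allele
    if (grepl(js, refseq, fixed = TRUE)) {
      warning("dropping clone ", out$clone_id[j],
              ": junction signature occurs in the reference")
      ok[j] <- FALSE
      next
    }
    sig[j] <- js
    wsig[j] <- wt_signature(reference, out$insertion_site[j], k_flank)
    dup[j] <- sub0(refseq, out$insertion_site[j] - out$itd_length[j],
                   out$insertion_site[j])
    ok[j] <- TRUE
  }
  out$junction_signature <- sig
  out$wt_sig <- wsig
  out$duplicated_seq <- dup
  out <- out[ok, c("clone_id", "itd_length", "insertion_site",
                   "junction_signature", "wt_sig", "duplicated_seq",
                   "support"), drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("itd_catalog", "data.frame")
  attr(out, "n_unanchored") <- n_unanchored
  out
}

# one-row counts container shared by the two counting paths
new_clone_counts <- function(sample_id, clone_id, itd_reads, wt_reads,
                             other, total) {
  out <- data.frame(sample_id = sample_id, clone_id = clone_id,
                    itd_reads = itd_reads, wt_reads = wt_reads,
                    other_reads = other, total_merged = total,
                    stringsAsFactors = FALSE)
  class(out) <- c("clone_counts", "data.frame")
  out
}

clone_fields <- function(clone) {
  # accept a catalog row (data frame) or a plain list
  if (is.data.frame(clone)) {
    stopifnot(nrow(clone) == 1L)
    clone <- as.list(clone)
  }
  clone
}

check_clone_valid <- function(clone, reference) {
  if (grepl(clone$junction_signature, reference$sequence, fixed = TRUE))
    stop("invalid clone ", clone$clone_id,
         ": junction signature occurs in the reference", call. = FALSE)
}

hit_either_strand <- function(seqs, sig) {
  rc <- as.character(revcomp_cpp(sig))
  grepl(sig, seqs, fixed = TRUE) | grepl(rc, seqs, fixed = TRUE)
}

#' Count ITD and wild-type breakpoint reads for a clone
#'
#' Exact substring counting of the clone's junction signature (ITD allele)
#' and of the wild-type signature at the clone's site over all merged reads
#' of a sample, in both orientations; a read counts at most once per
#' signature, and a read matching both (pathological) counts as ITD.
#'
#' @param merged A `merged_reads` data frame.
#' @param clone One catalog row (or a list with `clone_id`, `itd_length`,
#'   `insertion_site`, `junction_signature`).
#' @param reference An `amplicon_reference`.
#' @param k_flank Flank used for the wild-type signature; must match the
#'   catalog's. Default 12.
#' @param sample_id Optional sample label carried into the result.
#'
#' @return A one-row `clone_counts` data frame: `itd_reads`, `wt_reads`,
#'   `other_reads` (reads covering neither signature), `total_merged`.
#'   Conservation: itd + wt + other = total.
#' @export
count_breakpoints <- function(merged, clone, reference, k_flank = 12L,
                              sample_id = "sample") {
  stopifnot(inherits(merged, "merged_reads"))
  clone <- clone_fields(clone)
  check_clone_valid(clone, reference)
  wsig <- wt_signature(reference, clone$insertion_site, k_flank)
  seqs <- merged$seq[merged$merged]
  total <- length(seqs)
  if (total == 0L)
    return(new_clone_counts(sample_id, clone$clone_id, 0L, 0L, 0L, 0L))
  itd_hit <- hit_either_strand(seqs, clone$junction_signature)
  wt_hit <- hit_either_strand(seqs, wsig) & !itd_hit
  new_clone_counts(sample_id, clone$clone_id, sum(itd_hit), sum(wt_hit),
                   total - sum(itd_hit) - sum(wt_hit), total)
}

#' Count breakpoint reads directly on unmerged pairs (fast path)
#'
#' Deep follow-up samples do not need merging to be counted: a 2*k_flank
#' signature is fully contained in a single mate whenever it is covered at
#' all, so the pair's two mates are searched directly (both orientations)
#' and each pair counts at most once per signature. Used for
#' dilution/sensitivity experiments at millions of pairs; equivalent to
#' [count_breakpoints()] on merged reads up to pairs whose signature falls
#' in an unmergeable fragment's unsequenced gap.
#'
#' @param pairs A `read_pairs` object.
#' @inheritParams count_breakpoints
#' @return A one-row `clone_counts` data frame; `total_merged` holds the
#'   number of pairs.
#' @export
count_breakpoints_pairs <- function(pairs, clone, reference, k_flank = 12L,
                                    sample_id = "sample") {
  stopifnot(inherits(pairs, "read_pairs"))
  clone <- clone_fields(clone)
  check_clone_valid(clone, reference)
  wsig <- wt_signature(reference, clone$insertion_site, k_flank)
  total <- length(pairs)
  if (total == 0L)
    return(new_clone_counts(sample_id, clone$clone_id, 0L, 0L, 0L, 0L))
  itd_hit <- hit_either_strand(pairs$seq1, clone$junction_signature) |
    hit_either_strand(pairs$seq2, clone$junction_signature)
  wt_hit <- (hit_either_strand(pairs$seq1, wsig) |
               hit_either_strand(pairs$seq2, wsig)) & !itd_hit
  new_clone_counts(sample_id, clone$clone_id, sum(itd_hit), sum(wt_hit),
                   total - sum(itd_hit) - sum(wt_hit), total)
}
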