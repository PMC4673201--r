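# Paired-end amplicon read simulator with truth tables.
#
# Emulates the focused-PCR + tagmentation library: per pair an allele
# (wild-type or one of the ITD clones) is drawn by allele fraction, a
# fragment of truncated-normal length and uniform start is taken from the
# allele sequence, and the two mates read the fragment ends with iid
# per-base substitution errors. Quality strings are constant Q40 (learned
# quality profiles are out of scope). Deterministic given the config seed.

#' Simulation configuration
#'
#' @param reference An `amplicon_reference`.
#' @param clones List of clones, each a list/vector with `itd_length`,
#'   `insertion_site` (0-based; stored left-aligned via [canonical_site()])
#'   and `allele_fraction`. Fractions must lie in `[0, 1]` and sum to at
#'   most 1; the remainder is wild-type.
#' @param n_pairs Number of read pairs to emit.
#' @param read_length Mate length, bp. Default 150 (2x150 chemistry).
#' @param fragment_mean,fragment_sd Fragment length model, bp: normal,
#'   truncated to `[min_fragment, allele length]` by resampling. Defaults
#'   250 / 60 (tagmentation cuts roughly every 150-300 bp; values chosen so
#'   most pairs overlap and merge).
#' @param min_fragment Lower truncation bound; default `read_length + 30`.
#'   Must be at least `read_length` (shorter fragments would make mates
#'   read past the fragment) -- violating geometry errors at validation.
#' @param error_rate Per-base substitution probability. Default 1e-3
#'   (dominant short-read error mode; no indels).
#' @param seed Integer seed; the same config and seed give byte-identical
#'   output.
#' @param sample_id Label prefixed to read ids.
#'
#' @return A `sim_config` object. Each clone gains `site` (canonical),
#'   `mutant_seq` and `junction_signature` fields; the implied ITD/WT
#'   allele ratio `sum(f)/(1 - sum(f))` is stored as `implied_ratio`.
#' @export
sim_config <- function(reference, clones = list(), n_pairs,
                       read_length = 150L, fragment_mean = 250,
                       fragment_sd = 60, min_fragment = NULL,
                       error_rate = 1e-3, seed = 1L, sample_id = "sim") {
  stopifnot(inherits(reference, "amplicon_reference"),
            n_pairs >= 0, read_length > 0, fragment_sd >= 0,
            error_rate >= 0, error_rate < 1)
  if (is.null(min_fragment)) min_fragment <- read_length + 30L
  if (min_fragment < read_length)
    stop("impossible geometry: min_fragment (", min_fragment,
         ") is shorter than read_length (", read_length, ")", call. = FALSE)
  if (min_fragment > nchar(reference$sequence))
    stop("impossible geometry: min_fragment exceeds the amplicon length",
         call. = FALSE)
  fr <- vapply(clones, function(cl) as.numeric(cl[["allele_fraction"]]),
               numeric(1))
  if (length(fr) && (any(fr < 0) || any(fr > 1) || sum(fr) > 1))
    stop("clone allele fractions must lie in [0, 1] and sum to at most 1",
         call. = FALSE)
  cl2 <- lapply(clones, function(cl) {
    L <- as.integer(cl[["itd_length"]])
    site <- as.integer(cl[["insertion_site"]])
    w <- reference$itd_window
    if (site < w[1] || site >= w[2])
      stop("clone insertion_site ", site, " outside the ITD window [",
           w[1], ", ", w[2], ")", call. = FALSE)
    if (site - L < 0L)
      stop("clone at site ", site, " with length ", L,
           " would duplicate past the amplicon start", call. = FALSE)
    site <- canonical_site(reference, site, L)
    list(itd_length = L, insertion_site = site,
         allele_fraction = as.numeric(cl[["allele_fraction"]]),
         mutant_seq = mutant_sequence(reference, site, L),
         junction_signature = junction_signature(reference, site, L))
  })
  structure(
    list(reference = reference, clones = cl2, n_pairs = as.integer(n_pairs),
         read_length = as.integer(read_length),
         fragment_mean = fragment_mean, fragment_sd = fragment_sd,
         min_fragment = as.integer(min_fragment), error_rate = error_rate,
         seed = as.integer(seed), sample_id = sample_id,
         implied_ratio = if (sum(fr) < 1) sum(fr) / (1 - sum(fr)) else Inf),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$sample_id, "-", x$n_pairs, "pairs,",
      length(x$clones), "clone(s), error rate", x$error_rate, "\n")
  for (cl in x$clones)
    cat(sprintf("  ITD %d bp @ %d, allele fraction %g\n", cl$itd_length,
                cl$insertion_site, cl$allele_fraction))
  invisible(x)
}

# truncated-normal fragment lengths by resampling
draw_fragments <- function(n, mean, sd, lo, hi) {
  if (lo > hi) stop("fragment bounds are empty", call. = FALSE)
  x <- round(rnorm(n, mean, sd))
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  as.integer(x)
}

#' Simulate one amplicon sample
#'
#' @param config A `sim_config`.
#' @param fastq_prefix Optional path prefix; when given, the pairs are
#'   written to `<prefix>_R1.fastq` / `<prefix>_R2.fastq` and the truth
#'   table to `<prefix>_truth.tsv`.
#'
#' @return A `sim_sample` list: `pairs` (a `read_pairs`), `truth` (data
#'   frame `read_id`, `allele` -- `0` for wild-type or the 1-based clone
#'   index -- `frag_start`, `frag_len`, on the originating allele's
#'   coordinates) and `config`.
#' @export
simulate_sample <- function(config, fastq_prefix = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_pairs
  rl <- config$read_length
  allele_seqs <- c(config$reference$sequence,
                   vapply(config$clones, `[[`, character(1), "mutant_seq"))
  fr <- vapply(config$clones, `[[`, numeric(1), "allele_fraction")
  # allele 0 = WT, i = clone i
  allele <- integer(n)
  if (length(fr) && n > 0) {
    u <- runif(n)
    br <- cumsum(fr)
    allele <- as.integer(findInterval(u, br, left.open = TRUE) + 1L)
    allele[allele > length(fr)] <- 0L  # remainder: wild-type
  }
  ids <- sprintf("%s_%07d", config$sample_id, seq_len(max(n, 0L)))
  if (n == 0L) {
    pairs <- make_read_pairs(character(0), character(0), character(0))
    truth <- data.frame(read_id = character(0), allele = integer(0),
                        frag_start = integer(0), frag_len = integer(0),
                        stringsAsFactors = FALSE)
    return(structure(list(pairs = pairs, truth = truth, config = config),
                     class = "sim_sample"))
  }

  frag_len <- integer(n)
  frag_start <- integer(n)
  for (ai in sort(unique(allele))) {
    idx <- which(allele == ai)
    alen <- nchar(allele_seqs[ai + 1L])
    fl <- draw_fragments(length(idx), config$fragment_mean,
                         config$fragment_sd, config$min_fragment, alen)
    frag_len[idx] <- fl
    frag_start[idx] <- as.integer(floor(runif(length(idx)) * (alen - fl + 1)))
  }
  frags <- substring(allele_seqs[allele + 1L], frag_start + 1L,
                     frag_start + frag_len)
  mate1 <- substr(frags, 1L, rl)
  mate2 <- as.character(revcomp_cpp(substring(frags, frag_len - rl + 1L,
                                              frag_len)))
  if (config$error_rate > 0) {
    mate1 <- as.character(add_errors_cpp(mate1, config$error_rate))
    mate2 <- as.character(add_errors_cpp(mate2, config$error_rate))
  }
  pairs <- make_read_pairs(ids, mate1, mate2)
  truth <- data.frame(read_id = ids, allele = allele,
                      frag_start = frag_start, frag_len = frag_len,
                      stringsAsFactors = FALSE)
  out <- structure(list(pairs = pairs, truth = truth, config = config),
                   class = "sim_sample")
  if (!is.null(fastq_prefix)) {
    write_fastq_pair(pairs, paste0(fastq_prefix, "_R1.fastq"),
                     paste0(fastq_prefix, "_R2.fastq"))
    write.table(truth, paste0(fastq_prefix, "_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
print.sim_sample <- function(x, ...) {
  cat("sim_sample:", x$config$sample_id, "-", length(x$pairs), "pairs (",
      sum(x$truth$allele > 0), "mutant )\n")
  invisible(x)
}

#' Expected truth counts for a simulated sample
#'
#' Mirrors the breakpoint-counting definition on the truth table alone: a
#' pair is an ITD-breakpoint pair when a sequenced mate fully contains the
#' clone's junction window, and a wild-type-breakpoint pair when a mate
#' contains the wild-type window at the clone's site without containing
#' the junction. Note that the wild-type window also exists on the mutant
#' allele, at the end of the second copy (a tandem insertion recreates the
#' wild-type junction context downstream), so mutant pairs covering that
#' context but not the mutant junction legitimately count as wild-type --
#' exactly as the signature counting sees them. With a zero error rate
#' these counts equal [count_breakpoints_pairs()] output exactly.
#'
#' @param sim A `sim_sample`.
#' @param clone_index 1-based index into the config's clone list.
#' @param k_flank Signature flank (must match the counting call).
#' @return A list: `itd_reads`, `wt_reads`.
#' @export
truth_breakpoint_counts <- function(sim, clone_index = 1L, k_flank = 12L) {
  cf <- sim$config
  cl <- cf$clones[[clone_index]]
  site <- cl$insertion_site
  L <- cl$itd_length
  k <- k_flank
  rl <- cf$read_length
  tr <- sim$truth
  covered <- function(w_lo, w_hi, idx) {
    # window [w_lo, w_hi) on the allele; contained in mate 1 or mate 2?
    fs <- tr$frag_start[idx]; fl <- tr$frag_len[idx]
    m1 <- (w_lo >= fs) & (w_hi <= fs + pmin(rl, fl))
    m2 <- (w_lo >= fs + fl - pmin(rl, fl)) & (w_hi <= fs + fl)
    m1 | m2
  }
  mut <- which(tr$allele == clone_index)
  # on the clone's allele: junction window [site-k, site+k); the wild-type
  # context reappears at the second copy's end, [site+L-k, site+L+k)
  itd <- sum(covered(site - k, site + k, mut))
  wt_on_mut <- sum(covered(site + L - k, site + L + k, mut) &
                     !covered(site - k, site + k, mut))
  # wild-type allele: the window at the site itself
  wt_idx <- which(tr$allele == 0L)
  wt <- sum(covered(site - k, site + k, wt_idx))
  # other clones' alleles: the window exists shifted by their insertion
  # when their duplication lies entirely on one side of it
  other <- setdiff(unique(tr$allele), c(0L, clone_index))
  for (oc in other) {
    ocl <- cf$clones[[oc]]
    idx <- which(tr$allele == oc)
    if (ocl$insertion_site <= site - k) {
      wt <- wt + sum(covered(site - k + ocl$itd_length,
                             site + k + ocl$itd_length, idx))
    } else if (ocl$insertion_site >= site + k) {
      wt <- wt + sum(covered(site - k, site + k, idx))
    }  # duplication inside the window: the context is disrupted; no count
  }
  list(itd_reads = itd, wt_reads = wt + wt_on_mut)
}

#' Serial dilution of a positive sample into negative background
#'
#' For each dilution `d` the clone allele fractions of the positive config
#' are scaled by `d` (`d = 0` gives an all-wild-type sample); `n_pairs` and
#' all other parameters are preserved. Returns configs, not materialised
#' samples, so deep ladders can be simulated one sample at a time; the
#' i-th config uses `seed + i` and a `_d<dilution>` sample-id suffix.
#'
#' @param positive A `sim_config` with at least one clone.
#' @param dilutions Numeric vector of dilution fractions.
#' @return A list of `sim_config`s, one per dilution.
#' @export
dilution_series <- function(positive, dilutions) {
  stopifnot(inherits(positive, "sim_config"), length(positive$clones) >= 1L)
  lapply(seq_along(dilutions), function(i) {
    d <- dilutions[i]
    stopifnot(d >= 0, d <= 1)
    clones <- lapply(positive$clones, function(cl) {
      list(itd_length = cl$itd_length, insertion_site = cl$insertion_site,
           allele_fraction = cl$allele_fraction * d)
    })
    sim_config(positive$reference, clones, positive$n_pairs,
               read_length = positive$read_length,
               fragment_mean = positive$fragment_mean,
               fragment_sd = positive$fragment_sd,
               min_fragment = positive$min_fragment,
               error_rate = positive$error_rate,
               seed = positive$seed + i,
               sample_id = sprintf("%s_d%g", positive$sample_id, d))
  })
}
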