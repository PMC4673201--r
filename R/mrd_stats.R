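# MRD statistics: ITD/WT ratio, Fisher-exact positivity against in-run
# controls, per-sample sensitivity, longitudinal log reductions.

#' ITD/WT breakpoint read ratio
#'
#' Reads containing the ITD junction breakpoint divided by reads containing
#' the wild-type breakpoint at the same site. May exceed 1 (duplicated
#' alleles are often over-represented; no correction is applied).
#'
#' @param itd_reads,wt_reads Breakpoint read counts.
#' @return The ratio; `Inf` (with a warning) when `wt_reads` is 0 but
#'   `itd_reads` > 0; `NA` when both are 0.
#' @examples
#' compute_ratio(119, 100)  # ratio x 100 of 119%
#' @export
compute_ratio <- function(itd_reads, wt_reads) {
  stopifnot(length(itd_reads) == 1L, length(wt_reads) == 1L,
            itd_reads >= 0, wt_reads >= 0)
  if (wt_reads == 0) {
    if (itd_reads == 0) return(NA_real_)
    warning("no wild-type breakpoint reads; ratio is infinite")
    return(Inf)
  }
  itd_reads / wt_reads
}

#' Fisher-exact MRD positivity against in-run controls
#'
#' One-sided Fisher exact test of the 2x2 table
#' `[[itd_reads, total - itd_reads], [control_itd, control_total -
#' control_itd]]`, alternative: the sample's junction-read rate is greater
#' than the pooled controls'. Controls are the pooled counts of the same
#' junction signature over the other samples of the run (see
#' [pool_controls()]); comparing against in-run background controls for
#' cross-sample contamination. No multiple-testing correction is applied
#' across clones by default; pass `alpha = 0.05 / n_clones` for a
#' Bonferroni-style switch.
#'
#' @param itd_reads,total Sample junction-read count and total read units.
#' @param control_itd,control_total Pooled control counts. When the control
#'   pool has depth but no hit count for this clone, pass `control_itd = 0`.
#'   When `control_total` is 0 (no controls at all), positivity falls back
#'   to `itd_reads >= min_support` and the result is flagged.
#' @param alpha Significance level. Default 0.05.
#' @param min_support Fallback support floor when no control depth exists.
#'
#' @return A list: `p_value`, `positive` (`p < alpha`), `alpha`, `note`
#'   (`NA` or `"no_controls"`).
#' @export
fisher_positivity <- function(itd_reads, total, control_itd, control_total,
                              alpha = 0.05, min_support = 5L) {
  stopifnot(itd_reads >= 0, total >= itd_reads,
            control_itd >= 0, control_total >= control_itd)
  if (control_total == 0) {
    return(list(p_value = NA_real_, positive = itd_reads >= min_support,
                alpha = alpha, note = "no_controls"))
  }
  tab <- matrix(c(itd_reads, total - itd_reads,
                  control_itd, control_total - control_itd),
                nrow = 2, byrow = TRUE)
  p <- fisher.test(tab, alternative = "greater")$p.value
  list(p_value = p, positive = p < alpha, alpha = alpha, note = NA_character_)
}

#' Minimal detectable ITD/WT ratio at a sample's depth
#'
#' The smallest junction-read count `k` that would yield a positive Fisher
#' test against the given controls, expressed as a ratio over the sample's
#' wild-type breakpoint reads. For negative samples, the wild-type
#' signature reads at the clone's site are the denominator (observable even
#' when `itd_reads = 0`). The search is a binary scan over `k`, exact by
#' monotonicity of the one-sided test.
#'
#' @param total Sample total read units.
#' @param wt_reads Wild-type breakpoint reads (ratio denominator).
#' @param control_itd,control_total Pooled control counts.
#' @param alpha Significance level. Default 0.05.
#'
#' @return A list: `k_min` (smallest positive count; `NA` if no count up to
#'   `total` is positive or `total` is 0) and `min_detectable_ratio`
#'   (`k_min / wt_reads`; `NA` when undefined).
#' @export
compute_sensitivity <- function(total, wt_reads, control_itd, control_total,
                                alpha = 0.05) {
  if (total <= 0)
    return(list(k_min = NA_integer_, min_detectable_ratio = NA_real_))
  pos_at <- function(k) {
    fisher_positivity(k, total, control_itd, control_total, alpha)$positive
  }
  if (!pos_at(total))
    return(list(k_min = NA_integer_, min_detectable_ratio = NA_real_))
  lo <- 0L; hi <- as.integer(total)  # pos_at(lo) FALSE (k=0 never positive)
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (pos_at(mid)) hi <- mid else lo <- mid
  }
  list(k_min = hi,
       min_detectable_ratio = if (wt_reads > 0) hi / wt_reads else NA_real_)
}

#' Pool in-run control counts for one sample
#'
#' Controls are the other samples of the same run, excluding any sample of
#' the same patient (contamination control against "other patients"). When
#' the run contains samples with role `control` or `negative`, pooling is
#' restricted to those; otherwise all eligible samples count.
#'
#' @param counts A data frame of per-sample clone counts (columns
#'   `sample_id`, `clone_id`, `itd_reads`, `total_merged`).
#' @param manifest A validated manifest data frame.
#' @param sample_id The sample being tested.
#' @param clone_id The clone being tested.
#' @return A list: `control_itd`, `control_total`, `n_controls`.
#' @export
pool_controls <- function(counts, manifest, sample_id, clone_id) {
  me <- manifest[manifest$sample_id == sample_id, , drop = FALSE]
  stopifnot(nrow(me) == 1L)
  cand <- manifest[manifest$run_id == me$run_id &
                     manifest$sample_id != sample_id &
                     manifest$patient_id != me$patient_id, , drop = FALSE]
  if (any(cand$role %in% c("control", "negative")))
    cand <- cand[cand$role %in% c("control", "negative"), , drop = FALSE]
  rows <- counts[counts$clone_id == clone_id &
                   counts$sample_id %in% cand$sample_id, , drop = FALSE]
  list(control_itd = sum(rows$itd_reads),
       control_total = sum(rows$total_merged),
       n_controls = nrow(rows))
}

#' Per-patient, per-clone MRD timeline with log reductions
#'
#' Orders a patient's samples by timepoint, takes the diagnosis sample as
#' baseline, and reports for each clone and timepoint the ITD/WT ratio,
#' positivity, and the decimal log reduction `log10(baseline_ratio /
#' ratio)`. A follow-up with zero junction reads is reported as below the
#' sample's sensitivity (no log value). Clones positive at a follow-up but
#' without junction reads at diagnosis are flagged emergent (mutational
#' shift); clones positive at diagnosis but negative at the latest
#' timepoint are flagged lost.
#'
#' @param report A per-sample x clone results data frame as produced by
#'   [detect_run()] (columns `sample_id`, `clone_id`, `itd_reads`,
#'   `wt_reads`, `ratio`, `positive`, `min_detectable_ratio`).
#' @param manifest A validated manifest data frame.
#' @param patient_id The patient to build a timeline for.
#'
#' @return An `mrd_timeline`: list with `patient_id`, `points` (one row per
#'   clone x timepoint, with `log_reduction` and `status`), and `clones`
#'   (per-clone `baseline_ratio`, `emergent`, `lost_at_latest`).
#' @export
build_timeline <- function(report, manifest, patient_id) {
  pm <- manifest[manifest$patient_id == patient_id, , drop = FALSE]
  if (nrow(pm) == 0L)
    stop("no samples for patient ", patient_id, call. = FALSE)
  if (!any(pm$role == "diagnosis"))
    stop("no diagnosis sample for patient ", patient_id,
         "; a baseline is required", call. = FALSE)
  pm <- pm[order(pm$timepoint), , drop = FALSE]
  dx <- pm$sample_id[pm$role == "diagnosis"][1]

  rows <- report[report$sample_id %in% pm$sample_id, , drop = FALSE]
  # the manifest is authoritative for timepoint/role
  rows <- rows[, setdiff(names(rows), c("timepoint", "role")), drop = FALSE]
  rows <- merge(rows, pm[, c("sample_id", "timepoint", "role")],
                by = "sample_id", sort = FALSE)
  rows <- rows[order(rows$clone_id, rows$timepoint), , drop = FALSE]

  clones <- unique(rows$clone_id)
  pts <- NULL
  summ <- NULL
  for (cl in clones) {
    cr <- rows[rows$clone_id == cl, , drop = FALSE]
    base <- cr[cr$sample_id == dx, , drop = FALSE]
    baseline_ratio <- if (nrow(base)) base$ratio[1] else NA_real_
    lr <- ifelse(cr$itd_reads > 0 & !is.na(baseline_ratio) &
                   is.finite(baseline_ratio) & baseline_ratio > 0 &
                   is.finite(cr$ratio) & cr$ratio > 0,
                 log10(baseline_ratio / cr$ratio), NA_real_)
    status <- ifelse(cr$itd_reads == 0, "below_sensitivity",
                     ifelse(cr$positive, "positive", "detected"))
    cr$baseline_ratio <- baseline_ratio
    cr$log_reduction <- lr
    cr$status <- status
    pts <- rbind(pts, cr)
    latest <- cr[which.max(cr$timepoint), , drop = FALSE]
    emergent <- (nrow(base) == 0L || base$itd_reads[1] == 0L) &&
      any(cr$positive[cr$role != "diagnosis"])
    lost <- nrow(base) > 0L && isTRUE(base$positive[1]) &&
      !isTRUE(latest$positive[1])
    summ <- rbind(summ, data.frame(
      clone_id = cl, baseline_ratio = baseline_ratio,
      emergent = emergent, lost_at_latest = lost,
      stringsAsFactors = FALSE))
  }
  structure(list(patient_id = patient_id, points = pts, clones = summ),
            class = "mrd_timeline")
}

#' @export
print.mrd_timeline <- function(x, ...) {
  cat("MRD timeline for patient", x$patient_id, "\n")
  cols <- c("clone_id", "timepoint", "role", "itd_reads", "wt_reads",
            "ratio", "positive", "log_reduction", "status")
  print(x$points[, intersect(cols, names(x$points)), drop = FALSE],
        row.names = FALSE)
  cat("\nClone summary:\n")
  print(x$clones, row.names = FALSE)
  invisible(x)
}
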