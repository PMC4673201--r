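# Run-level orchestration: merge -> repeat finding -> clone discovery
# (diagnosis samples only) -> breakpoint counting (all samples) -> Fisher
# positivity and sensitivity; plus multi-run MRD reporting.

#' Pipeline parameters with defaults
#'
#' Every stage parameter in one validated list, so a run is reproducible
#' from its config alone.
#'
#' @param min_overlap,max_mismatch_frac Merging, see [merge_pairs()].
#' @param min_period,max_period,resolution Repeat finding, see
#'   [find_tandem_repeats()].
#' @param k_flank,anchor_len,min_support Clone discovery, see
#'   [discover_clones()].
#' @param max_discovery_reads Cap on merged reads scanned per diagnosis
#'   sample at discovery (support, not depth, is what discovery needs).
#' @param alpha Fisher significance level.
#' @return A named list of parameters.
#' @export
detect_params <- function(min_overlap = 10L, max_mismatch_frac = 0.1,
                          min_period = 15L, max_period = 150L,
                          resolution = 1L, k_flank = 12L, anchor_len = 20L,
                          min_support = 5L, max_discovery_reads = 100000L,
                          alpha = 0.05) {
  list(min_overlap = as.integer(min_overlap),
       max_mismatch_frac = max_mismatch_frac,
       min_period = as.integer(min_period),
       max_period = as.integer(max_period),
       resolution = as.integer(resolution),
       k_flank = as.integer(k_flank),
       anchor_len = as.integer(anchor_len),
       min_support = as.integer(min_support),
       max_discovery_reads = as.integer(max_discovery_reads),
       alpha = alpha)
}

#' Detect and quantify ITD clones in one sequencing run
#'
#' For every sample of the run: read the FASTQ pair and merge. Clones are
#' discovered on diagnosis samples only (follow-up runs never contribute
#' reads to discovery; an optional `catalog` carries diagnosis clones into
#' follow-up runs). Every sample is then counted against every clone, and
#' positivity is called per sample against its in-run controls
#' ([pool_controls()]), with per-sample sensitivity at the observed depth.
#'
#' @param manifest A manifest data frame or TSV path ([read_manifest()]);
#'   all samples must share one `run_id`.
#' @param reference An `amplicon_reference`.
#' @param params A [detect_params()] list.
#' @param catalog Optional `itd_catalog` of previously discovered clones
#'   (e.g. from the diagnosis run) used in addition to -- or, for a pure
#'   follow-up run, instead of -- in-run discovery.
#' @param output_dir Optional directory; when given, the catalog, report
#'   and QC tables are written as TSV, the report as JSON, and a JSON-lines
#'   log with per-stage read tallies.
#'
#' @return A `detect_result` list: `catalog`, `report` (one row per sample
#'   x clone: counts, ratio, p-value, positivity, sensitivity), `qc`
#'   (per-sample pair/merge tallies), `params`, `run_id`.
#' @export
detect_run <- function(manifest, reference, params = detect_params(),
                       catalog = NULL, output_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  manifest <- validate_manifest(manifest)
  if (length(unique(manifest$run_id)) != 1L)
    stop("detect_run() processes one run at a time; got runs: ",
         paste(unique(manifest$run_id), collapse = ", "), call. = FALSE)
  run_id <- manifest$run_id[1]
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- c(list(stage = stage), list(...))
  }

  merged_by_sample <- list()
  qc <- NULL
  for (i in seq_len(nrow(manifest))) {
    sm <- manifest[i, ]
    pairs <- read_fastq_pair(sm$fastq1, sm$fastq2)
    merged <- merge_pairs(pairs, params$min_overlap,
                          params$max_mismatch_frac)
    st <- merge_stats(merged)
    merged_by_sample[[sm$sample_id]] <- merged
    qc <- rbind(qc, data.frame(sample_id = sm$sample_id,
                               n_pairs = st$n_pairs,
                               n_merged = st$n_merged,
                               merge_rate = st$merge_rate,
                               stringsAsFactors = FALSE))
    note("merge", sample_id = sm$sample_id, n_pairs = st$n_pairs,
         n_merged = st$n_merged)
  }

  # discovery: diagnosis samples only
  cat_all <- if (is.null(catalog)) NULL else catalog
  for (sid in manifest$sample_id[manifest$role == "diagnosis"]) {
    cc <- discover_clones(merged_by_sample[[sid]], reference,
                          min_period = params$min_period,
                          max_period = params$max_period,
                          resolution = params$resolution,
                          k_flank = params$k_flank,
                          anchor_len = params$anchor_len,
                          min_support = params$min_support,
                          max_reads = params$max_discovery_reads)
    note("discover", sample_id = sid, n_clones = nrow(cc),
         n_unanchored = attr(cc, "n_unanchored"))
    if (nrow(cc)) cat_all <- rbind(cat_all, as.data.frame(cc))
  }
  if (!is.null(cat_all) && nrow(cat_all)) {
    # union by clone key, summing support across diagnosis samples
    agg <- stats::aggregate(support ~ clone_id, data = cat_all, FUN = sum)
    cat_all <- cat_all[!duplicated(cat_all$clone_id), , drop = FALSE]
    cat_all$support <- agg$support[match(cat_all$clone_id, agg$clone_id)]
    cat_all <- cat_all[order(-cat_all$support), , drop = FALSE]
    rownames(cat_all) <- NULL
    class(cat_all) <- c("itd_catalog", "data.frame")
  } else {
    cat_all <- empty_catalog()
  }

  # counting + positivity
  counts <- NULL
  for (sid in manifest$sample_id) {
    for (j in seq_len(nrow(cat_all))) {
      counts <- rbind(counts, count_breakpoints(
        merged_by_sample[[sid]], cat_all[j, ], reference,
        k_flank = params$k_flank, sample_id = sid))
    }
  }

  report <- NULL
  if (!is.null(counts)) {
    for (r in seq_len(nrow(counts))) {
      row <- counts[r, ]
      ctl <- pool_controls(counts, manifest, row$sample_id, row$clone_id)
      fp <- fisher_positivity(row$itd_reads, row$total_merged,
                              ctl$control_itd, ctl$control_total,
                              alpha = params$alpha,
                              min_support = params$min_support)
      sens <- compute_sensitivity(row$total_merged, row$wt_reads,
                                  ctl$control_itd, ctl$control_total,
                                  alpha = params$alpha)
      sm <- manifest[manifest$sample_id == row$sample_id, ]
      cl <- cat_all[cat_all$clone_id == row$clone_id, ]
      report <- rbind(report, data.frame(
        run_id = run_id, sample_id = row$sample_id,
        patient_id = sm$patient_id, timepoint = sm$timepoint,
        role = sm$role, clone_id = row$clone_id,
        itd_length = cl$itd_length, insertion_site = cl$insertion_site,
        itd_reads = row$itd_reads, wt_reads = row$wt_reads,
        total_merged = row$total_merged,
        ratio = suppressWarnings(compute_ratio(row$itd_reads,
                                               row$wt_reads)),
        p_value = fp$p_value, positive = fp$positive,
        min_detectable_ratio = sens$min_detectable_ratio,
        control_itd = ctl$control_itd, control_total = ctl$control_total,
        flag = fp$note, stringsAsFactors = FALSE))
    }
    note("positivity", n_tests = nrow(report),
         n_positive = sum(report$positive))
  }

  res <- structure(list(run_id = run_id, catalog = cat_all, report = report,
                        qc = qc, params = params, log = log),
                   class = "detect_result")
  if (!is.null(output_dir)) write_detect_result(res, output_dir)
  res
}

#' @export
print.detect_result <- function(x, ...) {
  cat("detect_result for run", x$run_id, "-", nrow(x$qc), "samples,",
      nrow(x$catalog), "clone(s)\n")
  if (!is.null(x$report) && nrow(x$report)) {
    cols <- c("sample_id", "clone_id", "itd_reads", "wt_reads", "ratio",
              "p_value", "positive")
    print(x$report[, cols], row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write detect results to disk
#'
#' Catalog, report and QC as TSV; the report also as JSON; the stage log as
#' JSON lines (an audit trail with per-stage read tallies).
#'
#' @param res A `detect_result`.
#' @param output_dir Directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_detect_result <- function(res, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) write.table(x, file.path(output_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(as.data.frame(res$catalog), "clone_catalog.tsv")
  if (!is.null(res$report)) {
    tsv(res$report, "mrd_report.tsv")
    jsonlite::write_json(res$report, file.path(output_dir,
                                               "mrd_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  tsv(res$qc, "qc.tsv")
  con <- file(file.path(output_dir, "log.jsonl"), "wt")
  on.exit(close(con))
  for (entry in res$log)
    writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), con)
  invisible(output_dir)
}

#' Longitudinal MRD report across runs
#'
#' Combines the reports of one or more [detect_run()] results (typically
#' the diagnosis run plus follow-up runs) and builds per-patient, per-clone
#' timelines with decimal log reductions and emergent/lost clone flags.
#'
#' @param results A single `detect_result` or a list of them.
#' @param manifest The combined manifest covering all runs.
#' @param patient_ids Patients to report; default: all patients with a
#'   diagnosis sample.
#' @param output_dir Optional directory for a TSV/JSON timeline report.
#' @return A named list of `mrd_timeline` objects.
#' @export
mrd_report <- function(results, manifest, patient_ids = NULL,
                       output_dir = NULL) {
  if (inherits(results, "detect_result")) results <- list(results)
  report <- do.call(rbind, lapply(results, `[[`, "report"))
  if (is.null(report) || nrow(report) == 0L)
    stop("no clone counts to report on", call. = FALSE)
  manifest <- validate_manifest(manifest)
  if (is.null(patient_ids))
    patient_ids <- unique(manifest$patient_id[manifest$role == "diagnosis"])
  tls <- lapply(patient_ids, function(p) build_timeline(report, manifest, p))
  names(tls) <- patient_ids
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    pts <- do.call(rbind, lapply(tls, function(t) {
      cbind(patient_id = t$patient_id, t$points)
    }))
    write.table(pts, file.path(output_dir, "mrd_timelines.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(pts, file.path(output_dir, "mrd_timelines.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  tls
}
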