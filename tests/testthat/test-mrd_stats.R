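test_that("the ITD/WT ratio follows the printed definition, including the
           >1 regime", {
  expect_identical(compute_ratio(10, 100), 0.1)
  expect_identical(compute_ratio(0, 5000), 0)
  # the dilution source sample: ratio x 100 of 119%
  expect_equal(compute_ratio(119, 100) * 100, 119)
  expect_warning(r <- compute_ratio(3, 0), "infinite")
  expect_identical(r, Inf)
  expect_identical(compute_ratio(0, 0), NA_real_)
})

test_that("Fisher positivity matches the hypergeometric tail and behaves at
           the boundary cases", {
  # no signal anywhere -> p = 1, negative
  fp <- fisher_positivity(0, 1e6, 0, 1e7)
  expect_identical(fp$p_value, 1)
  expect_false(fp$positive)

  # clear signal against clean controls -> positive at alpha 0.05
  fp <- fisher_positivity(50, 1e4, 0, 1e5)
  expect_true(fp$positive)
  expect_equal(fp$p_value,
               oracle_fisher_greater(50, 1e4 - 50, 0, 1e5),
               tolerance = 1e-10)

  # identical rates -> one-sided p > 0.5, negative
  fp <- fisher_positivity(10, 1e5, 10, 1e5)
  expect_gt(fp$p_value, 0.5)
  expect_false(fp$positive)

  # agreement with the tail formula on a grid
  for (a in c(0, 1, 3, 12)) {
    for (ci in c(0, 2, 8)) {
      got <- fisher_positivity(a, 5000, ci, 20000)$p_value
      expect_equal(got, oracle_fisher_greater(a, 5000 - a, ci, 20000 - ci),
                   tolerance = 1e-9)
    }
  }
})

test_that("the p-value is non-increasing in the sample's junction reads", {
  p <- vapply(0:20, function(k)
    fisher_positivity(k, 1e4, 2, 1e5)$p_value, numeric(1))
  expect_true(all(diff(p) <= 1e-12))
})

test_that("empty controls fall back to the flagged support rule", {
  fp <- fisher_positivity(6, 1000, 0, 0)
  expect_identical(fp$note, "no_controls")
  expect_true(fp$positive)
  expect_false(fisher_positivity(2, 1000, 0, 0)$positive)
})

test_that("minimal detectable ratio equals an exhaustive scan and improves
           with depth", {
  scan_k <- function(total, ci, ct, alpha = 0.05) {
    for (k in 1:total) {
      if (oracle_fisher_greater(k, total - k, ci, ct - ci) < alpha) return(k)
    }
    NA_integer_
  }
  for (total in c(500, 2000, 10000)) {
    for (ci in c(0, 3)) {
      ct <- 50000
      s <- compute_sensitivity(total, wt_reads = total %/% 2,
                               control_itd = ci, control_total = ct)
      expect_identical(s$k_min, scan_k(total, ci, ct))
      expect_equal(s$min_detectable_ratio, s$k_min / (total %/% 2))
    }
  }
  # doubling depth with clean controls never hurts sensitivity
  s1 <- compute_sensitivity(1e4, 5e3, 0, 1e5)
  s2 <- compute_sensitivity(2e4, 1e4, 0, 1e5)
  expect_lte(s2$min_detectable_ratio, s1$min_detectable_ratio)
  # degenerate depth
  s0 <- compute_sensitivity(0, 0, 0, 1e5)
  expect_identical(s0$k_min, NA_integer_)
})

# small synthetic per-sample x clone report for timeline tests
fake_report <- function() {
  data.frame(
    sample_id = c("dx", "fu1", "fu2", "dx", "fu1", "fu2"),
    clone_id = rep(c("A", "B"), each = 3),
    itd_reads = c(1000, 10, 0, 120, 40, 500),
    wt_reads = c(1000, 10000, 9000, 1000, 10000, 9000),
    ratio = c(1.0, 0.001, NA, 0.12, 0.004, 0.0556),
    positive = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    min_detectable_ratio = rep(3e-4, 6),
    stringsAsFactors = FALSE
  )
}

fake_manifest <- function() {
  data.frame(run_id = c("r1", "r2", "r2"),
             sample_id = c("dx", "fu1", "fu2"),
             patient_id = "p1", timepoint = c(0, 1, 2),
             fastq1 = "x", fastq2 = "y",
             role = c("diagnosis", "followup", "followup"),
             stringsAsFactors = FALSE)
}

test_that("log reductions are decimal logs against the diagnosis baseline,
           with zero-count points reported below sensitivity", {
  tl <- build_timeline(fake_report(), fake_manifest(), "p1")
  a <- tl$points[tl$points$clone_id == "A", ]
  expect_equal(a$log_reduction[a$sample_id == "fu1"], 3.0)
  expect_identical(a$status[a$sample_id == "fu2"], "below_sensitivity")
  expect_true(is.na(a$log_reduction[a$sample_id == "fu2"]))
})

test_that("mutational shift: a dominant clone lost at the latest timepoint
           and a persisting minor clone are flagged", {
  tl <- build_timeline(fake_report(), fake_manifest(), "p1")
  cs <- tl$clones
  expect_true(cs$lost_at_latest[cs$clone_id == "A"])
  expect_false(cs$lost_at_latest[cs$clone_id == "B"])
  expect_false(any(cs$emergent))  # both clones were present at diagnosis
})

test_that("an emergent clone (absent at diagnosis, positive later) is
           flagged", {
  rep <- fake_report()
  rep$itd_reads[rep$clone_id == "B" & rep$sample_id == "dx"] <- 0
  rep$positive[rep$clone_id == "B" & rep$sample_id == "dx"] <- FALSE
  tl <- build_timeline(rep, fake_manifest(), "p1")
  expect_true(tl$clones$emergent[tl$clones$clone_id == "B"])
})

test_that("a timeline without a diagnosis sample is an error", {
  m <- fake_manifest()
  m$role[1] <- "followup"
  expect_error(build_timeline(fake_report(), m, "p1"), "diagnosis")
  expect_error(build_timeline(fake_report(), fake_manifest(), "nobody"),
               "no samples")
})

test_that("in-run control pooling excludes the sample and its patient and
           prefers designated negative controls", {
  counts <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    clone_id = "A",
    itd_reads = c(100, 7, 3, 9),
    total_merged = c(1000, 2000, 3000, 4000),
    stringsAsFactors = FALSE)
  man <- data.frame(run_id = "r1",
                    sample_id = c("s1", "s2", "s3", "s4"),
                    patient_id = c("p1", "p1", "p2", "p3"),
                    timepoint = 0, fastq1 = "x", fastq2 = "y",
                    role = c("diagnosis", "followup", "followup",
                             "followup"),
                    stringsAsFactors = FALSE)
  # no designated controls: all other patients' samples pool
  ctl <- pool_controls(counts, man, "s1", "A")
  expect_identical(ctl$control_itd, 12)
  expect_identical(ctl$control_total, 7000)
  # same-patient sample s2 is never a control for s1
  expect_identical(ctl$n_controls, 2L)
  # designated negative restricts the pool
  man$role[3] <- "negative"
  ctl <- pool_controls(counts, man, "s1", "A")
  expect_identical(ctl$control_total, 3000)
})
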