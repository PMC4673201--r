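test_that("the same config and seed give byte-identical FASTQ output", {
  ref <- default_reference()
  cfg <- sim_config(ref, clones = list(list(itd_length = 21,
                                            insertion_site = 150,
                                            allele_fraction = 0.2)),
                    n_pairs = 300, error_rate = 1e-3, seed = 42)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_sample(cfg, fastq_prefix = d1)
  simulate_sample(cfg, fastq_prefix = d2)
  for (suf in c("_R1.fastq", "_R2.fastq", "_truth.tsv")) {
    expect_identical(readLines(paste0(d1, suf)), readLines(paste0(d2, suf)))
  }
  unlink(c(paste0(d1, c("_R1.fastq", "_R2.fastq", "_truth.tsv")),
           paste0(d2, c("_R1.fastq", "_R2.fastq", "_truth.tsv"))))
})

test_that("allele fraction 0 and dilution 0 emit pure wild-type samples", {
  ref <- default_reference()
  cfg <- sim_config(ref, clones = list(list(itd_length = 48,
                                            insertion_site = 200,
                                            allele_fraction = 0)),
                    n_pairs = 200, seed = 1)
  expect_true(all(simulate_sample(cfg)$truth$allele == 0))

  pos <- sim_config(ref, clones = list(list(itd_length = 48,
                                            insertion_site = 200,
                                            allele_fraction = 0.54)),
                    n_pairs = 200, seed = 1)
  zero <- dilution_series(pos, 0)[[1]]
  expect_true(all(simulate_sample(zero)$truth$allele == 0))
})

test_that("dilution scales clone fractions and preserves everything else", {
  ref <- default_reference()
  pos <- sim_config(ref, clones = list(list(itd_length = 48,
                                            insertion_site = 200,
                                            allele_fraction = 0.54)),
                    n_pairs = 500, seed = 9)
  lad <- dilution_series(pos, c(1, 1e-2))
  expect_equal(lad[[1]]$clones[[1]]$allele_fraction, 0.54)
  expect_equal(lad[[2]]$clones[[1]]$allele_fraction, 0.0054)
  expect_identical(lad[[2]]$n_pairs, pos$n_pairs)
  expect_identical(lad[[2]]$clones[[1]]$insertion_site,
                   pos$clones[[1]]$insertion_site)
})

test_that("breakpoint counting reproduces the truth table exactly without
           errors and within binomial tolerance with errors", {
  ref <- default_reference()
  mk <- function(err, seed) {
    cfg <- sim_config(ref, clones = list(list(itd_length = 48,
                                              insertion_site = 200,
                                              allele_fraction = 0.5)),
                      n_pairs = 10000, error_rate = err, seed = seed)
    sim <- simulate_sample(cfg)
    cl <- list(clone_id = "c", itd_length = 48L,
               insertion_site = cfg$clones[[1]]$insertion_site,
               junction_signature = cfg$clones[[1]]$junction_signature)
    list(cc = count_breakpoints_pairs(sim$pairs, cl, ref),
         tb = truth_breakpoint_counts(sim))
  }
  # error-free counting is exact against the truth table
  x <- mk(0, 10)
  expect_identical(x$cc$itd_reads, x$tb$itd_reads)
  expect_identical(x$cc$wt_reads, x$tb$wt_reads)

  # with errors, a 24-base signature is lost with probability
  # ~ 1 - (1-e)^24 = 2.4%; counts stay within 3 SD of that expectation
  y <- mk(1e-3, 10)
  keep <- (1 - 1e-3)^24
  tol <- function(n) 4 * sqrt(n * keep * (1 - keep)) + 5
  expect_lt(abs(y$cc$itd_reads - y$tb$itd_reads * keep),
            tol(y$tb$itd_reads))
  # wt can only gain from mutant pairs whose junction was hit by an error
  # but whose downstream wild-type context survived
  expect_gt(y$cc$wt_reads, y$tb$wt_reads * keep - tol(y$tb$wt_reads))
  expect_lt(y$cc$wt_reads,
            y$tb$wt_reads * keep + y$tb$itd_reads * (1 - keep) +
              tol(y$tb$wt_reads))
})

test_that("fragments always respect the geometry bounds and impossible
           geometry errors at validation", {
  ref <- default_reference()
  cfg <- sim_config(ref, clones = list(), n_pairs = 500, seed = 3)
  sim <- simulate_sample(cfg)
  expect_true(all(sim$truth$frag_len >= cfg$min_fragment))
  expect_true(all(sim$truth$frag_len <= nchar(ref$sequence)))
  expect_true(all(sim$truth$frag_start >= 0))
  expect_true(all(sim$truth$frag_start + sim$truth$frag_len <=
                    nchar(ref$sequence)))
  expect_error(sim_config(ref, clones = list(), n_pairs = 10,
                          read_length = 200, min_fragment = 150),
               "geometry")
  expect_error(sim_config(ref, clones = list(list(itd_length = 48,
                                                  insertion_site = 200,
                                                  allele_fraction = 1.2)),
                          n_pairs = 10),
               "fraction")
})

test_that("a duplication longer than the fragment span leaves no read
           containing both copies", {
  ref <- default_reference()
  cfg <- sim_config(ref, clones = list(list(itd_length = 183,
                                            insertion_site = 210,
                                            allele_fraction = 1)),
                    n_pairs = 500, error_rate = 0, seed = 5)
  sim <- simulate_sample(cfg)
  m <- merge_pairs(sim$pairs)
  spans <- nchar(m$seq[m$merged])
  expect_true(all(spans < 2 * 183))
})
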