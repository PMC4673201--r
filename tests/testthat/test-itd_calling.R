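# Shared fixture: simulate, merge, discover in one call.
sim_and_discover <- function(clones, n_pairs = 1000, error_rate = 0,
                             seed = 101, ...) {
  ref <- default_reference()
  cfg <- sim_config(ref, clones = clones, n_pairs = n_pairs,
                    error_rate = error_rate, seed = seed)
  sim <- simulate_sample(cfg)
  merged <- merge_pairs(sim$pairs)
  list(ref = ref, cfg = cfg, sim = sim, merged = merged,
       catalog = discover_clones(merged, ref, ...))
}

test_that("a single simulated clone is recovered with exact length and site", {
  x <- sim_and_discover(list(list(itd_length = 48, insertion_site = 200,
                                  allele_fraction = 0.3)))
  expect_identical(nrow(x$catalog), 1L)
  expect_identical(x$catalog$itd_length, 48L)
  expect_identical(x$catalog$insertion_site,
                   x$cfg$clones[[1]]$insertion_site)
  expect_identical(x$catalog$junction_signature,
                   x$cfg$clones[[1]]$junction_signature)
})

test_that("an all-wild-type sample yields an empty clone catalog", {
  x <- sim_and_discover(list(), n_pairs = 500)
  expect_identical(nrow(x$catalog), 0L)
})

test_that("two clones are recovered and ranked by support
           (dominant 39 bp + minor 60 bp)", {
  x <- sim_and_discover(list(
    list(itd_length = 39, insertion_site = 180, allele_fraction = 0.25),
    list(itd_length = 60, insertion_site = 250, allele_fraction = 0.10)
  ), n_pairs = 2500, error_rate = 1e-3, seed = 103)
  expect_identical(nrow(x$catalog), 2L)
  expect_setequal(x$catalog$itd_length, c(39L, 60L))
  expect_identical(x$catalog$itd_length[1], 39L)  # dominant first
  truth_sites <- vapply(x$cfg$clones, `[[`, integer(1), "insertion_site")
  expect_setequal(x$catalog$insertion_site, truth_sites)
})

test_that("breakpoint counts conserve reads and match the truth table
           exactly on error-free data", {
  ref <- default_reference()
  cfg <- sim_config(ref, clones = list(list(itd_length = 48,
                                            insertion_site = 200,
                                            allele_fraction = 0.35)),
                    n_pairs = 3000, error_rate = 0, seed = 104)
  sim <- simulate_sample(cfg)
  clone <- list(clone_id = "ITD48",
                itd_length = 48L,
                insertion_site = cfg$clones[[1]]$insertion_site,
                junction_signature = cfg$clones[[1]]$junction_signature)
  cc <- count_breakpoints_pairs(sim$pairs, clone, ref)
  tb <- truth_breakpoint_counts(sim)
  expect_identical(cc$itd_reads, tb$itd_reads)
  expect_identical(cc$wt_reads, tb$wt_reads)
  expect_identical(cc$itd_reads + cc$wt_reads + cc$other_reads,
                   cc$total_merged)

  # merged-read counting conserves as well
  m <- merge_pairs(sim$pairs)
  cm <- count_breakpoints(m, clone, ref)
  expect_identical(cm$itd_reads + cm$wt_reads + cm$other_reads,
                   cm$total_merged)
})

test_that("a clone is never counted in another patient's clean negative
           sample, and spurious hits under sequencing error stay within the
           analytic bound", {
  ref <- default_reference()
  clone <- list(clone_id = "ITD48",
                itd_length = 48L,
                insertion_site = canonical_site(ref, 200, 48),
                junction_signature = junction_signature(
                  ref, canonical_site(ref, 200, 48), 48))

  neg0 <- simulate_sample(sim_config(ref, clones = list(), n_pairs = 2000,
                                     error_rate = 0, seed = 105))
  cc <- count_breakpoints_pairs(neg0$pairs, clone, ref)
  expect_identical(cc$itd_reads, 0L)

  # with 1e-3 substitutions, a junction hit needs several coordinated
  # errors within a 24-base window; expected spurious hits are far below 1
  neg <- simulate_sample(sim_config(ref, clones = list(), n_pairs = 20000,
                                    error_rate = 1e-3, seed = 106))
  cce <- count_breakpoints_pairs(neg$pairs, clone, ref)
  expect_lte(cce$itd_reads, 1L)
})

test_that("counting a clone whose signature occurs in the reference is an
           error", {
  ref <- default_reference()
  fake <- list(clone_id = "bad", itd_length = 24L, insertion_site = 100L,
               junction_signature = substr(ref$sequence, 101, 124))
  m <- merge_pairs(make_read_pairs("r", random_dna(150), random_dna(150)))
  expect_error(count_breakpoints(m, fake, ref), "reference")
})

test_that("itd_reads grows with the simulated allele fraction and tracks the
           truth expectation within binomial tolerance", {
  ref <- default_reference()
  counts <- numeric(0)
  for (f in c(0.1, 0.25, 0.5)) {
    cfg <- sim_config(ref, clones = list(list(itd_length = 48,
                                              insertion_site = 200,
                                              allele_fraction = f)),
                      n_pairs = 2000, error_rate = 0, seed = 107)
    sim <- simulate_sample(cfg)
    cl <- list(clone_id = "c", itd_length = 48L,
               insertion_site = cfg$clones[[1]]$insertion_site,
               junction_signature = cfg$clones[[1]]$junction_signature)
    cc <- count_breakpoints_pairs(sim$pairs, cl, ref)
    tb <- truth_breakpoint_counts(sim)
    expect_identical(cc$itd_reads, tb$itd_reads)  # error-free: exact
    counts <- c(counts, cc$itd_reads)
  }
  expect_true(all(diff(counts) > 0))
})

test_that("ITD lengths spanning the observed 15-90 bp range are recovered
           exactly when reads can span the duplication", {
  for (L in c(15L, 39L, 90L)) {
    site <- 120L + L  # keep the duplicated unit inside the amplicon
    x <- sim_and_discover(list(list(itd_length = L, insertion_site = site,
                                    allele_fraction = 0.3)),
                          n_pairs = 1500, error_rate = 1e-3,
                          seed = 108L + L)
    expect_identical(nrow(x$catalog), 1L)
    expect_identical(x$catalog$itd_length, L)
    expect_identical(x$catalog$insertion_site,
                     x$cfg$clones[[1]]$insertion_site)
  }
})

test_that("a 183-bp duplication cannot be called from 150-bp reads of
           ~250-bp fragments (fragmentation inside the ITD)", {
  x <- sim_and_discover(list(list(itd_length = 183, insertion_site = 210,
                                  allele_fraction = 0.5)),
                        n_pairs = 4000, error_rate = 1e-3, seed = 109)
  expect_identical(nrow(x$catalog), 0L)
  # structural reason: no merged read can span both copies
  expect_true(all(nchar(x$merged$seq[x$merged$merged]) < 2 * 183))
})
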