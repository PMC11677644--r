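# two diploids per group with exact target allele frequencies
gm_from_freqs <- function(p1, p2, span = 1e5) {
  # 5 diploids per group so frequencies in multiples of 0.1 are exact
  dos_for <- function(p) {
    cnt <- round(p * 10)
    c(rep(2L, cnt %/% 2), rep(1L, cnt %% 2),
      rep(0L, 5 - cnt %/% 2 - cnt %% 2))
  }
  m <- length(p1)
  pos0 <- as.integer(seq(0, span - 1, length.out = m))
  d <- rbind(vapply(seq_len(m), function(s) dos_for(p1[s]), integer(5)),
             vapply(seq_len(m), function(s) dos_for(p2[s]), integer(5)))
  gm <- genotype_matrix(sprintf("s%02d", 1:10),
                        data.frame(chrom = "chr1", pos0 = pos0,
                                   ref = "A", alt = "G"),
                        d)
  pops <- population_set(setNames(rep(c("A", "B"), each = 5),
                                  gm$sample_ids))
  list(gm = gm, pops = pops)
}

test_that("make_windows follows the 100kb/50kb sliding rule", {
  spec <- window_spec()
  expect_equal(spec$window_size, 100000L)
  expect_equal(spec$step_size, 50000L)
  w <- make_windows(c(chr1 = 250000), spec)
  expect_equal(nrow(w), 5L)
  expect_equal(w$start, c(0, 50000, 100000, 150000, 200000))
  expect_equal(w$end[5], 250000)          # truncated trailing window
  w2 <- make_windows(c(chr1 = 60000), spec)
  expect_equal(nrow(w2), 1L)
  expect_equal(c(w2$start, w2$end), c(0, 60000))
  expect_error(window_spec(step_size = 0), "step_size")
  expect_error(window_spec(window_size = 100, step_size = 200), "step_size")
})

test_that("window_pi matches hand values and degenerate cases", {
  # 2 diploids, one site split 2/2 among 4 haplotypes
  gm <- genotype_matrix(c("a", "b"),
                        data.frame(chrom = "chr1", pos0 = 500L, ref = "A",
                                   alt = "G"),
                        matrix(c(1L, 1L), 2, 1))
  pops <- population_set(c(a = "G1", b = "G1"))
  w <- list(chrom = "chr1", start = 0, end = 1e5)
  expect_equal(window_pi(gm, pops, "G1", w), 2 * 0.5 * 0.5 / 1e5)  # 5e-6
  # empty window
  expect_equal(window_pi(gm, pops, "G1", list(chrom = "chr1", start = 2e5,
                                              end = 3e5)), 0)
  # monomorphic site contributes nothing
  gm2 <- genotype_matrix(c("a", "b"),
                         data.frame(chrom = "chr1", pos0 = c(1L, 2L),
                                    ref = "A", alt = "G"),
                         matrix(c(2L, 2L, 1L, 1L), 2, 2))
  expect_equal(window_pi(gm2, pops, "G1", w), 5e-6)
  expect_error(window_pi(gm, pops, "nope", w), "unknown group")
})

test_that("window_pi equals the with-replacement haplotype-pair oracle", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(2:5, 1)                   # <= 10 haplotypes
    m <- sample(1:50, 1)
    gm <- rand_gm(n = n, m = m, missing_rate = 0.15)
    pops <- population_set(setNames(rep("G", n), gm$sample_ids))
    w <- list(chrom = "chr1", start = 0, end = 1e5)
    expect_equal(window_pi(gm, pops, "G", w),
                 pi_oracle(gm$dosages, 1e5), tolerance = 1e-12)
  }
})

test_that("the unbiased flag applies the 2N/(2N-1) correction", {
  gm <- genotype_matrix(c("a", "b"),
                        data.frame(chrom = "chr1", pos0 = 500L, ref = "A",
                                   alt = "G"),
                        matrix(c(1L, 1L), 2, 1))
  pops <- population_set(c(a = "G", b = "G"))
  w <- list(chrom = "chr1", start = 0, end = 1e5)
  expect_equal(window_pi(gm, pops, "G", w, unbiased = TRUE),
               5e-6 * 4 / 3)
})

test_that("pi_ratio handles identity, arithmetic and undefined cases", {
  expect_equal(pi_ratio(0.004, 0.004), 1)
  expect_equal(pi_ratio(0.004, 0.002), 2)
  expect_true(is.na(pi_ratio(0.004, 0)))
  expect_true(is.na(pi_ratio(NA, 0.002)))
  expect_equal(pi_ratio(c(1, 2), c(2, 0)), c(0.5, NA))
})

test_that("window_fst hits the analytic endpoints and the hand value", {
  w <- list(chrom = "chr1", start = 0, end = 1e5)
  # identical frequencies -> 0
  x <- gm_from_freqs(rep(0.3, 10), rep(0.3, 10))
  expect_identical(window_fst(x$gm, x$pops, c("A", "B"), w), 0)
  # opposite fixation -> 1
  y <- gm_from_freqs(rep(0, 20), rep(1, 20))
  expect_identical(window_fst(y$gm, y$pops, c("A", "B"), w), 1)
  # single site p1=0.2, p2=0.8 -> Fst = 1 - 0.32/0.5 = 0.36
  z <- gm_from_freqs(0.2, 0.8)
  expect_equal(window_fst(z$gm, z$pops, c("A", "B"), w), 0.36)
  expect_error(window_fst(z$gm, z$pops, "A", w), "exactly 2")
})

test_that("fst is within [0,1], symmetric, and pi ignores labels in group", {
  set.seed(13)
  w <- list(chrom = "chr1", start = 0, end = 1e5)
  for (rep in 1:25) {
    gm <- rand_gm(n = 8, m = 30, missing_rate = 0.1)
    pops <- population_set(setNames(rep(c("A", "B"), each = 4),
                                    gm$sample_ids))
    f <- window_fst(gm, pops, c("A", "B"), w)
    if (!is.na(f)) {
      expect_gte(f, 0)
      expect_lte(f, 1)
      expect_equal(window_fst(gm, pops, c("B", "A"), w), f)
    }
  }
})

test_that("hudson estimator recovers the endpoints too", {
  w <- list(chrom = "chr1", start = 0, end = 1e5)
  y <- gm_from_freqs(rep(0, 20), rep(1, 20))
  expect_equal(window_fst(y$gm, y$pops, c("A", "B"), w,
                          estimator = "hudson"), 1)
})

test_that("call_outliers reproduces the interpolated-quantile worked example", {
  vals <- 0.005 * (1:40)
  out <- call_outliers(vals, 0.95)
  expect_equal(unname(out$thresholds["upper"]), 0.19025)
  expect_equal(sum(!is.na(out$direction)), 2L)
  expect_equal(which(out$direction == "high"), c(39L, 40L))
})

test_that("call_outliers degenerate and two-sided behaviour", {
  expect_equal(sum(!is.na(call_outliers(rep(0.5, 30), 0.95)$direction)), 0L)
  # symmetric values flag equal counts in both tails
  vals <- c(-(20:1), 1:20)
  out <- call_outliers(vals, c(0.025, 0.975))
  expect_equal(sum(out$direction == "low", na.rm = TRUE),
               sum(out$direction == "high", na.rm = TRUE))
  expect_true(all(which(out$direction == "low") <= 2))
  # too few values: warn, flag nothing
  expect_warning(out2 <- call_outliers(1:5, 0.95), "defined values")
  expect_equal(sum(!is.na(out2$direction)), 0L)
  # NA values are never flagged
  out3 <- call_outliers(c(rep(1, 30), NA, 100), 0.95)
  expect_true(is.na(out3$direction[31]))
})

test_that("scan_windows agrees with the single-window operations", {
  cfg <- sim_config(seed = 3, chromosome_lengths = c(chr1 = 4e5, chr2 = 2e5),
                    n_snps = 400, diploids_per_pop = 8, missing_rate = 0.05)
  sim <- simulate_genotypes(simulate_frequencies(cfg), cfg)
  sw <- scan_windows(sim$gm, sim$pops, c("pop1", "pop2"),
                     chromosome_lengths = cfg$chromosome_lengths)
  expect_equal(nrow(sw), 8 + 4)
  for (i in c(1, 3, 9)) {
    w <- list(chrom = sw$chrom[i], start = sw$start[i], end = sw$end[i])
    expect_equal(sw$pi_pop1[i], window_pi(sim$gm, sim$pops, "pop1", w))
    expect_equal(sw$fst[i], window_fst(sim$gm, sim$pops, c("pop1", "pop2"), w))
    expect_equal(sw$pi_ratio[i], pi_ratio(sw$pi_pop1[i], sw$pi_pop2[i]))
  }
  # min_snps gates the statistics
  sw2 <- scan_windows(sim$gm, sim$pops, c("pop1", "pop2"),
                      spec = window_spec(min_snps = 1e5),
                      chromosome_lengths = cfg$chromosome_lengths)
  expect_true(all(is.na(sw2$fst)))
})
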