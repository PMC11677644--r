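test_that("config validation enforces the model's parameter ranges", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, F_background = 0), "F_background")
  expect_error(sim_config(seed = 1,
                          selected_windows = data.frame(chrom = "chrX",
                                                        start = 0, end = 1,
                                                        F_high = 0.5)))
  expect_error(sim_config(seed = 1, missing_rate = 1))
  expect_error(sim_config(seed = 1, n_pops = 3,
                          mixture = list(pop = 1, parents = c(1, 3),
                                         weight = 0.5)))
})

test_that("identical config and seed give bit-identical study outputs", {
  cfg <- sim_config(seed = 99, chromosome_lengths = c(chr1 = 3e5),
                    n_snps = 300, diploids_per_pop = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_study(cfg, d1, n_genes = 30, n_terms = 5)
  s2 <- simulate_study(cfg, d2, n_genes = 30, n_terms = 5)
  for (p in c("vcf", "populations", "gff", "go_map", "traits")) {
    expect_identical(readLines(s1[[p]]), readLines(s2[[p]]))
  }
})

test_that("Balding-Nichols frequencies have the advertised moments", {
  # degenerate F -> frequencies equal the ancestral values exactly
  cfg0 <- sim_config(seed = 4, n_snps = 200, F_background = 1e-7,
                     chromosome_lengths = c(chr1 = 1e5))
  fr0 <- simulate_frequencies(cfg0)
  expect_equal(fr0$p_pop[1, ], fr0$p_anc)
  expect_equal(fr0$p_pop[2, ], fr0$p_anc)
  # high F -> near fixation
  cfg9 <- sim_config(seed = 4, n_snps = 5000, F_background = 0.99,
                     chromosome_lengths = c(chr1 = 1e6))
  fr9 <- simulate_frequencies(cfg9)
  expect_lt(mean(abs(fr9$p_pop[1, ] - round(fr9$p_pop[1, ]))), 0.05)
  # mean of p_k over many draws is the ancestral p (3 se of Beta sd)
  cfg <- sim_config(seed = 8, n_snps = 10000, F_background = 0.2,
                    ancestral_freq_range = c(0.499, 0.501),
                    chromosome_lengths = c(chr1 = 1e6))
  fr <- simulate_frequencies(cfg)
  se <- sqrt(0.2 * 0.25 / 10000)
  expect_lt(abs(mean(fr$p_pop[1, ]) - 0.5), 3 * se)
  # realised Beta variance close to F p (1-p)
  expect_equal(var(fr$p_pop[1, ]), 0.2 * 0.25, tolerance = 0.05)
})

test_that("selected windows use their elevated F", {
  cfg <- sim_config(seed = 2, n_snps = 1000,
                    chromosome_lengths = c(chr1 = 1e6),
                    F_background = 0.05,
                    selected_windows = data.frame(chrom = "chr1",
                                                  start = 4e5, end = 5e5,
                                                  F_high = 0.6))
  fr <- simulate_frequencies(cfg)
  inw <- fr$sites$pos0 >= 4e5 & fr$sites$pos0 < 5e5
  expect_true(all(fr$site_F[inw] == 0.6))
  expect_true(all(fr$site_F[!inw] == 0.05))
})

test_that("genotype draws follow the population frequencies", {
  cfg <- sim_config(seed = 12, n_snps = 50, diploids_per_pop = 1000,
                    chromosome_lengths = c(chr1 = 1e5), missing_rate = 0)
  fr <- simulate_frequencies(cfg)
  # force degenerate and balanced frequencies to check the binomial layer
  fr$p_pop[1, ] <- 0
  fr$p_pop[2, ] <- 1
  sim <- simulate_genotypes(fr, cfg)
  gf <- group_frequencies(sim$gm, sim$pops)
  expect_true(all(gf$freq["pop1", ] == 0))
  expect_true(all(gf$freq["pop2", ] == 1))
  fr$p_pop[1, ] <- 0.5
  sim2 <- simulate_genotypes(fr, cfg)
  md <- mean(sim2$gm$dosages[sim$pops$assignment == "pop1", ])
  se <- sqrt(2 * 0.5 * 0.5 / (1000 * 50))
  expect_lt(abs(md - 1), 3 * se)
})

test_that("missingness is applied at the configured rate", {
  cfg <- sim_config(seed = 13, n_snps = 500, diploids_per_pop = 20,
                    chromosome_lengths = c(chr1 = 1e6), missing_rate = 0.1)
  sim <- simulate_genotypes(simulate_frequencies(cfg), cfg)
  rate <- mean(is.na(sim$gm$dosages))
  se <- sqrt(0.1 * 0.9 / length(sim$gm$dosages))
  expect_lt(abs(rate - 0.1), 3 * se)
})

test_that("simulated annotation tiles disjoint genes and plants the signal", {
  cfg <- sim_config(seed = 6, chromosome_lengths = c(chr1 = 1e6, chr2 = 5e5),
                    n_snps = 100,
                    selected_windows = data.frame(chrom = "chr1",
                                                  start = 0, end = 1e6,
                                                  F_high = 0.5))
  ann <- simulate_annotation(cfg, n_genes = 60, n_terms = 8,
                             p_linked_inside = 1, p_linked_outside = 0)
  expect_equal(nrow(ann$genes), 60L)
  for (chr in unique(ann$genes$chrom)) {
    g <- ann$genes[ann$genes$chrom == chr, ]
    g <- g[order(g$start), ]
    expect_true(all(g$end[-nrow(g)] <= g$start[-1]))  # pairwise disjoint
    expect_true(all(g$end <= cfg$chromosome_lengths[[chr]]))
  }
  # with prob 1 inside / 0 outside, carriers are exactly the chr1 genes
  carriers <- unique(ann$go_map$gene_id[ann$go_map$go_id == ann$linked_term])
  expect_setequal(carriers, ann$genes$gene_id[ann$genes$chrom == "chr1"])
  # empty case
  ann0 <- simulate_annotation(cfg, n_genes = 0)
  expect_equal(nrow(ann0$genes), 0L)
  expect_equal(nrow(ann0$go_map), 0L)
  # GFF round-trips through the reader
  f <- withr::local_tempfile(fileext = ".gff3")
  silkscan:::write_gff3(ann$genes, f)
  back <- read_gff(f)
  expect_equal(back$gene_id, ann$genes$gene_id)
  expect_equal(back$start, ann$genes$start)
  expect_equal(back$end, ann$genes$end)
})

test_that("windowed Fst in planted sweep windows dominates the background", {
  sel <- data.frame(chrom = "chr1", start = c(1e6, 3e6), end = c(1.1e6, 3.1e6),
                    F_high = 0.6)
  cfg <- sim_config(seed = 14, chromosome_lengths = c(chr1 = 5e6),
                    n_snps = 5000, F_background = 0.05, diploids_per_pop = 15,
                    selected_windows = sel)
  sim <- simulate_genotypes(simulate_frequencies(cfg), cfg)
  sw <- scan_windows(sim$gm, sim$pops, c("pop1", "pop2"),
                     chromosome_lengths = cfg$chromosome_lengths)
  in_sel <- sw$start %in% sel$start
  out_sel <- !mapply(function(s, e) any(s < sel$end & e > sel$start),
                     sw$start, sw$end)
  expect_gt(min(sw$fst[in_sel]), max(sw$fst[out_sel]))
  w <- wilcox.test(sw$fst[in_sel], sw$fst[out_sel], alternative = "greater")
  expect_lt(w$p.value, 0.01)
})

test_that("simulated traits are deterministic with the expected layout", {
  cfg <- sim_config(seed = 44)
  t1 <- simulate_traits(cfg)
  t2 <- simulate_traits(cfg)
  expect_identical(t1, t2)
  expect_equal(names(t1), c("strain_id", "group", "trait", "value"))
  expect_equal(sum(t1$trait == "egg_number"), 30L)
  # sd = 0 gives exactly the group means
  spec0 <- data.frame(name = "fixed", mean_A = 1, mean_B = 2, sd = 0, n = 3)
  t0 <- simulate_traits(cfg, spec0)
  expect_equal(unique(t0$value[t0$group == "pop1"]), 1)
  res <- suppressMessages(compare_groups(t0$value[t0$group == "pop1"],
                                         t0$value[t0$group == "pop2"]))
  expect_equal(res$p_value, 0)
})
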