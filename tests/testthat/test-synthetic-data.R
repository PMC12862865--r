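test_that("ancestral frequency draws respect bounds, mean and seed", {
  expect_error(draw_ancestral_frequencies(10, 0, 0.9), "bound")
  expect_error(draw_ancestral_frequencies(10, 0.9, 0.1), "exceeds")
  # degenerate interval collapses to a constant
  expect_equal(draw_ancestral_frequencies(3, 0.5, 0.5), rep(0.5, 3))
  x <- draw_ancestral_frequencies(1e4, 0.05, 0.95, seed = 1)
  expect_true(all(x >= 0.05 & x <= 0.95))
  expect_lt(abs(mean(x) - 0.5), 0.02)  # uniform mean
  expect_identical(x, draw_ancestral_frequencies(1e4, 0.05, 0.95, seed = 1))
})

test_that("Balding-Nichols frequencies have the closed-form variance", {
  anc <- rep(0.5, 1e5)
  expect_error(balding_nichols_frequencies(anc, 1), "F")
  expect_error(balding_nichols_frequencies(c(0, anc), 0.1), "strictly")
  # F = 0: no drift
  expect_equal(balding_nichols_frequencies(anc[1:10], 0)[1, ], anc[1:10])
  # Beta variance p(1-p)F = 0.0125 at p = 0.5, F = 0.05
  p <- balding_nichols_frequencies(anc, 0.05, seed = 2)[1, ]
  expect_lt(abs(var(p) - 0.0125) / 0.0125, 0.10)
  expect_lt(abs(mean(p) - 0.5), 0.005)
  # determinism across populations
  two <- balding_nichols_frequencies(anc[1:100], c(0.1, 0.1), seed = 3)
  expect_identical(two, balding_nichols_frequencies(anc[1:100], c(0.1, 0.1),
                                                    seed = 3))
})

test_that("diploid simulation follows the binomial admixture model", {
  pf <- rbind(rep(0, 10), rep(1, 10))
  expect_error(simulate_diploids(pf, matrix(1, 2, 3)), "columns")
  expect_true(all(simulate_diploids(pf, rbind(c(1, 0)), seed = 1) == 0))
  expect_true(all(simulate_diploids(pf, rbind(c(0, 1)), seed = 1) == 2))
  # 50/50 admixture between fixed 0 and fixed 1: mean dosage 2q = 1
  pf2 <- rbind(rep(0, 2000), rep(1, 2000))
  a <- matrix(0.5, 40, 2)
  g <- simulate_diploids(pf2, a, seed = 4)
  expect_lt(abs(mean(g) - 1), 0.02)
})

test_that("pseudo-haploidization maps homozygotes and flips a fair coin", {
  expect_error(pseudo_haploidize(matrix(3L, 2, 2)), "0/1/2")
  hom <- matrix(c(0L, 2L, 0L, 2L, NA), 1)
  expect_identical(pseudo_haploidize(hom, seed = 1)[1, ],
                   c(0L, 1L, 0L, 1L, NA))
  het <- matrix(1L, 1, 1e4)
  h <- pseudo_haploidize(het, seed = 2)
  expect_lt(abs(mean(h) - 0.5), 0.02)
  expect_identical(h, pseudo_haploidize(het, seed = 2))
})

test_that("duplicate draws mismatch at half the heterozygous sites", {
  hom <- c(0L, 2L, 2L, 0L)
  expect_identical(make_duplicate(hom, seed = 1),
                   pseudo_haploidize(matrix(hom, 1), seed = 99)[1, ])
  het <- rep(1L, 1e4)
  d1 <- make_duplicate(het, seed = 1)
  d2 <- make_duplicate(het, seed = 2)
  expect_lt(abs(mean(d1 != d2) - 0.5), 0.02)  # independent fair coins
})

test_that("missingness thinning is MCAR at the requested rate", {
  g <- matrix(0L, 2, 1e4)
  expect_error(apply_missingness(g, 1), "rate")
  expect_identical(apply_missingness(g, 0, seed = 1), g)
  m <- apply_missingness(g, 0.5, seed = 1)
  expect_lt(abs(mean(is.na(m)) - 0.5), 0.02)
  expect_identical(m, apply_missingness(g, 0.5, seed = 1))
  # already-missing entries stay missing
  g2 <- g; g2[1, 1:100] <- NA
  expect_true(all(is.na(apply_missingness(g2, 0.3, seed = 2)[1, 1:100])))
})

test_that("SNP positions are distinct, sorted, length-proportional", {
  expect_error(assign_snp_positions(101, 100), "distinct")
  sat <- assign_snp_positions(100, 100, seed = 1)
  expect_identical(sat$pos, 1:100)  # saturation
  tab <- assign_snp_positions(5000, c(a = 1e6, b = 5e5), seed = 2)
  for (ch in unique(tab$chrom)) {
    p <- tab$pos[tab$chrom == ch]
    expect_false(is.unsorted(p, strictly = TRUE))
  }
  big <- assign_snp_positions(1e4, c(c1 = 9e6, c2 = 1e6), seed = 3)
  expect_lt(abs(mean(big$chrom == "c1") - 0.9), 0.02)  # multinomial share
})

test_that("build_dataset plants migrants and duplicates with ground truth", {
  cfg <- sim_config(n_pops = 3, n_snps = 200, pop_F = c(0.1, 0.1, 0.1),
                    sample_sizes = c(5L, 5L, 5L), missing_rate = 0.2,
                    chrom_lengths = 1e6, seed = 7)
  b <- build_dataset(cfg)
  expect_identical(unname(b$truth$true_pop), b$dataset$ind$group)
  expect_null(b$truth$duplicate_pairs)

  cfg2 <- sim_config(n_pops = 2, n_snps = 200, pop_F = c(0.1, 0.1),
                     sample_sizes = c(5L, 5L), missing_rate = 0.2,
                     duplicate_pairs = 1L, chrom_lengths = 1e6, seed = 8)
  b2 <- build_dataset(cfg2)
  expect_identical(nrow(b2$truth$duplicate_pairs), 1L)
  expect_identical(nrow(b2$dataset$geno), 11L)

  # six-site study design: per-group sizes as configured
  cfg3 <- sim_config(n_snps = 100, chrom_lengths = 1e6, seed = 9)
  b3 <- build_dataset(cfg3)
  expect_identical(as.integer(table(b3$dataset$ind$group)[cfg3$pop_names]),
                   c(8L, 7L, 26L, 25L, 22L, 26L))

  # migrants: capture label differs from true pop; over-large count rejected
  mig <- data.frame(capture_label = "pop1", true_source_pop = "pop2",
                    count = 2)
  cfg4 <- sim_config(n_pops = 2, n_snps = 100, pop_F = c(0.1, 0.1),
                     sample_sizes = c(5L, 5L), migrants = mig,
                     chrom_lengths = 1e6, seed = 10)
  b4 <- build_dataset(cfg4)
  planted <- b4$dataset$ind$group == "pop1" &
    b4$truth$true_pop[b4$dataset$ind$sample_id] == "pop2"
  expect_identical(sum(planted), 2L)
  expect_error(sim_config(n_pops = 2, n_snps = 100, pop_F = c(0.1, 0.1),
                          sample_sizes = c(5L, 5L),
                          migrants = data.frame(capture_label = "pop1",
                                                true_source_pop = "pop2",
                                                count = 6),
                          chrom_lengths = 1e6),
               "exceeds")
})

test_that("the generator is bit-identical under a fixed seed", {
  cfg <- sim_config(n_pops = 2, n_snps = 300, pop_F = c(0.05, 0.1),
                    sample_sizes = c(6L, 6L), missing_rate = 0.3,
                    duplicate_pairs = 1L, chrom_lengths = c(1e6, 1e6),
                    seed = 42)
  expect_identical(build_dataset(cfg), build_dataset(cfg))
})

test_that("duplicate-pair PMR sits near half the unrelated PMR under HWE", {
  b <- two_pop_dataset(F = 0.05, n_per_pop = 12L, n_snps = 20000L,
                       missing_rate = 0.2, duplicate_pairs = 1L, seed = 21)
  pm <- pmr_matrix(b$dataset, min_overlap = 500L)
  dp <- b$truth$duplicate_pairs
  is_dup <- (pm$id1 == dp$id1 & pm$id2 == dp$id2) |
    (pm$id1 == dp$id2 & pm$id2 == dp$id1)
  within <- pm$group1 == pm$group2 & !is_dup
  ratio <- pm$pmr[is_dup] / median(pm$pmr[within])
  expect_gt(ratio, 0.45)
  expect_lt(ratio, 0.55)
})
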