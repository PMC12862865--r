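make_partition <- function(pos, chrom = "chr1", block_bp = 3e6) {
  block_partition(data.frame(chrom = chrom, pos = pos), block_bp)
}

test_that("block partition respects span boundaries per chromosome", {
  bp <- make_partition(c(1, 3000001))
  expect_identical(nrow(bp), 2L)  # 3,000,001 starts a new 3 Mb block
  bp2 <- make_partition(c(1, 1500000, 2999999))
  expect_identical(nrow(bp2), 1L)
  expect_error(make_partition(c(5, 2)), "sorted")
  # random multi-chromosome sweep: spans bounded, blocks cover all SNPs
  set.seed(6)
  snp <- do.call(rbind, lapply(1:10, function(ch)
    data.frame(chrom = paste0("chr", ch),
               pos = sort(sample.int(2e7, 300)))))
  bp3 <- block_partition(snp, block_bp = 3e6)
  expect_identical(sum(bp3$n_snps), nrow(snp))
  expect_true(all(bp3$end - bp3$start < 3e6))
  sb <- attr(bp3, "snp_block")
  expect_true(all(tapply(snp$chrom, sb, function(x) length(unique(x))) == 1))
})

test_that("f3 matches hand arithmetic and is nonnegative for a = b", {
  freq <- rbind(t = c(0.5, 0.5), a = c(0.1, 0.9), b = c(0.3, 0.7),
                b2 = c(0.3, 0.7))
  part <- make_partition(c(100, 200))
  f <- f3_statistic(freq, "t", "a", "b", part)
  expect_equal(f$estimate, 0.08)  # terms 0.4*0.2 and (-0.4)*(-0.2)
  expect_identical(f$n_snps, 2L)
  f_same <- f3_statistic(freq, "t", "b", "b2", part)
  expect_gte(f_same$estimate, 0)
  expect_error(f3_statistic(freq, "t", "a", "a", part), "distinct")
})

test_that("f4 matches hand arithmetic and its sign symmetries", {
  freq <- rbind(a = c(0.2, 0.8), b = c(0.4, 0.4), c = c(0.1, 0.9),
                d = c(0.5, 0.5), b2 = c(0.4, 0.4))
  part <- make_partition(c(100, 200))
  f <- f4_statistic(freq, "a", "b", "c", "d", part)
  expect_equal(f$estimate, 0.12)  # terms 0.08 and 0.16
  # identical frequency vectors in one pair: exactly zero
  expect_equal(f4_statistic(freq, "b", "b2", "c", "d", part)$estimate, 0)
  # swap within a pair: negated; swap the pairs: unchanged
  expect_equal(f4_statistic(freq, "b", "a", "c", "d", part)$estimate, -0.12)
  expect_equal(f4_statistic(freq, "c", "d", "a", "b", part)$estimate, 0.12)
})

test_that("f4 is additive per SNP across a chain of populations", {
  set.seed(17)
  freq <- matrix(runif(5 * 40), 5, dimnames = list(letters[1:5], NULL))
  part <- make_partition(seq_len(40) * 1000)
  lhs <- f4_statistic(freq, "a", "b", "d", "e", part)$estimate
  rhs <- f4_statistic(freq, "a", "c", "d", "e", part)$estimate +
    f4_statistic(freq, "c", "b", "d", "e", part)$estimate
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("weighted jackknife reduces to the classical delete-one form", {
  loo <- c(0.9, 1.1, 1.0, 1.05, 0.95)
  est <- 1.0
  jk <- jackknife_sem(loo, rep(10, 5), est)
  g <- 5
  classical <- sqrt((g - 1) / g * sum((loo - mean(loo))^2))
  expect_equal(jk$sem, classical, tolerance = 1e-12)
  # identical block estimates: zero error
  expect_equal(jackknife_sem(rep(0.3, 4), c(5, 6, 7, 8), 0.3)$sem, 0)
  # rescaling weights leaves the error unchanged
  jw <- jackknife_sem(loo, c(3, 9, 6, 12, 10), est)
  jw2 <- jackknife_sem(loo, 2 * c(3, 9, 6, 12, 10), est)
  expect_equal(jw$sem, jw2$sem, tolerance = 1e-12)
  expect_error(jackknife_sem(loo[1], 1, est), "two blocks")
  expect_error(jackknife_sem(loo, rep(0, 5), est), "positive")
})

test_that("f-statistic jackknife matches a direct leave-one-block oracle", {
  set.seed(18)
  L <- 500
  freq <- matrix(runif(4 * L), 4, dimnames = list(c("a", "b", "c", "d"),
                                                  NULL))
  pos <- sort(sample.int(3e7, L))
  part <- make_partition(pos)
  f <- f4_statistic(freq, "a", "b", "c", "d", part)
  terms <- (freq["a", ] - freq["b", ]) * (freq["c", ] - freq["d", ])
  blocks <- attr(part, "snp_block")
  loo <- vapply(unique(blocks), function(bl) mean(terms[blocks != bl]),
                numeric(1))
  w <- as.numeric(table(blocks))
  oracle <- jackknife_sem(loo, w, mean(terms))
  expect_equal(f$estimate, mean(terms), tolerance = 1e-12)
  expect_equal(f$sem, oracle$sem, tolerance = 1e-10)
  expect_equal(f$z * f$sem, f$estimate, tolerance = 1e-10)
})

test_that("triplet and quartet enumerations are complete and consistent", {
  set.seed(19)
  freq <- matrix(runif(5 * 30), 5,
                 dimnames = list(c("a", "b", "c", "d", "e"), NULL))
  part <- make_partition(seq_len(30) * 1e5)
  f3s <- enumerate_f3(freq[1:4, ], part)
  expect_identical(nrow(f3s), 12L)  # 4 targets x C(3, 2)
  for (k in seq_len(nrow(f3s))) {
    direct <- f3_statistic(freq, f3s$pop1[k], f3s$pop2[k], f3s$pop3[k], part)
    expect_equal(f3s$estimate[k], direct$estimate)
    expect_equal(f3s$sem[k], direct$sem)
  }
  f4s <- enumerate_f4(freq, part)
  expect_identical(nrow(f4s), 15L)  # 3 x C(5, 4) canonical quartets
  expect_false(any(duplicated(f4s[, 1:4])))
  for (k in seq_len(nrow(f4s))) {
    swapped <- f4_statistic(freq, f4s$pop2[k], f4s$pop1[k], f4s$pop3[k],
                            f4s$pop4[k], part)
    expect_equal(swapped$estimate, -f4s$estimate[k])
  }
})

test_that("groups with no data are flagged, not dropped", {
  freq <- rbind(a = c(0.2, 0.4), b = c(0.3, 0.1), c = c(0.25, 0.5),
                gone = c(NA_real_, NA_real_))
  part <- make_partition(c(10, 4e6))  # two blocks so sem is defined
  f3s <- enumerate_f3(freq, part)
  gone_rows <- f3s$pop1 == "gone" | f3s$pop2 == "gone" | f3s$pop3 == "gone"
  expect_true(all(f3s$flagged[gone_rows]))
  expect_true(all(f3s$n_snps[gone_rows] == 0L))
  expect_false(any(f3s$flagged[!gone_rows]))
})

test_that("sister populations share more drift than distant ones", {
  # topology: a and b diverge recently from a common node; c is distant
  hits <- 0L
  n_rep <- 10L
  for (s in seq_len(n_rep)) {
    anc <- draw_ancestral_frequencies(4000, 0.1, 0.9, seed = 700 + s)
    node <- balding_nichols_frequencies(anc, 0.08, seed = 800 + s)[1, ]
    node <- pmin(pmax(node, 1e-6), 1 - 1e-6)
    ab <- balding_nichols_frequencies(node, c(0.02, 0.02), seed = 900 + s)
    c_pop <- balding_nichols_frequencies(anc, 0.08, seed = 1000 + s)
    o_pop <- balding_nichols_frequencies(anc, 0.15, seed = 1100 + s)
    freq <- rbind(o = o_pop[1, ], a = ab[1, ], b = ab[2, ], c = c_pop[1, ])
    part <- make_partition(seq_len(4000) * 8000)
    f_ab <- f3_statistic(freq, "o", "a", "b", part)$estimate
    f_ac <- f3_statistic(freq, "o", "a", "c", part)$estimate
    if (f_ab > f_ac) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})
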