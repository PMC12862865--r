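# shared fixtures, built in code

# tiny hand-specified dataset: 4 individuals x 5 SNPs, two groups
toy_dataset <- function() {
  g <- rbind(a1 = c(0L, 1L, 0L, 1L, NA),
             a2 = c(0L, 1L, 1L, NA, 1L),
             b1 = c(1L, 0L, 0L, 1L, 0L),
             b2 = c(1L, NA, 1L, 0L, 0L))
  snp <- data.frame(snp_id = paste0("s", 1:5), chrom = "chr1",
                    pos = c(10L, 20L, 30L, 40L, 50L),
                    ref = "A", alt = "T", stringsAsFactors = FALSE)
  ind <- data.frame(sample_id = rownames(g), group = c("a", "a", "b", "b"),
                    stringsAsFactors = FALSE)
  phap_dataset(g, snp, ind)
}

# two Balding-Nichols populations, pseudo-haploid with missingness
two_pop_dataset <- function(F = 0.05, n_per_pop = 50L, n_snps = 5000L,
                            missing_rate = 0.3, duplicate_pairs = 0L,
                            seed = 1L) {
  cfg <- sim_config(n_pops = 2L, n_snps = n_snps, pop_F = c(F, F),
                    sample_sizes = rep(n_per_pop, 2L),
                    missing_rate = missing_rate,
                    duplicate_pairs = duplicate_pairs,
                    chrom_lengths = rep(3e7, 5), seed = seed)
  build_dataset(cfg)
}

# random small pseudo-haploid matrix with holes, for brute-force oracles
random_holey_matrix <- function(n, L, miss = 0.25, seed = 1L) {
  set.seed(seed)
  g <- matrix(rbinom(n * L, 1L, runif(L)[rep(seq_len(L), each = n)]), n, L)
  g[matrix(runif(n * L) < miss, n, L)] <- NA
  storage.mode(g) <- "integer"
  rownames(g) <- paste0("i", seq_len(n))
  g
}

dataset_from_matrix <- function(g, groups = rep("g1", nrow(g)),
                                chrom = "chr1") {
  if (is.null(rownames(g))) rownames(g) <- paste0("i", seq_len(nrow(g)))
  snp <- data.frame(snp_id = paste0("s", seq_len(ncol(g))), chrom = chrom,
                    pos = seq_len(ncol(g)) * 100L, ref = "A", alt = "T",
                    stringsAsFactors = FALSE)
  ind <- data.frame(sample_id = rownames(g), group = groups,
                    stringsAsFactors = FALSE)
  phap_dataset(g, snp, ind)
}
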