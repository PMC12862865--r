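#' Draw ancestral allele frequencies
#'
#' Frequencies of the shared ancestral population from which all simulated
#' populations diverge, drawn uniformly on `[low, high]`.
#'
#' @param n_snps number of SNPs.
#' @param low,high bounds of the uniform interval, `0 < low <= high < 1`.
#' @param seed optional integer seed.
#' @return numeric vector of length `n_snps`.
#' @export
draw_ancestral_frequencies <- function(n_snps, low = 0.05, high = 0.95,
                                       seed = NULL) {
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || high >= 1)
    stop("frequency bounds must satisfy 0 < low <= high < 1 (got low = ",
         low, ", high = ", high, ")", call. = FALSE)
  if (low > high)
    stop("`low` (", low, ") exceeds `high` (", high, ")", call. = FALSE)
  with_seed(seed, stats::runif(n_snps, low, high))
}

#' Balding-Nichols population allele frequencies
#'
#' Each population's frequency at SNP j is drawn from a Beta distribution
#' centred on the ancestral frequency p_j with variance p_j (1 - p_j) F_k,
#' the Balding-Nichols model. `F = 0` reproduces the ancestral frequencies
#' exactly (no drift).
#'
#' @param ancestral ancestral frequency vector, values in (0, 1).
#' @param pop_F per-population divergence parameter, each in `[0, 1)`.
#' @param seed optional integer seed.
#' @return matrix, populations x SNPs.
#' @export
balding_nichols_frequencies <- function(ancestral, pop_F, seed = NULL) {
  if (any(ancestral <= 0) || any(ancestral >= 1))
    stop("ancestral frequencies must lie strictly in (0, 1)", call. = FALSE)
  if (any(pop_F < 0) || any(pop_F >= 1))
    stop("each F must lie in [0, 1); F = 1 gives a degenerate Beta",
         call. = FALSE)
  L <- length(ancestral)
  K <- length(pop_F)
  with_seed(seed, {
    out <- matrix(NA_real_, K, L)
    for (k in seq_len(K)) {
      Fk <- pop_F[k]
      if (Fk == 0) {
        out[k, ] <- ancestral
      } else {
        scale <- (1 - Fk) / Fk
        out[k, ] <- stats::rbeta(L, ancestral * scale, (1 - ancestral) * scale)
      }
    }
    rownames(out) <- names(pop_F)
    out
  })
}

#' Simulate diploid genotypes under admixture
#'
#' Individual i's dosage at SNP j is Binomial(2, q_ij) with
#' q_ij = sum_k a_ik p_kj, where `a` is the ancestry-proportion matrix and
#' `p` the population frequency table.
#'
#' @param pop_freqs matrix, populations x SNPs.
#' @param admixture matrix, individuals x populations; rows sum to 1.
#' @param seed optional integer seed.
#' @return integer matrix, individuals x SNPs, values 0/1/2.
#' @export
simulate_diploids <- function(pop_freqs, admixture, seed = NULL) {
  admixture <- as.matrix(admixture)
  if (ncol(admixture) != nrow(pop_freqs))
    stop("admixture has ", ncol(admixture), " columns but pop_freqs has ",
         nrow(pop_freqs), " populations", call. = FALSE)
  if (any(abs(rowSums(admixture) - 1) > 1e-12))
    stop("admixture rows must sum to 1", call. = FALSE)
  q <- admixture %*% pop_freqs
  with_seed(seed, {
    g <- matrix(stats::rbinom(length(q), 2L, q), nrow(q), ncol(q))
    storage.mode(g) <- "integer"
    rownames(g) <- rownames(admixture)
    g
  })
}

#' Pseudo-haploidize a diploid matrix
#'
#' Emulates random-haploid calling from sequencing reads: homozygotes map
#' deterministically (0 -> 0, 2 -> 1) and each heterozygote contributes one
#' of its two alleles by a fair coin. Missing entries stay missing.
#'
#' @param diploid integer matrix with values in `{0, 1, 2, NA}`.
#' @param seed optional integer seed.
#' @return integer matrix of the same shape with values in `{0, 1, NA}`.
#' @export
pseudo_haploidize <- function(diploid, seed = NULL) {
  bad <- setdiff(unique(diploid[!is.na(diploid)]), c(0L, 1L, 2L))
  if (length(bad))
    stop("diploid genotypes must be 0/1/2/NA; found ",
         paste(bad, collapse = ","), call. = FALSE)
  out <- diploid
  out[out == 2L] <- 1L
  het <- which(diploid == 1L)
  with_seed(seed, {
    out[het] <- stats::rbinom(length(het), 1L, 0.5)
    storage.mode(out) <- "integer"
    out
  })
}

#' Second independent pseudo-haploid draw from a diploid genotype
#'
#' Models the genotypes obtained from two independently built sequencing
#' libraries of the same individual: an independent random-haploid draw
#' from the identical underlying diploid genotype.
#'
#' @param diploid_row integer vector of diploid dosages (0/1/2/NA).
#' @param seed optional integer seed.
#' @return integer vector of pseudo-haploid calls.
#' @export
make_duplicate <- function(diploid_row, seed = NULL) {
  pseudo_haploidize(matrix(diploid_row, nrow = 1L), seed = seed)[1L, ]
}

#' Thin a genotype matrix with per-individual missingness
#'
#' Each observed call is independently set missing with its row's rate
#' (missing completely at random); already-missing entries stay missing.
#'
#' @param geno genotype matrix, individuals x SNPs.
#' @param rate scalar or per-individual vector of probabilities in `[0, 1)`.
#' @param seed optional integer seed.
#' @return matrix of the same shape.
#' @export
apply_missingness <- function(geno, rate, seed = NULL) {
  if (any(rate < 0) || any(rate >= 1))
    stop("missingness rate must lie in [0, 1)", call. = FALSE)
  rate <- rep_len(rate, nrow(geno))
  with_seed(seed, {
    drop <- matrix(stats::runif(length(geno)) < rate, nrow(geno), ncol(geno))
    geno[drop] <- NA
    geno
  })
}

#' Scatter SNPs across chromosomes
#'
#' Samples `n_snps` distinct 1-based positions uniformly from the
#' concatenated genome, so chromosomes receive SNPs in proportion to their
#' length; positions are sorted within chromosome.
#'
#' @param n_snps number of SNPs.
#' @param chrom_lengths named or unnamed vector of chromosome lengths (bp).
#' @param seed optional integer seed.
#' @return data frame with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`.
#' @export
assign_snp_positions <- function(n_snps, chrom_lengths, seed = NULL) {
  total <- sum(chrom_lengths)
  if (n_snps > total)
    stop("cannot place ", n_snps, " distinct SNPs on ", total, " bp",
         call. = FALSE)
  chroms <- names(chrom_lengths)
  if (is.null(chroms)) chroms <- paste0("chr", seq_along(chrom_lengths))
  with_seed(seed, {
    gpos <- sort(sample.int(total, n_snps))
    offset <- cumsum(c(0, chrom_lengths))
    idx <- findInterval(gpos, offset + 1)  # gpos in (offset[i], offset[i+1]]
    data.frame(snp_id = paste0("snp", seq_len(n_snps)),
               chrom = chroms[idx],
               pos = as.integer(gpos - offset[idx]),
               ref = "A", alt = "T",
               stringsAsFactors = FALSE)
  })
}

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. Defaults emulate a
#' six-site reduced-representation study of a low-differentiation species:
#' Balding-Nichols F between 0.025 and 0.10 (pairwise F_ST ~ 0.03-0.10),
#' heavy per-individual missingness, a few duplicate library pairs and a
#' few long-distance migrants mislabeled by capture site.
#'
#' @param n_pops number of populations.
#' @param n_snps number of SNPs.
#' @param chrom_lengths chromosome lengths in bp.
#' @param pop_F per-population Balding-Nichols divergence, each in `[0, 1)`.
#' @param sample_sizes per-population individual counts.
#' @param admixture optional individuals x populations ancestry matrix;
#'   default: every individual pure for its own population.
#' @param missing_rate scalar or per-individual missingness in `[0, 1)`.
#' @param duplicate_pairs number of planted duplicate pairs.
#' @param migrants data frame with columns `capture_label`,
#'   `true_source_pop`, `count`: `count` individuals labelled
#'   `capture_label` are actually drawn from `true_source_pop`.
#' @param anc_low,anc_high ancestral-frequency bounds.
#' @param pop_names population labels (default pop1..popK).
#' @param seed root seed for the generator.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 6L,
                       n_snps = 20000L,
                       chrom_lengths = rep(30e6, 10),
                       pop_F = c(0.10, 0.06, 0.03, 0.025, 0.025, 0.08),
                       sample_sizes = c(8L, 7L, 26L, 25L, 22L, 26L),
                       admixture = NULL,
                       missing_rate = 0.4,
                       duplicate_pairs = 0L,
                       migrants = NULL,
                       anc_low = 0.05, anc_high = 0.95,
                       pop_names = NULL,
                       seed = 1L) {
  if (n_pops < 1 || n_snps < 1 || any(sample_sizes < 1))
    stop("counts must be positive", call. = FALSE)
  if (length(pop_F) != n_pops || length(sample_sizes) != n_pops)
    stop("pop_F and sample_sizes must have length n_pops", call. = FALSE)
  if (any(pop_F < 0) || any(pop_F >= 1))
    stop("pop_F values must lie in [0, 1)", call. = FALSE)
  if (any(missing_rate < 0) || any(missing_rate >= 1))
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(n_pops))
  n_ind <- sum(sample_sizes)
  if (!is.null(admixture)) {
    admixture <- as.matrix(admixture)
    if (nrow(admixture) != n_ind || ncol(admixture) != n_pops)
      stop("admixture must be ", n_ind, " x ", n_pops, call. = FALSE)
    if (any(abs(rowSums(admixture) - 1) > 1e-12))
      stop("admixture rows must sum to 1", call. = FALSE)
  }
  if (!is.null(migrants)) {
    migrants <- as.data.frame(migrants, stringsAsFactors = FALSE)
    need <- c("capture_label", "true_source_pop", "count")
    if (!all(need %in% names(migrants)))
      stop("migrants needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    if (!all(migrants$capture_label %in% pop_names) ||
        !all(migrants$true_source_pop %in% pop_names))
      stop("migrant labels must be population names", call. = FALSE)
    per_group <- tapply(migrants$count, migrants$capture_label, sum)
    cap <- sample_sizes[match(names(per_group), pop_names)]
    if (any(per_group > cap))
      stop("migrant count exceeds group size for ",
           paste(names(per_group)[per_group > cap], collapse = ", "),
           call. = FALSE)
  }
  structure(list(n_pops = as.integer(n_pops), n_snps = as.integer(n_snps),
                 chrom_lengths = chrom_lengths, pop_F = pop_F,
                 sample_sizes = as.integer(sample_sizes),
                 admixture = admixture, missing_rate = missing_rate,
                 duplicate_pairs = as.integer(duplicate_pairs),
                 migrants = migrants, anc_low = anc_low,
                 anc_high = anc_high, pop_names = pop_names,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a full synthetic pseudo-haploid dataset
#'
#' Runs the generator end to end: ancestral frequencies, Balding-Nichols
#' population frequencies, admixed diploids, pseudo-haploid calls,
#' MCAR missingness, planted duplicate library pairs and mislabeled
#' migrants. Ground truth (true population of every individual, duplicate
#' pairs, the frequency tables) is returned alongside for validation.
#'
#' Migrants are simulated as pure individuals of their true source
#' population but carry their capture label in the sample table, emulating
#' long-distance dispersers genotyped at the capture site. Duplicates are
#' appended as extra individuals (`<id>_dup`): a second, independent
#' pseudo-haploid draw from the same diploid genotype.
#'
#' @param config a [sim_config()].
#' @return list with elements `dataset` (a [phap_dataset()]) and `truth`
#'   (list: `true_pop`, `duplicate_pairs`, `pop_freqs`, `ancestral_freqs`).
#' @export
build_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  anc <- draw_ancestral_frequencies(cf$n_snps, cf$anc_low, cf$anc_high,
                                    seed = child_seed(cf$seed, "ancestral"))
  pf <- balding_nichols_frequencies(anc, cf$pop_F,
                                    seed = child_seed(cf$seed, "popfreq"))
  rownames(pf) <- cf$pop_names

  n_ind <- sum(cf$sample_sizes)
  capture <- rep(cf$pop_names, cf$sample_sizes)
  true_pop <- capture
  # plant migrants: first `count` members of the capture group get the
  # source population's ancestry but keep the capture label
  if (!is.null(cf$migrants)) {
    used <- integer(0)
    for (i in seq_len(nrow(cf$migrants))) {
      m <- cf$migrants[i, ]
      slots <- setdiff(which(capture == m$capture_label), used)
      take <- slots[seq_len(m$count)]
      true_pop[take] <- m$true_source_pop
      used <- c(used, take)
    }
  }
  adm <- cf$admixture
  if (is.null(adm)) {
    adm <- matrix(0, n_ind, cf$n_pops)
    adm[cbind(seq_len(n_ind), match(true_pop, cf$pop_names))] <- 1
  }
  ids <- sprintf("%s_%02d", capture,
                 stats::ave(seq_len(n_ind), capture, FUN = seq_along))
  rownames(adm) <- ids

  dip <- simulate_diploids(pf, adm, seed = child_seed(cf$seed, "diploid"))
  hap <- pseudo_haploidize(dip, seed = child_seed(cf$seed, "haploid"))

  dup_pairs <- NULL
  if (cf$duplicate_pairs > 0) {
    if (cf$duplicate_pairs > n_ind)
      stop("more duplicate pairs than individuals", call. = FALSE)
    picks <- with_seed(child_seed(cf$seed, "duppick"),
                       sort(sample.int(n_ind, cf$duplicate_pairs)))
    extra <- matrix(NA_integer_, cf$duplicate_pairs, cf$n_snps)
    for (j in seq_along(picks)) {
      extra[j, ] <- make_duplicate(dip[picks[j], ],
                                   seed = child_seed(cf$seed,
                                                     paste0("dup", j)))
    }
    dup_ids <- paste0(ids[picks], "_dup")
    rownames(extra) <- dup_ids
    hap <- rbind(hap, extra)
    capture <- c(capture, capture[picks])
    true_pop <- c(true_pop, true_pop[picks])
    ids <- c(ids, dup_ids)
    dup_pairs <- data.frame(id1 = ids[picks], id2 = dup_ids,
                            stringsAsFactors = FALSE)
  }

  hap <- apply_missingness(hap, cf$missing_rate,
                           seed = child_seed(cf$seed, "missing"))

  snp <- assign_snp_positions(cf$n_snps, cf$chrom_lengths,
                              seed = child_seed(cf$seed, "positions"))
  ind <- data.frame(sample_id = ids, group = capture,
                    stringsAsFactors = FALSE)
  ds <- phap_dataset(hap, snp, ind)
  truth <- list(true_pop = stats::setNames(true_pop, ids),
                duplicate_pairs = dup_pairs,
                pop_freqs = pf,
                ancestral_freqs = anc)
  list(dataset = ds, truth = truth)
}

#' Write generator ground truth as tab-separated text
#'
#' @param truth the `truth` element of [build_dataset()].
#' @param prefix output path prefix; writes `<prefix>.true_pop.tsv` and,
#'   when present, `<prefix>.duplicates.tsv`.
#' @return invisibly, the paths written.
#' @export
write_sim_truth <- function(truth, prefix) {
  paths <- character(0)
  tp <- data.frame(sample_id = names(truth$true_pop),
                   true_pop = unname(truth$true_pop))
  p1 <- paste0(prefix, ".true_pop.tsv")
  utils::write.table(tp, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- p1
  if (!is.null(truth$duplicate_pairs)) {
    p2 <- paste0(prefix, ".duplicates.tsv")
    utils::write.table(truth$duplicate_pairs, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
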