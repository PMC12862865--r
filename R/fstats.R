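#' Partition SNPs into contiguous genomic blocks
#'
#' Greedy per-chromosome blocking for the block jackknife: a block spans at
#' most `block_bp` bases (half-open, `[start, start + block_bp)`); the next
#' SNP at or beyond that span starts a new block. Empty blocks are never
#' emitted.
#'
#' @param snp a SNP table (columns `chrom`, `pos`, positions sorted within
#'   chromosome) or a [phap_dataset()].
#' @param block_bp block span in base pairs (default 3,000,000).
#' @return data frame of class `block_partition`: `block`, `chrom`,
#'   `start`, `end` (1-based inclusive bounds of the SNPs contained),
#'   `n_snps`; with attribute `snp_block` giving each SNP's block index.
#' @export
block_partition <- function(snp, block_bp = 3e6) {
  if (inherits(snp, "phap_dataset")) snp <- snp$snp
  if (block_bp < 1) stop("block_bp must be positive", call. = FALSE)
  for (ch in unique(snp$chrom)) {
    if (is.unsorted(snp$pos[snp$chrom == ch], strictly = TRUE))
      stop("SNP table not sorted within chromosome ", ch, call. = FALSE)
  }
  snp_block <- integer(nrow(snp))
  blk <- 0L
  rows <- list()
  for (ch in unique(snp$chrom)) {
    idx <- which(snp$chrom == ch)
    start <- NA_real_
    for (i in idx) {
      if (is.na(start) || snp$pos[i] >= start + block_bp) {
        blk <- blk + 1L
        start <- snp$pos[i]
      }
      snp_block[i] <- blk
    }
  }
  agg_first <- tapply(seq_len(nrow(snp)), snp_block, function(ii)
    c(min(snp$pos[ii]), max(snp$pos[ii]), length(ii)))
  out <- data.frame(block = as.integer(names(agg_first)),
                    chrom = tapply(snp$chrom, snp_block, `[`, 1),
                    t(vapply(agg_first, identity, numeric(3))),
                    stringsAsFactors = FALSE)
  names(out)[3:5] <- c("start", "end", "n_snps")
  out$n_snps <- as.integer(out$n_snps)
  rownames(out) <- NULL
  attr(out, "snp_block") <- snp_block
  attr(out, "block_bp") <- block_bp
  class(out) <- c("block_partition", "data.frame")
  out
}

#' Weighted delete-one-block jackknife standard error
#'
#' Busing-style weighted jackknife for unequal block sizes: with g blocks
#' of weight m_j (total n), inflation factors h_j = n / m_j and
#' leave-one-out estimates theta_{-j}, the weighted jackknife mean is
#' theta_J = g * theta_hat - sum_j (1 - m_j / n) * theta_{-j} and the
#' variance is
#' (1/g) * sum_j (h_j * theta_hat - (h_j - 1) * theta_{-j} - theta_J)^2 /
#' (h_j - 1). With equal weights this reduces exactly to the classical
#' delete-one formula ((g-1)/g) * sum (theta_{-j} - mean)^2.
#'
#' @param loo per-block leave-one-out estimates theta_{-j}.
#' @param weights positive per-block weights (block SNP counts).
#' @param estimate the full-data estimate theta_hat.
#' @return list: `sem`, `bias_corrected` (the weighted jackknife mean
#'   theta_J), `n_blocks`.
#' @export
jackknife_sem <- function(loo, weights, estimate) {
  g <- length(loo)
  if (length(weights) != g)
    stop("weights and leave-one-out estimates differ in length",
         call. = FALSE)
  if (g < 2) stop("need at least two blocks", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  n <- sum(weights)
  h <- n / weights
  theta_J <- g * estimate - sum((1 - weights / n) * loo)
  pseudo <- h * estimate - (h - 1) * loo
  variance <- sum((pseudo - theta_J)^2 / (h - 1)) / g
  list(sem = sqrt(variance), bias_corrected = theta_J, n_blocks = g)
}

# shared core: per-SNP products, block jackknife, result row
fstat_core <- function(terms, usable, partition, populations) {
  snp_block <- attr(partition, "snp_block")
  if (is.null(snp_block) || length(snp_block) != length(terms))
    stop("partition does not match the frequency table's SNP count",
         call. = FALSE)
  t_u <- terms[usable]
  b_u <- snp_block[usable]
  n_snps <- length(t_u)
  if (n_snps == 0) {
    return(structure(list(populations = populations, estimate = NA_real_,
                          sem = NA_real_, z = NA_real_, n_snps = 0L,
                          n_blocks = 0L, flagged = TRUE),
                     class = "fstat_result"))
  }
  est <- mean(t_u)
  bs <- rowsum(t_u, b_u)                       # per-block term sums
  bm <- rowsum(rep(1L, n_snps), b_u)[, 1]      # per-block SNP counts
  g <- length(bm)
  if (g < 2) {
    return(structure(list(populations = populations, estimate = est,
                          sem = NA_real_, z = NA_real_,
                          n_snps = as.integer(n_snps), n_blocks = g,
                          flagged = TRUE),
                     class = "fstat_result"))
  }
  total <- sum(t_u)
  loo <- (total - bs[, 1]) / (n_snps - bm)
  jk <- jackknife_sem(loo, bm, est)
  z <- if (jk$sem > 0) est / jk$sem else NA_real_
  structure(list(populations = populations, estimate = est, sem = jk$sem,
                 z = z, n_snps = as.integer(n_snps),
                 n_blocks = as.integer(g), flagged = FALSE),
            class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("f-statistic (%s): %.6g  sem %.3g  Z %.3g  (%d SNPs, %d blocks)%s\n",
              paste(x$populations, collapse = ", "), x$estimate, x$sem,
              x$z, x$n_snps, x$n_blocks,
              if (x$flagged) "  [flagged]" else ""))
  invisible(x)
}

#' f3 statistic with block-jackknife error
#'
#' f3(target; a, b) is the mean over usable SNPs of
#' (p_target - p_a)(p_target - p_b): the covariance of the allele-frequency
#' differences of (target, a) and (target, b). With the target an outgroup
#' it measures drift shared by a and b since their divergence from it.
#' SNPs are usable when all three groups have at least one call. No
#' finite-sample bias correction is applied: the usual diploid
#' heterozygosity correction is invalid for pseudo-haploid calls, so the
#' raw estimate is biased upward by an additive term that cancels in
#' comparisons between f3 values (see the methods vignette).
#'
#' @param freq group frequency table from [group_allele_frequencies()]
#'   (its `freq` matrix, or the list itself).
#' @param target,a,b group labels (rows of `freq`), all distinct.
#' @param partition a [block_partition()] over the same SNPs.
#' @return an `fstat_result`: `populations`, `estimate`, `sem`, `z`,
#'   `n_snps`, `n_blocks`, `flagged` (sem undefined or no usable SNPs).
#' @export
f3_statistic <- function(freq, target, a, b, partition) {
  if (is.list(freq) && !is.null(freq$freq)) freq <- freq$freq
  pops <- c(target, a, b)
  if (anyDuplicated(pops)) stop("groups must be distinct", call. = FALSE)
  missing_pop <- setdiff(pops, rownames(freq))
  if (length(missing_pop))
    stop("group(s) not in frequency table: ",
         paste(missing_pop, collapse = ", "), call. = FALSE)
  pt <- freq[target, ]
  pa <- freq[a, ]
  pb <- freq[b, ]
  terms <- (pt - pa) * (pt - pb)
  fstat_core(terms, !is.na(terms), partition, pops)
}

#' f4 statistic with block-jackknife error
#'
#' f4(a, b; c, d) is the mean over usable SNPs of (p_a - p_b)(p_c - p_d):
#' the covariance of the allele-frequency differences of the (a, b) and
#' (c, d) pairs. Zero under treeness; systematic deviation indicates gene
#' flow. SNPs are usable when all four groups have at least one call.
#'
#' @inheritParams f3_statistic
#' @param a,b,c,d group labels, all distinct.
#' @return an `fstat_result`.
#' @export
f4_statistic <- function(freq, a, b, c, d, partition) {
  if (is.list(freq) && !is.null(freq$freq)) freq <- freq$freq
  pops <- c(a, b, c, d)
  if (anyDuplicated(pops)) stop("groups must be distinct", call. = FALSE)
  missing_pop <- setdiff(pops, rownames(freq))
  if (length(missing_pop))
    stop("group(s) not in frequency table: ",
         paste(missing_pop, collapse = ", "), call. = FALSE)
  terms <- (freq[a, ] - freq[b, ]) * (freq[c, ] - freq[d, ])
  fstat_core(terms, !is.na(terms), partition, pops)
}

fstat_row <- function(res) {
  pops <- res$populations
  nm <- paste0("pop", seq_along(pops))
  out <- as.data.frame(as.list(stats::setNames(pops, nm)),
                       stringsAsFactors = FALSE)
  cbind(out, data.frame(estimate = res$estimate, sem = res$sem, z = res$z,
                        n_snps = res$n_snps, n_blocks = res$n_blocks,
                        flagged = res$flagged))
}

#' Enumerate f3 statistics for all triplets
#'
#' All ordered targets with unordered (a, b) pairs, a < b lexicographic;
#' rows in deterministic order. Triplets with no usable SNPs are flagged
#' rather than dropped.
#'
#' @inheritParams f3_statistic
#' @param groups groups to enumerate (default: all rows of `freq`).
#' @return data frame, one row per (target; a, b).
#' @export
enumerate_f3 <- function(freq, partition, groups = NULL) {
  if (is.list(freq) && !is.null(freq$freq)) freq <- freq$freq
  if (is.null(groups)) groups <- rownames(freq)
  groups <- sort(groups)
  if (length(groups) < 3) stop("need at least three groups", call. = FALSE)
  rows <- list()
  for (tg in groups) {
    others <- setdiff(groups, tg)
    prs <- utils::combn(others, 2)
    for (j in seq_len(ncol(prs)))
      rows[[length(rows) + 1L]] <-
        fstat_row(f3_statistic(freq, tg, prs[1, j], prs[2, j], partition))
  }
  do.call(rbind, rows)
}

#' Enumerate f4 statistics for all canonical quartets
#'
#' One row per canonical quartet (a < b, c < d, (a, b) < (c, d)
#' lexicographically), i.e. 3 distinct statistics per 4-group subset; all
#' other orderings follow by the f4 sign symmetries.
#'
#' @inheritParams enumerate_f3
#' @return data frame, one row per canonical quartet.
#' @export
enumerate_f4 <- function(freq, partition, groups = NULL) {
  if (is.list(freq) && !is.null(freq$freq)) freq <- freq$freq
  if (is.null(groups)) groups <- rownames(freq)
  groups <- sort(groups)
  if (length(groups) < 4) stop("need at least four groups", call. = FALSE)
  quads <- utils::combn(groups, 4)
  rows <- list()
  for (j in seq_len(ncol(quads))) {
    q <- quads[, j]  # sorted
    splits <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
    for (sp in splits)
      rows[[length(rows) + 1L]] <-
        fstat_row(f4_statistic(freq, q[sp[1]], q[sp[2]], q[sp[3]], q[sp[4]],
                               partition))
  }
  do.call(rbind, rows)
}
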