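# Weir-Cockerham theta for haploid calls, computed from per-group
# call-sum and call-count matrices (groups x SNPs). Returns the
# ratio-of-averages estimate plus per-locus components.
#
# Per usable locus (>= 2 groups with >= 1 call, polymorphic overall,
# positive within-group degrees of freedom): with group call counts n_i,
# sample frequencies p_i, N = sum n_i, r = number of groups with calls,
#   MSP = sum n_i (p_i - pbar)^2 / (r - 1)
#   MSG = sum n_i p_i (1 - p_i) / sum (n_i - 1)
#   n_c = (N - sum n_i^2 / N) / (r - 1)
#   A = MSP - MSG,  B = MSP + (n_c - 1) MSG,  theta = sum A / sum B.
wc_theta_from_sums <- function(s, n) {
  N <- colSums(n)
  r <- colSums(n > 0)
  pbar <- colSums(s) / N
  p <- s / n
  p[n == 0] <- 0
  MSP_num <- colSums(n * sweep(p, 2, pbar)^2)
  msg_terms <- s - s^2 / n
  msg_terms[n == 0] <- 0
  df_within <- N - r
  usable <- r >= 2 & df_within >= 1 & pbar > 0 & pbar < 1
  MSP <- MSP_num / (r - 1)
  MSG <- colSums(msg_terms) / df_within
  n_c <- (N - colSums(n^2) / N) / (r - 1)
  A <- MSP - MSG
  B <- MSP + (n_c - 1) * MSG
  sumA <- sum(A[usable])
  sumB <- sum(B[usable])
  list(theta = if (sum(usable) == 0 || sumB == 0) NA_real_ else sumA / sumB,
       A = A, B = B, usable = usable, n_snps_used = sum(usable))
}

# group call-sum / call-count matrices for a label vector
group_sums <- function(geno, labels, levels) {
  obs <- !is.na(geno)
  g0 <- geno
  g0[!obs] <- 0L
  f <- factor(labels, levels = levels)
  keep <- !is.na(f)
  list(s = rowsum(g0[keep, , drop = FALSE] + 0, f[keep]),
       n = rowsum(obs[keep, , drop = FALSE] + 0, f[keep]))
}

#' Weir-Cockerham F_ST for pseudo-haploid groups
#'
#' A haploid-sample adaptation of the Weir-Cockerham variance-components
#' estimator: each pseudo-haploid call is one sampled allele, so the
#' within-group mean square comes from allele-frequency binomial variance
#' rather than heterozygosity. The estimate is the ratio of the summed
#' per-locus numerator and denominator components (ratio of averages).
#' Loci are used when at least two groups have calls, the pooled frequency
#' is polymorphic and the within-group degrees of freedom are positive.
#'
#' @param dataset a [phap_dataset()].
#' @param groups group labels to compare (at least two).
#' @return list: `theta`, `n_snps_used`, and per-locus components `A`
#'   (numerator), `B` (denominator), `usable`.
#' @export
wc_theta <- function(dataset, groups) {
  groups <- unique(groups)
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  unknown <- setdiff(groups, dataset$ind$group)
  if (length(unknown))
    stop("group(s) with no members: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  gs <- group_sums(dataset$geno, dataset$ind$group, groups)
  res <- wc_theta_from_sums(gs$s, gs$n)
  if (is.na(res$theta))
    warning("theta undefined: no usable polymorphic loci", call. = FALSE)
  res
}

#' Permutation empirical p-value
#'
#' The empirical p-value of an observed statistic against `n_perm`
#' permuted replicates: `(n_exceed + 1) / (n_perm + 1)`, where `n_exceed`
#' counts permuted statistics greater than or equal to the observed one
#' (ties count). Never exactly zero.
#'
#' @param n_exceed number of permuted statistics `>=` the observed.
#' @param n_perm number of permutations.
#' @return the exact rational p-value as a double.
#' @export
empirical_pvalue <- function(n_exceed, n_perm) {
  if (n_perm < 1 || n_exceed < 0 || n_exceed > n_perm)
    stop("need 0 <= n_exceed <= n_perm with n_perm >= 1", call. = FALSE)
  (n_exceed + 1) / (n_perm + 1)
}

#' Label-permutation test for F_ST
#'
#' Group labels are randomly reassigned (permuted, preserving group sizes)
#' across the individuals of the permutation pool, and the identical
#' statistic is recomputed on each permuted labelling. Permuted values
#' greater than or equal to the observed statistic count as exceedances.
#' The pool defaults to all individuals of the listed groups; the
#' statistic can be restricted to a subset of groups (e.g. one pair) while
#' permuting across the whole pool, mirroring designs where labels are
#' shuffled across all main groups.
#'
#' @param dataset a [phap_dataset()].
#' @param pool_groups groups whose individuals enter the permutation pool.
#' @param statistic_groups groups entering the F_ST statistic
#'   (default: `pool_groups`).
#' @param n_perm number of permutations (default 2500).
#' @param seed optional integer seed.
#' @param statistic optional replacement statistic: a
#'   `function(geno, labels)` returning a scalar (`NA` = undefined).
#'   Default: Weir-Cockerham theta over `statistic_groups`.
#' @return list: `theta`, `n_snps_used`, `n_perm`, `n_exceed`,
#'   `p_empirical`, `n_redrawn` (permutations redrawn because the
#'   statistic was undefined).
#' @export
permutation_test <- function(dataset, pool_groups,
                             statistic_groups = pool_groups,
                             n_perm = 2500L, seed = NULL,
                             statistic = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (!all(statistic_groups %in% pool_groups))
    stop("statistic_groups must be a subset of pool_groups", call. = FALSE)
  pool <- which(dataset$ind$group %in% pool_groups)
  labels <- dataset$ind$group[pool]
  geno <- dataset$geno[pool, , drop = FALSE]
  n_used <- NA_integer_
  if (is.null(statistic)) {
    # precompute the 0-filled call and mask matrices once; per permutation
    # only a rowsum over pool labels is needed, with the statistic groups
    # selected from its rows
    obs_mask <- !is.na(geno)
    g0 <- geno
    g0[!obs_mask] <- 0L
    storage.mode(g0) <- "double"
    m0 <- obs_mask + 0
    lv <- sort(unique(pool_groups))
    statistic <- function(geno, labels) {
      f <- factor(labels, levels = lv)
      s <- rowsum(g0, f)
      n <- rowsum(m0, f)
      wc_theta_from_sums(s[statistic_groups, , drop = FALSE],
                         n[statistic_groups, , drop = FALSE])$theta
    }
    gs <- group_sums(geno, labels, statistic_groups)
    n_used <- wc_theta_from_sums(gs$s, gs$n)$n_snps_used
  }
  theta_obs <- statistic(geno, labels)
  if (is.na(theta_obs))
    stop("observed statistic undefined", call. = FALSE)
  n_exceed <- 0L
  n_redrawn <- 0L
  with_seed(seed, {
    done <- 0L
    while (done < n_perm) {
      perm_lab <- sample(labels)
      th <- statistic(geno, perm_lab)
      if (is.na(th)) {          # degenerate labelling: redraw, log
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 100L * n_perm)
          stop("statistic undefined on nearly all permutations",
               call. = FALSE)
        next
      }
      if (th >= theta_obs) n_exceed <- n_exceed + 1L
      done <- done + 1L
    }
  })
  if (n_redrawn > 0)
    message(n_redrawn, " permutation(s) redrawn (undefined statistic)")
  list(theta = theta_obs, n_snps_used = n_used,
       n_perm = as.integer(n_perm), n_exceed = n_exceed,
       p_empirical = empirical_pvalue(n_exceed, n_perm),
       n_redrawn = n_redrawn)
}

#' Pairwise and multi-group F_ST table with permutation p-values
#'
#' One row per unordered pair of the listed groups (lexicographic order),
#' followed by a multi-group row over all listed groups (`Multi/all`) and
#' one row per configured subset (`Multi/<name>`). With `n_perm > 0` each
#' row receives a label-permutation empirical p-value; by default labels
#' are permuted across all listed groups' individuals for every row
#' (`perm_scope = "all"`), or only within the two groups of a pairwise row
#' (`perm_scope = "pair"`).
#'
#' @param dataset a [phap_dataset()].
#' @param groups main group labels (default: all groups present).
#' @param subsets named list of group subsets for extra multi-group rows.
#' @param n_perm permutations per row (0 = no p-values).
#' @param seed optional integer seed.
#' @param perm_scope `"all"` or `"pair"`.
#' @return data frame with columns `pair1`, `pair2`, `fst`,
#'   `n_snps_used`, and with permutations `n_perm`, `n_exceed`,
#'   `p_empirical`.
#' @export
pairwise_fst_table <- function(dataset, groups = NULL, subsets = list(),
                               n_perm = 0L, seed = NULL,
                               perm_scope = c("all", "pair")) {
  perm_scope <- match.arg(perm_scope)
  if (is.null(groups)) groups <- sort(unique(dataset$ind$group))
  groups <- sort(unique(groups))
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  empty <- setdiff(groups, dataset$ind$group)
  if (length(empty))
    stop("group(s) with no members: ", paste(empty, collapse = ", "),
         call. = FALSE)
  pairs <- utils::combn(groups, 2)
  rows <- list()
  row_id <- 0L
  add_row <- function(p1, p2, stat_groups, pool_groups) {
    row_id <<- row_id + 1L
    if (n_perm > 0) {
      pt <- permutation_test(dataset, pool_groups, stat_groups,
                             n_perm = n_perm,
                             seed = child_seed(seed, paste0(p1, "|", p2)))
      data.frame(pair1 = p1, pair2 = p2, fst = pt$theta,
                 n_snps_used = pt$n_snps_used, n_perm = pt$n_perm,
                 n_exceed = pt$n_exceed, p_empirical = pt$p_empirical,
                 stringsAsFactors = FALSE)
    } else {
      th <- wc_theta(dataset, stat_groups)
      data.frame(pair1 = p1, pair2 = p2, fst = th$theta,
                 n_snps_used = th$n_snps_used, stringsAsFactors = FALSE)
    }
  }
  for (j in seq_len(ncol(pairs))) {
    pool <- if (perm_scope == "all") groups else pairs[, j]
    rows[[length(rows) + 1L]] <-
      add_row(pairs[1, j], pairs[2, j], pairs[, j], pool)
  }
  rows[[length(rows) + 1L]] <- add_row("Multi", "all", groups, groups)
  if (length(subsets)) {
    nm <- names(subsets)
    if (is.null(nm) || any(nm == ""))
      nm <- paste0("subset", seq_along(subsets))
    for (j in seq_along(subsets))
      rows[[length(rows) + 1L]] <-
        add_row("Multi", nm[j], subsets[[j]], subsets[[j]])
  }
  do.call(rbind, rows)
}
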