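#' Pairwise mismatch rate between two pseudo-haploid genotype rows
#'
#' The PMR of a pair is the proportion of SNPs with valid genotypes in both
#' individuals at which their random-haploid calls differ. With zero
#' overlap the rate is undefined (`NA`) and flagged.
#'
#' @param a,b integer vectors of equal length, values in `{0, 1, NA}`.
#' @return list with `n_overlap`, `n_mismatch`, `pmr`, `defined`.
#' @export
pairwise_mismatch <- function(a, b) {
  if (length(a) != length(b))
    stop("rows differ in length (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  both <- !is.na(a) & !is.na(b)
  n_overlap <- sum(both)
  n_mismatch <- sum(a[both] != b[both])
  list(n_overlap = n_overlap, n_mismatch = n_mismatch,
       pmr = if (n_overlap > 0) n_mismatch / n_overlap else NA_real_,
       defined = n_overlap > 0)
}

#' All-pairs pairwise mismatch rates
#'
#' Computes PMR for every unordered pair of individuals via binary matrix
#' products. Pairs whose overlap falls below `min_overlap` are flagged
#' (`low_overlap`), not dropped.
#'
#' @param dataset a [phap_dataset()].
#' @param min_overlap minimum joint non-missing SNP count for a pair to be
#'   considered reliable (default 500).
#' @return data frame: `id1`, `id2`, `group1`, `group2`, `n_overlap`,
#'   `n_mismatch`, `pmr`, `low_overlap`; one row per unordered pair, ids in
#'   input order.
#' @export
pmr_matrix <- function(dataset, min_overlap = 500L) {
  g <- dataset$geno
  n <- nrow(g)
  if (n < 2) stop("need at least two individuals", call. = FALSE)
  M <- (!is.na(g)) + 0
  X <- g
  X[is.na(X)] <- 0L
  storage.mode(X) <- "double"
  overlap <- M %*% t(M)
  match1 <- X %*% t(X)              # both called 1
  Y <- M - X                        # indicator of called 0
  match0 <- Y %*% t(Y)              # both called 0
  mism <- overlap - match1 - match0
  iu <- which(upper.tri(overlap), arr.ind = TRUE)
  ids <- dataset$ind$sample_id
  grp <- dataset$ind$group
  ov <- overlap[iu]
  mm <- mism[iu]
  data.frame(id1 = ids[iu[, 1]], id2 = ids[iu[, 2]],
             group1 = grp[iu[, 1]], group2 = grp[iu[, 2]],
             n_overlap = as.integer(round(ov)),
             n_mismatch = as.integer(round(mm)),
             pmr = ifelse(ov > 0, mm / ov, NA_real_),
             low_overlap = ov < min_overlap,
             stringsAsFactors = FALSE)
}

#' Expected PMR of a related pair
#'
#' A pair with coefficient of relationship `r` is expected to show
#' `baseline * (1 - r/2)` of the unrelated-pair mismatch rate: identical
#' twins or duplicate libraries (r = 1) give half the unrelated PMR.
#'
#' @param r coefficient of relationship in `[0, 1]`.
#' @param baseline PMR of an unrelated pair, in `[0, 1]`.
#' @return expected PMR.
#' @export
expected_pmr <- function(r, baseline) {
  stop_if_not_prob(r, "r")
  stop_if_not_prob(baseline, "baseline")
  baseline * (1 - r / 2)
}

#' Detect duplicate / near-identical pairs from a PMR table
#'
#' Flags pairs whose PMR falls at or below `factor` times the median PMR of
#' within-group pairs of the relevant group. Within-group pairs are judged
#' against their own group's median (groups need at least 3 members for a
#' meaningful median; smaller groups fall back to the global within-group
#' median, with a warning). Cross-group pairs are judged against the global
#' within-group median. Pairs with unreliable overlap are never flagged.
#'
#' @param pmr a [pmr_matrix()] table.
#' @param factor flagging threshold as a fraction of the median (default
#'   0.6, midway between the 0.5 duplicate expectation and 1.0 unrelated).
#' @param min_overlap pairs with `n_overlap` below this are not flagged.
#' @return the input table with columns `median_ref` (the reference median
#'   used) and `flagged` appended.
#' @export
detect_duplicates <- function(pmr, factor = 0.6, min_overlap = 500L) {
  stop_if_not_prob(factor, "factor")
  within <- pmr$group1 == pmr$group2 & !is.na(pmr$pmr)
  global_med <- stats::median(pmr$pmr[within])
  med_by_group <- tapply(pmr$pmr[within], pmr$group1[within], stats::median)
  # a within-group median is meaningful only with >= 3 members
  # (>= 3 pairs); smaller groups use the global median
  n_pairs_by_group <- table(pmr$group1[within])
  small <- names(n_pairs_by_group)[n_pairs_by_group < 3]
  if (length(small)) {
    warning("group(s) too small for a median, using global median: ",
            paste(small, collapse = ", "), call. = FALSE)
    med_by_group[small] <- global_med
  }
  ref <- rep(global_med, nrow(pmr))
  is_within <- pmr$group1 == pmr$group2
  ref[is_within] <- med_by_group[pmr$group1[is_within]]
  flag <- !is.na(pmr$pmr) & !is.na(ref) & pmr$n_overlap >= min_overlap &
    pmr$pmr <= factor * ref
  flag[is.na(flag)] <- FALSE
  pmr$median_ref <- unname(ref)
  pmr$flagged <- flag
  pmr
}

#' Resolve flagged duplicate pairs to a drop list
#'
#' Flagged pairs are joined into connected components; within each
#' component the individual with the largest non-missing call count is
#' kept and the rest are dropped. Ties on call count are broken by
#' lexicographic sample id (the smaller id is kept).
#'
#' @param flagged a [detect_duplicates()] table (only rows with
#'   `flagged == TRUE` are used), or any data frame with `id1`, `id2`.
#' @param sample_table the dataset's `ind` table (`sample_id`, `n_calls`).
#' @return character vector of sample ids to drop (possibly empty).
#' @export
resolve_duplicates <- function(flagged, sample_table) {
  if ("flagged" %in% names(flagged))
    flagged <- flagged[flagged$flagged, , drop = FALSE]
  if (nrow(flagged) == 0) return(character(0))
  unknown <- setdiff(c(flagged$id1, flagged$id2), sample_table$sample_id)
  if (length(unknown))
    stop("flagged pairs reference unknown sample(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  # connected components by repeated label propagation
  ids <- unique(c(flagged$id1, flagged$id2))
  comp <- stats::setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(flagged))) {
      c1 <- comp[[flagged$id1[i]]]
      c2 <- comp[[flagged$id2[i]]]
      if (c1 != c2) {
        comp[comp == max(c1, c2)] <- min(c1, c2)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  drop <- character(0)
  for (cc in unique(comp)) {
    members <- names(comp)[comp == cc]
    nc <- sample_table$n_calls[match(members, sample_table$sample_id)]
    ord <- order(-nc, members)  # highest coverage first, then lexicographic
    drop <- c(drop, members[ord][-1])
  }
  sort(drop)
}
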