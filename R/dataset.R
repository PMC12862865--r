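#' Assemble a pseudo-haploid SNP dataset
#'
#' The central container of the package: a genotype matrix of pseudo-haploid
#' calls together with its SNP and sample annotation tables. Calls are coded
#' `0` (reference / major allele), `1` (alternate / minor allele) and `NA`
#' (missing). Diploid dosages (`2` present) are tolerated when
#' `haploid = FALSE`, which is how diploid matrices travel to
#' [pseudo_haploidize()].
#'
#' @param geno integer matrix, individuals x SNPs, values in `{0, 1, NA}`
#'   (`{0, 1, 2, NA}` when `haploid = FALSE`).
#' @param snp data frame with columns `snp_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`; one row per SNP, positions strictly increasing within
#'   chromosome.
#' @param ind data frame with columns `sample_id`, `group`; one row per
#'   individual. A `n_calls` column (non-missing call count per individual)
#'   is recomputed on construction.
#' @param haploid if `TRUE` (default), reject calls equal to 2.
#'
#' @return An object of class `phap_dataset`: a list with elements `geno`,
#'   `snp`, `ind`.
#' @export
phap_dataset <- function(geno, snp, ind, haploid = TRUE) {
  if (!is.matrix(geno)) stop("`geno` must be a matrix", call. = FALSE)
  storage.mode(geno) <- "integer"
  allowed <- if (haploid) c(0L, 1L) else c(0L, 1L, 2L)
  bad <- setdiff(unique(geno[!is.na(geno)]), allowed)
  if (length(bad))
    stop("genotype values outside {", paste(allowed, collapse = ","),
         ", NA}: ", paste(bad, collapse = ","), call. = FALSE)
  snp <- as.data.frame(snp, stringsAsFactors = FALSE)
  ind <- as.data.frame(ind, stringsAsFactors = FALSE)
  need_snp <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(need_snp %in% names(snp)))
    stop("`snp` must have columns ", paste(need_snp, collapse = ", "),
         call. = FALSE)
  if (!all(c("sample_id", "group") %in% names(ind)))
    stop("`ind` must have columns sample_id, group", call. = FALSE)
  if (nrow(ind) != nrow(geno) || nrow(snp) != ncol(geno))
    stop("dimension mismatch between geno (", nrow(geno), " x ", ncol(geno),
         "), ind (", nrow(ind), "), snp (", nrow(snp), ")", call. = FALSE)
  if (anyDuplicated(ind$sample_id))
    stop("duplicate sample_ids in `ind`", call. = FALSE)
  for (ch in unique(snp$chrom)) {
    p <- snp$pos[snp$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions not strictly increasing on chromosome ", ch,
           call. = FALSE)
  }
  rownames(geno) <- ind$sample_id
  colnames(geno) <- snp$snp_id
  ind$n_calls <- as.integer(rowSums(!is.na(geno)))
  structure(list(geno = geno, snp = snp, ind = ind),
            haploid = haploid, class = "phap_dataset")
}

#' @export
print.phap_dataset <- function(x, ...) {
  cat("phap_dataset:", nrow(x$geno), "individuals x", ncol(x$geno), "SNPs\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing: %.1f%%; groups: %s\n", 100 * miss,
              paste(sort(unique(x$ind$group)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.phap_dataset <- function(x) dim(x$geno)

# Subset a dataset by individual and/or SNP index, keeping tables in sync.
subset_dataset <- function(x, ind_keep = NULL, snp_keep = NULL) {
  g <- x$geno
  ind <- x$ind
  snp <- x$snp
  if (!is.null(ind_keep)) {
    g <- g[ind_keep, , drop = FALSE]
    ind <- ind[ind_keep, , drop = FALSE]
  }
  if (!is.null(snp_keep)) {
    g <- g[, snp_keep, drop = FALSE]
    snp <- snp[snp_keep, , drop = FALSE]
  }
  rownames(ind) <- NULL
  rownames(snp) <- NULL
  phap_dataset(g, snp, ind, haploid = isTRUE(attr(x, "haploid")))
}
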