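#' Centre a pseudo-haploid genotype matrix
#'
#' Subtracts from each SNP column its mean allele frequency over
#' non-missing calls; missing entries remain missing. SNPs with no calls
#' at all are rejected (they should have been filtered upstream).
#'
#' @param geno genotype matrix (individuals x SNPs) or a [phap_dataset()].
#' @return numeric matrix of centred values with `NA` preserved.
#' @export
center_genotypes <- function(geno) {
  if (inherits(geno, "phap_dataset")) geno <- geno$geno
  n_obs <- colSums(!is.na(geno))
  if (any(n_obs == 0))
    stop(sum(n_obs == 0), " SNP(s) with no non-missing calls; ",
         "filter before centring", call. = FALSE)
  mu <- colMeans(geno, na.rm = TRUE)
  sweep(geno, 2, mu)
}

#' Pairwise-complete genetic similarity matrix
#'
#' Cell (i, k) is the mean product of centred genotype values over the
#' SNPs observed in both individuals i and k — a covariance-like matrix
#' that uses every complete observation pair and never imputes. Cells
#' whose complete-pair count falls below `min_pairs` are flagged (not
#' excluded).
#'
#' @param centered output of [center_genotypes()].
#' @param min_pairs minimum complete-pair count per cell (default 100).
#' @return object of class `similarity_matrix`: list with `values`
#'   (individuals x individuals), `n_pairs` (per-cell complete-pair
#'   counts) and `low_pairs` (logical flag matrix).
#' @export
similarity_matrix <- function(centered, min_pairs = 100L) {
  if (nrow(centered) < 2) stop("need at least two individuals", call. = FALSE)
  M <- (!is.na(centered)) + 0
  X <- centered
  X[is.na(X)] <- 0
  n_pairs <- M %*% t(M)
  values <- (X %*% t(X)) / n_pairs
  values[n_pairs == 0] <- NA_real_
  values <- (values + t(values)) / 2  # enforce exact symmetry
  structure(list(values = values,
                 n_pairs = n_pairs,
                 low_pairs = n_pairs < min_pairs),
            class = "similarity_matrix")
}

#' Principal components by eigendecomposition of a similarity matrix
#'
#' Eigenpairs are returned in descending eigenvalue order; each
#' component's sign is fixed so its largest-magnitude loading is positive.
#' Because a pairwise-complete similarity matrix can be indefinite,
#' negative eigenvalues are reported as-is and excluded from the
#' variance-explained denominator.
#'
#' @param sim a [similarity_matrix()], or a plain symmetric matrix.
#' @param n_components number of leading components to return.
#' @param scale `"none"` (coordinates are eigenvector entries, default) or
#'   `"sqrt_eigenvalue"` (entries scaled by the square root of the
#'   eigenvalue; only available for positive eigenvalues).
#' @return list of class `phap_pca`: `coordinates` (individuals x
#'   components), `eigenvalues` (all, descending), `variance_explained`
#'   (fraction of the positive-eigenvalue total; `NA` for non-positive
#'   components).
#' @export
eigen_pca <- function(sim, n_components = 10L, scale = c("none",
                                                         "sqrt_eigenvalue")) {
  scale <- match.arg(scale)
  V <- if (inherits(sim, "similarity_matrix")) sim$values else sim
  if (anyNA(V))
    stop("similarity matrix contains NA cells (pairs with zero overlap)",
         call. = FALSE)
  if (max(abs(V - t(V))) > 1e-8 * max(1, max(abs(V))))
    stop("matrix is not symmetric within tolerance", call. = FALSE)
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  k <- min(n_components, ncol(V))
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- vec[, j]
    if (v[which.max(abs(v))] < 0) vec[, j] <- -v
  }
  pos_total <- sum(e$values[e$values > 0])
  ve <- ifelse(e$values > 0, e$values / pos_total, NA_real_)
  coords <- vec
  if (scale == "sqrt_eigenvalue") {
    ev_k <- e$values[seq_len(k)]
    if (any(ev_k < 0))
      stop("sqrt-eigenvalue scaling needs positive eigenvalues", call. = FALSE)
    coords <- sweep(vec, 2, sqrt(ev_k), `*`)
  }
  rownames(coords) <- rownames(V)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 variance_explained = ve),
            class = "phap_pca")
}

#' PCA of a subset of a precomputed similarity matrix
#'
#' Eigendecomposes the row/column submatrix of an existing similarity
#' matrix without recomputing it from genotypes — the similarity of the
#' retained individuals is unchanged by dropping others, so removing e.g.
#' duplicates or whole groups only subsets the matrix. A
#' recompute-from-genotypes route is available via [center_genotypes()] +
#' [similarity_matrix()] on the subset dataset; note the two differ
#' because re-centring changes the per-SNP means.
#'
#' @param sim a [similarity_matrix()].
#' @param keep sample ids (row names) to retain.
#' @param n_components number of components.
#' @inheritParams eigen_pca
#' @return a `phap_pca` object for the subset.
#' @export
subset_pca <- function(sim, keep, n_components = 10L,
                       scale = c("none", "sqrt_eigenvalue")) {
  stopifnot(inherits(sim, "similarity_matrix"))
  V <- sim$values
  if (is.null(rownames(V)))
    stop("similarity matrix has no sample ids", call. = FALSE)
  unknown <- setdiff(keep, rownames(V))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  idx <- match(keep, rownames(V))
  eigen_pca(V[idx, idx, drop = FALSE], n_components = n_components,
            scale = match.arg(scale))
}
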