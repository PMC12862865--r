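#' Flag migrant candidates from PCA position with f4 confirmation
#'
#' Each individual is assigned to the group whose PC-space centroid
#' (median over the first `n_pcs` components, excluding the individual
#' itself) is nearest; individuals whose assigned group differs from their
#' capture label are migrant candidates. Each candidate is then tested
#' with an f4 statistic f4(pool, candidate; capture group, inferred
#' source), where `pool` merges all remaining groups: a significantly
#' positive value (Z above `z_min`) confirms that the candidate shares
#' drift with the inferred source rather than its capture group.
#'
#' @param dataset a [phap_dataset()] (post-filtering).
#' @param pca a `phap_pca` for the same individuals.
#' @param partition a [block_partition()] over the dataset's SNPs.
#' @param groups groups eligible as capture/source (default: all).
#' @param n_pcs number of leading components used for assignment
#'   (default: `min(6, available)`).
#' @param z_min f4 confirmation threshold (default 2).
#' @return data frame, one row per candidate: `sample_id`, `capture`,
#'   `inferred_source`, `f4`, `sem`, `z`, `n_snps`, `confirmed`.
#' @export
detect_migrants <- function(dataset, pca, partition, groups = NULL,
                            n_pcs = NULL, z_min = 2) {
  coords <- pca$coordinates
  ids <- dataset$ind$sample_id
  if (!setequal(rownames(coords), ids))
    stop("PCA and dataset contain different individuals", call. = FALSE)
  coords <- coords[ids, , drop = FALSE]
  if (is.null(n_pcs)) n_pcs <- min(6L, ncol(coords))
  coords <- coords[, seq_len(n_pcs), drop = FALSE]
  lab <- dataset$ind$group
  if (is.null(groups)) groups <- sort(unique(lab))

  candidates <- list()
  for (i in seq_along(ids)) {
    if (!(lab[i] %in% groups)) next
    d2 <- vapply(groups, function(gp) {
      members <- which(lab == gp)
      members <- setdiff(members, i)  # leave-self-out centroid
      if (!length(members)) return(Inf)
      ctr <- apply(coords[members, , drop = FALSE], 2, stats::median)
      sum((coords[i, ] - ctr)^2)
    }, numeric(1))
    best <- groups[which.min(d2)]
    if (best != lab[i])
      candidates[[length(candidates) + 1L]] <-
        data.frame(sample_id = ids[i], capture = lab[i],
                   inferred_source = best, stringsAsFactors = FALSE)
  }
  if (!length(candidates)) {
    return(data.frame(sample_id = character(), capture = character(),
                      inferred_source = character(), f4 = numeric(),
                      sem = numeric(), z = numeric(), n_snps = integer(),
                      confirmed = logical(), stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, candidates)

  out <- list()
  for (i in seq_len(nrow(cand))) {
    id <- cand$sample_id[i]
    cap <- cand$capture[i]
    src <- cand$inferred_source[i]
    # relabel: candidate alone, capture group without it, others pooled
    lab2 <- ifelse(lab %in% c(cap, src), lab, "..pool..")
    lab2[ids == id] <- "..cand.."
    if (!all(c("..pool..", cap, src) %in% lab2)) {
      # no third-party pool (or capture group emptied): f4 unavailable
      out[[i]] <- cbind(cand[i, , drop = FALSE],
                        data.frame(f4 = NA_real_, sem = NA_real_,
                                   z = NA_real_, n_snps = 0L,
                                   confirmed = FALSE))
      next
    }
    ds2 <- dataset
    ds2$ind$group <- lab2
    fr <- group_allele_frequencies(ds2, c("..pool..", "..cand..", cap, src))
    f4 <- f4_statistic(fr, "..pool..", "..cand..", cap, src, partition)
    confirmed <- !f4$flagged && !is.na(f4$z) && f4$z > z_min
    out[[i]] <- cbind(cand[i, , drop = FALSE],
                      data.frame(f4 = f4$estimate, sem = f4$sem, z = f4$z,
                                 n_snps = f4$n_snps, confirmed = confirmed))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pipeline configuration
#'
#' Collects the parameters of every stage of [run_pipeline()]. Either
#' `sim` (a [sim_config()]) or `input_prefix` (an EIGENSTRAT triplet) must
#' be given.
#'
#' @param sim a [sim_config()], or `NULL` to read from disk.
#' @param input_prefix EIGENSTRAT prefix, used when `sim` is `NULL`.
#' @param maf,geno first-pass SNP filter (minor-allele frequency,
#'   max missing fraction).
#' @param pmr_factor,pmr_min_overlap duplicate-detection parameters.
#' @param geno2,mac,mind second-pass filters (SNP max missing,
#'   minor-allele count, individual max missing).
#' @param n_components number of principal components.
#' @param fst_groups groups for the F_ST table (default: all main groups).
#' @param fst_subsets named list of extra multi-group F_ST rows.
#' @param n_perm permutations per F_ST row.
#' @param block_bp jackknife block span (bp).
#' @param f4_quartets optional list of 4-vectors of group labels; `NULL`
#'   skips the exhaustive f4 enumeration (migrant-candidate f4 tests are
#'   always run), `"all"` enumerates every canonical quartet.
#' @param f3_enumerate enumerate all f3 triplets (logical).
#' @param migrant_pcs,migrant_z migrant-detection parameters.
#' @param seed root seed; per-stage substreams are derived from it.
#' @param outdir output directory for tables and the report (`NULL` = no
#'   files written).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, input_prefix = NULL,
                            maf = 0.01, geno = 0.5,
                            pmr_factor = 0.6, pmr_min_overlap = 500L,
                            geno2 = 0.6, mac = 3L, mind = 0.7,
                            n_components = 10L,
                            fst_groups = NULL, fst_subsets = list(),
                            n_perm = 0L, block_bp = 3e6,
                            f4_quartets = NULL, f3_enumerate = FALSE,
                            migrant_pcs = NULL, migrant_z = 2,
                            seed = 1L, outdir = NULL) {
  if (is.null(sim) && is.null(input_prefix))
    stop("either `sim` or `input_prefix` is required", call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate (or read) pseudo-haploid genotypes; SNP
#' filter (maf/geno); PMR duplicate screen and coverage-based
#' deduplication; second SNP filter (missingness + minor-allele count) and
#' individual filter; pairwise-complete PCA; pairwise and multi-group
#' Weir-Cockerham F_ST with permutation p-values; f3/f4 statistics with
#' block-jackknife errors; migrant-candidate detection. Per-stage survivor
#' counts are logged, all tables are returned (and written as
#' tab-separated text when `outdir` is set), and two runs with the same
#' config and seed produce identical results.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `config`, `log` (character),
#'   `counts` (per-stage SNP/individual survivor counts), `truth` (for
#'   simulated input), `pmr`, `dropped`, `dataset` (final), `pca`,
#'   `similarity`, `fst`, `f3`, `f4`, `migrants`, `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cf <- config
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  for (p in c("maf", "geno", "pmr_factor", "pmr_min_overlap", "geno2",
              "mac", "mind", "n_components", "n_perm", "block_bp",
              "migrant_z", "seed"))
    say("param %s = %s", p, paste(format(cf[[p]]), collapse = ","))

  counts <- list()
  note_count <- function(stage, ds) {
    counts[[stage]] <<- c(individuals = nrow(ds$geno), snps = ncol(ds$geno))
    say("stage %-12s %5d individuals x %6d SNPs", stage, nrow(ds$geno),
        ncol(ds$geno))
  }

  truth <- NULL
  if (!is.null(cf$sim)) {
    sim_cf <- cf$sim
    sim_cf$seed <- child_seed(cf$seed, "simulate")
    built <- build_dataset(sim_cf)
    ds <- built$dataset
    truth <- built$truth
  } else {
    ds <- read_eigenstrat(cf$input_prefix)
  }
  note_count("input", ds)

  ds <- filter_snps(ds, maf_min = cf$maf, max_missing = cf$geno)
  note_count("snp_filter", ds)

  pmr <- pmr_matrix(ds, min_overlap = cf$pmr_min_overlap)
  pmr <- detect_duplicates(pmr, factor = cf$pmr_factor,
                           min_overlap = cf$pmr_min_overlap)
  dropped <- resolve_duplicates(pmr, ds$ind)
  say("stage dedupe       %d pair(s) flagged, %d individual(s) dropped",
      sum(pmr$flagged), length(dropped))
  if (length(dropped))
    ds <- subset_dataset(ds, ind_keep = which(!ds$ind$sample_id %in% dropped))
  note_count("dedupe", ds)

  ds <- filter_snps_by_count(ds, max_missing = cf$geno2,
                             min_minor_count = cf$mac)
  ds <- filter_individuals(ds, max_missing = cf$mind)
  note_count("final_filter", ds)

  centered <- center_genotypes(ds)
  sim_mat <- similarity_matrix(centered)
  pca <- eigen_pca(sim_mat, n_components = cf$n_components)
  ve <- pca$variance_explained
  say("stage pca          top PC variance explained: %s",
      paste(sprintf("%.1f%%", 100 * utils::head(ve[!is.na(ve)], 3)),
            collapse = ", "))

  fst_groups <- cf$fst_groups
  if (is.null(fst_groups)) {
    tab <- table(ds$ind$group)
    fst_groups <- names(tab)[tab >= 2]  # groups of one cannot enter F_ST
  }
  fst <- NULL
  if (length(fst_groups) >= 2) {
    fst <- pairwise_fst_table(ds, fst_groups, subsets = cf$fst_subsets,
                              n_perm = cf$n_perm,
                              seed = child_seed(cf$seed, "fst"))
    say("stage fst          %d rows (%d permutations each)", nrow(fst),
        cf$n_perm)
  }

  partition <- block_partition(ds, block_bp = cf$block_bp)
  freq <- group_allele_frequencies(ds)
  f3 <- f4 <- NULL
  if (isTRUE(cf$f3_enumerate) && length(fst_groups) >= 3)
    f3 <- enumerate_f3(freq, partition, groups = fst_groups)
  if (identical(cf$f4_quartets, "all") && length(fst_groups) >= 4) {
    f4 <- enumerate_f4(freq, partition, groups = fst_groups)
  } else if (is.list(cf$f4_quartets)) {
    f4 <- do.call(rbind, lapply(cf$f4_quartets, function(q)
      fstat_row(f4_statistic(freq, q[1], q[2], q[3], q[4], partition))))
  }

  migrants <- detect_migrants(ds, pca, partition, groups = fst_groups,
                              n_pcs = cf$migrant_pcs, z_min = cf$migrant_z)
  say("stage migrants     %d candidate(s), %d confirmed", nrow(migrants),
      sum(migrants$confirmed))

  result <- structure(list(config = cf, log = log_lines, counts = counts,
                           truth = truth, pmr = pmr, dropped = dropped,
                           dataset = ds, similarity = sim_mat, pca = pca,
                           fst = fst, f3 = f3, f4 = f4,
                           migrants = migrants),
                      class = "pipeline_result")
  result$report <- write_report(result, path = NULL)

  if (!is.null(cf$outdir)) {
    dir.create(cf$outdir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, name) {
      if (is.null(x)) return()
      utils::write.table(x, file.path(cf$outdir, paste0(name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    wt(pmr, "pmr")
    coords <- data.frame(sample_id = rownames(pca$coordinates),
                         pca$coordinates, check.names = FALSE)
    wt(coords, "pca_coordinates")
    wt(data.frame(eigenvalue = pca$eigenvalues,
                  variance_explained = pca$variance_explained),
       "pca_eigenvalues")
    wt(fst, "fst")
    wt(f3, "f3")
    wt(f4, "f4")
    wt(migrants, "migrants")
    writeLines(log_lines, file.path(cf$outdir, "run.log"))
    writeLines(result$report, file.path(cf$outdir, "report.txt"))
    if (!is.null(truth)) write_sim_truth(truth, file.path(cf$outdir, "truth"))
    write_eigenstrat(ds, file.path(cf$outdir, "final"))
  }
  result
}

#' Human-readable pipeline summary
#'
#' Regenerable from the stage outputs alone: survivor counts, top-PC
#' variance explained, significant F_ST pairs, |Z| >= 2 f4 rows, and
#' flagged migrant candidates.
#'
#' @param result a `pipeline_result` (or a list with the same elements).
#' @param path optional file to write the report to.
#' @param p_threshold significance threshold for F_ST rows (default 0.05).
#' @return the report, invisibly when written, as a character vector.
#' @export
write_report <- function(result, path = NULL, p_threshold = 0.05) {
  ln <- c("== pipeline report ==", "")
  for (stage in names(result$counts)) {
    cc <- result$counts[[stage]]
    ln <- c(ln, sprintf("%-14s %5d individuals x %6d SNPs", stage,
                        cc["individuals"], cc["snps"]))
  }
  if (length(result$dropped))
    ln <- c(ln, "", paste("dropped as duplicates:",
                          paste(result$dropped, collapse = ", ")))
  ve <- result$pca$variance_explained
  ve <- ve[!is.na(ve)]
  ln <- c(ln, "", sprintf("top PCs variance explained: %s",
                          paste(sprintf("PC%d %.2f%%", seq_len(min(5, length(ve))),
                                        100 * utils::head(ve, 5)),
                                collapse = ", ")))
  if (!is.null(result$fst) && "p_empirical" %in% names(result$fst)) {
    sig <- result$fst[result$fst$p_empirical <= p_threshold, , drop = FALSE]
    ln <- c(ln, "", sprintf("F_ST rows with empirical p <= %g: %d of %d",
                            p_threshold, nrow(sig), nrow(result$fst)))
    if (nrow(sig))
      ln <- c(ln, sprintf("  %s - %s: F_ST %.4f, p %.3g", sig$pair1,
                          sig$pair2, sig$fst, sig$p_empirical))
  }
  if (!is.null(result$f4)) {
    big <- result$f4[!result$f4$flagged & !is.na(result$f4$z) &
                       abs(result$f4$z) >= 2, , drop = FALSE]
    ln <- c(ln, "", sprintf("f4 rows with |Z| >= 2: %d of %d", nrow(big),
                            nrow(result$f4)))
  }
  mg <- result$migrants
  if (!is.null(mg) && nrow(mg)) {
    ln <- c(ln, "", "migrant candidates (PCA position + f4):")
    ln <- c(ln, sprintf("  %s: captured %s, resembles %s (f4 Z %.2f%s)",
                        mg$sample_id, mg$capture, mg$inferred_source, mg$z,
                        ifelse(mg$confirmed, ", confirmed", "")))
  } else {
    ln <- c(ln, "", "migrant candidates: none")
  }
  if (!is.null(path)) {
    writeLines(ln, path)
    return(invisible(ln))
  }
  ln
}
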