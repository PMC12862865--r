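#' Read an EIGENSTRAT geno/snp/ind triplet
#'
#' The geno file holds one row per SNP and one character per individual
#' (`9` = missing); the snp file six whitespace-separated columns (snp id,
#' chromosome, genetic position, physical position, ref, alt); the ind file
#' three columns (sample id, sex, group).
#'
#' @param prefix path prefix; reads `<prefix>.geno`, `<prefix>.snp`,
#'   `<prefix>.ind`.
#' @param haploid if `TRUE` (default), a genotype of 2 is an error
#'   (strict pseudo-haploid mode); if `FALSE`, 0/1/2 values are preserved.
#' @return a [phap_dataset()].
#' @export
read_eigenstrat <- function(prefix, haploid = TRUE) {
  fg <- paste0(prefix, ".geno")
  fs <- paste0(prefix, ".snp")
  fi <- paste0(prefix, ".ind")
  for (f in c(fg, fs, fi))
    if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  snp <- utils::read.table(fs, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(snp) != 6)
    stop(fs, ": expected 6 columns, found ", ncol(snp), call. = FALSE)
  names(snp) <- c("snp_id", "chrom", "gpos", "pos", "ref", "alt")
  snp$pos <- as.integer(snp$pos)
  ind <- utils::read.table(fi, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(ind) != 3)
    stop(fi, ": expected 3 columns, found ", ncol(ind), call. = FALSE)
  names(ind) <- c("sample_id", "sex", "group")

  lines <- readLines(fg)
  if (length(lines) != nrow(snp))
    stop(fg, ": ", length(lines), " genotype rows but ", nrow(snp),
         " SNPs in ", fs, call. = FALSE)
  n_ind <- nrow(ind)
  g <- matrix(NA_integer_, n_ind, length(lines))
  for (j in seq_along(lines)) {
    v <- utf8ToInt(lines[j]) - 48L
    if (length(v) != n_ind)
      stop(fg, " line ", j, ": ", length(v), " genotypes but ", n_ind,
           " individuals in ", fi, call. = FALSE)
    bad <- setdiff(unique(v), c(0L, 1L, 2L, 9L))
    if (length(bad))
      stop(fg, " line ", j, ": invalid genotype symbol '",
           intToUtf8(bad[1] + 48L), "'", call. = FALSE)
    v[v == 9L] <- NA_integer_
    g[, j] <- v
  }
  if (haploid && any(g == 2L, na.rm = TRUE))
    stop(fg, ": diploid-coded genotypes (2) present in haploid strict mode",
         call. = FALSE)
  phap_dataset(g, snp[c("snp_id", "chrom", "pos", "ref", "alt")],
               ind[c("sample_id", "group")], haploid = haploid)
}

#' Write an EIGENSTRAT geno/snp/ind triplet
#'
#' Round-trips bit-exactly with [read_eigenstrat()].
#'
#' @param dataset a [phap_dataset()].
#' @param prefix output path prefix.
#' @return invisibly, the three paths written.
#' @export
write_eigenstrat <- function(dataset, prefix) {
  g <- dataset$geno
  g[is.na(g)] <- 9L
  lines <- apply(g, 2, function(col) intToUtf8(col + 48L))
  writeLines(lines, paste0(prefix, ".geno"))
  snp <- dataset$snp
  utils::write.table(
    data.frame(snp$snp_id, snp$chrom, 0, snp$pos, snp$ref, snp$alt),
    paste0(prefix, ".snp"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(dataset$ind$sample_id, "U", dataset$ind$group),
    paste0(prefix, ".ind"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".geno", ".snp", ".ind")))
}

#' Read a VCF and draw random pseudo-haploid calls
#'
#' For every sample and biallelic site, one allele of the GT field is
#' chosen uniformly at random; half-calls and `./.` become missing.
#' Multi-allelic records are skipped with a message. Parsing is done with
#' \pkg{vcfR}.
#'
#' @param path VCF file (plain text or gzipped).
#' @param seed optional integer seed for the allele draws.
#' @param group optional per-sample group labels (default `"all"`).
#' @return a [phap_dataset()].
#' @export
read_vcf_haploidize <- function(path, seed = NULL, group = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- v@gt[, 1]
  if (!all(grepl("(^|:)GT(:|$)", fmt)))
    stop("VCF records without a GT format field", call. = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  if (any(multi))
    message("skipping ", sum(multi), " multi-allelic record(s)")
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  # split each GT into its two (or one) alleles
  a1 <- sub("^([^/|]*)[/|].*$", "\\1", gt)
  a2 <- sub("^.*[/|]([^/|]*)$", "\\1", gt)
  a1[a1 %in% c(".", "")] <- NA
  a2[a2 %in% c(".", "")] <- NA
  haploid_entry <- !is.na(gt) & !grepl("[/|]", gt)
  a1[haploid_entry] <- gt[haploid_entry]
  a2[haploid_entry] <- gt[haploid_entry]
  n_site <- nrow(gt)
  n_ind <- ncol(gt)
  pick <- with_seed(seed, matrix(stats::runif(n_site * n_ind) < 0.5,
                                 n_site, n_ind))
  call <- ifelse(pick, a1, a2)
  call[is.na(a1) | is.na(a2)] <- NA  # half-calls and ./. -> missing
  g <- matrix(suppressWarnings(as.integer(call)), n_site, n_ind)
  g <- t(g)  # individuals x SNPs
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[
    is.na(ids) | ids == "."]
  snp <- data.frame(snp_id = ids, chrom = fix$CHROM,
                    pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  if (is.null(group)) group <- rep("all", n_ind)
  ind <- data.frame(sample_id = colnames(gt), group = group,
                    stringsAsFactors = FALSE)
  phap_dataset(g, snp, ind)
}

#' Write pseudo-haploid calls as a haploid-GT VCF
#'
#' Emits a minimal VCF 4.2 with one haploid GT per sample (`0`, `1`, or
#' `.` for missing).
#'
#' @param dataset a [phap_dataset()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_vcf_haploid <- function(dataset, path) {
  g <- t(dataset$geno)  # SNPs x individuals
  gchar <- matrix(as.character(g), nrow(g), ncol(g))
  gchar[is.na(gchar)] <- "."
  body <- cbind(dataset$snp$chrom, dataset$snp$pos, dataset$snp$snp_id,
                dataset$snp$ref, dataset$snp$alt, ".", "PASS", ".", "GT",
                gchar)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", dataset$ind$sample_id),
                     collapse = "\t")), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

# per-SNP missing fraction and pooled minor-allele statistics
snp_stats <- function(dataset) {
  g <- dataset$geno
  n_obs <- colSums(!is.na(g))
  n_alt <- colSums(g == 1L, na.rm = TRUE)
  freq_alt <- ifelse(n_obs > 0, n_alt / n_obs, NA_real_)
  list(n_obs = n_obs,
       miss_frac = 1 - n_obs / nrow(g),
       mac = pmin(n_alt, n_obs - n_alt),
       maf = pmin(freq_alt, 1 - freq_alt))
}

#' Filter SNPs on missingness and minor-allele frequency
#'
#' PLINK-style `--geno` / `--maf` filtering: a SNP is retained when its
#' missing fraction is at most `max_missing` and its minor-allele frequency
#' (computed over pooled non-missing calls) is at least `maf_min`.
#'
#' @param dataset a [phap_dataset()].
#' @param maf_min minimum minor-allele frequency (default 0.01).
#' @param max_missing maximum per-SNP missing fraction (default 0.5).
#' @return the filtered dataset; SNP order preserved.
#' @export
filter_snps <- function(dataset, maf_min = 0.01, max_missing = 0.5) {
  stop_if_not_prob(maf_min, "maf_min")
  stop_if_not_prob(max_missing, "max_missing")
  st <- snp_stats(dataset)
  keep <- st$miss_frac <= max_missing & !is.na(st$maf) & st$maf >= maf_min
  if (!any(keep)) warning("no SNPs survive the filter", call. = FALSE)
  subset_dataset(dataset, snp_keep = which(keep))
}

#' Filter SNPs on missingness and minor-allele count
#'
#' The rare-variant variant of [filter_snps()]: retains SNPs whose missing
#' fraction is at most `max_missing` and whose pooled minor-allele count is
#' at least `min_minor_count` (default 3, i.e. removes SNPs with minor
#' allele counts of 2 or less).
#'
#' @inheritParams filter_snps
#' @param min_minor_count minimum minor-allele call count.
#' @return the filtered dataset.
#' @export
filter_snps_by_count <- function(dataset, max_missing = 0.6,
                                 min_minor_count = 3L) {
  stop_if_not_prob(max_missing, "max_missing")
  st <- snp_stats(dataset)
  keep <- st$miss_frac <= max_missing & st$mac >= min_minor_count
  if (!any(keep)) warning("no SNPs survive the filter", call. = FALSE)
  subset_dataset(dataset, snp_keep = which(keep))
}

#' Filter individuals on missing-data fraction
#'
#' Removes individuals whose missing fraction exceeds `max_missing`;
#' per-individual call counts are recomputed.
#'
#' @inheritParams filter_snps
#' @param max_missing maximum per-individual missing fraction (default 0.7).
#' @return the filtered dataset.
#' @export
filter_individuals <- function(dataset, max_missing = 0.7) {
  stop_if_not_prob(max_missing, "max_missing")
  miss <- rowMeans(is.na(dataset$geno))
  subset_dataset(dataset, ind_keep = which(miss <= max_missing))
}

#' Group allele frequencies
#'
#' Pooled alternate-allele frequency per group and SNP (mean of non-missing
#' calls), with the per-cell call count. Cells with zero calls are `NA`.
#'
#' @param dataset a [phap_dataset()].
#' @param groups group labels to tabulate (default: all groups present).
#' @return list with matrices `freq` and `n_calls` (groups x SNPs).
#' @export
group_allele_frequencies <- function(dataset, groups = NULL) {
  lab <- dataset$ind$group
  if (is.null(groups)) groups <- sort(unique(lab))
  unknown <- setdiff(groups, lab)
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  g <- dataset$geno
  obs <- !is.na(g)
  g0 <- g
  g0[!obs] <- 0L
  keep <- lab %in% groups
  f <- factor(lab[keep], levels = groups)
  s <- rowsum(g0[keep, , drop = FALSE], f)        # alt-allele call sums
  n <- rowsum(obs[keep, , drop = FALSE] + 0L, f)  # call counts
  freq <- s / n
  freq[n == 0] <- NA_real_
  colnames(freq) <- colnames(n) <- dataset$snp$snp_id
  list(freq = freq, n_calls = n)
}
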