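#' Genotype- and site-level filter settings
#'
#' @param min_depth genotypes supported by fewer than this many reads are
#'   set to missing (default 4).
#' @param max_missing maximum tolerated fraction of missing genotypes per
#'   site; a site must have data in at least `1 - max_missing` of samples
#'   (ties pass). Default 0.30.
#' @param min_maf minimum minor allele frequency; sites are kept only when
#'   MAF is strictly larger than this (default 0.05).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_depth = 4L, max_missing = 0.30,
                          min_maf = 0.05) {
  if (min_depth < 0) stop("min_depth must be >= 0")
  if (max_missing < 0 || max_missing > 1)
    stop("max_missing must be in [0, 1]")
  if (min_maf < 0 || min_maf > 1) stop("min_maf must be in [0, 1]")
  structure(list(min_depth = as.integer(min_depth),
                 max_missing = max_missing, min_maf = min_maf),
            class = "filter_config")
}

#' Apply depth, missingness and MAF filters to a snp_table
#'
#' Three stages, in order:
#' \enumerate{
#'   \item genotypes supported by fewer than `min_depth` reads become
#'     missing;
#'   \item sites with a non-missing genotype fraction below
#'     `1 - max_missing` are dropped;
#'   \item minor allele frequency is computed on the allele scale from the
#'     remaining non-missing genotypes (homozygotes contribute 2 copies,
#'     heterozygotes 1 of each) and sites with MAF not strictly above
#'     `min_maf` are dropped.
#' }
#'
#' @param table a [snp_table()].
#' @param config a [filter_config()].
#' @return List with `table` (the filtered [snp_table()]) and `counts`, a
#'   named vector: genotypes masked at stage 1 and sites removed at stages
#'   2 and 3.
#' @export
apply_filters <- function(table, config = filter_config()) {
  stopifnot(inherits(table, "snp_table"), inherits(config, "filter_config"))
  if (n_sites(table) == 0) stop("empty snp_table")
  gt <- table$genotypes
  low <- table$depths < config$min_depth & !is.na(gt)
  gt[low] <- NA_integer_
  n_masked <- sum(low)

  nonmiss <- rowMeans(!is.na(gt))
  # tie tolerance: a site with exactly the threshold fraction passes
  keep_miss <- nonmiss >= (1 - config$max_missing) - 1e-9
  n_drop_miss <- sum(!keep_miss)

  alt <- rowSums(gt, na.rm = TRUE)
  total <- 2 * rowSums(!is.na(gt))
  maf <- ifelse(total > 0, pmin(alt, total - alt) / total, 0)
  keep_maf <- maf > config$min_maf
  n_drop_maf <- sum(keep_miss & !keep_maf)

  keep <- keep_miss & keep_maf
  out <- snp_table(table$sites[keep, , drop = FALSE],
                   gt[keep, , drop = FALSE],
                   table$depths[keep, , drop = FALSE],
                   table$samples)
  list(table = out,
       counts = c(genotypes_masked = n_masked,
                  sites_dropped_missingness = n_drop_miss,
                  sites_dropped_maf = n_drop_maf,
                  sites_kept = sum(keep)))
}
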