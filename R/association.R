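#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities of all
#' tables with the observed margins whose point probability does not
#' exceed the observed table's probability times `1 + 1e-7` (the standard
#' tie tolerance).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value; 1 for the all-zero table by convention.
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(tab != round(tab))) stop("counts must be integers")
  if (sum(tab) == 0) return(1)
  fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
}

# Scalar core: margins r1 = a+b, r2 = c+d, first-column total k = a+c.
fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  lo <- max(0, k - r2); hi <- min(r1, k)
  dens <- stats::dhyper(lo:hi, r1, r2, k)
  obs <- stats::dhyper(a, r1, r2, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

#' Per-SNP Fisher exact sex GWAS with Bonferroni control
#'
#' Builds, at every site, the allelic 2x2 table of (reference, alternate)
#' allele counts by sex from non-missing genotypes (homozygotes contribute
#' 2 copies of their allele, heterozygotes 1 of each) and tests it with the
#' two-sided Fisher exact test. A site is untested (p undefined) when
#' either sex has fewer than 2 non-missing genotypes or when an allele or
#' sex margin is zero; untested sites are excluded from the Bonferroni
#' denominator M, so the genome-wide significance threshold is
#' `alpha / M` with M the number of tested markers.
#'
#' @param table a filtered [snp_table()].
#' @param sexes a [sex_map()] covering the table's samples.
#' @param alpha genome-wide significance level before correction
#'   (default 0.05).
#' @return data.frame with one row per site: `scaffold`, `pos`, `p`
#'   (NA when untested) and `significant`; attributes `n_tested` (M) and
#'   `threshold` (`alpha / M`).
#' @export
sex_gwas <- function(table, sexes, alpha = 0.05) {
  grp <- check_sex_map(sexes, table)
  gm <- table$genotypes[, grp$males, drop = FALSE]
  gf <- table$genotypes[, grp$females, drop = FALSE]
  nm_ok <- rowSums(!is.na(gm))
  nf_ok <- rowSums(!is.na(gf))
  alt_m <- rowSums(gm, na.rm = TRUE)
  alt_f <- rowSums(gf, na.rm = TRUE)
  ref_m <- 2 * nm_ok - alt_m
  ref_f <- 2 * nf_ok - alt_f
  tested <- nm_ok >= 2 & nf_ok >= 2 &
    (alt_m + alt_f) > 0 & (ref_m + ref_f) > 0
  p <- rep(NA_real_, n_sites(table))
  idx <- which(tested)
  p[idx] <- vapply(idx, function(i)
    fisher_p(ref_m[i], ref_f[i], alt_m[i], alt_f[i]), 0)
  m <- sum(tested)
  thr <- if (m > 0) alpha / m else NA_real_
  out <- data.frame(scaffold = table$sites$scaffold, pos = table$sites$pos,
                    p = p, significant = !is.na(p) & p < thr)
  attr(out, "n_tested") <- m
  attr(out, "threshold") <- thr
  out
}

#' Per-SNP heterozygosity by sex and relative male heterozygosity
#'
#' For each site and each sex s, `H_s` is the fraction of heterozygous
#' calls among the non-missing genotypes of that sex; the relative male
#' heterozygosity is `dH = H_m - H_f`. Either quantity is NA when a sex
#' has no non-missing genotypes at the site.
#'
#' @inheritParams sex_gwas
#' @return data.frame with columns `scaffold`, `pos`, `H_m`, `H_f`, `dH`.
#' @export
heterozygosity_by_sex <- function(table, sexes) {
  grp <- check_sex_map(sexes, table)
  gm <- table$genotypes[, grp$males, drop = FALSE]
  gf <- table$genotypes[, grp$females, drop = FALSE]
  H_m <- rowSums(gm == 1L, na.rm = TRUE) / rowSums(!is.na(gm))
  H_f <- rowSums(gf == 1L, na.rm = TRUE) / rowSums(!is.na(gf))
  H_m[!is.finite(H_m)] <- NA_real_
  H_f[!is.finite(H_f)] <- NA_real_
  data.frame(scaffold = table$sites$scaffold, pos = table$sites$pos,
             H_m = H_m, H_f = H_f, dH = H_m - H_f)
}
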