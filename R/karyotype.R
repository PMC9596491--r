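#' Karyotype area measurements paired with scaffold sizes
#'
#' Holds per-chromosome area measurements from a karyotype image together
#' with the assembly scaffold each chromosome is paired with. Areas are in
#' arbitrary units and refer to the XX chromosome complement; if the X was
#' measured once, name it in `double_area_for` and its area is doubled.
#'
#' @param chromosome chromosome ids.
#' @param area measured areas (> 0), one per chromosome.
#' @param scaffold paired scaffold ids (one-to-one).
#' @param scaffold_bp paired scaffold sizes in bp.
#' @param assembly_total total assembly size in bp.
#' @param double_area_for optional chromosome id (e.g. the X) whose
#'   measured area is doubled to reflect the XX complement.
#' @return data.frame of class `karyotype_table` with attribute
#'   `assembly_total`.
#' @export
karyotype_table <- function(chromosome, area, scaffold, scaffold_bp,
                            assembly_total, double_area_for = NULL) {
  if (length(chromosome) < 3) stop("need at least 3 chromosomes")
  if (any(area <= 0)) stop("areas must be positive")
  if (anyDuplicated(chromosome) || anyDuplicated(scaffold))
    stop("chromosome-scaffold pairing must be one-to-one")
  if (!is.null(double_area_for)) {
    i <- match(double_area_for, chromosome)
    if (is.na(i)) stop("double_area_for names an unknown chromosome")
    area[i] <- 2 * area[i]
  }
  structure(data.frame(chromosome = chromosome, area = area,
                       scaffold = scaffold, scaffold_bp = scaffold_bp),
            assembly_total = assembly_total,
            class = c("karyotype_table", "data.frame"))
}

#' Read a karyotype measurement TSV
#'
#' Tab-separated with header columns `chromosome`, `area`, `scaffold`,
#' `scaffold_bp`.
#'
#' @param path path to the TSV.
#' @param assembly_total total assembly size in bp.
#' @param double_area_for see [karyotype_table()].
#' @return A [karyotype_table()].
#' @export
read_karyotype <- function(path, assembly_total, double_area_for = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  karyotype_table(d$chromosome, d$area, d$scaffold, d$scaffold_bp,
                  assembly_total, double_area_for = double_area_for)
}

#' Estimate chromosome nucleotide content from karyotype area fractions
#'
#' Each chromosome's estimate is its fraction of the total measured
#' karyotype area multiplied by the total assembly size, so the estimates
#' sum exactly to the assembly total.
#'
#' @param table a [karyotype_table()].
#' @return `table` with an `estimated_bp` column added.
#' @export
estimate_chrom_sizes <- function(table) {
  stopifnot(inherits(table, "karyotype_table"))
  total_area <- sum(table$area)
  if (total_area <= 0) stop("total area must be positive")
  table$estimated_bp <- table$area / total_area *
    attr(table, "assembly_total")
  table
}

#' Concordance between estimated chromosome sizes and scaffold sizes
#'
#' Ordinary least-squares regression of scaffold size on the area-based
#' size estimate; reports r-squared, slope, intercept and the F-test
#' p-value on the slope.
#'
#' @param estimates estimated chromosome sizes (bp), or a
#'   [karyotype_table()] with an `estimated_bp` column (in which case
#'   `sizes` is taken from its `scaffold_bp`).
#' @param sizes paired scaffold sizes (bp); ignored when `estimates` is a
#'   karyotype table.
#' @return List with `r_squared`, `slope`, `intercept`, `p` and the
#'   underlying `lm` fit.
#' @export
karyotype_concordance <- function(estimates, sizes = NULL) {
  if (inherits(estimates, "karyotype_table")) {
    if (!"estimated_bp" %in% names(estimates))
      estimates <- estimate_chrom_sizes(estimates)
    sizes <- estimates$scaffold_bp
    estimates <- estimates$estimated_bp
  }
  if (length(estimates) < 3) stop("need at least 3 pairs")
  if (length(estimates) != length(sizes))
    stop("estimates and sizes differ in length")
  if (stats::var(estimates) == 0) stop("zero variance in estimates")
  fit <- stats::lm(sizes ~ estimates)
  sm <- summary(fit)
  list(r_squared = sm$r.squared,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p = unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                            sm$fstatistic[3], lower.tail = FALSE)),
       fit = fit)
}
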