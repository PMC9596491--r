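#' SNP genotype and depth table
#'
#' The central container of the package: per-site biallelic genotypes and
#' per-sample sequencing depths for a population sample. Genotypes are coded
#' as alternate-allele counts (0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternate, `NA` = missing). A missing genotype may still
#' carry a depth value.
#'
#' @param sites data.frame with columns `scaffold` (character), `pos`
#'   (1-based integer position), `ref`, `alt` (single bases in A/C/G/T).
#' @param genotypes integer matrix, sites x samples, values in
#'   \{0, 1, 2, NA\}.
#' @param depths non-negative integer matrix, sites x samples.
#' @param samples character vector of sample identifiers (column order of
#'   the matrices).
#' @return An object of class `snp_table`.
#' @export
snp_table <- function(sites, genotypes, depths, samples) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("scaffold", "pos", "ref", "alt") %in% names(sites)))
  genotypes <- as.matrix(genotypes)
  depths <- as.matrix(depths)
  ns <- nrow(sites)
  if (nrow(genotypes) != ns || nrow(depths) != ns)
    stop("matrix row counts do not match number of sites")
  if (ncol(genotypes) != length(samples) || ncol(depths) != length(samples))
    stop("matrix column counts do not match number of samples")
  if (anyDuplicated(samples))
    stop("duplicate sample ids")
  bad_gt <- !(genotypes %in% c(0L, 1L, 2L) | is.na(genotypes))
  if (any(bad_gt)) stop("genotypes must be 0, 1, 2 or NA")
  if (any(depths < 0, na.rm = TRUE)) stop("depths must be non-negative")
  depths[is.na(depths)] <- 0L
  bases <- c("A", "C", "G", "T")
  if (ns > 0) {
    if (!all(sites$ref %in% bases) || !all(sites$alt %in% bases))
      stop("ref/alt alleles must be single bases in A,C,G,T")
    if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
    for (sc in unique(sites$scaffold)) {
      p <- sites$pos[sites$scaffold == sc]
      if (any(diff(p) <= 0))
        stop("positions must be strictly increasing within scaffold ", sc)
    }
  }
  rownames(genotypes) <- NULL
  rownames(depths) <- NULL
  colnames(genotypes) <- samples
  colnames(depths) <- samples
  structure(
    list(sites = sites, genotypes = genotypes, depths = depths,
         samples = as.character(samples)),
    class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat("snp_table:", nrow(x$sites), "sites x", length(x$samples), "samples\n")
  cat("scaffolds:", paste(unique(x$sites$scaffold), collapse = ", "), "\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

n_sites <- function(x) nrow(x$sites)
n_samples <- function(x) length(x$samples)

subset_sites <- function(x, keep) {
  snp_table(x$sites[keep, , drop = FALSE],
            x$genotypes[keep, , drop = FALSE],
            x$depths[keep, , drop = FALSE],
            x$samples)
}

#' Sample-to-sex assignment
#'
#' @param samples character vector of sample ids.
#' @param sex character vector, one of `"male"`/`"female"` (or `M`/`F`,
#'   case-insensitive) per sample.
#' @return Named character vector (values `"male"`/`"female"`) of class
#'   `sex_map`.
#' @export
sex_map <- function(samples, sex) {
  if (length(samples) != length(sex)) stop("samples and sex differ in length")
  if (anyDuplicated(samples)) stop("duplicate sample ids in sex map")
  norm <- tolower(as.character(sex))
  norm[norm == "m"] <- "male"
  norm[norm == "f"] <- "female"
  bad <- !norm %in% c("male", "female")
  if (any(bad))
    stop("invalid sex token(s): ", paste(unique(sex[bad]), collapse = ", "))
  structure(stats::setNames(norm, samples), class = "sex_map")
}

# Validate a sex map against a snp_table; returns male/female sample ids.
check_sex_map <- function(map, table) {
  missing <- setdiff(table$samples, names(map))
  if (length(missing) > 0)
    stop("samples without sex assignment: ", paste(missing, collapse = ", "))
  males <- table$samples[unclass(map)[table$samples] == "male"]
  females <- table$samples[unclass(map)[table$samples] == "female"]
  if (length(males) < 2 || length(females) < 2)
    stop("need at least 2 males and 2 females")
  list(males = males, females = females)
}

#' Genome layout: scaffold lengths and region annotations
#'
#' Describes the scaffolds of a (real or simulated) assembly together with
#' optional region labels. A sex scaffold must be tiled completely by the
#' ordered regions PAR1, HRX, PAR2; scaffolds without regions are treated as
#' autosomal.
#'
#' @param scaffolds data.frame with columns `id` and `length` (bp).
#' @param regions data.frame with columns `scaffold`, `start`, `end`
#'   (1-based inclusive) and `label` in \{autosomal, PAR1, HRX, PAR2\};
#'   may be empty.
#' @return Object of class `genome_layout`.
#' @export
genome_layout <- function(scaffolds, regions = NULL) {
  scaffolds <- as.data.frame(scaffolds)
  stopifnot(all(c("id", "length") %in% names(scaffolds)))
  if (anyDuplicated(scaffolds$id)) stop("duplicate scaffold ids")
  if (any(scaffolds$length <= 0)) stop("scaffold lengths must be positive")
  if (is.null(regions))
    regions <- data.frame(scaffold = character(), start = integer(),
                          end = integer(), label = character())
  regions <- as.data.frame(regions)
  if (nrow(regions) > 0) {
    stopifnot(all(c("scaffold", "start", "end", "label") %in% names(regions)))
    ok_lab <- c("autosomal", "PAR1", "HRX", "PAR2")
    if (!all(regions$label %in% ok_lab))
      stop("region labels must be in: ", paste(ok_lab, collapse = ", "))
    for (sc in unique(regions$scaffold)) {
      len <- scaffolds$length[scaffolds$id == sc]
      if (length(len) == 0) stop("region on unknown scaffold ", sc)
      r <- regions[regions$scaffold == sc, , drop = FALSE]
      r <- r[order(r$start), , drop = FALSE]
      if (any(r$start > r$end) || any(r$start < 1) || any(r$end > len))
        stop("region bounds outside scaffold ", sc)
      if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)]))
        stop("overlapping regions on scaffold ", sc)
      sexlab <- r$label[r$label != "autosomal"]
      if (length(sexlab) > 0) {
        if (!identical(r$label, c("PAR1", "HRX", "PAR2")))
          stop("sex scaffold ", sc,
               " must carry exactly the ordered regions PAR1, HRX, PAR2")
        if (r$start[1] != 1 || r$end[3] != len ||
            any(r$start[-1] != r$end[-3] + 1))
          stop("PAR1/HRX/PAR2 must tile scaffold ", sc, " completely")
      }
    }
  }
  structure(list(scaffolds = scaffolds, regions = regions),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$scaffolds), "scaffolds,",
      sum(as.numeric(x$scaffolds$length)) / 1e6, "Mb total\n")
  if (nrow(x$regions) > 0) {
    sex <- x$regions[x$regions$label != "autosomal", , drop = FALSE]
    if (nrow(sex) > 0) {
      cat("sex scaffold regions:\n")
      print(sex, row.names = FALSE)
    }
  }
  invisible(x)
}

# Region label for each (scaffold, pos); "autosomal" where no region applies.
region_label <- function(layout, scaffold, pos) {
  lab <- rep("autosomal", length(scaffold))
  r <- layout$regions
  if (nrow(r) > 0) {
    for (i in seq_len(nrow(r))) {
      hit <- scaffold == r$scaffold[i] & pos >= r$start[i] & pos <= r$end[i]
      lab[hit] <- r$label[i]
    }
  }
  lab
}

#' Default simulated genome layout
#'
#' Three 100 Mb autosomal scaffolds plus a 111 Mb sex scaffold partitioned
#' into PAR1 (21 Mb), HRX (71 Mb) and PAR2 (19 Mb) — the geometry of a
#' neo-XY system in which most of the genome is autosomal and the
#' hemizygous region spans the middle of the sex scaffold.
#'
#' @return A `genome_layout`.
#' @export
default_layout <- function() {
  genome_layout(
    scaffolds = data.frame(
      id = c("scaffold_1", "scaffold_2", "scaffold_3", "scaffold_7"),
      length = c(100e6, 100e6, 100e6, 111e6)),
    regions = data.frame(
      scaffold = "scaffold_7",
      start = c(1, 21e6 + 1, 92e6 + 1),
      end = c(21e6, 92e6, 111e6),
      label = c("PAR1", "HRX", "PAR2")))
}
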