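#' Read a multi-sample VCF into a snp_table
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}) keeping only biallelic SNP
#' records: exactly one ALT allele, REF and ALT both single bases.
#' Multi-allelic and indel records are skipped and their count reported via
#' a message. Genotypes `./.` (or `.|.`) map to missing; phased separators
#' are accepted. Records without a DP value get depth 0.
#'
#' @param path path to a VCF (optionally gzipped).
#' @return A [snp_table()]. The number of skipped non-biallelic-SNP records
#'   is attached as attribute `"skipped"`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0) {
    samples <- colnames(v@gt)[-1]
    if (is.null(samples)) samples <- character()
    return(snp_table(
      data.frame(scaffold = character(), pos = integer(),
                 ref = character(), alt = character()),
      matrix(integer(), 0, length(samples)),
      matrix(integer(), 0, length(samples)),
      samples))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  keep <- fix$REF %in% bases & fix$ALT %in% bases
  n_skip <- sum(!keep)
  if (n_skip > 0)
    message("read_vcf: skipped ", n_skip, " non-biallelic-SNP record(s)")
  pos <- as.integer(fix$POS)
  for (sc in unique(fix$CHROM)) {
    i <- which(fix$CHROM == sc)
    if (any(diff(pos[i]) <= 0)) {
      bad <- i[which(diff(pos[i]) <= 0)[1] + 1]
      stop("non-monotone position within scaffold ", sc,
           " at VCF record ", bad)
    }
  }
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  samples <- colnames(v@gt)[-1]
  gt_chr <- gsub("|", "/", gt_chr, fixed = TRUE)
  gt <- matrix(NA_integer_, nrow(fix), length(samples))
  gt[gt_chr == "0/0"] <- 0L
  gt[gt_chr %in% c("0/1", "1/0")] <- 1L
  gt[gt_chr == "1/1"] <- 2L
  if (is.null(dp)) dp <- matrix(NA_real_, nrow(fix), length(samples))
  dp[is.na(dp)] <- 0
  out <- snp_table(
    data.frame(scaffold = fix$CHROM[keep], pos = pos[keep],
               ref = fix$REF[keep], alt = fix$ALT[keep]),
    gt[keep, , drop = FALSE],
    matrix(as.integer(dp[keep, , drop = FALSE]), sum(keep), length(samples)),
    samples)
  attr(out, "skipped") <- n_skip
  out
}

#' Write a snp_table as a minimal VCF v4.2
#'
#' Emits one FORMAT field pair, `GT:DP`, which is all the downstream
#' analysis consumes. Missing genotypes are written `./.`.
#'
#' @param table a [snp_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=sexscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$samples), collapse = "\t")), con)
  if (n_sites(table) > 0) {
    gt_str <- matrix("./.", n_sites(table), n_samples(table))
    gt_str[table$genotypes == 0L] <- "0/0"
    gt_str[table$genotypes == 1L] <- "0/1"
    gt_str[table$genotypes == 2L] <- "1/1"
    cells <- matrix(paste(gt_str, table$depths, sep = ":"),
                    n_sites(table), n_samples(table))
    body <- paste(table$sites$scaffold, table$sites$pos, ".",
                  table$sites$ref, table$sites$alt, ".", "PASS", ".",
                  "GT:DP", apply(cells, 1, paste, collapse = "\t"),
                  sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a two-column sample-to-sex TSV
#'
#' Expects lines of `sample<TAB>sex` with sex in M/F/male/female
#' (case-insensitive); no header. Duplicate sample ids or unknown sex
#' tokens are errors naming the offending line.
#'
#' @param path path to the TSV.
#' @return A [sex_map()].
#' @export
read_sex_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2))
    stop("sex map line ", which(lengths(parts) < 2)[1],
         " does not have two tab-separated fields")
  ids <- trimws(vapply(parts, `[`, "", 1))
  sex <- trimws(vapply(parts, `[`, "", 2))
  if (anyDuplicated(ids))
    stop("duplicate sample id in sex map at line ",
         which(duplicated(ids))[1], ": ", ids[which(duplicated(ids))[1]])
  ok <- tolower(sex) %in% c("m", "f", "male", "female")
  if (!all(ok))
    stop("invalid sex token at line ", which(!ok)[1], ": ", sex[!ok][1])
  sex_map(ids, sex)
}

#' Write sample sexes as a two-column TSV
#'
#' @param map a [sex_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sex_map <- function(map, path) {
  writeLines(paste(names(map), ifelse(unclass(map) == "male", "M", "F"),
                   sep = "\t"), path)
  invisible(path)
}

#' Write genome-layout regions as BED4
#'
#' Converts the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention (start - 1); the BED name column carries the region
#' label.
#'
#' @param regions a [genome_layout()] (its `regions` are written) or a
#'   data.frame with columns `scaffold`, `start`, `end`, `label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  r <- if (inherits(regions, "genome_layout")) regions$regions else regions
  if (nrow(r) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  writeLines(paste(r$scaffold, format(r$start - 1, scientific = FALSE,
                                      trim = TRUE),
                   format(r$end, scientific = FALSE, trim = TRUE),
                   r$label, sep = "\t"), path)
  invisible(path)
}
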