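#' Per-site male:female sequencing depth ratio
#'
#' `r = mean(male depths) / mean(female depths)` per site, over all
#' samples of each sex regardless of genotype missingness (hemizygosity
#' manifests as depth, not as missingness, so zero depths count). A ratio
#' near 1 is expected for autosomes and near 0.5 for the hemizygous X.
#' Undefined (NA) when the female mean is 0.
#'
#' @inheritParams sex_gwas
#' @return data.frame with columns `scaffold`, `pos`, `r`.
#' @export
depth_ratio <- function(table, sexes) {
  grp <- check_sex_map(sexes, table)
  mm <- rowMeans(table$depths[, grp$males, drop = FALSE])
  mf <- rowMeans(table$depths[, grp$females, drop = FALSE])
  r <- ifelse(mf > 0, mm / mf, NA_real_)
  data.frame(scaffold = table$sites$scaffold, pos = table$sites$pos, r = r)
}

#' Interquartile-range outlier thresholds
#'
#' Quartiles by the interpolated (type-7) convention; outlier bounds at
#' `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`.
#'
#' @param values numeric vector; non-finite values are ignored; at least 4
#'   finite values are required.
#' @return List of class `iqr_thresholds` with `q1`, `q3`, `iqr`, `low`,
#'   `high`.
#' @export
iqr_thresholds <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 4) stop("need at least 4 finite values")
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  structure(list(q1 = q[1], q3 = q[2], iqr = iqr,
                 low = q[1] - 1.5 * iqr, high = q[2] + 1.5 * iqr),
            class = "iqr_thresholds")
}

#' @export
print.iqr_thresholds <- function(x, ...) {
  cat(sprintf("IQR thresholds: Q1 = %.4g, Q3 = %.4g, low = %.4g, high = %.4g\n",
              x$q1, x$q3, x$low, x$high))
  invisible(x)
}

#' Classify SNPs into sex-linkage classes
#'
#' Applies the classification rules to per-SNP statistics, in precedence
#' order:
#' \enumerate{
#'   \item `unclassified` — any of p, dH, r undefined;
#'   \item `duplicated-candidate` — significant sex association with a
#'     high depth-ratio outlier (`r > high`): the signature of a region
#'     duplicated between an autosome and the Y, giving males excess
#'     coverage;
#'   \item `Y-linked` — significant sex association;
#'   \item `X-linked` — low depth-ratio outlier (`r < low`) with male
#'     heterozygosity no higher than female (`dH <= 0`);
#'   \item `autosomal` — everything else.
#' }
#'
#' @param stats data.frame with per-site columns `p`, `significant`, `dH`,
#'   `r` (as assembled by [sexlink_scan()] or by joining [sex_gwas()],
#'   [heterozygosity_by_sex()] and [depth_ratio()]).
#' @param thresholds an [iqr_thresholds()] computed from the genome-wide
#'   depth-ratio distribution.
#' @return `stats` with a `class` column added (factor-free character).
#' @export
classify_snps <- function(stats, thresholds) {
  stopifnot(inherits(thresholds, "iqr_thresholds"),
            all(c("p", "significant", "dH", "r") %in% names(stats)))
  cls <- rep("autosomal", nrow(stats))
  undef <- is.na(stats$p) | is.na(stats$dH) | is.na(stats$r)
  sig <- !undef & stats$significant
  cls[sig] <- "Y-linked"
  cls[sig & stats$r > thresholds$high] <- "duplicated-candidate"
  cls[!undef & !sig & stats$r < thresholds$low & stats$dH <= 0] <- "X-linked"
  cls[undef] <- "unclassified"
  stats$class <- cls
  stats
}

# Sliding windows (1-based inclusive); terminal partial windows retained.
make_windows <- function(len, window, step) {
  starts <- seq(1, len, by = step)
  starts <- starts[starts <= len]
  data.frame(start = starts, end = pmin(starts + window - 1, len))
}

#' Sliding-window summary of the depth ratio
#'
#' Summarizes the per-site log2 male:female depth ratio and the percentage
#' of sex-linked (X- or Y-linked) SNPs in sliding windows along each
#' scaffold (defaults: 2 Mb windows, 500 kb step).
#'
#' @param stats classified per-site statistics (see [classify_snps()]);
#'   requires columns `scaffold`, `pos`, `r`, `class`.
#' @param layout a [genome_layout()] supplying scaffold lengths.
#' @param window window size in bp.
#' @param step step size in bp; must not exceed `window`.
#' @return data.frame with one row per window: `scaffold`, `start`, `end`,
#'   `n` (SNPs in window), `mean_log2_r` (NA when no site has a defined
#'   ratio) and `pct_sex_linked`.
#' @export
window_depth_summary <- function(stats, layout, window = 2e6, step = 5e5) {
  if (step > window) stop("step must not exceed window size")
  out <- list()
  for (i in seq_len(nrow(layout$scaffolds))) {
    sc <- layout$scaffolds$id[i]
    w <- make_windows(layout$scaffolds$length[i], window, step)
    s <- stats[stats$scaffold == sc, , drop = FALSE]
    res <- lapply(seq_len(nrow(w)), function(j) {
      in_w <- s$pos >= w$start[j] & s$pos <= w$end[j]
      r <- s$r[in_w]
      cls <- s$class[in_w]
      n_classified <- sum(cls != "unclassified")
      data.frame(
        scaffold = sc, start = w$start[j], end = w$end[j], n = sum(in_w),
        mean_log2_r = if (any(is.finite(log2(r))))
          mean(log2(r)[is.finite(log2(r))]) else NA_real_,
        pct_sex_linked = if (n_classified > 0)
          100 * sum(cls %in% c("X-linked", "Y-linked")) / n_classified
        else NA_real_)
    })
    out[[i]] <- do.call(rbind, res)
  }
  do.call(rbind, out)
}
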