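#' Fit a sex-linkage scan to a population genotype table
#'
#' The package's central estimator. Runs, in order: genotype/site filtering
#' ([apply_filters()]), the Fisher exact sex GWAS with Bonferroni control
#' ([sex_gwas()]), per-sex heterozygosity ([heterozygosity_by_sex()]) and
#' male:female depth ratios ([depth_ratio()]); calls IQR outlier thresholds
#' on the genome-wide depth-ratio distribution ([iqr_thresholds()]);
#' classifies every SNP as autosomal, X-linked, Y-linked,
#' duplicated-candidate or unclassified ([classify_snps()]); summarizes the
#' depth ratio in sliding windows ([window_depth_summary()]); and finally
#' segments the focal sex scaffold into PAR1/HRX/PAR2 from non-overlapping
#' window tallies of sex-linked SNPs ([tally_sex_linked()],
#' [segment_regions()]).
#'
#' The focal scaffold defaults to the scaffold carrying the highest share
#' of sex-linked SNPs. The segmentation threshold `tau` defaults to the
#' highest window percent observed on non-focal scaffolds plus one
#' percentage point (a data-driven empirical null), with a floor of 5%.
#'
#' @param table a [snp_table()] (unfiltered; filtering is part of the fit).
#' @param sexes a [sex_map()] covering the table's samples.
#' @param layout optional [genome_layout()]; when absent, scaffold lengths
#'   are inferred as the largest observed SNP position per scaffold.
#' @param filter a [filter_config()].
#' @param alpha genome-wide significance level for the GWAS (default 0.05,
#'   Bonferroni-corrected internally).
#' @param window,step sliding-window size and step for the depth summary
#'   (defaults 2 Mb / 500 kb).
#' @param tally_window non-overlapping window size for the sex-linked SNP
#'   tally used in segmentation (default 1 Mb).
#' @param tau segmentation threshold percent; NULL for the data-driven
#'   default.
#' @param gap number of sub-threshold windows a sex-linked run may bridge.
#' @param focal focal scaffold id override; NULL to auto-select.
#' @return Object of class `sexlink_scan`: a list with per-site `stats`
#'   (scaffold, pos, p, significant, H_m, H_f, dH, r, class),
#'   `filter_counts`, `thresholds` (IQR bounds on r), `n_tested`,
#'   `bonferroni` (the corrected p threshold), `windows`, `tally` (list of
#'   per-scaffold tallies), `segmentation` (a `par_segmentation` or NULL),
#'   `focal`, `tau`, `gap`, `layout` and the matched `call`.
#' @seealso [simulate_xy_population()] to generate data with known truth.
#' @export
sexlink_scan <- function(table, sexes, layout = NULL,
                         filter = filter_config(), alpha = 0.05,
                         window = 2e6, step = 5e5, tally_window = 1e6,
                         tau = NULL, gap = 2, focal = NULL) {
  cl <- match.call()
  if (is.null(layout)) {
    lens <- tapply(table$sites$pos, table$sites$scaffold, max)
    layout <- genome_layout(data.frame(id = names(lens),
                                       length = as.numeric(lens)))
  }
  filt <- apply_filters(table, filter)
  ft <- filt$table
  gwas <- sex_gwas(ft, sexes, alpha = alpha)
  het <- heterozygosity_by_sex(ft, sexes)
  dr <- depth_ratio(ft, sexes)
  stats <- data.frame(scaffold = ft$sites$scaffold, pos = ft$sites$pos,
                      p = gwas$p, significant = gwas$significant,
                      H_m = het$H_m, H_f = het$H_f, dH = het$dH, r = dr$r)
  thr <- iqr_thresholds(stats$r)
  stats <- classify_snps(stats, thr)
  windows <- window_depth_summary(stats, layout, window = window,
                                  step = step)
  tallies <- lapply(seq_len(nrow(layout$scaffolds)), function(i)
    tally_sex_linked(stats, layout$scaffolds$id[i],
                     layout$scaffolds$length[i], window = tally_window))
  names(tallies) <- layout$scaffolds$id

  sex_linked <- stats$class %in% c("X-linked", "Y-linked")
  seg <- NULL
  if (is.null(focal)) {
    if (any(sex_linked)) {
      per_sc <- tapply(sex_linked, stats$scaffold, sum)
      focal <- names(per_sc)[which.max(per_sc)]
    }
  }
  if (!is.null(focal)) {
    nonfocal <- unlist(lapply(tallies[names(tallies) != focal],
                              function(t) t$pct_sex_linked))
    if (is.null(tau)) tau <- default_tau(nonfocal)
    len <- layout$scaffolds$length[layout$scaffolds$id == focal]
    seg <- tryCatch(
      segment_regions(tallies[[focal]], tau = tau, gap = gap,
                      scaffold = focal, scaffold_length = len),
      error = function(e) NULL)
  }
  structure(list(stats = stats, filter_counts = filt$counts,
                 thresholds = thr, n_tested = attr(gwas, "n_tested"),
                 bonferroni = attr(gwas, "threshold"), alpha = alpha,
                 windows = windows, tally = tallies, segmentation = seg,
                 focal = focal, tau = tau, gap = gap, layout = layout,
                 call = cl),
            class = "sexlink_scan")
}

#' @export
print.sexlink_scan <- function(x, ...) {
  cat("Sex-linkage scan\n")
  cat("  sites retained after filtering:", nrow(x$stats), "\n")
  cat("  tested markers (Bonferroni M):", x$n_tested,
      sprintf(" (p threshold %.3g)\n", x$bonferroni))
  tab <- table(x$stats$class)
  cat("  classes:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$focal))
    cat("  focal scaffold:", x$focal,
        sprintf("(tau = %.3g%%)\n", x$tau))
  if (!is.null(x$segmentation)) print(x$segmentation)
  invisible(x)
}

#' @export
summary.sexlink_scan <- function(object, ...) {
  x <- object
  cat("Sex-linkage scan summary\n\n")
  cat("Filtering:\n")
  print(x$filter_counts)
  cat("\nGWAS: M =", x$n_tested, "tested markers, alpha =", x$alpha,
      sprintf("-> Bonferroni threshold %.3g\n", x$bonferroni))
  cat(sprintf("  significant sites: %d\n", sum(x$stats$significant,
                                               na.rm = TRUE)))
  cat("\nDepth-ratio outlier thresholds:\n  ")
  print(x$thresholds)
  cat("\nPer-class site counts:\n")
  print(table(x$stats$class))
  sl <- x$stats$class %in% c("X-linked", "Y-linked")
  if (any(sl)) {
    per_sc <- 100 * table(x$stats$scaffold[sl]) / sum(sl)
    cat("\nShare of sex-linked SNPs per scaffold (%):\n")
    print(round(per_sc, 1))
  }
  if (!is.null(x$segmentation)) {
    cat("\n")
    print(x$segmentation)
  }
  invisible(x)
}

#' @export
as.data.frame.sexlink_scan <- function(x, ...) x$stats

#' Plot the depth-ratio track of a sex-linkage scan
#'
#' Per-site log2 male:female depth ratio along one scaffold with the
#' sliding-window mean overlaid and any segmented PAR/HRX boundaries
#' marked.
#'
#' @param x a [sexlink_scan()] fit.
#' @param scaffold scaffold to plot; defaults to the focal scaffold.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sexlink_scan <- function(x, scaffold = x$focal, ...) {
  if (is.null(scaffold)) stop("no focal scaffold; supply `scaffold`")
  s <- x$stats[x$stats$scaffold == scaffold & is.finite(x$stats$r) &
                 x$stats$r > 0, , drop = FALSE]
  cls_col <- c(`autosomal` = "grey60", `X-linked` = "dodgerblue3",
               `Y-linked` = "firebrick3", `duplicated-candidate` = "orange",
               `unclassified` = "grey85")
  graphics::plot(s$pos / 1e6, log2(s$r), pch = 16, cex = 0.4,
                 col = cls_col[s$class], xlab = "position (Mb)",
                 ylab = expression(log[2] ~ "male/female depth ratio"),
                 main = paste("Depth ratio along", scaffold), ...)
  w <- x$windows[x$windows$scaffold == scaffold, , drop = FALSE]
  graphics::lines((w$start + w$end) / 2e6, w$mean_log2_r, lwd = 2)
  graphics::abline(h = 0, lty = 3)
  seg <- x$segmentation
  if (!is.null(seg) && identical(seg$scaffold, scaffold) &&
      !is.null(seg$HRX))
    graphics::abline(v = c(seg$HRX[1], seg$HRX[2]) / 1e6, lty = 2)
  graphics::legend("bottomleft", legend = names(cls_col), col = cls_col,
                   pch = 16, cex = 0.7, bg = "white")
  invisible(x)
}
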