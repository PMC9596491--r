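#' Tally the percent of sex-linked SNPs in non-overlapping windows
#'
#' Along one scaffold, in consecutive windows (default 1 Mb), computes
#' `100 * (#X-linked + #Y-linked) / (#classified SNPs)`. Windows
#' containing no classified SNPs are flagged uninformative (`NA` percent).
#'
#' @param stats classified per-site statistics (see [classify_snps()]).
#' @param scaffold scaffold id to tally.
#' @param scaffold_length scaffold length in bp.
#' @param window window size in bp (windows do not overlap).
#' @return data.frame with `start`, `end`, `n_classified`, `pct_sex_linked`
#'   and `informative` per window.
#' @export
tally_sex_linked <- function(stats, scaffold, scaffold_length,
                             window = 1e6) {
  w <- make_windows(scaffold_length, window, window)
  s <- stats[stats$scaffold == scaffold, , drop = FALSE]
  res <- lapply(seq_len(nrow(w)), function(j) {
    cls <- s$class[s$pos >= w$start[j] & s$pos <= w$end[j]]
    cls <- cls[cls != "unclassified"]
    n <- length(cls)
    data.frame(start = w$start[j], end = w$end[j], n_classified = n,
               pct_sex_linked = if (n > 0)
                 100 * sum(cls %in% c("X-linked", "Y-linked")) / n
               else NA_real_,
               informative = n > 0)
  })
  do.call(rbind, res)
}

#' Segment a sex scaffold into PAR1 / HRX / PAR2
#'
#' The HRX is taken as the maximal-length run of windows whose percent of
#' sex-linked SNPs exceeds the threshold `tau`, allowing runs to bridge up
#' to `gap` consecutive sub-threshold or uninformative windows. The HRX
#' span runs from the first bp of the run's first window to the last bp of
#' its last window; PAR1 is whatever precedes it on the scaffold and PAR2
#' whatever follows (either may be absent). When no window exceeds `tau`
#' the result carries no HRX and a warning is raised.
#'
#' @param tally per-window percent table from [tally_sex_linked()].
#' @param tau threshold percent for a window to count as sex-linked.
#' @param gap number of consecutive sub-threshold or uninformative windows
#'   a run may bridge (default 2).
#' @param scaffold scaffold id (recorded in the result).
#' @param scaffold_length scaffold length in bp.
#' @return List of class `par_segmentation` with elements `scaffold`,
#'   `PAR1`, `HRX`, `PAR2` (each `c(start, end)` or NULL), `tally`, `tau`,
#'   `gap`.
#' @export
segment_regions <- function(tally, tau, gap = 2, scaffold = NA_character_,
                            scaffold_length = max(tally$end)) {
  if (!any(tally$informative)) stop("no informative window")
  above <- which(tally$informative & !is.na(tally$pct_sex_linked) &
                   tally$pct_sex_linked > tau)
  res <- structure(list(scaffold = scaffold, PAR1 = NULL, HRX = NULL,
                        PAR2 = NULL, tally = tally, tau = tau, gap = gap),
                   class = "par_segmentation")
  if (length(above) == 0) {
    warning("no window exceeds tau = ", tau, "; no HRX detected")
    return(res)
  }
  # group above-threshold windows separated by <= gap bridgeable windows
  grp <- cumsum(c(1, diff(above) > gap + 1))
  runs <- split(above, grp)
  span <- vapply(runs, function(x) max(x) - min(x) + 1L, 1L)
  run <- runs[[which.max(span)]]
  hrx <- c(tally$start[min(run)], tally$end[max(run)])
  res$HRX <- hrx
  if (hrx[1] > 1) res$PAR1 <- c(1, hrx[1] - 1)
  if (hrx[2] < scaffold_length) res$PAR2 <- c(hrx[2] + 1, scaffold_length)
  res
}

#' @export
print.par_segmentation <- function(x, ...) {
  cat("PAR/HRX segmentation of", x$scaffold,
      sprintf("(tau = %.3g%%, gap = %d windows)\n", x$tau, x$gap))
  fmt <- function(nm, sp) {
    if (is.null(sp)) cat(" ", nm, ": absent\n")
    else cat(sprintf("  %s: %s-%s (%.1f Mb)\n", nm,
                     format(sp[1], big.mark = ",", scientific = FALSE),
                     format(sp[2], big.mark = ",", scientific = FALSE),
                     (sp[2] - sp[1] + 1) / 1e6))
  }
  fmt("PAR1", x$PAR1); fmt("HRX", x$HRX); fmt("PAR2", x$PAR2)
  invisible(x)
}

# Data-driven tau: the highest window percent seen on non-focal scaffolds
# plus one percentage point, with a floor of 5%.
default_tau <- function(nonfocal_pcts) {
  pcts <- nonfocal_pcts[is.finite(nonfocal_pcts)]
  max(5, if (length(pcts) > 0) max(pcts) + 1 else -Inf)
}
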