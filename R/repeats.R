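#' Kimura 2-parameter divergence of an insert from its consensus
#'
#' Over the ungapped, unambiguous columns of a pairwise alignment, computes
#' the transition proportion p and transversion proportion q and returns
#' `K = -0.5 * ln((1 - 2p - q) * sqrt(1 - 2q))`, the standard proxy for a
#' repeat insertion's age. With `cpg_correction`, a transition whose
#' consensus position lies within a consensus CpG dinucleotide is
#' down-weighted to 1/10 (CpG sites are hypermutable, so counting their
#' transitions fully overestimates age-relevant divergence).
#'
#' @param consensus,insert aligned sequences of equal length; alphabet
#'   A/C/G/T/N/-.
#' @param cpg_correction down-weight consensus-CpG transitions by 1/10.
#' @param min_sites minimum number of ungapped unambiguous columns
#'   (default 20); shorter alignments return NA.
#' @return List with `K` (NA when the alignment is too short or
#'   saturated), `p`, `q`, `n` (columns used) and `saturated`.
#' @export
k2p_divergence <- function(consensus, insert, cpg_correction = TRUE,
                           min_sites = 20L) {
  cc <- strsplit(toupper(consensus), "")[[1]]
  ii <- strsplit(toupper(insert), "")[[1]]
  if (length(cc) != length(ii))
    stop("consensus and insert must be aligned to equal length")
  bases <- c("A", "C", "G", "T")
  valid <- cc %in% bases & ii %in% bases
  n <- sum(valid)
  if (n < min_sites)
    return(list(K = NA_real_, p = NA_real_, q = NA_real_, n = n,
                saturated = FALSE))
  # CpG dinucleotides on the ungapped consensus, mapped back to alignment
  cons_pos <- which(cc %in% bases)
  u <- cc[cons_pos]
  cpg_start <- u[-length(u)] == "C" & u[-1] == "G"
  in_cpg <- logical(length(cc))
  in_cpg[cons_pos[c(cpg_start, FALSE)]] <- TRUE
  in_cpg[cons_pos[c(FALSE, cpg_start)]] <- TRUE

  mism <- valid & cc != ii
  purine <- c("A", "G")
  is_ts <- mism & ((cc %in% purine) == (ii %in% purine))
  is_tv <- mism & !is_ts
  w <- ifelse(is_ts, ifelse(cpg_correction & in_cpg, 0.1, 1), 0)
  p <- sum(w) / n
  q <- sum(is_tv) / n
  arg1 <- 1 - 2 * p - q
  arg2 <- 1 - 2 * q
  if (arg1 <= 0 || arg2 <= 0)
    return(list(K = NA_real_, p = p, q = q, n = n, saturated = TRUE))
  list(K = -0.5 * log(arg1 * sqrt(arg2)), p = p, q = q, n = n,
       saturated = FALSE)
}

#' Per-record K2P divergence for a table of repeat alignments
#'
#' @param records data.frame of repeat alignments (columns `family`,
#'   `class`, `genome`, `consensus`, `insert`), e.g. from
#'   [simulate_repeat_alignments()] or [read_repeat_alignments()].
#' @inheritParams k2p_divergence
#' @return `records` with columns `K`, `p`, `q`, `n_aligned`, `saturated`
#'   and `insert_bp` (ungapped insert length) added.
#' @export
repeat_divergence <- function(records, cpg_correction = TRUE,
                              min_sites = 20L) {
  res <- lapply(seq_len(nrow(records)), function(i)
    k2p_divergence(records$consensus[i], records$insert[i],
                   cpg_correction = cpg_correction, min_sites = min_sites))
  records$K <- vapply(res, `[[`, 0, "K")
  records$p <- vapply(res, `[[`, 0, "p")
  records$q <- vapply(res, `[[`, 0, "q")
  records$n_aligned <- vapply(res, `[[`, 0L, "n")
  records$saturated <- vapply(res, `[[`, TRUE, "saturated")
  records$insert_bp <- nchar(gsub("-", "", records$insert, fixed = TRUE))
  records
}

#' Read repeat insert-vs-consensus alignments from TSV
#'
#' Tab-separated with header columns `family`, `class`, `genome`,
#' `consensus`, `insert` (aligned, equal length, gaps as `-`).
#'
#' @param path path to the TSV.
#' @return data.frame of alignment records.
#' @export
read_repeat_alignments <- function(path) {
  rec <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("family", "class", "genome", "consensus", "insert")
  if (!all(need %in% names(rec)))
    stop("repeat alignment TSV must have columns: ",
         paste(need, collapse = ", "))
  if (any(nchar(rec$consensus) != nchar(rec$insert)))
    stop("consensus and insert must be aligned to equal length")
  rec
}

#' Bin repeat insertions into a divergence landscape
#'
#' Each non-saturated record contributes its ungapped insert bp to the
#' integer percent-divergence bin `floor(100 K)` of its repeat class
#' (left-closed bins `[k%, k+1%)`); bp are converted to genome proportions
#' by dividing by the genome size. Saturated or too-short records are
#' excluded with a message.
#'
#' @param records repeat alignment records (divergence columns are added
#'   via [repeat_divergence()] if absent).
#' @param genome_size assembly size in bp (> 0).
#' @inheritParams k2p_divergence
#' @return data.frame with one row per (class, bin): `class`, `bin`,
#'   `bp`, `proportion`.
#' @export
build_landscape <- function(records, genome_size, cpg_correction = TRUE) {
  if (genome_size <= 0) stop("genome_size must be positive")
  if (!"K" %in% names(records))
    records <- repeat_divergence(records, cpg_correction = cpg_correction)
  drop <- is.na(records$K)
  if (any(drop))
    message("build_landscape: excluded ", sum(drop),
            " saturated or too-short record(s)")
  rec <- records[!drop, , drop = FALSE]
  if (nrow(rec) == 0)
    return(data.frame(class = character(), bin = integer(),
                      bp = numeric(), proportion = numeric()))
  rec$bin <- pmin(50L, as.integer(floor(100 * rec$K)))
  agg <- stats::aggregate(insert_bp ~ class + bin, data = rec, FUN = sum)
  names(agg)[names(agg) == "insert_bp"] <- "bp"
  agg$proportion <- agg$bp / genome_size
  agg[order(agg$class, agg$bin), ]
}

#' Compare the recent-insertion fraction of two genomes per repeat class
#'
#' For every repeat class present in both genomes, each repeat family is
#' one observation: the proportion of its genome occupied by insertions
#' with divergence at or below `cutoff`. The two genomes' family values
#' are compared with the Kruskal--Wallis rank test (midranks, tie
#' correction, chi-square with 1 df). Classes absent from either genome
#' are skipped with a warning.
#'
#' @param records repeat alignment records from exactly two genomes
#'   (divergence columns added if absent).
#' @param genome_sizes named numeric vector of assembly sizes (bp), names
#'   matching the two genome ids in `records`.
#' @param cutoff divergence cutoff defining "recent" (default 0.10).
#' @inheritParams k2p_divergence
#' @return data.frame with one row per class: `class`, `H`, `p`, and the
#'   aggregate recent genome proportion of each genome
#'   (`recent_<genome>`).
#' @export
compare_recent_fraction <- function(records, genome_sizes, cutoff = 0.10,
                                    cpg_correction = TRUE) {
  if (!"K" %in% names(records))
    records <- repeat_divergence(records, cpg_correction = cpg_correction)
  genomes <- sort(unique(records$genome))
  if (length(genomes) != 2) stop("records must come from exactly 2 genomes")
  if (!all(genomes %in% names(genome_sizes)))
    stop("genome_sizes must be named with the genome ids")
  records <- records[!is.na(records$K), , drop = FALSE]
  out <- list()
  for (cl in sort(unique(records$class))) {
    rc <- records[records$class == cl, , drop = FALSE]
    if (!all(genomes %in% rc$genome)) {
      warning("class ", cl, " absent from one genome; skipped")
      next
    }
    vals <- list(); grp <- list()
    for (g in genomes) {
      rg <- rc[rc$genome == g, , drop = FALSE]
      recent_bp <- tapply(rg$insert_bp * (rg$K <= cutoff), rg$family, sum)
      vals[[g]] <- as.numeric(recent_bp) / genome_sizes[[g]]
      grp[[g]] <- rep(g, length(recent_bp))
    }
    v <- unlist(vals, use.names = FALSE)
    g <- factor(unlist(grp, use.names = FALSE))
    kw <- if (length(unique(v)) == 1)
      list(statistic = c(H = 0), p.value = 1)
    else stats::kruskal.test(v, g)
    row <- data.frame(class = cl, H = unname(kw$statistic),
                      p = kw$p.value)
    for (g2 in genomes)
      row[[paste0("recent_", g2)]] <- sum(vals[[g2]])
    out[[cl]] <- row
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
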