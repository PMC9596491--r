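#' Simulation configuration for an XY population
#'
#' Describes the generative model used by [simulate_xy_population()]: a
#' male-heterogametic population genotyped at SNPs scattered over a genome
#' with autosomes plus one sex scaffold carrying PAR1--HRX--PAR2 structure.
#' Within the HRX, males are hemizygous: they carry one X copy, so their
#' expected sequencing depth is half the female depth, and diploid-assuming
#' genotype callers emit homozygous calls for their single allele. A
#' fraction of HRX sites are fixed X--Y gametolog differences, which appear
#' as male-limited heterozygosity when Y-derived reads map onto the X
#' scaffold.
#'
#' @param seed integer RNG seed; a fixed seed gives identical output.
#' @param n_males,n_females sample counts per sex.
#' @param layout a [genome_layout()] giving scaffolds and true regions.
#' @param snp_spacing mean distance in bp between adjacent SNPs
#'   (exponential inter-SNP gaps).
#' @param maf_range range of the uniform minor-allele-frequency
#'   distribution for polymorphic sites.
#' @param lambda mean reads per chromosome copy, so a diploid site has
#'   expected depth `2 * lambda`.
#' @param gametolog_fraction proportion of HRX sites that are fixed X--Y
#'   differences.
#' @param xpoly_fraction proportion of HRX sites polymorphic on the X only;
#'   `gametolog_fraction + xpoly_fraction` must be at most 1 (any remainder
#'   is monomorphic hemizygous sequence).
#' @param rho probability that a Y-derived read maps onto the X scaffold at
#'   a gametolog site (0 elsewhere in the HRX); at `rho = 1` gametolog
#'   sites show male heterozygosity together with near-diploid male depth.
#' @param dropout probability that a genotype call is masked at random.
#' @param overdispersion depth variance multiplier; 1 gives Poisson depth,
#'   values above 1 use a negative binomial with the same mean.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_males = 25L, n_females = 25L,
                       layout = default_layout(), snp_spacing = 3e4,
                       maf_range = c(0.05, 0.5), lambda = 10,
                       gametolog_fraction = 0.1, xpoly_fraction = 0.9,
                       rho = 1, dropout = 0.01, overdispersion = 1) {
  stopifnot(inherits(layout, "genome_layout"),
            n_males >= 2, n_females >= 2, snp_spacing > 0, lambda > 0,
            rho >= 0, rho <= 1, dropout >= 0, dropout < 1,
            gametolog_fraction >= 0, xpoly_fraction >= 0,
            overdispersion >= 1)
  if (gametolog_fraction + xpoly_fraction > 1)
    stop("gametolog_fraction + xpoly_fraction must be <= 1")
  structure(list(seed = as.integer(seed), n_males = as.integer(n_males),
                 n_females = as.integer(n_females), layout = layout,
                 snp_spacing = snp_spacing, maf_range = maf_range,
                 lambda = lambda, gametolog_fraction = gametolog_fraction,
                 xpoly_fraction = xpoly_fraction, rho = rho,
                 dropout = dropout, overdispersion = overdispersion),
            class = "sim_config")
}

# Exponential inter-SNP gaps (minimum 1 bp), truncated at scaffold length.
sim_positions <- function(len, spacing) {
  n_guess <- ceiling(len / spacing * 1.4) + 25
  pos <- cumsum(pmax(1, round(stats::rexp(n_guess, 1 / spacing))))
  while (pos[length(pos)] < len) {
    extra <- cumsum(pmax(1, round(stats::rexp(n_guess, 1 / spacing))))
    pos <- c(pos, pos[length(pos)] + extra)
  }
  pos[pos <= len]
}

sim_depth <- function(n, mu, overdispersion) {
  if (overdispersion == 1) {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, mu = mu, size = mu / (overdispersion - 1))
  }
}

#' Simulate an XY population genotype table
#'
#' Generates a [snp_table()], [sex_map()] and the true [genome_layout()]
#' under the model described in [sim_config()]:
#' \itemize{
#'   \item autosomal and PAR sites: minor-allele frequency drawn from
#'     `maf_range`, Hardy--Weinberg genotypes in both sexes, copy number 2;
#'   \item HRX X-polymorphic sites: females Hardy--Weinberg diploid; males
#'     carry a single X allele, called homozygous for it, copy number 1;
#'   \item HRX gametolog sites: females homozygous reference (copy 2);
#'     males called heterozygous (X reference + Y alternate) with
#'     probability `rho`, otherwise homozygous reference, with copy number
#'     `1 + rho`;
#'   \item depth per sample per site is Poisson with mean
#'     `copy_number * lambda` (negative binomial if overdispersed);
#'   \item genotypes are masked at random at the `dropout` rate.
#' }
#'
#' @param config a [sim_config()].
#' @return A list of class `xy_sim` with elements `snp` ([snp_table()]),
#'   `sexes` ([sex_map()]), `layout` (the truth layout, unchanged) and
#'   `truth`, a data.frame with one row per site giving the true `region`
#'   (autosomal/PAR1/HRX/PAR2) and `sim_class` (one of `diploid`,
#'   `x_poly`, `gametolog`, `x_mono`).
#' @export
simulate_xy_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  layout <- config$layout
  if (config$gametolog_fraction > 0 &&
      !any(layout$regions$label == "HRX"))
    stop("layout has no HRX region but gametolog_fraction > 0")
  set.seed(config$seed)
  nm <- config$n_males; nf <- config$n_females; ntot <- nm + nf
  samples <- c(sprintf("m%02d", seq_len(nm)), sprintf("f%02d", seq_len(nf)))
  sexes <- sex_map(samples, rep(c("male", "female"), c(nm, nf)))
  male_idx <- seq_len(nm); female_idx <- nm + seq_len(nf)

  sites_list <- lapply(seq_len(nrow(layout$scaffolds)), function(i) {
    pos <- sim_positions(layout$scaffolds$length[i], config$snp_spacing)
    data.frame(scaffold = layout$scaffolds$id[i], pos = pos)
  })
  sites <- do.call(rbind, sites_list)
  ns <- nrow(sites)
  region <- region_label(layout, sites$scaffold, sites$pos)

  sim_class <- rep("diploid", ns)
  hrx <- which(region == "HRX")
  if (length(hrx) > 0) {
    u <- stats::runif(length(hrx))
    sim_class[hrx] <- ifelse(
      u < config$gametolog_fraction, "gametolog",
      ifelse(u < config$gametolog_fraction + config$xpoly_fraction,
             "x_poly", "x_mono"))
  }

  ref <- sample(c("A", "C", "G", "T"), ns, replace = TRUE)
  alt <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")

  gt <- matrix(0L, ns, ntot)
  copy <- matrix(2, ns, ntot)

  dip <- which(sim_class == "diploid")
  if (length(dip) > 0) {
    p <- stats::runif(length(dip), config$maf_range[1], config$maf_range[2])
    gt[dip, ] <- matrix(stats::rbinom(length(dip) * ntot, 2, rep(p, ntot)),
                        length(dip), ntot)
  }
  xp <- which(sim_class == "x_poly")
  if (length(xp) > 0) {
    p <- stats::runif(length(xp), config$maf_range[1], config$maf_range[2])
    gt[xp, female_idx] <- matrix(
      stats::rbinom(length(xp) * nf, 2, rep(p, nf)), length(xp), nf)
    # single X allele per male, reported as a homozygous diploid call
    gt[xp, male_idx] <- 2L * matrix(
      stats::rbinom(length(xp) * nm, 1, rep(p, nm)), length(xp), nm)
    copy[xp, male_idx] <- 1
  }
  gam <- which(sim_class == "gametolog")
  if (length(gam) > 0) {
    gt[gam, male_idx] <- matrix(
      stats::rbinom(length(gam) * nm, 1, config$rho), length(gam), nm)
    copy[gam, male_idx] <- 1 + config$rho
  }
  xm <- which(sim_class == "x_mono")
  if (length(xm) > 0) copy[xm, male_idx] <- 1

  dp <- matrix(sim_depth(ns * ntot, as.vector(copy) * config$lambda,
                         config$overdispersion), ns, ntot)
  if (config$dropout > 0)
    gt[matrix(stats::runif(ns * ntot) < config$dropout, ns, ntot)] <-
      NA_integer_

  snp <- snp_table(cbind(sites, ref = ref, alt = alt), gt, dp, samples)
  structure(list(
    snp = snp, sexes = sexes, layout = layout,
    truth = data.frame(scaffold = sites$scaffold, pos = sites$pos,
                       region = region, sim_class = sim_class)),
    class = "xy_sim")
}

#' @export
print.xy_sim <- function(x, ...) {
  cat("xy_sim:", n_sites(x$snp), "sites,",
      sum(unclass(x$sexes) == "male"), "males +",
      sum(unclass(x$sexes) == "female"), "females\n")
  print(table(x$truth$sim_class))
  invisible(x)
}

# Solve the per-site transversion rate q giving K2P divergence K under a
# 2:1 transition:transversion ratio (p = 2q):
# K = -0.5 * log((1 - 5q) * sqrt(1 - 2q)).
k2p_rates_for <- function(K) {
  if (K == 0) return(c(p = 0, q = 0))
  f <- function(q) -0.5 * log((1 - 5 * q) * sqrt(1 - 2 * q)) - K
  q <- stats::uniroot(f, c(1e-12, 0.2 - 1e-10), tol = 1e-12)$root
  c(p = 2 * q, q = q)
}

#' Simulate repeat insert-vs-consensus alignments
#'
#' Draws random consensus sequences (optionally seeded with CpG
#' dinucleotides) and derives each insert by applying substitutions at
#' per-site rates consistent with the requested Kimura 2-parameter
#' divergence, using a 2:1 transition:transversion ratio. At planted CpG
#' sites the transition rate is multiplied by 10 (capped below `1 - q`),
#' mirroring CpG hypermutability; a CpG-corrected estimator that
#' down-weights CpG transitions by 1/10 recovers the requested divergence.
#'
#' @param seed RNG seed.
#' @param n_per_class number of alignment records (= repeat families) per
#'   class.
#' @param divergence named numeric vector: requested true K2P divergence
#'   per repeat class (names become the class labels); values in
#'   `[0, 0.45]`.
#' @param cpg_density fraction of consensus positions seeded as CpG
#'   dinucleotide starts (0 disables CpG structure).
#' @param genome genome identifier attached to every record.
#' @param seq_length alignment length in bp.
#' @return data.frame with columns `family`, `class`, `genome`,
#'   `consensus`, `insert`, `true_divergence`.
#' @export
simulate_repeat_alignments <- function(seed = 1L, n_per_class = 10L,
                                       divergence = c(LINE = 0.1),
                                       cpg_density = 0,
                                       genome = "genomeA",
                                       seq_length = 1000L) {
  if (any(divergence < 0) || any(divergence > 0.45))
    stop("divergence must be in [0, 0.45]")
  if (is.null(names(divergence)))
    stop("divergence must be a named vector (names are repeat classes)")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  out <- list()
  for (cl in names(divergence)) {
    rates <- k2p_rates_for(divergence[[cl]])
    for (i in seq_len(n_per_class)) {
      cons <- sample(bases, seq_length, replace = TRUE)
      if (cpg_density == 0) {
        # CpG-free consensus, so CpG hypermutation and its correction
        # are both inert
        repeat {
          cpg <- which(cons[-seq_length] == "C" & cons[-1] == "G")
          if (length(cpg) == 0) break
          cons[cpg + 1] <- sample(c("A", "C", "T"), length(cpg),
                                  replace = TRUE)
        }
      }
      if (cpg_density > 0) {
        starts <- sample(seq_len(seq_length - 1),
                         max(1, round(cpg_density * seq_length)))
        cons[starts] <- "C"; cons[starts + 1] <- "G"
      }
      in_cpg <- c(cons[-seq_length] == "C" & cons[-1] == "G", FALSE) |
        c(FALSE, cons[-seq_length] == "C" & cons[-1] == "G")
      p_site <- ifelse(in_cpg, pmin(10 * rates["p"], 1 - rates["q"] - 1e-9),
                       rates["p"])
      u <- stats::runif(seq_length)
      ins <- cons
      ts <- u < p_site
      ins[ts] <- transition[cons[ts]]
      tv <- !ts & u < p_site + rates["q"]
      for (j in which(tv))
        ins[j] <- sample(transversions[[cons[j]]], 1)
      out[[length(out) + 1]] <- data.frame(
        family = sprintf("%s_fam%03d", cl, i), class = cl,
        genome = genome, consensus = paste(cons, collapse = ""),
        insert = paste(ins, collapse = ""),
        true_divergence = divergence[[cl]])
    }
  }
  do.call(rbind, out)
}
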