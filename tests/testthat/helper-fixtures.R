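# Small layouts and simulations shared across test files.

# 10 Mb sex scaffold (PAR1 2 / HRX 6 / PAR2 2 Mb) + one 30 Mb autosome.
small_layout <- function() {
  genome_layout(
    scaffolds = data.frame(id = c("auto_1", "sex_1"),
                           length = c(30e6, 10e6)),
    regions = data.frame(scaffold = "sex_1",
                         start = c(1, 2e6 + 1, 8e6 + 1),
                         end = c(2e6, 8e6, 10e6),
                         label = c("PAR1", "HRX", "PAR2")))
}

small_sim <- function(seed = 1, ...) {
  simulate_xy_population(sim_config(seed = seed, layout = small_layout(),
                                    snp_spacing = 2e4, ...))
}

# Purely autosomal genome (no sex scaffold).
autosomal_layout <- function(len = 20e6) {
  genome_layout(scaffolds = data.frame(id = "auto_1", length = len))
}

autosomal_sim <- function(seed = 1, len = 20e6, ...) {
  simulate_xy_population(sim_config(seed = seed,
                                    layout = autosomal_layout(len),
                                    snp_spacing = 2e4,
                                    gametolog_fraction = 0, ...))
}

# Hand-built tiny snp_table.
tiny_table <- function(genotypes, depths = NULL,
                       samples = paste0("s", seq_len(ncol(genotypes)))) {
  ns <- nrow(genotypes)
  if (is.null(depths)) depths <- matrix(10L, ns, ncol(genotypes))
  snp_table(data.frame(scaffold = "chr1", pos = seq_len(ns) * 100L,
                       ref = "A", alt = "G"),
            genotypes, depths, samples)
}

# Join scan stats back to simulation truth by (scaffold, pos).
truth_classes <- function(fit, sim) {
  key <- paste(sim$truth$scaffold, sim$truth$pos)
  m <- match(paste(fit$stats$scaffold, fit$stats$pos), key)
  data.frame(class = fit$stats$class,
             sim_class = sim$truth$sim_class[m],
             region = sim$truth$region[m])
}

# Brute-force two-sided Fisher p by enumeration of all tables with the
# observed margins, point probabilities via choose() (independent of
# dhyper and of the package implementation).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  ks <- max(0, k - r2):min(r1, k)
  prob <- choose(r1, ks) * choose(r2, k - ks) / choose(n, k)
  obs <- choose(r1, a) * choose(r2, k - a) / choose(n, k)
  sum(prob[prob <= obs * (1 + 1e-7)])
}
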