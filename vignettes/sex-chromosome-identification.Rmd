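---
title: "Identifying sex-linked regions from population genotype data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying sex-linked regions from population genotype data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexscan)
```

## The model

`sexscan` targets species with a male-heterogametic (XY) system whose X
chromosome is assembled as one scaffold, genotyped across a mixed-sex
population sample with a diploid-assuming variant caller. Three per-SNP
statistics carry the sex-linkage signal:

* **Depth ratio** $r = \bar d_m / \bar d_f$, the ratio of mean male to
  mean female sequencing depth. Copy number drives the expectation:
  $r \approx 1$ on autosomes and in pseudoautosomal regions (PARs, still
  recombining between X and Y), $r \approx 0.5$ in the hemizygous region
  of the X (HRX), where males carry a single copy. Depth means include
  all samples of a sex, zero depths included — hemizygosity manifests as
  *depth*, not as missingness.
* **Sex association.** Each SNP is tested with a two-sided Fisher exact
  test on the allelic $2\times2$ table of (reference, alternate) allele
  counts by sex; homozygotes contribute two copies of their allele,
  heterozygotes one of each. The two-sided $p$ is the sum of
  hypergeometric point probabilities not exceeding the observed table's
  probability times $1 + 10^{-7}$. Genome-wide significance uses the
  Bonferroni threshold $\alpha/M$, where $M$ counts *tested* markers
  only: sites with a zero allele or sex margin, or fewer than two
  non-missing genotypes in either sex, are untested and excluded from
  $M$. The allelic (rather than genotypic) coding makes male-limited
  heterozygosity — one alternate allele in every male — maximally
  detectable.
* **Relative male heterozygosity** $\Delta H = H_m - H_f$, where $H_s$
  is the fraction of heterozygous calls among non-missing genotypes of
  sex $s$. Fixed X–Y gametolog differences appear heterozygous in males
  only ($\Delta H \to 1$); X-linked polymorphism gives males homozygous
  single-allele calls ($\Delta H \le 0$).

### Classification

Outlier bounds on $r$ come from the genome-wide interquartile range:
$[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$, quartiles by the
interpolated type-7 convention (a deliberate, oracle-tested choice; no
single convention is canonical). Classes are assigned in precedence
order:

1. *unclassified* — any of $p$, $\Delta H$, $r$ undefined;
2. *duplicated-candidate* — significant association **and** $r$ above
   the high bound: excess male coverage at a sex-associated site is the
   signature of a region duplicated between an autosome and the Y, not
   of Y linkage proper, so this rule must precede the next;
3. *Y-linked* — significant sex association;
4. *X-linked* — $r$ below the low bound and $\Delta H \le 0$;
5. *autosomal* — everything else.

The IQR rule presumes sex-linked SNPs are a minority of the genome-wide
$r$ distribution; if the X made up, say, forty percent of all markers,
$Q_1$ itself would sit in the hemizygous mode and the low bound would
never fire. This mirrors real genomes, where one chromosome contributes
a modest fraction of markers, and is reflected in the simulator's
default genome (below). Thresholds are computed genome-wide, not per
scaffold, reading "genomic outliers" literally.

### Segmentation

The percent of sex-linked (X- or Y-linked) SNPs among classified SNPs is
tallied in non-overlapping 1 Mb windows along the focal scaffold — the
scaffold with the most sex-linked SNPs, unless overridden. The HRX is
the maximal-length run of windows with percent above a threshold
$\tau$, allowed to bridge up to `gap = 2` consecutive sub-threshold or
SNP-free windows (RAD data are sparse; an empty megabase should not
split the HRX). PAR1 and PAR2 are the flanks. Since no principled fixed
$\tau$ exists, the default is data-driven: the highest window percent
observed on *non-focal* scaffolds plus one percentage point — an
empirical null for the false-positive rate per window — floored at 5%.
Both $\tau$ and the gap tolerance are recorded in the fitted object.

## The simulator

`simulate_xy_population()` generates the statistical structure the
estimator assumes, with ground truth for recovery testing:

* genotypes: autosomal/PAR sites are Hardy–Weinberg in both sexes with
  minor allele frequency uniform on $[0.05, 0.5]$; HRX X-polymorphic
  sites give females Hardy–Weinberg diploid genotypes while each male
  carries one X allele *called homozygous* (diploid-assuming callers
  emit homozygous calls for hemizygous loci); HRX gametolog sites are
  fixed: females homozygous reference, males heterozygous with
  probability $\rho$ (the chance a Y-derived read maps onto the X
  scaffold; default 1, so gametolog sites combine male heterozygosity
  with near-diploid male depth $1+\rho$ — which is why Y-linked GWAS
  hits are *not* low-depth outliers);
* depth: Poisson with mean $\text{copy number} \times \lambda$ per
  sample per site ($\lambda$ = reads per chromosome copy, default 10;
  an `overdispersion` multiplier switches to a negative binomial with
  the same mean);
* missingness: random dropout (default 1%) plus the depth-threshold
  masking applied later by filtering.

Defaults define the reference study conditions: 25 males + 25 females;
three 100 Mb autosomal scaffolds plus a 111 Mb sex scaffold partitioned
as PAR1 21 Mb / HRX 71 Mb / PAR2 19 Mb; mean SNP spacing 30 kb. That
spacing puts roughly 2,100 X-polymorphic and 200 gametolog sites on the
sex scaffold among ~13,700 total — enough sites per compartment for
stable depth-ratio means while keeping hemizygous sites ~15% of the
genome-wide distribution, inside the IQR rule's operating regime. Tests
on smaller genomes use the same generative model scaled down (a 10 Mb
sex scaffold and a 30 Mb autosome at 20 kb spacing).

What the simulator does **not** emulate: linkage disequilibrium and
shared genealogy (sites are independent), population structure across
the sampled individuals, allele-specific mapping bias, batch effects in
depth, and reference bias against Y reads beyond the single parameter
$\rho$. Recovery of the planted PAR/HRX boundaries therefore
demonstrates correctness of the estimator under its own model
assumptions, not robustness to every artefact of real RAD data.

## Filtering

Defaults follow common RAD-seq practice: genotypes under 4 reads are
masked; sites need data in at least 70% of samples (a site at exactly
70% passes — the comparison carries a $10^{-9}$ tie tolerance so the
threshold is not at the mercy of floating-point representation); minor
allele frequency, computed on the allele scale from non-missing
genotypes, must be *strictly* above 5%. Filtering is idempotent.
Raising the depth threshold is monotone (never adds survivors) through
the depth and missingness stages; the MAF stage can break strict
monotonicity because masking genotypes can move a site's MAF across the
cutoff in either direction — a property worth knowing when comparing
filter settings. Missing data are handled by missing-aware statistics
rather than imputation; a MAPQ filter belongs upstream in the caller.

## Repeat landscapes

`k2p_divergence()` estimates a repeat insert's age proxy from its
alignment to the family consensus: over ungapped, unambiguous columns,
transition proportion $p$ and transversion proportion $q$ give
$K = -\tfrac12 \ln\big((1-2p-q)\sqrt{1-2q}\big)$. With CpG correction, a
transition whose consensus position lies in a consensus CpG dinucleotide
is weighted $1/10$ — CpG sites are hypermutable, and counting their
transitions fully inflates the age estimate. Alignments with fewer than
20 usable columns are excluded; saturated records (logarithm argument
$\le 0$) are flagged and dropped from landscapes rather than clamped,
with a reported count. Landscapes bin each record's ungapped insert bp
at $\lfloor 100K \rfloor$ (left-closed percent bins) and normalise by
genome size. For the two-genome comparison of recent insertions
($K \le 10\%$), the observation unit is the *repeat family* — its
genome proportion of recent bp — compared between genomes per class
with the Kruskal–Wallis rank test (midranks, tie correction, chi-square
with 1 df). Families, not bins or individual elements, were chosen as
the unit because families are the independent replicates of the
invasion process; this is a documented analysis decision.

## Karyotype concordance

`estimate_chrom_sizes()` converts measured chromosome areas from a
karyotype image into nucleotide estimates: each chromosome's fraction
of total area (for the XX complement — an X measured once can be
doubled via `double_area_for`) times the assembly size, so estimates
sum exactly to the total. `karyotype_concordance()` regresses scaffold
size on the estimate by ordinary least squares and reports $r^2$, slope,
intercept and the F-test p-value. The regression direction is a
convention; $r^2$ is symmetric, so the headline statistic does not
depend on it. The bundled `synthetic_karyotype.tsv` is a constructed
example (areas proportional to scaffold sizes with ~2.5% measurement
noise), not measurements from any published karyotype.

## Numerical and degenerate-input choices

* Fisher tie handling uses the $1+10^{-7}$ relative tolerance on point
  probabilities; the all-zero table returns $p = 1$.
* Depth means treat a missing DP field as 0, biasing ratios
  conservatively toward no signal rather than inventing coverage.
* Undefined statistics propagate as `NA` and route a site to
  *unclassified*; a female mean depth of 0 leaves $r$ undefined.
* Terminal partial windows are retained in sliding summaries; the
  window log-ratio uses base 2 so halved coverage reads as $-1$.
* Ties in the maximal-run selection during segmentation resolve to the
  leftmost run.
* Seeds: every simulation entry point takes an explicit seed and is
  bit-reproducible under it.

## Limitations

The scan assumes exactly two sexes with male heterogamety (for ZW
systems, swap the sex labels and the logic transfers with roles
reversed); it cannot separate Y-linked from W-linked logic
automatically. Boundary resolution is limited to the tally window
(1 Mb): reported PAR boundaries are window-aligned approximations, not
base-pair calls. Very small samples (a handful per sex) leave the
Fisher test underpowered at Bonferroni stringency, and depth-ratio
outlier calling degrades when the sex scaffold carries a large share of
all markers. The repeat module estimates divergence from provided
alignments; it does not discover repeat families or mask genomes.
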