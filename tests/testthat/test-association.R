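test_that("Fisher two-sided p matches exhaustive enumeration", {
  # [[3,0],[0,3]]: both extreme tables have probability 1/20 -> p = 0.1
  expect_equal(fisher_exact_two_sided(matrix(c(3, 0, 0, 3), 2)), 0.1)
  # balanced table carries no association
  expect_equal(fisher_exact_two_sided(matrix(c(5, 5, 5, 5), 2)), 1)
  # all-zero table -> 1 by convention
  expect_equal(fisher_exact_two_sided(matrix(0, 2, 2)), 1)
  expect_error(fisher_exact_two_sided(matrix(c(-1, 1, 1, 1), 2)),
               "non-negative")

  set.seed(21)
  for (i in 1:200) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_two_sided(tab)
    expect_equal(p, fisher_oracle(tab[1, 1], tab[1, 2],
                                  tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
    # stats::fisher.test as a second, independent reference
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    # invariance to row and column swaps
    expect_equal(p, fisher_exact_two_sided(tab[2:1, ]), tolerance = 1e-12)
    expect_equal(p, fisher_exact_two_sided(tab[, 2:1]), tolerance = 1e-12)
  }
})

test_that("sex GWAS builds allelic tables and excludes untested sites from M", {
  # 10 males all het, 10 females all hom-ref: allelic [[10,20],[10,0]]
  gt <- rbind(rep(c(1L, 0L), each = 10),      # gametolog-like
              rep(0L, 20),                    # monomorphic -> untested
              rep(c(1L, 1L), each = 10))      # no sex contrast
  tab <- tiny_table(gt)
  sexes <- sex_map(tab$samples, rep(c("M", "F"), each = 10))
  res <- sex_gwas(tab, sexes)
  expect_equal(attr(res, "n_tested"), 2)  # monomorphic site excluded
  expect_true(is.na(res$p[2]))
  expect_equal(res$p[1], fisher_oracle(10, 20, 10, 0), tolerance = 1e-12)
  expect_lt(res$p[1], 0.05 / 100)
  expect_true(res$significant[1])
  expect_false(res$significant[3])

  # fewer than 2 non-missing genotypes in one sex -> untested
  gt2 <- rbind(c(1L, NA, NA, NA, NA, rep(0L, 5)))
  tab2 <- tiny_table(gt2, samples = paste0("s", 1:10))
  res2 <- sex_gwas(tab2, sex_map(tab2$samples, rep(c("M", "F"), each = 5)))
  expect_true(is.na(res2$p[1]))
  expect_equal(attr(res2, "n_tested"), 0)
})

test_that("per-sex heterozygosity and its difference are counted by hand", {
  # 3 males: het, het, missing; 4 females: het, hom, hom, hom
  gt <- matrix(c(1L, 1L, NA, 1L, 0L, 0L, 0L), 1)
  tab <- tiny_table(gt, samples = paste0("s", 1:7))
  sexes <- sex_map(tab$samples, c("M", "M", "M", "F", "F", "F", "F"))
  h <- heterozygosity_by_sex(tab, sexes)
  expect_equal(h$H_m, 1.0)
  expect_equal(h$H_f, 0.25)
  expect_equal(h$dH, 0.75)

  # extremes and symmetry
  gt2 <- rbind(c(rep(1L, 3), rep(0L, 4)),  # all males het, females hom
               c(1L, 0L, 2L, 1L, 0L, 2L, 0L))
  h2 <- heterozygosity_by_sex(tiny_table(gt2, samples = tab$samples), sexes)
  expect_equal(h2$dH[1], 1)
  gt3 <- rbind(c(1L, 0L, 2L, 1L, 0L, 2L))  # identical vectors by sex
  h3 <- heterozygosity_by_sex(
    tiny_table(gt3, samples = paste0("s", 1:6)),
    sex_map(paste0("s", 1:6), c("M", "M", "M", "F", "F", "F")))
  expect_equal(h3$dH, 0)
})

test_that("gametolog sites light up and null simulations stay quiet", {
  sim <- small_sim(seed = 8)
  filt <- apply_filters(sim$snp, filter_config())
  res <- sex_gwas(filt$table, sim$sexes)
  key <- paste(sim$truth$scaffold, sim$truth$pos)
  simc <- sim$truth$sim_class[match(paste(res$scaffold, res$pos), key)]
  expect_gte(mean(res$significant[simc == "gametolog"]), 0.9)

  # significant hits show male heterozygosity excess
  het <- heterozygosity_by_sex(filt$table, sim$sexes)
  expect_gte(mean(het$dH[res$significant] > 0), 0.96)

  # all-autosomal simulations: expected Bonferroni-significant count <= alpha
  n_sig <- vapply(1:20, function(s) {
    a <- autosomal_sim(seed = 100 + s, len = 10e6)
    f <- apply_filters(a$snp, filter_config())
    sum(sex_gwas(f$table, a$sexes)$significant)
  }, 0L)
  expect_lte(sum(n_sig), 4)  # E[total] <= 20 * alpha = 1
})
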