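test_that("depth ratio is forced arithmetic over all samples of each sex", {
  dp <- rbind(c(10L, 10L, 20L, 20L),
              c(5L, 5L, 5L, 5L),
              c(3L, 7L, 0L, 0L))
  gt <- matrix(0L, 3, 4)
  gt[1, 2] <- NA  # missing genotype still contributes its depth
  tab <- tiny_table(gt, dp, samples = paste0("s", 1:4))
  sexes <- sex_map(tab$samples, c("M", "M", "F", "F"))
  r <- depth_ratio(tab, sexes)$r
  expect_equal(r[1], 0.5)
  expect_equal(r[2], 1)
  expect_true(is.na(r[3]))  # female mean depth 0 -> undefined
})

test_that("IQR thresholds follow the interpolated quantile convention", {
  thr <- iqr_thresholds(1:8)
  expect_equal(thr$q1, 2.75)
  expect_equal(thr$q3, 6.25)
  expect_equal(thr$low, -2.5)
  expect_equal(thr$high, 11.5)

  thr_c <- iqr_thresholds(rep(3.5, 10))
  expect_equal(thr_c$iqr, 0)
  expect_equal(thr_c$low, 3.5)
  expect_equal(thr_c$high, 3.5)
  expect_error(iqr_thresholds(c(1, 2, 3)), "at least 4")

  # independent re-implementation of the type-7 interpolation
  q7 <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  set.seed(31)
  for (i in 1:20) {
    v <- stats::rnorm(sample(4:50, 1))
    thr <- iqr_thresholds(v)
    q1 <- q7(v, 0.25); q3 <- q7(v, 0.75)
    expect_equal(thr$q1, q1, tolerance = 1e-12)
    expect_equal(thr$high, q3 + 1.5 * (q3 - q1), tolerance = 1e-12)
  }
})

test_that("classification rules apply in the documented precedence", {
  thr <- structure(list(q1 = 0.9, q3 = 1.1, iqr = 0.2, low = 0.6,
                        high = 1.4), class = "iqr_thresholds")
  stats <- data.frame(
    p = c(0.5, 1e-9, 1e-9, 0.5, NA, 0.5),
    significant = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    dH = c(-0.02, 0.8, 0.1, 0.01, 0.0, 0.0),
    r = c(0.45, 1.0, 1.6, 0.45, 1.0, NA))
  out <- classify_snps(stats, thr)
  expect_equal(out$class,
               c("X-linked",              # low-r outlier, dH <= 0
                 "Y-linked",              # significant
                 "duplicated-candidate",  # significant AND high-r outlier
                 "autosomal",             # low r but dH > 0
                 "unclassified",          # p undefined
                 "unclassified"))         # r undefined
  # invariant to site order
  perm <- sample(nrow(stats))
  expect_equal(classify_snps(stats[perm, ], thr)$class, out$class[perm])
})

test_that("simulation truth classes are recovered at the stated rates", {
  sim <- simulate_xy_population(sim_config(seed = 1))
  fit <- sexlink_scan(sim$snp, sim$sexes, layout = sim$layout)
  tc <- truth_classes(fit, sim)
  expect_gte(mean(tc$class[tc$sim_class == "gametolog"] == "Y-linked"), 0.9)
  expect_gte(mean(tc$class[tc$sim_class == "x_poly"] == "X-linked"), 0.8)
  auto <- tc$region == "autosomal"
  expect_lte(mean(tc$class[auto] %in% c("X-linked", "Y-linked")), 0.01)
})

test_that("window depth summaries match hand computation", {
  layout <- genome_layout(data.frame(id = "c1", length = 5e6))
  stats <- data.frame(
    scaffold = "c1",
    pos = c(0.5e6, 1.5e6, 2.5e6, 3.1e6),
    p = 0.5, significant = FALSE, dH = 0,
    r = c(0.5, 1, 2, 4),
    class = c("X-linked", "autosomal", "autosomal", "autosomal"))
  w <- window_depth_summary(stats, layout, window = 2e6, step = 1e6)
  # window 1 (1..2e6): sites 1,2 -> mean(log2(0.5), log2(1)) = -0.5
  expect_equal(w$n[1], 2)
  expect_equal(w$mean_log2_r[1], -0.5)
  expect_equal(w$pct_sex_linked[1], 50)
  # window 3 (2e6+1..4e6): sites 3,4 -> mean(1, 2) = 1.5
  expect_equal(w$mean_log2_r[3], 1.5)
  # window 5 (4e6+1..5e6): terminal partial, empty
  expect_equal(w$end[5], 5e6)
  expect_equal(w$n[5], 0)
  expect_true(is.na(w$mean_log2_r[5]))
  expect_error(window_depth_summary(stats, layout, window = 1e6,
                                    step = 2e6), "step")
})

test_that("autosomal windows centre on log2 ratio zero", {
  sim <- autosomal_sim(seed = 12)
  fit <- suppressWarnings(
    sexlink_scan(sim$snp, sim$sexes, layout = sim$layout))
  w <- fit$windows
  expect_lt(max(abs(w$mean_log2_r[w$n > 10])), 0.1)
})
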