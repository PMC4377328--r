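test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 2), b = c(3, 4))
  expect_equal(unname(quantile_normalize(m)), cbind(c(2, 3), c(2, 3)),
               ignore_attr = TRUE)

  # identical columns pass through unchanged
  m2 <- cbind(c(5, 1, 3), c(5, 1, 3))
  expect_equal(quantile_normalize(m2), m2, ignore_attr = TRUE)

  # a permuted column maps to the same permutation of the output
  set.seed(1)
  x <- rnorm(20)
  perm <- sample(20)
  m3 <- cbind(x, x[perm])
  q <- quantile_normalize(m3)
  expect_equal(q[perm, 1], q[, 2], ignore_attr = TRUE)

  # identical multisets across columns; idempotence
  set.seed(2)
  m4 <- matrix(rnorm(200), 50)
  q4 <- quantile_normalize(m4)
  for (j in 2:4) expect_equal(sort(q4[, j]), sort(q4[, 1]))
  expect_equal(quantile_normalize(q4), q4, tolerance = 1e-12)

  m4[1] <- NA
  expect_error(quantile_normalize(m4), "finite")
})

test_that("two-Gaussian mixture fit locates the density crossing", {
  x <- degnet:::with_seed(10, c(rnorm(2500, 4, 1), rnorm(2500, 10, 1)))
  fit <- fit_expression_mixture(x, seed = 1)
  # equal-weight equal-sd components cross at the midpoint
  expect_lt(abs(fit$threshold - 7), 0.2)
  expect_true(fit$mean_low < fit$threshold && fit$threshold < fit$mean_high)
  # weighted densities are equal at the threshold
  d_lo <- fit$weight_low * dnorm(fit$threshold, fit$mean_low, fit$sd_low)
  d_hi <- fit$weight_high * dnorm(fit$threshold, fit$mean_high, fit$sd_high)
  expect_equal(d_lo, d_hi, tolerance = 1e-6)

  # symmetric unimodal heavy-tailed data: EM collapses to two components
  # with coincident means (a scale mixture), which must be rejected
  y <- degnet:::with_seed(1, rt(600, df = 3))
  expect_error(fit_expression_mixture(y, seed = 1), "not separable")

  # unequal weights shift the crossing past the midpoint; grid oracle
  z <- degnet:::with_seed(4, c(rnorm(4500, 4, 1), rnorm(500, 10, 1)))
  fit2 <- fit_expression_mixture(z, seed = 2)
  expect_gt(fit2$threshold, 7)
  grid <- seq(fit2$mean_low, fit2$mean_high, length.out = 20001)
  gap <- abs(fit2$weight_low * dnorm(grid, fit2$mean_low, fit2$sd_low) -
             fit2$weight_high * dnorm(grid, fit2$mean_high, fit2$sd_high))
  expect_lt(abs(grid[which.min(gap)] - fit2$threshold), 1e-3)

  expect_error(fit_expression_mixture(rnorm(10)), "50")
  expect_error(fit_expression_mixture(rep(1, 100)), "variance")
})

test_that("expressed filter uses a strict maximum-intensity rule", {
  fit <- structure(list(threshold = 7), class = "mixture_fit")
  m <- matrix(c(6, 7.5, 6, 7.0, 5, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("hi", "at", "lo"), c("s1", "s2")))
  ds <- expression_dataset(m, c("cancer", "normal"))
  expect_equal(filter_expressed(ds, fit), "hi")
  fit2 <- structure(list(threshold = 100), class = "mixture_fit")
  expect_warning(out <- filter_expressed(ds, fit2), "no gene")
  expect_length(out, 0L)
})

test_that("t statistic matches the closed form and is antisymmetric", {
  expect_equal(t_statistic(c(1, 2, 3), c(4 - 3, 5 - 3, 6 - 3)), 0)
  # pooled sd 1, SE sqrt(2/3): t = 3 / sqrt(2/3)
  expect_equal(t_statistic(c(4, 5, 6), c(1, 2, 3)), 3 / sqrt(2 / 3),
               tolerance = 1e-3)
  expect_equal(t_statistic(c(1, 2, 3), c(4, 5, 6)),
               -t_statistic(c(4, 5, 6), c(1, 2, 3)))
  expect_error(t_statistic(1, c(1, 2)), "2 samples")
  expect_equal(t_statistic(c(2, 2), c(1, 1)), Inf)
})

test_that("log2-median-ratio is a difference of medians", {
  expect_equal(log2_median_ratio(c(1, 2, 3), c(3, 2, 1)), 0)
  expect_equal(log2_median_ratio(c(7, 8, 9), c(5, 6, 7)), 2)
  # one outlier that does not move the median
  expect_equal(log2_median_ratio(c(7, 8, 1e6), c(5, 6, 7)), 2)
  expect_error(log2_median_ratio(numeric(0), 1), "nonempty")
})

test_that("empirical null is seeded, symmetric under no signal, and guarded", {
  ds <- generate_expression_cohort(n_genes = 80, n_cancer = 6,
                                   n_normal = 6, frac_de = 0,
                                   seed = 5)$dataset
  null1 <- empirical_null(ds, "t", n_perm = 150, seed = 9)
  null2 <- empirical_null(ds, "t", n_perm = 150, seed = 9)
  expect_identical(null1$values, null2$values)
  # no-signal permuted t pool is symmetric about 0 within MC error
  expect_lt(abs(null1$cdf(0) - 0.5), 0.02)
  expect_lt(abs(mean(null1$values)), 0.05)

  expect_error(empirical_null(ds, "t", n_perm = 50), "at least 100")
  tiny <- generate_expression_cohort(n_genes = 60, n_cancer = 3,
                                     n_normal = 3, frac_de = 0,
                                     seed = 1)$dataset
  expect_error(empirical_null(tiny, "t", n_perm = 100),
               "exact enumeration")
})

test_that("two-tailed empirical P doubles the smaller tail and clamps", {
  null <- empirical_null_density(degnet:::with_seed(8, rnorm(20000)))
  expect_gt(two_tailed_p(median(null$values), null), 0.98)
  expect_lt(abs(two_tailed_p(1.96, null) - 0.05), 0.01)
  expect_equal(two_tailed_p(1e6, null), 1e-15)
  expect_equal(two_tailed_p(Inf, null), 1e-15)
  # monotone non-increasing in |stat| for a symmetric null
  p_seq <- two_tailed_p(seq(0, 4, by = 0.25), null)
  expect_true(all(diff(p_seq) <= 1e-12))
})

test_that("Stouffer combination matches the closed form", {
  # single P round-trips under either sign
  expect_equal(as.numeric(stouffer_combine(0.2, 1)), 0.2)
  expect_equal(as.numeric(stouffer_combine(0.2, -1)), 0.2)
  # frozen closed form: z = qnorm(0.975) = 1.959964, Z = 2 z / sqrt(2)
  comb <- stouffer_combine(c(0.05, 0.05), c(1, 1))
  expect_equal(attr(comb, "z"), 2.77181, tolerance = 1e-4)
  expect_equal(as.numeric(comb), 0.0055746, tolerance = 1e-4)
  # discordant directions cancel
  expect_equal(as.numeric(stouffer_combine(c(0.05, 0.05), c(1, -1))), 1)
  # k concordant copies give |Z| = sqrt(k) |z|
  z1 <- attr(stouffer_combine(0.05, 1), "z")
  for (k in c(2, 5, 9)) {
    zk <- attr(stouffer_combine(rep(0.05, k), rep(1, k)), "z")
    expect_equal(zk, sqrt(k) * z1, tolerance = 1e-12)
  }
  expect_error(stouffer_combine(numeric(0)), "no P values")
  expect_error(stouffer_combine(c(0.5, 0), c(1, 1)), "\\(0, 1\\]")
})

test_that("DEG identification recovers planted genes and is reproducible", {
  g <- generate_expression_cohort(n_genes = 250, frac_de = 0.1,
                                  effect_size = 2, noise_sd = 1,
                                  seed = 7)
  r1 <- identify_degs(g$dataset, n_perm = 150, seed = 3)
  r2 <- identify_degs(g$dataset, n_perm = 150, seed = 3)
  expect_identical(r1, r2)
  planted <- g$truth$planted_deg$gene
  expect_gte(mean(r1$is_de[match(planted, r1$gene)], na.rm = TRUE), 0.9)
  # unexpressed genes carry no statistics
  expect_true(all(is.na(r1$p_combined[!r1$expressed])))
  expect_true(all(r1$p_combined[r1$expressed] > 0 &
                  r1$p_combined[r1$expressed] <= 1))

  few <- generate_expression_cohort(n_genes = 60, n_cancer = 1,
                                    n_normal = 5, seed = 2)$dataset
  expect_error(identify_degs(few), "2 samples")
  expect_error(identify_degs(g$dataset, alpha = 1.5), "alpha")
})

test_that("dependence-adjusted combination restores type-I calibration", {
  # the t and lmr statistics share samples; the plain sqrt(2) Stouffer
  # denominator is anticonservative, the rho-adjusted one is calibrated
  g <- generate_expression_cohort(n_genes = 400, frac_de = 0, seed = 11)
  r <- identify_degs(g$dataset, n_perm = 150, seed = 5,
                     dependence_adjust = TRUE)
  frac <- mean(r$is_de, na.rm = TRUE)
  n <- sum(r$expressed)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("cancer-type summary combines datasets with Stouffer", {
  r <- identify_degs(
    generate_expression_cohort(n_genes = 150, frac_de = 0.1,
                               seed = 4)$dataset,
    n_perm = 120, seed = 2)
  s1 <- summarize_cancer_type(list(r))
  # one dataset: representative P equals that dataset's combined P
  i <- match(s1$gene, r$gene)
  expect_equal(s1$p_representative, r$p_combined[i], tolerance = 1e-12)
  expect_equal(s1$lfc_representative, r$lfc[i])

  # two concordant datasets at P = 0.05 give the closed-form 0.0055766
  ra <- r; rb <- r
  ra$p_combined[ra$expressed] <- 0.05
  rb$p_combined[rb$expressed] <- 0.05
  ra$lfc[ra$expressed] <- 1; rb$lfc[rb$expressed] <- 3
  s2 <- summarize_cancer_type(list(ra, rb))
  expect_equal(unique(round(s2$p_representative, 7)), 0.0055746,
               tolerance = 1e-4)
  expect_equal(unique(s2$lfc_representative), 2)
  expect_equal(unique(s2$n_datasets), 2L)
  expect_error(summarize_cancer_type(list()), "at least one")
})
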