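test_that("Pearson correlation matches the direct covariance formula", {
  p <- paired_measurements(data.frame(lesion_id = 1:4,
                                      value_full = c(1, 2, 3, 4),
                                      value_reduced = c(2, 1, 4, 3)))
  out <- pearson_with_ci(p)
  # brute-force oracle: r = sum((x - xb)(y - yb)) / sqrt(ssx * ssy)
  x <- p$value_full; y <- p$value_reduced
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$estimate, r_hand, tolerance = 1e-12)
  # Fisher-z CI oracle
  z <- atanh(r_hand); se <- 1 / sqrt(4 - 3)
  expect_equal(out$ci, tanh(z + c(-1, 1) * qnorm(0.975) * se),
               tolerance = 1e-10)
  # exact linear relation gives r = 1; permutation invariance
  lin <- paired_measurements(data.frame(lesion_id = 1:5,
                                        value_full = c(2, 4, 6, 8, 10),
                                        value_reduced = 1.5 * c(2, 4, 6, 8, 10) + 1))
  expect_equal(pearson_with_ci(lin)$estimate, 1)
  perm <- paired_measurements(lin[c(3, 1, 5, 2, 4), ])
  expect_equal(pearson_with_ci(perm), pearson_with_ci(lin))
  expect_error(pearson_with_ci(paired_measurements(data.frame(
    lesion_id = 1:4, value_full = rep(2, 4), value_reduced = 1:4))),
    "zero variance")
})

test_that("ICC(3,1) equals a from-scratch ANOVA decomposition", {
  p <- hand_pairs()
  out <- icc_two_way_mixed(p)
  # independent oracle: two-way ANOVA via stats::aov on the long layout
  long <- data.frame(y = c(p$value_full, p$value_reduced),
                     subject = factor(rep(p$lesion_id, 2)),
                     rater = factor(rep(c("full", "reduced"), each = 6)))
  ms <- summary(stats::aov(y ~ subject + rater, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; mse <- ms[3]
  icc_oracle <- (msr - mse) / (msr + mse)
  expect_equal(out$estimate, icc_oracle, tolerance = 1e-12)
  # Shrout-Fleiss F bounds oracle
  n <- 6; fo <- msr / mse
  fl <- fo / qf(0.975, n - 1, n - 1); fu <- fo * qf(0.975, n - 1, n - 1)
  expect_equal(out$lower, (fl - 1) / (fl + 1), tolerance = 1e-12)
  expect_equal(out$upper, (fu - 1) / (fu + 1), tolerance = 1e-12)
})

test_that("consistency ICC is 1 under identity and constant shift", {
  base <- data.frame(lesion_id = 1:6, value_full = c(2, 5, 7, 11, 16, 23))
  ident <- paired_measurements(cbind(base, value_reduced = base$value_full))
  expect_equal(icc_two_way_mixed(ident)$estimate, 1)
  shift <- paired_measurements(cbind(base,
                                     value_reduced = base$value_full - 1))
  expect_equal(icc_two_way_mixed(shift)$estimate, 1)
  # absolute-agreement form penalizes the shift
  expect_lt(icc_two_way_mixed(shift, type = "agreement")$estimate, 1)
  expect_warning(icc_two_way_mixed(paired_measurements(data.frame(
    lesion_id = 1:4, value_full = c(1, 2, 3, 4),
    value_reduced = c(1.1, 2.2, 2.9, 4.2)))), "fewer than 5")
})

test_that("Krippendorff's alpha equals exhaustive pairwise enumeration", {
  # O(n^2) oracle over all pairable values
  alpha_oracle <- function(x, delta) {
    vals <- as.numeric(t(x))
    n_tot <- length(vals)
    d_obs <- 0
    for (u in seq_len(nrow(x))) {
      vu <- x[u, ]
      for (i in 1:2) for (j in 1:2) if (i != j)
        d_obs <- d_obs + delta(vu[i], vu[j]) / (2 - 1)
    }
    d_obs <- d_obs / n_tot
    d_exp <- 0
    for (i in seq_len(n_tot)) for (j in seq_len(n_tot)) if (i != j)
      d_exp <- d_exp + delta(vals[i], vals[j])
    d_exp <- d_exp / (n_tot * (n_tot - 1))
    1 - d_obs / d_exp
  }
  tab <- data.frame(lesion_id = 1:5,
                    value_full = c(2.1, 3.9, 8.0, 12.5, 30.2),
                    value_reduced = c(2.4, 3.6, 7.1, 13.0, 28.9))
  p <- paired_measurements(tab)
  x <- as.matrix(tab[, 2:3])
  expect_equal(krippendorff_alpha(p, "interval"),
               unname(alpha_oracle(x, function(a, b) (a - b)^2)),
               tolerance = 1e-12)
  expect_equal(krippendorff_alpha(p, "ratio"),
               unname(alpha_oracle(x, function(a, b) ((a - b) / (a + b))^2)),
               tolerance = 1e-12)
  # the two metrics genuinely differ on data with a scale trend
  expect_false(isTRUE(all.equal(krippendorff_alpha(p, "interval"),
                                krippendorff_alpha(p, "ratio"))))
  # identical values: alpha = 1 by convention, flagged
  same <- paired_measurements(data.frame(lesion_id = 1:3,
                                         value_full = c(4, 4, 4),
                                         value_reduced = c(4, 4, 4)))
  a <- krippendorff_alpha(same)
  expect_equal(as.numeric(a), 1)
  expect_true(attr(a, "degenerate"))
  # unit with a missing value is dropped
  miss <- data.frame(lesion_id = 1:6,
                     value_full = c(tab$value_full, 5),
                     value_reduced = c(tab$value_reduced, NA))
  expect_equal(krippendorff_alpha(paired_measurements(miss)),
               krippendorff_alpha(p))
})

test_that("Bland-Altman bias, CI and limits of agreement", {
  p <- paired_measurements(data.frame(lesion_id = 1:3,
                                      value_full = c(10, 20, 30),
                                      value_reduced = c(9, 19, 29)))
  ba <- bland_altman(p)
  expect_equal(ba$bias, -1)
  expect_equal(ba$sd_diff, 0)
  expect_equal(unname(ba$loa), c(-1, -1))
  ident <- paired_measurements(data.frame(lesion_id = 1:3,
                                          value_full = c(5, 6, 7),
                                          value_reduced = c(5, 6, 7)))
  bai <- bland_altman(ident)
  expect_equal(bai$bias, 0)
  expect_equal(unname(bai$loa), c(0, 0))
  # hand-computed t-based CI
  p2 <- hand_pairs()
  d <- p2$value_reduced - p2$value_full
  ba2 <- bland_altman(p2)
  expect_equal(ba2$bias, mean(d))
  expect_equal(ba2$bias_ci,
               mean(d) + c(-1, 1) * qt(0.975, 5) * sd(d) / sqrt(6))
  expect_equal(unname(ba2$loa), mean(d) + c(-1.96, 1.96) * sd(d))
})

test_that("adding a constant to one arm shifts the bias but not PCC/ICC", {
  p <- generate_synthetic_cohort(seed = 8)
  shifted <- paired_measurements(data.frame(
    lesion_id = p$lesion_id, value_full = p$value_full,
    value_reduced = p$value_reduced + 2))
  expect_equal(pearson_with_ci(shifted)$estimate,
               pearson_with_ci(p)$estimate, tolerance = 1e-12)
  expect_equal(icc_two_way_mixed(shifted)$estimate,
               icc_two_way_mixed(p)$estimate, tolerance = 1e-12)
  expect_equal(bland_altman(shifted)$bias, bland_altman(p)$bias + 2)
})

test_that("maximum percentage deviation is the brute-force maximum", {
  single <- paired_measurements(data.frame(lesion_id = 1, value_full = 10,
                                           value_reduced = 8))
  expect_equal(max_percent_deviation(single), 20)
  p <- generate_synthetic_cohort(seed = 12)
  expect_equal(max_percent_deviation(p),
               max(abs(p$value_reduced / p$value_full - 1)) * 100)
  ident <- paired_measurements(data.frame(lesion_id = 1:3,
                                          value_full = c(1, 2, 3),
                                          value_reduced = c(1, 2, 3)))
  expect_equal(max_percent_deviation(ident), 0)
})

test_that("synthetic cohorts are reproducible and degenerate cleanly", {
  a <- generate_synthetic_cohort(seed = 4)
  b <- generate_synthetic_cohort(seed = 4)
  expect_identical(a, b)
  expect_equal(nrow(a), 30)
  # the generating SUV distribution spans more than an order of magnitude
  # (central 95% range), and the sampled cohort covers a wide spread too
  expect_gt(qlnorm(0.975, 2.1, 0.65) / qlnorm(0.025, 2.1, 0.65), 10)
  expect_gt(max(a$value_full) / min(a$value_full), 5)
  # noiseless, unbiased cohort: perfect agreement everywhere
  clean <- generate_synthetic_cohort(additive_bias = 0,
                                     proportional_noise_cv = 0, seed = 2)
  expect_equal(clean$value_full, clean$value_reduced)
  rep <- agreement_report(clean)
  expect_equal(rep$pcc$estimate, 1)
  expect_equal(rep$icc$estimate, 1)
  expect_equal(rep$kripp_alpha, 1)
  expect_equal(rep$bland_altman$bias, 0)
  expect_equal(rep$max_pct_dev, 0)
  # low-noise cohorts recover near-perfect ICC
  iccs <- vapply(1:20, function(s)
    icc_two_way_mixed(generate_synthetic_cohort(
      proportional_noise_cv = 0.03, seed = 100 + s))$estimate, 0)
  expect_true(all(iccs > 0.99))
})

test_that("interval alpha tracks agreement ICC across a noise sweep", {
  cvs <- c(0.01, 0.05, 0.15, 0.4)
  alphas <- iccs <- numeric(length(cvs))
  for (i in seq_along(cvs)) {
    p <- generate_synthetic_cohort(n_lesions = 60, additive_bias = 0,
                                   proportional_noise_cv = cvs[i], seed = 31)
    alphas[i] <- krippendorff_alpha(p)
    iccs[i] <- icc_two_way_mixed(p, type = "agreement")$estimate
  }
  expect_true(all(diff(alphas) < 0))
  expect_true(all(diff(iccs) < 0))
  expect_equal(order(alphas), order(iccs))
})
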