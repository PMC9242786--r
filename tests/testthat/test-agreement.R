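test_that("Spearman's rho is monotone-invariant and matches the rank oracle", {
  x <- 1:10
  expect_equal(spearman_rho(x, x^3)$rho, 1)
  expect_equal(spearman_rho(x, x^3)$p_value, 0)
  expect_equal(spearman_rho(x, rev(x))$rho, -1)

  x5 <- c(1, 2, 3, 4, 5); y5 <- c(2, 1, 4, 3, 5)
  expect_equal(spearman_rho(x5, y5)$rho, naive_spearman(x5, y5),
               tolerance = 1e-12)

  # ties handled by mid-ranks; agrees with the asymptotic cor.test estimate
  set.seed(51)
  for (rep in 1:25) {
    a <- sample(1:8, 30, replace = TRUE)
    b <- a + sample(1:4, 30, replace = TRUE)
    got <- spearman_rho(a, b)
    expect_equal(got$rho, naive_spearman(a, b), tolerance = 1e-12)
    ref <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                            exact = FALSE))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }

  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")

  # invariance under strictly monotone transforms of either argument
  set.seed(52)
  a <- rnorm(40); b <- rnorm(40)
  r0 <- spearman_rho(a, b)$rho
  expect_equal(spearman_rho(exp(a), b)$rho, r0)
  expect_equal(spearman_rho(a, b^3)$rho, r0)
})

test_that("ICC(2,1) matches the two-way ANOVA oracle and penalizes bias", {
  expect_equal(icc_2_1(1:20, 1:20)$icc, 1)
  expect_equal(icc_2_1(1:20, 1:20)$ci, c(1, 1))

  # a large constant shift leaves Pearson r = 1 but drags the
  # absolute-agreement ICC far down
  shifted <- icc_2_1(1:20, 1:20 + 100)
  expect_lt(shifted$icc, 0.2)
  expect_equal(shifted$icc, naive_icc21(1:20, 1:20 + 100), tolerance = 1e-12)

  set.seed(61)
  for (rep in 1:50) {
    a <- rnorm(25, 100, 20)
    b <- a + rnorm(25, 5, 10)
    got <- icc_2_1(a, b)
    expect_equal(got$icc, naive_icc21(a, b), tolerance = 1e-10)
    # symmetry in the two methods
    expect_equal(got$icc, icc_2_1(b, a)$icc, tolerance = 1e-12)
    expect_true(got$ci[1] <= got$icc && got$icc <= got$ci[2])
  }
  expect_error(icc_2_1(rep(3, 6), rep(3, 6)), "zero total variance")
})

test_that("ICC(2,1) point estimate and 95% CI reproduce a reference fixture", {
  # frozen from an independent two-way ANOVA implementation of the
  # single-rater absolute-agreement ICC (CI bounds to its printed precision)
  a <- c(103.0, 250.5, 87.2, 412.9, 199.4, 310.0, 150.7, 275.3, 95.8,
         360.1, 220.6, 130.2)
  b <- c(120.4, 231.0, 101.5, 398.7, 230.2, 295.6, 170.9, 301.2, 80.3,
         340.8, 241.1, 151.6)
  got <- icc_2_1(a, b)
  expect_equal(got$icc, 0.981518159614, tolerance = 1e-10)
  expect_equal(round(got$ci, 2), c(0.94, 0.99))
})

test_that("Bland-Altman bias and limits of agreement follow their construction", {
  ident <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$bias, 0)
  expect_equal(ident$loa, c(0, 0))
  expect_equal(ident$cv_pct, 0)

  shift <- bland_altman(11:20, 11:20 - 5)
  expect_equal(shift$bias, 5)
  expect_equal(shift$loa, c(5, 5))

  a <- c(10, 12, 14); b <- c(11, 11, 15)
  got <- bland_altman(a, b)
  ref <- naive_bland_altman(a, b)
  expect_equal(got$bias, -1 / 3)
  expect_equal(got$loa, ref$loa, tolerance = 1e-12)
  expect_equal(got$cv_pct, ref$cv_pct, tolerance = 1e-12)

  set.seed(71)
  for (rep in 1:50) {
    x <- rnorm(30, 50, 12); y <- rnorm(30, 55, 12)
    got <- bland_altman(x, y)
    ref <- naive_bland_altman(x, y)
    expect_equal(got$bias, ref$bias, tolerance = 1e-10)
    expect_equal(got$loa, ref$loa, tolerance = 1e-10)
    # antisymmetry and fixed LoA width
    expect_equal(got$bias, -bland_altman(y, x)$bias, tolerance = 1e-12)
    expect_equal(diff(got$loa), 2 * 1.96 * sd(x - y), tolerance = 1e-10)
  }

  expect_warning(out <- bland_altman(c(-1, 1), c(1, -1)), "undefined")
  expect_true(is.na(out$cv_pct) && out$bias == -0)
})

test_that("slope/offset come from OLS of predicted on actual", {
  expect_equal(linear_agreement(1:10, 1:10), list(slope = 1, offset = 0))
  expect_equal(linear_agreement(1:10, 2 * (1:10) + 3),
               list(slope = 2, offset = 3))

  set.seed(81)
  for (rep in 1:50) {
    x <- rnorm(25, 10, 3); y <- 0.8 * x + rnorm(25)
    got <- linear_agreement(x, y)
    ref <- naive_ols(x, y)
    expect_equal(got$slope, ref$slope, tolerance = 1e-10)
    expect_equal(got$offset, ref$offset, tolerance = 1e-10)
    # residuals orthogonal to the regressor
    resid <- y - got$slope * x - got$offset
    expect_lt(abs(sum(resid * x)), 1e-8)
  }
  expect_error(linear_agreement(rep(2, 5), 1:5), "zero variance")
})

test_that("the validity table gives one labeled row per sway metric", {
  ft <- feature_table(simulate_cohort(sim_config(n_subjects = 6, seed = 9)))
  vt <- validity_table(ft)
  expect_equal(vt$metric, c("rms", "range", "ac", "sd"))
  expect_true(all(vt$rho > 0.75) && all(vt$p_value < 0.001))

  # negative control: shuffling the COP paths destroys the correlation
  set.seed(91)
  null_rho <- replicate(20, {
    shuf <- ft
    shuf$cop_path_mm <- sample(shuf$cop_path_mm)
    mean(abs(validity_table(shuf)$rho))
  })
  expect_lt(mean(null_rho), 0.3)
})

test_that("agreement_report bundles all statistics coherently", {
  set.seed(95)
  ref <- rnorm(60, 500, 150)
  cand <- ref + rnorm(60, 20, 50)
  rep_ <- agreement_report(ref, cand)
  expect_equal(rep_$rho, spearman_rho(ref, cand)$rho)
  expect_equal(rep_$icc, icc_2_1(ref, cand)$icc)
  expect_equal(rep_$bias, mean(cand - ref))
  expect_equal(rep_$bias, mean(rep_$loa)) # bias is the LoA midpoint
  expect_true(rep_$icc_ci95[1] <= rep_$icc && rep_$icc <= rep_$icc_ci95[2])
})
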