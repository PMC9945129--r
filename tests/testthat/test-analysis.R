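test_that("standardized difference is a z-score difference with mean zero", {
  tr <- data.frame(mean_snr = c(0, 1), mean_contrast = c(1, 0))
  d <- standardized_difference(tr)$d
  expect_equal(d, c(-sqrt(2), sqrt(2)), tolerance = 1e-12)

  # affine-related variables give d = 0 everywhere
  tr2 <- data.frame(mean_snr = c(0.1, 0.3, 0.9), mean_contrast = 2 + 5 * c(0.1, 0.3, 0.9))
  expect_equal(standardized_difference(tr2)$d, rep(0, 3), tolerance = 1e-12)

  set.seed(61)
  tr3 <- data.frame(mean_snr = runif(50), mean_contrast = runif(50))
  d3 <- standardized_difference(tr3)$d
  expect_equal(mean(d3), 0, tolerance = 1e-12)
  zs <- (tr3$mean_snr - mean(tr3$mean_snr)) / sd(tr3$mean_snr)
  expect_equal(var(zs), 1, tolerance = 1e-12)

  # NA measurements are excluded, constants are an error
  tr3$mean_snr[1] <- NA
  expect_true(is.na(standardized_difference(tr3)$d[1]))
  expect_error(standardized_difference(data.frame(mean_snr = c(1, 1),
                                                  mean_contrast = c(0, 1))),
               "constant")
})

test_that("the GLMM recovers a known slope and flags degenerate input", {
  st <- small_study()
  obs <- observer_params(beta_d = 0.6, sigma_subject = 0.2,
                         sigma_stimulus = 0.2, seed = 62)
  r <- simulate_observer(st$schedule, obs)
  fit <- fit_binomial_glmm(r, fixed = c("d", "order", "repetition", "inversion"),
                           lrt_factors = "d", nAGQ = 0)
  est <- fit$coefficients["d", ]
  expect_lt(abs(est["estimate"] - 0.6), 3 * est["se"])
  expect_true(fit$tests$chisq[1] > qchisq(0.95, 1))  # strong effect detected
  expect_true(fit$converged)
  expect_equal(sort(names(fit$ranef_sd)), c("participant", "stimulus"))

  # all-identical responses: complete separation
  r2 <- r; r2$response_correct <- TRUE
  expect_error(fit_binomial_glmm(r2), "separation")

  # single participant: falls back to fixed effects with a warning
  r3 <- r[r$participant == 1, ]
  expect_warning(f3 <- fit_binomial_glmm(r3, fixed = "d", random = "participant",
                                         lrt_factors = character(0)),
                 "fixed effects only")
  expect_true(f3$fallback_fixed_only)
})

test_that("two-proportion z-test matches hand arithmetic and symmetry", {
  zt <- two_proportion_ztest(650, 1000, 600, 1000)
  expect_equal(zt$statistic, 0.05 / sqrt(0.65 * 0.35 / 1000 + 0.6 * 0.4 / 1000),
               tolerance = 1e-12)
  expect_equal(round(zt$statistic, 4), 2.3125)

  eq <- two_proportion_ztest(30, 100, 60, 200)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  sw <- two_proportion_ztest(600, 1000, 650, 1000)
  expect_equal(sw$statistic, -zt$statistic)
  expect_equal(sw$p_value, zt$p_value)

  expect_error(two_proportion_ztest(0, 10, 5, 10), NA)
  expect_error(two_proportion_ztest(10, 10, 0, 5), "undefined")
  expect_error(two_proportion_ztest(5, 0, 1, 2), "n > 0")
})

test_that("z-test SE agrees with a bootstrap SE within 5%", {
  set.seed(63)
  k1 <- 340; n1 <- 500; k2 <- 290; n2 <- 500
  zt <- two_proportion_ztest(k1, n1, k2, n2)
  se_formula <- (k1 / n1 - k2 / n2) / zt$statistic
  boots <- replicate(4000, {
    p1 <- mean(sample(c(rep(1, k1), rep(0, n1 - k1)), n1, TRUE))
    p2 <- mean(sample(c(rep(1, k2), rep(0, n2 - k2)), n2, TRUE))
    p1 - p2
  })
  expect_lt(abs(sd(boots) - se_formula) / se_formula, 0.05)
})

test_that("Friedman test matches hand computation and the stats oracle", {
  x <- matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3), 3, 3, byrow = TRUE)
  ft <- friedman_test(x)
  expect_equal(ft$statistic, 6)
  expect_equal(ft$effect, 1)  # Kendall's W

  allsame <- matrix(5, 3, 3)
  f0 <- friedman_test(allsame)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$effect, 0)

  # permuting condition labels together with the data leaves chi-square unchanged
  set.seed(64)
  y <- matrix(rnorm(15), 5, 3)
  perm <- sample(3)
  expect_equal(friedman_test(y, exact = FALSE)$statistic,
               friedman_test(y[, perm], exact = FALSE)$statistic)

  # agreement with stats::friedman.test on tie-free data
  ref <- stats::friedman.test(y)
  got <- friedman_test(y, exact = FALSE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  expect_error(friedman_test(y[, 1, drop = FALSE]), "conditions")
})

test_that("exact Friedman p matches full permutation enumeration", {
  set.seed(65)
  x <- matrix(rnorm(9), 3, 3)
  ft <- friedman_test(x, exact = TRUE)
  # brute-force oracle over all (3!)^3 within-subject orderings
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  stat <- function(m) {
    r <- t(apply(m, 1, rank))
    12 * sum((colSums(r) - 3 * 2)^2) / (3 * 3 * 4)
  }
  count <- 0; total <- 0
  for (a in perms) for (b in perms) for (cc in perms) {
    m <- rbind(x[1, a], x[2, b], x[3, cc])
    total <- total + 1
    if (stat(m) >= ft$statistic - 1e-12) count <- count + 1
  }
  expect_equal(ft$p_value, count / total, tolerance = 1e-12)
})

test_that("Wilcoxon against chance reproduces the maximal-statistic case", {
  set.seed(66)
  vals <- 0.5 + runif(10, 0.01, 0.2)  # all ten subjects above chance
  wt <- wilcoxon_vs_chance(vals)
  expect_equal(wt$statistic, 55)       # n(n+1)/2 for n = 10
  expect_equal(wt$p_value, 2 / 1024, tolerance = 1e-12)
  expect_equal(round(wt$p_value, 3), 0.002)

  sym <- 0.5 + c(-0.04, -0.03, -0.02, -0.01, 0.011, 0.021, 0.031, 0.041)
  expect_gt(wilcoxon_vs_chance(sym)$p_value, 0.5)

  expect_error(wilcoxon_vs_chance(rep(0.5, 6)), "chance level")
})

test_that("exact Wilcoxon p matches sign-flip enumeration on 6 points", {
  set.seed(67)
  vals <- 0.5 + c(0.02, -0.013, 0.05, 0.041, -0.007, 0.033)
  wt <- wilcoxon_vs_chance(vals)
  d <- vals - 0.5
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  # null: each |difference| signed +/- with probability 1/2
  vs <- vapply(0:63, function(mask) {
    signs <- ifelse(bitwAnd(mask, 2^(0:5)) > 0, 1, -1)
    sum(rk[signs > 0])
  }, numeric(1))
  p_exact <- mean(abs(vs - sum(rk) / 2) >= abs(v_obs - sum(rk) / 2) - 1e-12)
  expect_equal(wt$statistic, v_obs)
  expect_equal(wt$p_value, p_exact, tolerance = 1e-12)
})
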