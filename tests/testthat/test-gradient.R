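# Two-step gradient regression, Bayesian R2 and scale-of-effect.

test_that("location filtering applies the strict threshold", {
  counts <- c(A = 29, B = 30, C = 200, D = 45, E = 12, F = 60, G = 31,
              H = 90, I = 300)
  kept <- filter_locations(counts)
  expect_false("A" %in% kept)        # 29 observations: excluded
  expect_true("B" %in% kept)         # 30: boundary, included
  expect_equal(length(kept), 7)      # 9 locations, 2 below threshold
  expect_setequal(attr(kept, "excluded"), c("A", "E"))
  expect_error(filter_locations(c(A = 5, B = 6, C = 50, D = 50)),
               "fewer than 3")
})

test_that("standardize centers and scales with the sample SD", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(40, 5, 3)
  z <- standardize(x)
  expect_equal(mean(z), 0)
  expect_equal(stats::sd(z), 1)
  expect_equal(standardize(10 + 2.5 * x), z)   # affine invariance
  expect_error(standardize(rep(4, 10)), "constant")
})

test_that("planted noise-free relations are recovered exactly", {
  set.seed(1001)
  mean_isa <- c(u1 = 0.1, u2 = 0.2, u3 = 0.35, u4 = 0.5, u5 = 0.6,
                u6 = 0.75, u7 = 0.9)
  var_isa <- c(u1 = 0.02, u2 = 0.05, u3 = 0.01, u4 = 0.06, u5 = 0.03,
               u6 = 0.02, u7 = 0.05)
  cv <- 0.2 + 0.05 * standardize(mean_isa)
  cv_draws <- matrix(cv, 7, 200, dimnames = list(names(mean_isa), NULL))
  fit <- per_iteration_regression(cv_draws, mean_isa, var_isa,
                                  draws_per_iteration = 50, seed = 2)
  expect_lt(abs(fit$summaries$beta_meanISA$median - 0.05), 0.01)
  expect_lt(abs(fit$summaries$beta_varISA$median), 0.01)
  # least-squares oracle on one iteration
  ls <- stats::lm(cv ~ standardize(mean_isa) + standardize(var_isa))
  expect_equal(unname(coef(ls)[2]), 0.05, tolerance = 1e-10)
  # identical CVs across locations: slopes ~ 0, CIs cover 0
  flat <- matrix(0.3, 7, 100, dimnames = list(names(mean_isa), NULL))
  ffit <- per_iteration_regression(flat, mean_isa, var_isa, seed = 3)
  expect_true(ffit$summaries$beta_meanISA$ci_low <= 0 &&
              ffit$summaries$beta_meanISA$ci_high >= 0)
  # single iteration: pooled posterior is that iteration's distribution
  one <- cv_draws[, 1, drop = FALSE]
  f1 <- per_iteration_regression(one, mean_isa, var_isa,
                                 draws_per_iteration = 500, seed = 4)
  expect_equal(nrow(f1$coef_draws), 500)
})

test_that("per-iteration regression guards its preconditions", {
  mean_isa <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  var_col <- c(a = 2, b = 4, c = 6, d = 8, e = 10)     # rank correlation 1
  cvd <- matrix(rnorm(50), 5, 10, dimnames = list(names(mean_isa), NULL))
  expect_error(per_iteration_regression(cvd, mean_isa, var_col),
               "collinear")
  expect_error(per_iteration_regression(cvd[1:2, ], mean_isa[1:2],
                                        var_col[1:2]), ">= 3 locations")
  var_ok <- c(a = 0.3, b = 0.1, c = 0.4, d = 0.2, e = 0.5)
  expect_error(per_iteration_regression(cvd, mean_isa, var_ok,
                                        n_iterations_used = 99),
               "iterations")
})

test_that("pooled posterior propagates step-1 uncertainty", {
  set.seed(1011)
  mean_isa <- stats::setNames(c(0.1, 0.25, 0.4, 0.5, 0.65, 0.8, 0.9),
                              paste0("u", 1:7))
  var_isa <- stats::setNames(c(0.03, 0.06, 0.01, 0.05, 0.02, 0.07, 0.04),
                             paste0("u", 1:7))
  base <- 0.2 + 0.05 * standardize(mean_isa)
  noisy <- matrix(base, 7, 150) + matrix(rnorm(7 * 150, 0, 0.05), 7)
  rownames(noisy) <- paste0("u", 1:7)
  fixed <- matrix(base, 7, 150, dimnames = list(paste0("u", 1:7), NULL))
  fn <- per_iteration_regression(noisy, mean_isa, var_isa, seed = 5)
  ff <- per_iteration_regression(fixed, mean_isa, var_isa, seed = 5)
  expect_gt(stats::var(fn$coef_draws[, "beta_meanISA"]),
            stats::var(ff$coef_draws[, "beta_meanISA"]))
  # adding a constant to all CVs only moves the intercept
  sh <- per_iteration_regression(fixed + 5, mean_isa, var_isa, seed = 5)
  expect_equal(sh$summaries$beta_meanISA$median,
               ff$summaries$beta_meanISA$median, tolerance = 1e-6)
  expect_equal(sh$summaries$intercept$median,
               ff$summaries$intercept$median + 5, tolerance = 0.01)
})

test_that("bayesian R2 matches its definition and analytic signal fractions", {
  set.seed(1021)
  mean_isa <- stats::setNames(seq(0.1, 0.9, length.out = 7), paste0("u", 1:7))
  var_isa <- stats::setNames(c(.03, .01, .05, .02, .06, .01, .04),
                             paste0("u", 1:7))
  # near-noise-free linear signal: R2 ~ 1
  cvd <- matrix(0.2 + 0.1 * standardize(mean_isa), 7, 50) +
    matrix(rnorm(350, 0, 1e-4), 7)
  rownames(cvd) <- paste0("u", 1:7)
  fit <- per_iteration_regression(cvd, mean_isa, var_isa, seed = 6)
  expect_gt(bayesian_r2(fit)$average, 0.97)
  expect_true(all(fit$r2_iter >= 0 & fit$r2_iter < 1))
  # signal-to-noise 1:3 -> R2 ~ 0.25, averaged over many locations
  n_loc <- 40
  mi <- stats::setNames(rnorm(n_loc), paste0("L", 1:n_loc))
  vi <- stats::setNames(rnorm(n_loc), paste0("L", 1:n_loc))
  sig <- standardize(mi) * 1
  cv2 <- matrix(sig, n_loc, 60) + matrix(rnorm(n_loc * 60, 0, sqrt(3)), n_loc)
  rownames(cv2) <- names(mi)
  fit2 <- per_iteration_regression(cv2, mi, vi, seed = 7)
  expect_lt(abs(bayesian_r2(fit2)$average - 0.25), 0.06)
})

test_that("scale of effect selects the max-R2 scale with the tie rule", {
  expect_equal(scale_of_effect(c("100" = 0.52, "250" = 0.40, "1000" = 0.30)),
               100)
  expect_equal(scale_of_effect(c("100" = 0.3, "250" = 0.3)), 100)
  expect_equal(scale_of_effect(c("100" = 0.35, "1000" = 0.63)), 1000)
  expect_error(scale_of_effect(numeric(0)), "empty")
})

test_that("spearman correlation matches cor.test and the permutation oracle", {
  expect_equal(mean_variance_correlation(1:6, c(2, 4, 5, 7, 8, 11))$rho, 1)
  expect_equal(mean_variance_correlation(1:6, -(1:6))$rho, -1)
  set.seed(1031)
  for (i in 1:3) {
    m <- rnorm(7); v <- rnorm(7)
    got <- mean_variance_correlation(m, v)
    ref <- suppressWarnings(stats::cor.test(m, v, method = "spearman",
                                            exact = TRUE))
    expect_equal(got$rho, unname(ref$estimate))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(mean_variance_correlation(rep(1, 5), 1:5), "constant")
  expect_error(mean_variance_correlation(1:3, 1:3), ">= 4")
})
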