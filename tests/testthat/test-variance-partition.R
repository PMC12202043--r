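# Decomposition operations against closed-form and brute-force oracles.

test_that("fixed-effect variance matches Bernoulli algebra and a row oracle", {
  tab <- tiny_table(8)
  des_cols <- colnames(urbanvar:::build_design(
    tab, c("forest", "urban"), tab$habitat, FALSE)$X)
  # one draw with only a sex effect b: V_f = p(1-p) b^2, p = freq of males
  b <- matrix(0, 120, length(des_cols), dimnames = list(NULL, des_cols))
  b[, "beta_sex"] <- 2
  fit <- fake_fit(tab, b)
  vf <- fixed_effect_variance(fit, tab, "sex")
  p <- mean(tab$sex[tab$habitat == "forest"] == "M")
  expect_equal(unname(vf[1, "forest"]), p * (1 - p) * 2^2)
  # zero coefficients give zero V_f
  b0 <- b; b0[, "beta_sex"] <- 0
  expect_true(all(fixed_effect_variance(fake_fit(tab, b0), tab, "sex") == 0))
  # sex + hour model vs brute-force recomputation of per-row contributions
  set.seed(701)
  b2 <- b
  b2[, c("beta_sex", "beta_hour", "beta_hour2")] <- rnorm(3 * nrow(b2))
  fit2 <- fake_fit(tab, b2)
  vf2 <- fixed_effect_variance(fit2, tab)
  X <- fit2$design$X
  for (d in c(1, 57)) {
    contrib <- X[, c("beta_sex", "beta_hour", "beta_hour2")] %*%
      b2[d, c("beta_sex", "beta_hour", "beta_hour2")]
    for (g in c("forest", "urban")) {
      cg <- contrib[tab$habitat == g]
      expect_equal(unname(vf2[d, g]), mean(cg^2) - mean(cg)^2)
    }
  }
  expect_error(fixed_effect_variance(fit, tab, "nonexistent"),
               "not in the fitted model")
})

test_that("marginal means follow the balanced-grid algebra", {
  tab <- tiny_table(8)
  des_cols <- colnames(urbanvar:::build_design(
    tab, c("forest", "urban"), tab$habitat, FALSE)$X)
  b <- matrix(0, 150, length(des_cols), dimnames = list(NULL, des_cols))
  b[, "beta_intercept_forest"] <- rnorm(150, 5)
  b[, "beta_intercept_urban"] <- rnorm(150, 7)
  # intercept-only: marginal mean equals the intercept draw
  mm <- marginal_mean(fake_fit(tab, b), tab)
  expect_equal(mm[, "forest"], unname(b[, "beta_intercept_forest"]))
  # sex effect 3: balanced marginalization adds 3/2
  b[, "beta_sex"] <- 3
  mm2 <- marginal_mean(fake_fit(tab, b), tab)
  expect_equal(mm2[, "urban"], unname(b[, "beta_intercept_urban"]) + 1.5)
  # full covariate model vs brute-force grid prediction, spot-checked draws
  set.seed(702)
  bfull <- matrix(rnorm(150 * length(des_cols)), 150,
                  dimnames = list(NULL, des_cols))
  fitf <- fake_fit(tab, bfull)
  mmf <- marginal_mean(fitf, tab)
  ctr <- fitf$design$centers
  for (d in c(3, 99)) for (g in c("forest", "urban")) {
    rows <- tab$habitat == g
    grid <- expand.grid(sex = c(0, 1), age = c(0, 1))
    pred <- mean(apply(grid, 1, function(cell) {
      hm <- mean(tab$decimal_hour[rows]) - ctr[["hour"]]
      bfull[d, paste0("beta_intercept_", g)] +
        bfull[d, "beta_sex"] * cell["sex"] +
        bfull[d, "beta_age"] * cell["age"] +
        bfull[d, "beta_day_of_year"] *
          (mean(tab$day_of_year[rows]) - ctr[["day_of_year"]]) +
        bfull[d, "beta_hour"] * hm + bfull[d, "beta_hour2"] * hm^2 +
        bfull[d, "beta_protocol"]
    }))
    expect_equal(unname(mmf[d, g]), pred)
  }
})

test_that("assemble computes the documented hand-arithmetic case", {
  # V_i = 1, V_y = 0, V_f = 0, V_r = 3, mean = 2
  tab <- tiny_table(6)
  des_cols <- colnames(urbanvar:::build_design(
    tab, c("forest", "urban"), tab$habitat, FALSE)$X)
  b <- matrix(0, 120, length(des_cols), dimnames = list(NULL, des_cols))
  b[, "beta_intercept_forest"] <- 2
  b[, "beta_intercept_urban"] <- 2
  fit <- fake_fit(tab, b)
  fit$draws[, c("V_i_forest", "V_i_urban")] <- 1
  fit$draws[, c("V_r_forest", "V_r_urban")] <- 3
  fit$draws[, "V_y"] <- 0
  vf <- matrix(0, 120, 2, dimnames = list(NULL, c("forest", "urban")))
  cvs <- assemble(fit, vf, marginal_mean(fit, tab))
  expect_equal(unname(cvs$V_p[1, "forest"]), 4)
  expect_equal(unname(cvs$CV_P[1, "forest"]), 1)
  expect_equal(unname(cvs$CV_I[1, "forest"]), 0.5)
  expect_equal(unname(cvs$rpt[1, "forest"]), 0.25)
  # boundary: all variance among individuals flags rpt = 1
  fit2 <- fit
  fit2$draws[, c("V_r_forest", "V_r_urban")] <- 0
  expect_warning(assemble(fit2, vf, marginal_mean(fit2, tab)),
                 "boundary")
  # non-positive mean is an identified error
  b[, "beta_intercept_forest"] <- -1
  fit3 <- fake_fit(tab, b)
  expect_error(assemble(fit3, vf, marginal_mean(fit3, tab)),
               "draw 1, group forest")
})

test_that("V_p identity and observer exclusion hold on a real fit", {
  spec <- balanced_gaussian_spec(V_i = c(1, 2), V_r = 1, n_ind = 100, k = 3,
                                 V_y = 0.2, V_o = 0.2)
  tab <- simulate_observations(spec, seed = 801)
  fit <- fit_hetvar(tab, quick_config(seed = 802, n_iter = 900,
                                      burn_in = 300))
  cvs <- decompose_variance(fit, tab)
  # conservation: V_p - (V_i + V_y + V_f + V_r) = 0 exactly, every draw
  gap <- cvs$V_p - (cvs$V_i + cvs$V_y + cvs$V_f + cvs$V_r)
  expect_identical(unname(gap), matrix(0, nrow(gap), ncol(gap)))
  # V_o is tracked but never part of V_p
  expect_true(all(cvs$V_o > 0))
  expect_true(all(cvs$V_p < cvs$V_i + cvs$V_y + cvs$V_f + cvs$V_r +
                    cvs$V_o))
  # tidy export covers every draw x group x component
  td <- tidy_components(cvs)
  expect_equal(nrow(td), nrow(cvs$V_p) * 2 * 11)
})

test_that("gaussian CVs and repeatability are scale equivariant end-to-end", {
  spec <- balanced_gaussian_spec(V_i = c(1, 2), V_r = 1, n_ind = 120, k = 3,
                                 intercept = 10)
  tab <- simulate_observations(spec, seed = 811)
  tab2 <- tab; tab2$value <- tab$value * 3
  f1 <- fit_hetvar(tab, quick_config(seed = 812))
  f2 <- fit_hetvar(tab2, quick_config(seed = 812))
  c1 <- decompose_variance(f1, tab)
  c2 <- decompose_variance(f2, tab2)
  for (g in c("forest", "urban")) {
    expect_lt(abs(median(c2$mean[, g]) / median(c1$mean[, g]) - 3), 0.1)
    expect_lt(abs(median(c2$V_p[, g]) / median(c1$V_p[, g]) - 9), 0.5)
    expect_lt(abs(median(c2$CV_P[, g]) - median(c1$CV_P[, g])), 0.02)
    expect_lt(abs(median(c2$rpt[, g]) - median(c1$rpt[, g])), 0.05)
  }
})

test_that("ordinal decompositions omit CV_R", {
  spec <- variance_spec("ordinal", V_i = c(1, 1.5), n_individuals = 80,
                        repeats_dist = c("2" = 1))
  tab <- simulate_observations(spec, seed = 821)
  fit <- fit_hetvar(tab, quick_config("ordinal", seed = 822,
                                      n_iter = 900, burn_in = 300))
  cvs <- decompose_variance(fit, tab)
  expect_true(all(is.na(cvs$CV_R)))
  expect_true(all(cvs$V_r == 1))
  expect_false("lnCVR_R" %in% names(effect_sizes(cvs)))
})
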