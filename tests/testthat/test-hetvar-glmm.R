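# Sampler correctness against method-of-moments / analytic oracles, plus
# MCMC diagnostics with closed-form expectations.
#
# MCMC lengths here are deliberately short (documented reduced settings);
# the tolerances used are the spec-level ones, not tuned to a seed.

test_that("config invariants and family validation", {
  expect_error(model_config("gaussian", n_iter = 100, burn_in = 200),
               "burn_in")
  expect_error(model_config("gaussian", thin = 0), "thin")
  expect_error(model_config("negbin"), "unknown family")
})

test_that("gaussian posterior means match the ANOVA oracle", {
  spec <- balanced_gaussian_spec(V_i = 2, V_r = 1, n_ind = 250, k = 4)
  tab <- simulate_observations(spec, seed = 51)
  oracle <- anova_oracle(tab)
  fit <- fit_hetvar(tab, quick_config(seed = 52))
  for (g in c("forest", "urban")) {
    vi <- mean(fit$draws[, paste0("V_i_", g)])
    vr <- mean(fit$draws[, paste0("V_r_", g)])
    expect_lt(abs(vi - oracle["V_i"]) / oracle["V_i"], 0.15)
    expect_lt(abs(vr - oracle["V_r"]) / oracle["V_r"], 0.15)
  }
})

test_that("duplicated group under two labels gives lnCVR_I centered at 0", {
  spec <- balanced_gaussian_spec(V_i = 1.5, V_r = 1, n_ind = 150, k = 3,
                                 intercept = 8)
  tab <- simulate_observations(spec, seed = 61)
  half <- tab[tab$habitat == "forest", ]
  dup <- half
  dup$habitat <- "urban"
  dup$individual_id <- paste0(dup$individual_id, "_copy")
  dup$location_id <- "urban_1"
  both <- rbind(half, dup)
  fit <- fit_hetvar(both, quick_config(seed = 62))
  cvs <- decompose_variance(fit, both)
  e <- effect_sizes(cvs)$lnCVR_I
  expect_true(e$ci_low < 0 && e$ci_high > 0)
  expect_lt(abs(e$median), 0.2)
})

test_that("poisson fits recover V_i across replicates", {
  # posterior mean within 3 posterior SDs of truth in >= 16 of 20 fits
  hits <- 0L
  for (r in 1:20) {
    spec <- variance_spec("poisson", V_i = 0.5, V_r = 0.3, V_y = 0, V_o = 0,
                          intercept = 1, n_individuals = 150,
                          repeats_dist = c("3" = 1))
    tab <- simulate_observations(spec, seed = 700 + r)
    fit <- fit_hetvar(tab, quick_config("poisson", seed = 800 + r,
                                        n_iter = 1500, burn_in = 500))
    ok <- vapply(c("V_i_forest", "V_i_urban"), function(p)
      abs(mean(fit$draws[, p]) - 0.5) <= 3 * stats::sd(fit$draws[, p]),
      logical(1))
    hits <- hits + all(ok)
  }
  expect_gte(hits, 16L)
})

test_that("ordinal fit keeps thresholds ordered and residual fixed", {
  spec <- variance_spec("ordinal", V_i = c(1, 2), V_y = 0.05, V_o = 0.05,
                        n_individuals = 150,
                        repeats_dist = c("1" = 0.5, "3" = 0.5))
  tab <- simulate_observations(spec, seed = 71)
  fit <- fit_hetvar(tab, quick_config("ordinal", seed = 72,
                                      n_iter = 2500, burn_in = 1000))
  expect_false(any(grepl("^V_r", colnames(fit$draws))))
  cuts <- fit$draws[, paste0("cutpoint_", 2:6)]
  expect_true(all(t(apply(cbind(0, cuts), 1, diff)) > 0))
  expect_true(all(fit$draws[, grep("^V_", colnames(fit$draws))] > 0))
})

test_that("rank-deficient designs are reported with the aliased term", {
  spec <- balanced_gaussian_spec(n_ind = 40, k = 2)
  tab <- simulate_observations(spec, seed = 81)
  tab$sex <- tab$age_class <- NULL
  tab$sex <- ifelse(tab$habitat == "urban", "M", "F")   # aliased with group
  tab$age_class <- "adult"
  expect_error(fit_hetvar(tab, quick_config(seed = 82)),
               "rank deficient.*sex")
})

test_that("a group without repeats warns but still fits", {
  spec <- balanced_gaussian_spec(n_ind = c(60, 60), k = 2)
  tab <- simulate_observations(spec, seed = 91)
  forest_first <- tab$habitat == "forest" & tab$assay_rank == 0
  tab <- tab[tab$habitat == "urban" | forest_first, ]
  expect_warning(fit_hetvar(tab, quick_config(seed = 92,
                                              n_iter = 600, burn_in = 200)),
                 "no individual with repeated measures")
})

test_that("row order of the input table does not change the posterior", {
  spec <- balanced_gaussian_spec(V_i = c(1, 2), V_r = 1, n_ind = 150, k = 3)
  tab <- simulate_observations(spec, seed = 101)
  perm <- tab[sample(seq_len(nrow(tab))), ]
  f1 <- fit_hetvar(tab, quick_config(seed = 102))
  f2 <- fit_hetvar(perm, quick_config(seed = 102))
  for (p in c("V_i_forest", "V_i_urban", "V_r_forest", "V_r_urban")) {
    m1 <- mean(f1$draws[, p]); m2 <- mean(f2$draws[, p])
    expect_lt(abs(m1 - m2) / m1, 0.15)   # Monte-Carlo tolerance
  }
})

test_that("variance update matches the conjugate closed form", {
  # Degenerate model with beta fixed at truth (zero) and a single variance
  # component: y = e, e ~ N(0, V).  The sampler's own conditional update
  # must match the analytic scaled-inverse-chi-squared posterior
  # IG(a0 + n/2, b0 + ss/2).
  set.seed(111)
  e <- rnorm(400, 0, sqrt(2))
  draws <- urbanvar:::variance_posterior_draws(e, 5000)
  a0 <- 0.001; b0 <- 0.001
  cdf <- function(v) stats::pgamma(1 / v, a0 + length(e) / 2,
                                   rate = b0 + sum(e^2) / 2,
                                   lower.tail = FALSE)
  ks <- suppressWarnings(stats::ks.test(draws, cdf))$statistic
  expect_lt(unname(ks), 0.05)
  # and the full sampler's V_r stays consistent with the ANOVA-scale truth
  spec <- balanced_gaussian_spec(V_i = 0, V_r = 2, n_ind = 400, k = 2,
                                 intercept = 0)
  tab <- simulate_observations(spec, seed = 113)
  fit <- fit_hetvar(tab, model_config("gaussian", het_residual = FALSE,
                                      use_observer = FALSE,
                                      n_iter = 2000, burn_in = 500,
                                      thin = 2, seed = 112))
  tot <- mean(fit$draws[, "V_r"] + (fit$draws[, "V_i_forest"] +
                                      fit$draws[, "V_i_urban"]) / 2)
  expect_lt(abs(tot - stats::var(tab$value)) / stats::var(tab$value), 0.1)
})

test_that("doubling the prior scale barely moves variance posteriors", {
  spec <- balanced_gaussian_spec(V_i = 2, V_r = 1, n_ind = 300, k = 3)
  tab <- simulate_observations(spec, seed = 121)
  f1 <- fit_hetvar(tab, quick_config(seed = 122))
  f2 <- fit_hetvar(tab, quick_config(seed = 122, prior_V = 2))
  for (p in c("V_i_forest", "V_i_urban", "V_r_forest", "V_r_urban"))
    expect_lt(abs(mean(f1$draws[, p]) - mean(f2$draws[, p])) /
                mean(f1$draws[, p]), 0.10)
})

test_that("95% credible intervals for V_i achieve nominal coverage", {
  hits <- 0L
  for (r in 1:20) {
    spec <- balanced_gaussian_spec(V_i = c(1, 2), V_r = 1, n_ind = 120, k = 3)
    tab <- simulate_observations(spec, seed = 1300 + r)
    fit <- fit_hetvar(tab, quick_config(seed = 1400 + r,
                                        n_iter = 1200, burn_in = 400))
    ci_f <- stats::quantile(fit$draws[, "V_i_forest"], c(0.025, 0.975))
    ci_u <- stats::quantile(fit$draws[, "V_i_urban"], c(0.025, 0.975))
    hits <- hits + (ci_f[1] <= 1 && 1 <= ci_f[2] &&
                    ci_u[1] <= 2 && 2 <= ci_u[2])
  }
  expect_gte(hits, 18L)
})

# ---- diagnostics -----------------------------------------------------------

test_that("ESS matches iid and AR(1) closed forms", {
  set.seed(601)
  expect_true(abs(effective_sample_size(rnorm(2000)) - 2000) <= 400)
  # AR(1), rho = 0.5: ESS = n (1 - rho)/(1 + rho) = n/3
  n <- 6000
  x <- as.vector(stats::arima.sim(list(ar = 0.5), n))
  ess <- effective_sample_size(x)
  expect_lt(abs(ess - n / 3) / (n / 3), 0.25)
  expect_error(effective_sample_size(rep(1, 500)), "degenerate chain")
})

test_that("Geweke + ESS convergence report is calibrated and catches drift", {
  set.seed(602)
  passes <- vapply(1:100, function(i) {
    convergence_check(matrix(rnorm(1000), dimnames = list(NULL, "p")),
                      ess_min = 0)$pass
  }, logical(1))
  expect_gte(mean(passes), 0.95)   # nominal 99% pass rate, MC tolerance
  shifted <- c(rnorm(300), rnorm(300, 3))
  rep_shift <- convergence_check(matrix(shifted,
                                        dimnames = list(NULL, "p")),
                                 ess_min = 0)
  expect_false(rep_shift$pass)
  expect_identical(attr(rep_shift, "failures"), "p")
  clean <- convergence_check(matrix(rnorm(2500), dimnames = list(NULL, "p")),
                             ess_min = 1000)
  expect_length(attr(clean, "failures"), 0)
})
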