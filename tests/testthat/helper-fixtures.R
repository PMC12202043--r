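# Shared fixtures: all synthetic, built in code at test time.

# reduced MCMC settings used throughout the suite (documented deviation from
# the 65k-iteration reporting default, to stay inside the test time budget)
quick_config <- function(family = "gaussian", grouping = "by_habitat",
                         seed = 1L, n_iter = 1800, burn_in = 600, thin = 2,
                         ...) {
  model_config(family, grouping, n_iter = n_iter, burn_in = burn_in,
               thin = thin, seed = seed, ...)
}

# balanced Gaussian world: k repeats for every individual, no covariate
# effects, known variances
balanced_gaussian_spec <- function(V_i = c(2, 2), V_r = c(1, 1),
                                   n_ind = 400, k = 4, intercept = 10,
                                   V_y = 0, V_o = 0) {
  variance_spec("gaussian", V_i = V_i, V_r = V_r, V_y = V_y, V_o = V_o,
                intercept = intercept, n_individuals = n_ind,
                repeats_dist = stats::setNames(1, k))
}

# one-way ANOVA method-of-moments oracle for a balanced design:
# V_i = (MSB - MSW)/k, V_r = MSW
anova_oracle <- function(table) {
  k <- as.vector(table(table$individual_id))
  stopifnot(length(unique(k)) == 1L)
  k <- k[1]
  means <- tapply(table$value, table$individual_id, mean)
  msb <- k * stats::var(means)
  msw <- sum(tapply(table$value, table$individual_id,
                    function(v) sum((v - mean(v))^2))) /
    (length(table$value) - length(means))
  c(V_i = (msb - msw) / k, V_r = msw)
}

# minimal hand-built posterior_draws object with chosen coefficient draws,
# for unit-testing the decomposition operations against closed forms
fake_fit <- function(table, beta_draws, grouping = "by_habitat",
                     family = "gaussian", interactions = FALSE) {
  obs_group <- if (grouping == "by_habitat") as.character(table$habitat)
               else as.character(table$location_id)
  groups <- sort(unique(obs_group))
  des <- urbanvar:::build_design(table, groups, obs_group, interactions)
  stopifnot(identical(colnames(beta_draws), colnames(des$X)))
  nd <- nrow(beta_draws)
  extras <- cbind(matrix(1, nd, length(groups) * 2),
                  matrix(0.5, nd, 2))
  colnames(extras) <- c(paste0("V_i_", groups), paste0("V_r_", groups),
                        "V_y", "V_o")
  structure(list(draws = cbind(beta_draws, extras), family = family,
                 groups = groups, grouping = grouping,
                 obs_group = obs_group, use_observer = TRUE,
                 design = des,
                 config = quick_config(family)),
            class = "posterior_draws")
}

# tiny covariate table with fixed values (no randomness); covariate cycles
# have coprime periods so no dummy is aliased with another
tiny_table <- function(n_per_group = 6) {
  g <- rep(c("forest", "urban"), each = n_per_group)
  yr <- rep(c(2015L, 2018L, 2019L), length.out = length(g))
  data.frame(
    individual_id = paste0(g, "_i", seq_along(g)),
    location_id = paste0(g, "_1"),
    habitat = g,
    year = yr,
    observer_id = rep(c("obs1", "obs2"), length.out = length(g)),
    sex = rep(c("F", "M"), length.out = length(g)),
    age_class = rep(c("adult", "adult", "juvenile"), length.out = length(g)),
    day_of_year = rep(c(95L, 118L, 141L, 164L), length.out = length(g)),
    decimal_hour = rep(c(7.5, 9.25, 12, 15.5, 18.75), length.out = length(g)),
    assay_rank = 0L,
    protocol = ifelse(yr < 2017L, "pre2017", "post2017"),
    value = 1,
    stringsAsFactors = FALSE)
}
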