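# Simulation of long-format repeated behavioral assays with known ground
# truth.  The generative model mirrors the fitted one:
#
#   eta = intercept[g] + fixed part + u_ind + y_year + o_obs + e
#   u_ind ~ N(0, V_i[g]),  y_year ~ N(0, V_y),  o_obs ~ N(0, V_o),
#   e ~ N(0, V_r[g])
#
# with the trait value equal to eta (gaussian), the threshold category of eta
# (ordinal, 7 categories scored 0..3 by 0.5, latent residual variance fixed
# at 1), or a Poisson(exp(eta)) draw (count, e acting as log-normal
# overdispersion).  Continuous covariates enter centered (day at 135, hour at
# 13.5) so that intercepts are interpretable as latent group means at the
# reference covariate values.

DAY_CENTER <- 135
HOUR_CENTER <- 13.5
ORDINAL_SCORES <- seq(0, 3, by = 0.5)

#' Simulation ground-truth specification
#'
#' Defines the variance components, fixed effects and design sizes used by
#' [simulate_observations()].  Groups are the units carrying heterogeneous
#' among-individual (and residual) variances: the two habitats, or sampling
#' locations.
#'
#' @param family `"gaussian"`, `"ordinal"` or `"poisson"`.
#' @param groups character vector of group labels. For `group_type =
#'   "habitat"` must be `c("forest", "urban")`.
#' @param group_type `"habitat"` or `"location"`.
#' @param V_i,V_r per-group among-individual and residual variances (recycled
#'   if scalar; ordinal `V_r` is forced to 1 for every group).
#' @param V_y,V_o year and observer variances (shared across groups).
#' @param intercept per-group latent intercepts (recycled if scalar).
#' @param beta named list/vector of slopes on `sex` (M vs F), `age`
#'   (juvenile vs adult), `day_of_year` (centered), `hour` and `hour2`
#'   (centered), `assay_rank`, `protocol` (post2017 vs pre2017); missing
#'   entries default to 0.
#' @param thresholds 6 strictly increasing cutpoints for the 7 ordinal
#'   categories; `NULL` gives near-equal category probabilities under the
#'   implied total latent variance.
#' @param n_individuals per-group individual counts (recycled if scalar).
#' @param repeats_dist named numeric vector of probabilities over repeat
#'   counts; default `c("1" = .70, "2" = .18, "3" = .07, "4" = .05)`.
#' @param n_years,n_observers design sizes; years run 2014 onward.
#' @param locations_per_group number of sampling locations nested in each
#'   group when `group_type = "habitat"` (default: forest 1, urban 8).
#' @return An object of class `variance_spec`.
#' @export
variance_spec <- function(family = c("gaussian", "ordinal", "poisson"),
                          groups = c("forest", "urban"),
                          group_type = c("habitat", "location"),
                          V_i = 1, V_r = 1, V_y = 0.1, V_o = 0.1,
                          intercept = 0, beta = list(),
                          thresholds = NULL,
                          n_individuals = 300,
                          repeats_dist = c("1" = 0.70, "2" = 0.18,
                                           "3" = 0.07, "4" = 0.05),
                          n_years = 9, n_observers = 6,
                          locations_per_group = NULL) {
  family <- match.arg(family)
  group_type <- match.arg(group_type)
  groups <- as.character(groups)
  G <- length(groups)
  if (G < 1L) stop("at least one group is required")
  if (group_type == "habitat" && !setequal(groups, c("forest", "urban")))
    stop("habitat grouping requires groups 'forest' and 'urban'")
  rec <- function(x, nm) {
    x <- if (length(x) == 1L) rep(as.numeric(x), G) else as.numeric(x)
    if (length(x) != G) stop(nm, " must have length 1 or ", G)
    stats::setNames(x, groups)
  }
  V_i <- rec(V_i, "V_i"); V_r <- rec(V_r, "V_r")
  intercept <- rec(intercept, "intercept")
  if (any(c(V_i, V_r, V_y, V_o) < 0)) stop("variances must be >= 0")
  if (family == "ordinal") V_r[] <- 1   # probit identifiability
  slopes <- c(sex = 0, age = 0, day_of_year = 0, hour = 0, hour2 = 0,
              assay_rank = 0, protocol = 0)
  if (length(beta)) {
    beta <- unlist(beta)
    bad <- setdiff(names(beta), names(slopes))
    if (length(bad)) stop("unknown fixed-effect name(s): ",
                          paste(bad, collapse = ", "))
    slopes[names(beta)] <- beta
  }
  if (sum(repeats_dist) <= 0) stop("repeats_dist must have positive mass")
  repeats_dist <- repeats_dist / sum(repeats_dist)
  if (is.null(names(repeats_dist)))
    names(repeats_dist) <- seq_along(repeats_dist)
  n_individuals <- {
    x <- if (length(n_individuals) == 1L) rep(n_individuals, G) else n_individuals
    if (length(x) != G) stop("n_individuals must have length 1 or ", G)
    stats::setNames(as.integer(x), groups)
  }
  if (any(n_individuals < 1L)) stop("each group needs >= 1 individual")
  if (is.null(locations_per_group)) {
    locations_per_group <-
      if (group_type == "habitat")
        stats::setNames(ifelse(groups == "forest", 1L, 8L), groups)
      else stats::setNames(rep(1L, G), groups)
  } else locations_per_group <- stats::setNames(
    rep_len(as.integer(locations_per_group), G), groups)
  if (family == "ordinal" && !is.null(thresholds)) {
    if (length(thresholds) != 6L || any(diff(thresholds) <= 0))
      stop("thresholds must be 6 strictly increasing cutpoints")
  }
  if (is.null(thresholds) && family == "ordinal") {
    s <- sqrt(mean(V_i) + V_y + V_o + mean(V_r))
    thresholds <- mean(intercept) + s * stats::qnorm(seq_len(6) / 7)
  }
  structure(list(family = family, groups = groups, group_type = group_type,
                 V_i = V_i, V_r = V_r, V_y = V_y, V_o = V_o,
                 intercept = intercept, beta = slopes,
                 thresholds = thresholds,
                 n_individuals = n_individuals,
                 repeats_dist = repeats_dist,
                 n_years = as.integer(n_years),
                 n_observers = as.integer(n_observers),
                 locations_per_group = locations_per_group),
            class = "variance_spec")
}

#' @export
print.variance_spec <- function(x, ...) {
  cat(sprintf("<variance_spec> %s, %d %s group(s): %s\n", x$family,
              length(x$groups), x$group_type,
              paste(x$groups, collapse = ", ")))
  cat(sprintf("  V_i: %s | V_r: %s | V_y: %g | V_o: %g\n",
              paste(signif(x$V_i, 3), collapse = "/"),
              paste(signif(x$V_r, 3), collapse = "/"), x$V_y, x$V_o))
  invisible(x)
}

# latent fixed-effect contribution for rows of an observation table, given
# the spec's slopes (covariates centered as in the generator)
latent_fixed_part <- function(spec, df) {
  b <- spec$beta
  hc <- df$decimal_hour - HOUR_CENTER
  spec$intercept[df$.group] +
    b[["sex"]] * (df$sex == "M") +
    b[["age"]] * (df$age_class == "juvenile") +
    b[["day_of_year"]] * (df$day_of_year - DAY_CENTER) +
    b[["hour"]] * hc + b[["hour2"]] * hc^2 +
    b[["assay_rank"]] * df$assay_rank +
    b[["protocol"]] * (df$protocol == "post2017")
}

#' Simulate an observation table
#'
#' Draws a long-format table of repeated behavioral assays under the
#' generative model in `spec`.  Randomness is split into deterministic
#' substreams (design, individual effects, year effects, observer effects,
#' residuals) derived from the master seed, so identical `(spec, seed)` give
#' identical tables.
#'
#' @param spec a [variance_spec].
#' @param seed master integer seed.
#' @return data.frame of class `observation_table` with columns
#'   `individual_id`, `location_id`, `habitat`, `year`, `observer_id`, `sex`,
#'   `age_class`, `day_of_year`, `decimal_hour`, `assay_rank`, `protocol`,
#'   `value`.
#' @export
simulate_observations <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "variance_spec"))
  groups <- spec$groups
  years <- 2013L + seq_len(spec$n_years)

  # -- design stream: individuals, repeats, covariates ----------------------
  local_rng(substream_seed(seed, "design"))
  ids <- list(); rows <- list()
  k_opts <- as.integer(names(spec$repeats_dist))
  for (g in groups) {
    n <- spec$n_individuals[[g]]
    k <- k_opts[sample.int(length(k_opts), n, replace = TRUE,
                           prob = spec$repeats_dist)]
    nloc <- spec$locations_per_group[[g]]
    loc <- if (spec$group_type == "location") rep(g, n)
           else paste0(g, "_", sample.int(nloc, n, replace = TRUE))
    habitat <- if (spec$group_type == "habitat") g
               else c("forest", "urban")[1L + grepl("^urban", g)]
    sex <- c("F", "M")[1L + (stats::runif(n) < 0.5)]
    age <- c("adult", "juvenile")[1L + (stats::runif(n) < 0.5)]
    idx <- rep(seq_len(n), k)
    yr <- unlist(lapply(k, function(ki)
      sort(sample(years, ki, replace = ki > length(years)))))
    rows[[g]] <- data.frame(
      individual_id = paste0(g, "_ind", idx),
      location_id = loc[idx],
      habitat = habitat,
      year = yr,
      observer_id = paste0("obs", sample.int(spec$n_observers,
                                             length(idx), replace = TRUE)),
      sex = sex[idx], age_class = age[idx],
      day_of_year = sample(90:180, length(idx), replace = TRUE),
      decimal_hour = stats::runif(length(idx), 7, 20),
      assay_rank = unlist(lapply(k, function(ki) seq_len(ki) - 1L)),
      .group = g, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (nrow(df) == 0L) stop("design yields zero observations")
  df$protocol <- ifelse(df$year < 2017L, "pre2017", "post2017")

  # -- effect streams -------------------------------------------------------
  local_rng(substream_seed(seed, "individuals"))
  uid <- unique(df$individual_id)
  ug <- df$.group[match(uid, df$individual_id)]
  u <- stats::rnorm(length(uid), 0, sqrt(spec$V_i[ug]))
  names(u) <- uid
  local_rng(substream_seed(seed, "years"))
  yeff <- stats::setNames(stats::rnorm(length(years), 0, sqrt(spec$V_y)),
                          years)
  local_rng(substream_seed(seed, "observers"))
  oeff <- stats::setNames(
    stats::rnorm(spec$n_observers, 0, sqrt(spec$V_o)),
    paste0("obs", seq_len(spec$n_observers)))
  local_rng(substream_seed(seed, "residuals"))
  e <- stats::rnorm(nrow(df), 0, sqrt(spec$V_r[df$.group]))

  eta <- latent_fixed_part(spec, df) + u[df$individual_id] +
    yeff[as.character(df$year)] + oeff[df$observer_id] + e
  df$value <- switch(spec$family,
    gaussian = eta,
    ordinal = ORDINAL_SCORES[findInterval(eta, spec$thresholds) + 1L],
    poisson = stats::rpois(nrow(df), exp(eta)))
  df$.group <- NULL
  class(df) <- c("observation_table", "data.frame")
  attr(df, "family") <- spec$family
  attr(df, "seed") <- seed
  df
}

#' Exact ground truth implied by a specification
#'
#' Computes, on the latent scale and in closed form (never by simulation),
#' the per-group variance components, marginal means, coefficients of
#' variation, repeatabilities, and — for a two-group spec — the pairwise
#' effect sizes lnCVR (per component), lnRR and lnRPT.
#'
#' The marginal mean follows the reporting convention used downstream:
#' balanced over sex and age, continuous covariates at their centers, assay
#' rank 0, protocol post2017.  `V_f` is the variance of the sex + hour +
#' hour-squared contribution under the generator's covariate distributions
#' (sex Bernoulli(1/2); hour Uniform(7, 20)).
#'
#' @param spec a [variance_spec].
#' @param numerator,denominator group labels forming the effect-size ratio
#'   (defaults urban/forest).
#' @return list with elements `components` (data.frame per group) and, for
#'   two groups, `effects` (named numeric vector).
#' @export
ground_truth <- function(spec, numerator = "urban", denominator = "forest") {
  stopifnot(inherits(spec, "variance_spec"))
  b <- spec$beta
  # analytic V_f for the default biologically relevant terms (sex, hour, hour2)
  a <- (20 - 7) / 2                      # hour half-range after centering
  var_h <- a^2 / 3
  var_h2 <- a^4 / 5 - (a^2 / 3)^2        # Var of h^2, h ~ U(-a, a)
  v_f <- 0.25 * b[["sex"]]^2 + b[["hour"]]^2 * var_h + b[["hour2"]]^2 * var_h2
  comp <- data.frame(group = spec$groups,
                     V_i = as.numeric(spec$V_i),
                     V_y = spec$V_y, V_f = v_f,
                     V_r = as.numeric(spec$V_r),
                     V_o = spec$V_o, stringsAsFactors = FALSE)
  comp$V_p <- comp$V_i + comp$V_y + comp$V_f + comp$V_r
  comp$mean <- as.numeric(spec$intercept) + 0.5 * b[["sex"]] +
    0.5 * b[["age"]] + b[["protocol"]]
  bad <- comp$mean == 0 & comp$V_p > 0
  if (any(bad))
    stop("undefined CV: group mean is 0 with nonzero variance for ",
         paste(comp$group[bad], collapse = ", "))
  comp$CV_P <- sqrt(comp$V_p) / comp$mean
  comp$CV_I <- sqrt(comp$V_i) / comp$mean
  comp$CV_R <- sqrt(comp$V_r) / comp$mean
  comp$rpt <- comp$V_i / comp$V_p
  out <- list(components = comp)
  if (all(c(numerator, denominator) %in% spec$groups) &&
      length(spec$groups) == 2L) {
    nu <- comp[comp$group == numerator, ]
    de <- comp[comp$group == denominator, ]
    out$effects <- c(
      lnCVR_P = log(nu$CV_P / de$CV_P),
      lnCVR_I = log(nu$CV_I / de$CV_I),
      lnCVR_R = log(nu$CV_R / de$CV_R),
      lnRR = log(nu$mean / de$mean),
      lnRPT = log(nu$rpt / de$rpt))
  }
  out
}

#' Write / read observation tables
#'
#' The CSV carries exactly the documented columns; `write_observations` also
#' writes a `<path>.meta` sidecar with the family and seed for provenance.
#'
#' @param table an `observation_table`.
#' @param path CSV path.
#' @export
write_observations <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  meta <- c(paste0("family=", attr(table, "family") %||% "unknown"),
            paste0("seed=", attr(table, "seed") %||% "unknown"),
            paste0("n_rows=", nrow(table)),
            paste0("n_individuals=", length(unique(table$individual_id))))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}
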