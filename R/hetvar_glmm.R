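# Bayesian mixed models with group-specific (heterogeneous) among-individual
# and residual variances, for Gaussian, ordinal-threshold and Poisson
# log-normal responses.
#
# All three families share one Gaussian core on a working latent response l:
#
#   l_j = x_j' beta + u_{ind(j)} + y_{year(j)} + o_{obs(j)} + e_j,
#   u_i ~ N(0, V_i[g_i]),  e_j ~ N(0, V_r[g_j])
#
# For the Gaussian family l is the observed value.  For the Poisson family
# l_j is updated by a per-observation Metropolis step against the
# Poisson(exp(l_j)) likelihood (the observations are conditionally
# independent given the Gaussian part, so the update vectorizes).  For the
# ordinal family l_j is a truncated-normal draw between the cutpoints of the
# observed category, the residual variance is fixed at 1 (probit
# identifiability) and the free cutpoints get uniform conditional updates
# (the first cutpoint is fixed at 0).
#
# Priors: improper flat on beta; inverse-gamma on each variance, by default
# shape = rate = nu/2 with nu = 0.002 and V = 1 (the "weakly informative"
# default of the common animal-model software parameterization).

#' Model configuration for the heterogeneous-variance GLMM
#'
#' Captures the model structure and MCMC settings.  The two canonical
#' structures are the habitat model (two variance groups, habitat-by-covariate
#' interactions, heterogeneous year/observer variances) and the location model
#' (one variance group per sampling location, no interactions, homogeneous
#' year and observer variances); `variance_grouping` selects the defaults, and
#' every flag can be overridden.
#'
#' @param family `"gaussian"`, `"ordinal"` or `"poisson"`.
#' @param variance_grouping `"by_habitat"` or `"by_location"`.
#' @param interactions include group interactions with sex, age, date and the
#'   hour polynomial? Default `TRUE` for habitat grouping, `FALSE` for
#'   location grouping.
#' @param het_year,het_observer group-specific year / observer variances
#'   (effects nested in group)?  Defaults mirror `interactions`.
#' @param het_residual group-specific residual variances (ignored for the
#'   ordinal family, whose residual variance is fixed at 1).
#' @param use_observer fit an observer random effect at all?
#' @param n_iter,burn_in,thin,seed MCMC settings.  Defaults (65000 / 15000 /
#'   50) target effective sample sizes above 1000; reduce for exploratory
#'   runs.
#' @param prior_nu,prior_V inverse-gamma variance prior in the (V, nu)
#'   parameterization: shape = nu/2, rate = nu*V/2.
#' @return An object of class `model_config`.
#' @export
model_config <- function(family = c("gaussian", "ordinal", "poisson"),
                         variance_grouping = c("by_habitat", "by_location"),
                         interactions = NULL,
                         het_year = NULL, het_observer = NULL,
                         het_residual = TRUE,
                         use_observer = TRUE,
                         n_iter = 65000, burn_in = 15000, thin = 50,
                         seed = 1L,
                         prior_nu = 0.002, prior_V = 1) {
  family <- tryCatch(match.arg(family),
                     error = function(e) stop("unknown family: ",
                                              family[1], call. = FALSE))
  variance_grouping <- match.arg(variance_grouping)
  by_hab <- variance_grouping == "by_habitat"
  if (is.null(interactions)) interactions <- by_hab
  if (is.null(het_year)) het_year <- by_hab
  if (is.null(het_observer)) het_observer <- by_hab
  if (burn_in >= n_iter) stop("burn_in must be < n_iter")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(family = family, variance_grouping = variance_grouping,
                 interactions = interactions, het_year = het_year,
                 het_observer = het_observer, het_residual = het_residual,
                 use_observer = use_observer,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_nu = prior_nu, prior_V = prior_V),
            class = "model_config")
}

# ---- design construction ---------------------------------------------------

# Builds the fixed-effect design.  Continuous covariates are centered at
# their sample means (centers stored) so that "prediction at the sample
# mean" is a zero contribution; the hour polynomial is (h - c) and (h - c)^2.
# Returns X with a term map: term (covariate name), group (NA for shared).
build_design <- function(table, groups, obs_group, interactions) {
  n <- nrow(table)
  hc <- table$decimal_hour - mean(table$decimal_hour)
  dc <- table$day_of_year - mean(table$day_of_year)
  base <- list(sex = as.numeric(table$sex == "M"),
               age = as.numeric(table$age_class == "juvenile"),
               day_of_year = dc, hour = hc, hour2 = hc^2)
  cols <- list(); term <- character(); grp <- character()
  for (g in groups) {                      # one intercept per group
    cols[[length(cols) + 1L]] <- as.numeric(obs_group == g)
    term <- c(term, "intercept"); grp <- c(grp, g)
  }
  for (tn in names(base)) {
    v <- base[[tn]]
    if (length(unique(v)) < 2L) next       # constant covariate: drop
    if (interactions) {
      for (g in groups) {
        cols[[length(cols) + 1L]] <- v * (obs_group == g)
        term <- c(term, tn); grp <- c(grp, g)
      }
    } else {
      cols[[length(cols) + 1L]] <- v
      term <- c(term, tn); grp <- c(grp, NA_character_)
    }
  }
  cols[[length(cols) + 1L]] <- table$assay_rank
  term <- c(term, "assay_rank"); grp <- c(grp, NA_character_)
  if ("protocol" %in% names(table) &&
      length(unique(table$protocol)) == 2L) {
    cols[[length(cols) + 1L]] <- as.numeric(table$protocol == "post2017")
    term <- c(term, "protocol"); grp <- c(grp, NA_character_)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- ifelse(is.na(grp), paste0("beta_", term),
                        paste0("beta_", term, "_", grp))
  keep <- apply(X, 2, function(v) length(unique(v)) > 1L) | term == "intercept"
  X <- X[, keep, drop = FALSE]; term <- term[keep]; grp <- grp[keep]
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("design is rank deficient; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  list(X = X, term = term, group = grp,
       centers = c(day_of_year = mean(table$day_of_year),
                   hour = mean(table$decimal_hour)))
}

# inverse-gamma draw for a variance: IG(shape, rate)
rinvgamma1 <- function(shape, rate) 1 / stats::rgamma(1, shape, rate = rate)

# The conditional variance update used for every component in the sampler,
# exposed as repeated draws for a zero-mean deviation vector (the "known
# beta, single component" degenerate model).  Kept as a named function so
# the conjugate-oracle test exercises the sampler's own update rule.
variance_posterior_draws <- function(e, n_draws, prior_nu = 0.002,
                                     prior_V = 1) {
  a0 <- prior_nu / 2; b0 <- prior_nu * prior_V / 2
  vapply(seq_len(n_draws), function(i)
    rinvgamma1(a0 + length(e) / 2, b0 + sum(e^2) / 2), numeric(1))
}

# truncated-normal draws, vectorized, numerically guarded
rtruncnorm_vec <- function(mean, sd, lo, hi) {
  pl <- stats::pnorm(lo, mean, sd)
  ph <- stats::pnorm(hi, mean, sd)
  u <- pl + stats::runif(length(mean)) * pmax(ph - pl, 1e-12)
  out <- stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), mean, sd)
  pmin(pmax(out, lo + 1e-9), hi - 1e-9)
}

#' Fit the heterogeneous-variance Bayesian mixed model
#'
#' Draws from the posterior of the model described in [model_config()] by
#' Gibbs sampling (Gaussian core), with Metropolis latent updates for Poisson
#' counts and truncated-normal data augmentation plus uniform cutpoint
#' updates for ordinal scores.
#'
#' @param table an `observation_table` (or data.frame with the documented
#'   columns).
#' @param config a [model_config].
#' @return An object of class `posterior_draws`: a list with `draws` (matrix,
#'   one named column per parameter), `family`, `groups`, `obs_group`,
#'   `design` (fixed-effect design and term map), and `config`.
#' @export
fit_hetvar <- function(table, config) {
  stopifnot(inherits(config, "model_config"))
  table <- validate_observations(table, family = config$family)
  fam <- config$family
  obs_group <- if (config$variance_grouping == "by_habitat")
    as.character(table$habitat) else as.character(table$location_id)
  groups <- sort(unique(obs_group))
  if (length(groups) < 2L) stop("need >= 2 variance groups")

  # individuals must map to a single group
  ind <- factor(table$individual_id)
  ind_idx <- as.integer(ind)
  n_ind <- nlevels(ind)
  ind_group <- obs_group[match(levels(ind), table$individual_id)]
  if (any(tapply(obs_group, ind_idx, function(g) length(unique(g))) > 1L))
    stop("an individual maps to more than one variance group")
  reps <- tabulate(ind_idx, n_ind)
  for (g in groups)
    if (!any(reps[ind_group == g] > 1L))
      warning("group '", g, "' has no individual with repeated measures; ",
              "its V_i and V_r are weakly identified")

  gi <- match(obs_group, groups)           # per-row group index
  gii <- match(ind_group, groups)          # per-individual group index
  n <- nrow(table); G <- length(groups)

  # year / observer unit structure (possibly nested in group)
  yr_lab <- if (config$het_year) paste(table$year, obs_group, sep = ":")
            else as.character(table$year)
  yr <- factor(yr_lab); yr_idx <- as.integer(yr)
  yr_group <- if (config$het_year)
    match(sub("^.*:", "", levels(yr)), groups) else rep(1L, nlevels(yr))
  use_obs <- config$use_observer && "observer_id" %in% names(table) &&
    length(unique(table$observer_id)) > 1L
  if (use_obs) {
    ob_lab <- if (config$het_observer)
      paste(table$observer_id, obs_group, sep = ":")
      else as.character(table$observer_id)
    ob <- factor(ob_lab); ob_idx <- as.integer(ob)
    ob_group <- if (config$het_observer)
      match(sub("^.*:", "", levels(ob)), groups) else rep(1L, nlevels(ob))
  }

  des <- build_design(table, groups, obs_group, config$interactions)
  X <- des$X; P <- ncol(X)

  het_res <- if (fam == "ordinal") FALSE else config$het_residual
  n_vr <- if (fam == "ordinal") 1L else if (het_res) G else 1L
  vr_idx <- if (het_res) gi else rep(1L, n)
  n_vy <- if (config$het_year) G else 1L
  n_vo <- if (use_obs && config$het_observer) G else 1L

  a0 <- config$prior_nu / 2
  b0 <- config$prior_nu * config$prior_V / 2

  set.seed(config$seed)

  # ---- initialization ------------------------------------------------------
  y <- table$value
  l <- switch(fam,
    gaussian = y,
    poisson = log(y + 0.5),
    ordinal = NULL)
  cuts <- NULL
  if (fam == "ordinal") {
    cat_idx <- match(y, ORDINAL_SCORES)
    cum <- cumsum(tabulate(cat_idx, 7L)) / n
    cum <- pmin(pmax(cum[1:6], 0.02), 0.98)
    cum <- cummax(cum + seq(0, 1e-3, length.out = 6))  # strictly increasing
    cuts <- stats::qnorm(cum); cuts <- cuts - cuts[1]  # fix c1 = 0
    l <- (cuts[pmin(pmax(cat_idx - 1L, 1L), 6L)] +
          cuts[pmin(cat_idx, 6L)]) / 2
  }
  beta <- rep(0, P)
  for (g in seq_len(G)) beta[g] <- mean(l[gi == g])
  u <- rep(0, n_ind); yeff <- rep(0, nlevels(yr))
  oeff <- if (use_obs) rep(0, nlevels(ob)) else NULL
  V_i <- rep(max(stats::var(l) / 2, 0.05), G)
  V_r <- if (fam == "ordinal") 1 else rep(max(stats::var(l) / 2, 0.05), n_vr)
  V_y <- rep(0.1, n_vy); V_o <- rep(0.1, n_vo)

  mh_sd <- rep(0.5, n); mh_acc <- rep(0, n)   # poisson latent proposals
  cut_sd <- 0.05; cut_acc <- 0                # ordinal cutpoint proposals

  n_kept <- (config$n_iter - config$burn_in) %/% config$thin
  par_names <- c(colnames(X),
                 paste0("V_i_", groups),
                 if (fam != "ordinal") {
                   if (het_res) paste0("V_r_", groups) else "V_r"
                 },
                 if (n_vy == G) paste0("V_y_", groups) else "V_y",
                 if (use_obs) {
                   if (n_vo == G) paste0("V_o_", groups) else "V_o"
                 },
                 if (fam == "ordinal") paste0("cutpoint_", 2:6))
  draws <- matrix(NA_real_, n_kept, length(par_names),
                  dimnames = list(NULL, par_names))
  kept <- 0L

  Xt <- t(X)
  lo_b <- c(-Inf, cuts); hi_b <- c(cuts, Inf)   # per-category bounds template

  for (it in seq_len(config$n_iter)) {
    fit_re <- u[ind_idx] + yeff[yr_idx] + (if (use_obs) oeff[ob_idx] else 0)

    # latent update ---------------------------------------------------------
    if (fam == "poisson") {
      m <- as.vector(X %*% beta) + fit_re
      prop <- l + stats::rnorm(n, 0, mh_sd)
      vr_j <- V_r[vr_idx]
      logr <- (y * prop - exp(prop) - 0.5 * (prop - m)^2 / vr_j) -
              (y * l    - exp(l)    - 0.5 * (l    - m)^2 / vr_j)
      acc <- log(stats::runif(n)) < logr
      l[acc] <- prop[acc]
      if (it <= config$burn_in) {
        mh_acc <- mh_acc + acc
        if (it %% 50L == 0L) {
          rate <- mh_acc / 50
          mh_sd <- pmin(pmax(mh_sd * exp(rate - 0.44), 0.05), 5)
          mh_acc[] <- 0
        }
      }
    } else if (fam == "ordinal") {
      m <- as.vector(X %*% beta) + fit_re
      # Collapsed Metropolis update of the free cutpoints (2..6), with the
      # liabilities integrated out; then redraw l from its full conditional.
      # Parameterized by log-spacings so proposals keep the ordering.
      loglik_cuts <- function(cc) {
        pm <- stats::pnorm(outer(cc, m, "-"))     # 6 x n
        pr <- rbind(pm, 1)[cbind(cat_idx, seq_len(n))] -
              rbind(0, pm)[cbind(cat_idx, seq_len(n))]
        sum(log(pmax(pr, 1e-300)))
      }
      d <- log(diff(c(0, cuts[2:6])))
      dp <- d + stats::rnorm(5, 0, cut_sd)
      cuts_p <- c(0, cumsum(exp(dp)))
      logr <- loglik_cuts(cuts_p) - loglik_cuts(cuts) + sum(dp) - sum(d)
      cut_acc_now <- is.finite(logr) && log(stats::runif(1)) < logr
      if (cut_acc_now) cuts <- cuts_p
      if (it <= config$burn_in) {
        cut_acc <- cut_acc + cut_acc_now
        if (it %% 50L == 0L) {
          cut_sd <- min(max(cut_sd * exp(cut_acc / 50 - 0.23), 0.005), 1)
          cut_acc <- 0
        }
      }
      lo_b <- c(-Inf, cuts); hi_b <- c(cuts, Inf)
      l <- rtruncnorm_vec(m, 1, lo_b[cat_idx], hi_b[cat_idx])
    }

    # beta | rest (flat prior) ----------------------------------------------
    w <- 1 / V_r[vr_idx]
    r <- l - fit_re
    XtWX <- Xt %*% (w * X)
    diag(XtWX) <- diag(XtWX) + 1e-9
    ch <- chol(XtWX)
    mu_b <- backsolve(ch, forwardsolve(t(ch), Xt %*% (w * r)))
    beta <- as.vector(mu_b + backsolve(ch, stats::rnorm(P)))
    xb <- as.vector(X %*% beta)

    # individual effects ----------------------------------------------------
    r <- l - xb - yeff[yr_idx] - (if (use_obs) oeff[ob_idx] else 0)
    sw <- rowsum(w, ind_idx)[, 1]
    swr <- rowsum(w * r, ind_idx)[, 1]
    prec <- sw + 1 / V_i[gii]
    u <- stats::rnorm(n_ind, swr / prec, sqrt(1 / prec))

    # year effects ----------------------------------------------------------
    r <- l - xb - u[ind_idx] - (if (use_obs) oeff[ob_idx] else 0)
    sw <- rowsum(w, yr_idx)[, 1]
    swr <- rowsum(w * r, yr_idx)[, 1]
    prec <- sw + 1 / V_y[yr_group]
    yeff <- stats::rnorm(nlevels(yr), swr / prec, sqrt(1 / prec))

    # observer effects ------------------------------------------------------
    if (use_obs) {
      r <- l - xb - u[ind_idx] - yeff[yr_idx]
      sw <- rowsum(w, ob_idx)[, 1]
      swr <- rowsum(w * r, ob_idx)[, 1]
      prec <- sw + 1 / V_o[ob_group]
      oeff <- stats::rnorm(nlevels(ob), swr / prec, sqrt(1 / prec))
    }

    # variance components ---------------------------------------------------
    for (g in seq_len(G)) {
      ug <- u[gii == g]
      V_i[g] <- rinvgamma1(a0 + length(ug) / 2, b0 + sum(ug^2) / 2)
    }
    if (fam != "ordinal") {
      e <- l - xb - u[ind_idx] - yeff[yr_idx] -
        (if (use_obs) oeff[ob_idx] else 0)
      if (het_res) {
        for (g in seq_len(G)) {
          eg <- e[gi == g]
          V_r[g] <- rinvgamma1(a0 + length(eg) / 2, b0 + sum(eg^2) / 2)
        }
      } else V_r[1] <- rinvgamma1(a0 + n / 2, b0 + sum(e^2) / 2)
    }
    for (g in seq_len(n_vy)) {
      yg <- yeff[yr_group == g]
      V_y[g] <- rinvgamma1(a0 + length(yg) / 2, b0 + sum(yg^2) / 2)
    }
    if (use_obs) for (g in seq_len(n_vo)) {
      og <- oeff[ob_group == g]
      V_o[g] <- rinvgamma1(a0 + length(og) / 2, b0 + sum(og^2) / 2)
    }

    # store ------------------------------------------------------------------
    if (it > config$burn_in &&
        (it - config$burn_in) %% config$thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- c(beta, V_i,
                         if (fam != "ordinal") V_r,
                         V_y, if (use_obs) V_o,
                         if (fam == "ordinal") cuts[2:6])
    }
  }

  structure(list(draws = draws, family = fam, groups = groups,
                 grouping = config$variance_grouping,
                 obs_group = obs_group, use_observer = use_obs,
                 design = des, config = config, seed = config$seed),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %s model, %d groups (%s), %d kept draws, %d parameters\n",
              x$family, length(x$groups), x$grouping,
              nrow(x$draws), ncol(x$draws)))
  invisible(x)
}

# extract the per-group variance-component draw matrix for component
# "V_i", "V_r", "V_y" or "V_o"; homogeneous components are recycled to every
# group so downstream code can always index by group.
component_draws <- function(fit, comp) {
  nm <- colnames(fit$draws)
  per_group <- paste0(comp, "_", fit$groups)
  if (all(per_group %in% nm)) {
    m <- fit$draws[, per_group, drop = FALSE]
  } else if (comp %in% nm) {
    m <- fit$draws[, rep(comp, length(fit$groups)), drop = FALSE]
  } else if (comp == "V_r" && fit$family == "ordinal") {
    m <- matrix(1, nrow(fit$draws), length(fit$groups))
  } else if (comp == "V_o" && !isTRUE(fit$use_observer)) {
    m <- matrix(0, nrow(fit$draws), length(fit$groups))
  } else stop("component not found in draws: ", comp)
  colnames(m) <- fit$groups
  m
}

# ---- diagnostics -----------------------------------------------------------

# Geyer initial-monotone-sequence ESS for one chain
ess_one <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (!is.finite(v) || v <= .Machine$double.eps * max(1, mean(x)^2))
    stop("degenerate chain: parameter is (numerically) constant")
  ac <- stats::acf(x, lag.max = min(n - 1L, 1000L), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  # sum of adjacent pairs; truncate at first negative, enforce monotonicity
  m <- (length(ac) - 1L) %/% 2L
  if (m < 1L) return(n)
  pair <- ac[2 * seq_len(m)] + ac[2 * seq_len(m) + 1L]
  pos <- which(pair <= 0)
  if (length(pos)) pair <- pair[seq_len(pos[1] - 1L)]
  if (length(pair)) pair <- cummin(pair)
  # Geyer: 1 + 2*sum(rho_k) = -rho_0 + 2*sum(pair sums); rho_0 = 1
  tau <- max(-1 + 2 * sum(pair) + 2, 1e-12)
  min(n / tau, n)
}

#' Effective sample size of posterior draws
#'
#' Autocorrelation-based ESS (initial monotone positive sequence estimator)
#' per parameter.
#'
#' @param draws a `posterior_draws` object, a numeric matrix (columns =
#'   parameters) or a numeric vector.
#' @return Named numeric vector of ESS values, with attribute `flagged`
#'   naming parameters with ESS below 1000.
#' @export
effective_sample_size <- function(draws) {
  m <- if (inherits(draws, "posterior_draws")) draws$draws
       else if (is.matrix(draws)) draws
       else matrix(draws, dimnames = list(NULL, "x"))
  if (nrow(m) < 100L) stop("need >= 100 kept draws for ESS")
  ess <- vapply(seq_len(ncol(m)), function(j) ess_one(m[, j]), numeric(1))
  names(ess) <- colnames(m)
  attr(ess, "flagged") <- names(ess)[ess < 1000]
  ess
}

geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2L, floor(frac1 * n)))]
  b <- x[(n - max(2L, floor(frac2 * n)) + 1L):n]
  # spectral density at frequency zero via an AIC-selected AR fit
  s0 <- function(v) {
    if (stats::var(v) == 0) return(0)
    fit <- try(stats::ar(v, aic = TRUE,
                         order.max = min(20L, floor(length(v) / 5))),
               silent = TRUE)
    if (inherits(fit, "try-error") || is.null(fit$var.pred))
      return(stats::var(v))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  (mean(a) - mean(b)) / sqrt(s0(a) / length(a) + s0(b) / length(b))
}

#' Convergence report for posterior draws
#'
#' Computes a Geweke first-10%/last-50% z-score per parameter (pass when
#' |z| < 2.58) and flags parameters whose effective sample size falls below
#' `ess_min`.  Report-only: never errors on a failing parameter.
#'
#' @param draws a `posterior_draws` object or draw matrix.
#' @param ess_min ESS threshold (default 1000, the usual reporting standard).
#' @return data.frame with columns `parameter`, `geweke_z`, `ess`,
#'   `pass_geweke`, `pass_ess`, `pass`; attribute `failures` lists failing
#'   parameter names (empty means downstream stages may proceed silently).
#' @export
convergence_check <- function(draws, ess_min = 1000) {
  m <- if (inherits(draws, "posterior_draws")) draws$draws
       else if (is.matrix(draws)) draws
       else matrix(draws, dimnames = list(NULL, "x"))
  if (nrow(m) < 200L) stop("need >= 200 kept draws for the convergence check")
  ess <- suppressWarnings(effective_sample_size(m))
  z <- vapply(seq_len(ncol(m)), function(j) geweke_z(m[, j]), numeric(1))
  out <- data.frame(parameter = colnames(m),
                    geweke_z = z, ess = as.numeric(ess),
                    pass_geweke = abs(z) < 2.58,
                    pass_ess = as.numeric(ess) >= ess_min,
                    stringsAsFactors = FALSE)
  out$pass <- out$pass_geweke & out$pass_ess
  attr(out, "failures") <- out$parameter[!out$pass]
  out
}
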