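# Two-step continuous-urbanization analysis.  Step 1 (elsewhere) fits the
# location-grouped heterogeneous-variance model and yields, per posterior
# iteration, a mean-standardized variance (CV) for every location.  Step 2
# regresses each iteration's per-location CVs on the centered/scaled mean
# and within-site variance of impervious surface (ISA), one regression per
# iteration, and pools all coefficient draws into a single posterior — so
# step-1 uncertainty is propagated, not collapsed.

#' Filter locations by observation count
#'
#' @param counts named vector (or table) of observation counts per location.
#' @param min_obs minimum count to retain (default 30; strictly fewer is
#'   excluded).
#' @return Character vector of retained location ids, with attribute
#'   `excluded`.
#' @export
filter_locations <- function(counts, min_obs = 30) {
  counts <- c(counts)
  if (is.null(names(counts))) stop("counts must be named by location")
  keep <- names(counts)[counts >= min_obs]
  if (length(keep) < 3L)
    stop("fewer than 3 locations remain after filtering; ",
         "a two-predictor regression is unidentifiable")
  structure(keep, excluded = setdiff(names(counts), keep))
}

#' Center and scale a predictor
#'
#' `(x - mean(x)) / sd(x)` with the sample (n-1) standard deviation.
#'
#' @param x numeric vector with at least 2 distinct values.
#' @return Standardized vector (mean 0, sample SD 1).
#' @export
standardize <- function(x) {
  if (length(unique(x)) < 2L || stats::sd(x) == 0)
    stop("cannot standardize a constant predictor")
  (x - mean(x)) / stats::sd(x)
}

#' Per-iteration regression of location CVs on ISA metrics
#'
#' For each posterior iteration of the location model, fits a linear
#' regression of that iteration's per-location CV on standardized mean ISA
#' and variance ISA.  Each iteration's fit is exact conjugate Bayesian linear
#' regression under flat priors: the error variance is drawn from its
#' scaled-inverse-chi-squared marginal and coefficients from the matching
#' normal conditional, `draws_per_iteration` times; all draws are pooled
#' into one combined posterior.
#'
#' @param cv_draws numeric matrix, locations (rows, named) x iterations.
#' @param mean_isa,var_isa named per-location ISA summaries at one scale.
#' @param n_iterations_used number of iterations (columns) used, default
#'   `min(1000, ncol(cv_draws))`.
#' @param draws_per_iteration coefficient draws per iteration (default 100).
#' @param scale_m,response,with_forest metadata recorded in the result.
#' @param seed RNG seed for the step-2 draws.
#' @return Object of class `gradient_fit`: pooled coefficient draws
#'   (`intercept`, `beta_meanISA`, `beta_varISA`), summaries, per-iteration
#'   Bayesian R-squared and its average, included locations.
#' @export
per_iteration_regression <- function(cv_draws, mean_isa, var_isa,
                                     n_iterations_used = NULL,
                                     draws_per_iteration = 100,
                                     scale_m = NA_real_, response = "CV",
                                     with_forest = TRUE, seed = 1L) {
  if (is.null(rownames(cv_draws))) stop("cv_draws must have location rownames")
  locs <- rownames(cv_draws)
  if (length(locs) < 3L) stop("need >= 3 locations")
  if (is.null(names(mean_isa)) || is.null(names(var_isa)))
    stop("mean_isa and var_isa must be named by location")
  if (!all(locs %in% names(mean_isa)) || !all(locs %in% names(var_isa)))
    stop("ISA metrics missing for some locations")
  mean_isa <- mean_isa[locs]; var_isa <- var_isa[locs]
  rho <- stats::cor(mean_isa, var_isa, method = "spearman")
  if (is.finite(rho) && abs(rho) >= 0.8)
    stop(sprintf("mean and variance ISA are collinear (|rho| = %.2f >= 0.8)",
                 abs(rho)))
  n_it <- n_iterations_used %||% min(1000L, ncol(cv_draws))
  if (n_it > ncol(cv_draws))
    stop("requested ", n_it, " iterations but cv_draws has ", ncol(cv_draws))
  X <- cbind(intercept = 1,
             beta_meanISA = standardize(mean_isa),
             beta_varISA = standardize(var_isa))
  n <- nrow(X); p <- ncol(X)
  if (qr(X)$rank < p) stop("collinear step-2 design")
  df <- n - p
  if (df < 1L) stop("need more locations than regression coefficients")
  XtXi <- solve(crossprod(X))
  ch <- chol(XtXi)
  local_rng(seed)
  coef_draws <- matrix(NA_real_, n_it * draws_per_iteration, p,
                       dimnames = list(NULL, colnames(X)))
  r2_iter <- numeric(n_it)
  for (t in seq_len(n_it)) {
    yv <- cv_draws[, t]
    bhat <- XtXi %*% crossprod(X, yv)
    fitted <- as.vector(X %*% bhat)
    s2 <- sum((yv - fitted)^2) / df
    sig2 <- df * s2 / stats::rchisq(draws_per_iteration, df)
    z <- matrix(stats::rnorm(draws_per_iteration * p), p)
    bd <- t(as.vector(bhat) + t(ch) %*% z * rep(sqrt(sig2), each = p))
    idx <- (t - 1L) * draws_per_iteration + seq_len(draws_per_iteration)
    coef_draws[idx, ] <- bd
    # Bayesian R2 per draw of this iteration, then averaged within iteration
    fit_d <- X %*% t(bd)                               # n x draws
    vfit <- colMeans(fit_d^2) - colMeans(fit_d)^2
    r2_iter[t] <- mean(vfit / (vfit + sig2))
  }
  summaries <- lapply(colnames(X), function(cn)
    summarize_effect(coef_draws[, cn], name = cn))
  names(summaries) <- colnames(X)
  structure(list(scale_m = scale_m, response = response,
                 coef_draws = coef_draws, summaries = summaries,
                 r2_iter = r2_iter, r2_mean = mean(r2_iter),
                 included_locations = locs, with_forest = with_forest,
                 n_iterations_used = n_it,
                 draws_per_iteration = draws_per_iteration),
            class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("<gradient_fit> %s @ %s m, %d locations%s, %d pooled draws\n",
              x$response, format(x$scale_m), length(x$included_locations),
              if (x$with_forest) "" else " (forest excluded)",
              nrow(x$coef_draws)))
  for (s in x$summaries[c("beta_meanISA", "beta_varISA")])
    print(s)
  cat(sprintf("  mean Bayesian R2 = %.3f\n", x$r2_mean))
  invisible(x)
}

#' Bayesian R-squared of a gradient fit
#'
#' R2 = var(fitted) / (var(fitted) + expected error variance), per
#' iteration, and its average across iterations.
#'
#' @param fit a `gradient_fit`.
#' @return List with `per_iteration` and `average`.
#' @export
bayesian_r2 <- function(fit) {
  stopifnot(inherits(fit, "gradient_fit"))
  list(per_iteration = fit$r2_iter, average = fit$r2_mean)
}

#' Scale of effect
#'
#' The spatial scale whose models explain the most variance (largest average
#' Bayesian R-squared).  Ties break toward the smallest scale: the finer
#' scale is the more conservative claim about spatial reach.
#'
#' @param r2_by_scale named numeric vector, names = scales in meters.
#' @return Numeric scale (meters).
#' @export
scale_of_effect <- function(r2_by_scale) {
  if (length(r2_by_scale) == 0L) stop("empty R2-by-scale map")
  if (is.null(names(r2_by_scale))) stop("r2_by_scale must be named by scale")
  sc <- as.numeric(names(r2_by_scale))
  best <- max(r2_by_scale)
  min(sc[r2_by_scale == best])
}

#' Spearman correlation between location means and variances
#'
#' Rank correlation with an exact permutation p-value (full enumeration) for
#' n <= 8 pairs and the asymptotic t approximation otherwise.
#'
#' @param means,variances aligned numeric vectors (>= 4 pairs).
#' @return List with `rho` and `p_value`.
#' @export
mean_variance_correlation <- function(means, variances) {
  n <- length(means)
  if (n != length(variances)) stop("inputs must be aligned")
  if (n < 4L) stop("need >= 4 paired values")
  if (length(unique(means)) == 1L || length(unique(variances)) == 1L)
    stop("ranks undefined: an input is constant (all ties)")
  rho <- stats::cor(means, variances, method = "spearman")
  if (n <= 8L) {
    rm_ <- rank(means); rv <- rank(variances)
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rm_, rv[p]))
    p_value <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p_value <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p_value = p_value)
}

# all n! permutations of 1..n (n <= 8 -> at most 40320 rows)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
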