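# Posterior variance decomposition.  Everything is computed per draw so that
# downstream effect sizes and regressions propagate the full posterior
# uncertainty.  The total phenotypic variance is
#
#   V_p = V_i + V_y + V_f + V_r
#
# where V_f is the variance contributed by the biologically relevant fixed
# effects only (by default sex and the hour polynomial).  Observer variance
# V_o is tracked but never enters V_p: it is measurement, not biology.

#' Per-draw fixed-effect variance
#'
#' For each posterior draw and each variance group, the variance (computed
#' across the group's observed rows, denominator n) of the linear-predictor
#' contribution of only the selected fixed terms.
#'
#' @param fit a `posterior_draws` object from [fit_hetvar()].
#' @param table the observation table the model was fitted to.
#' @param selected_terms covariate names to include; default
#'   `c("sex", "hour", "hour2")`.
#' @return Matrix `n_kept x n_groups` of V_f draws.
#' @export
fixed_effect_variance <- function(fit, table,
                                  selected_terms = c("sex", "hour", "hour2")) {
  stopifnot(inherits(fit, "posterior_draws"))
  if (nrow(table) != length(fit$obs_group))
    stop("table does not match the fitted data")
  fitted_terms <- unique(fit$design$term)
  missing_t <- setdiff(selected_terms, fitted_terms)
  if (length(missing_t))
    stop("term(s) not in the fitted model: ", paste(missing_t, collapse = ", "))
  sel <- fit$design$term %in% selected_terms
  Xs <- fit$design$X[, sel, drop = FALSE]
  Bs <- t(fit$draws[, colnames(Xs), drop = FALSE])   # p_sel x n_kept
  contrib <- Xs %*% Bs                               # n x n_kept
  out <- sapply(fit$groups, function(g) {
    cg <- contrib[fit$obs_group == g, , drop = FALSE]
    colMeans(cg^2) - colMeans(cg)^2                  # population variance
  })
  matrix(out, ncol = length(fit$groups),
         dimnames = list(NULL, fit$groups))
}

#' Per-draw marginal mean per group
#'
#' The prediction for each group averaged over a balanced grid of the
#' marginalized categorical covariates (default sex and age, equal weights),
#' with continuous covariates held at the group's sample means, assay rank at
#' 0 (first assay) and protocol at post2017.  Gaussian means are on the data
#' scale; Poisson and ordinal means are on the latent scale.
#'
#' @param fit a `posterior_draws` object.
#' @param table the observation table the model was fitted to.
#' @param marginalize_over categorical covariates averaged with equal
#'   weights; subset of `c("sex", "age")`.
#' @return Matrix `n_kept x n_groups` of marginal-mean draws.
#' @export
marginal_mean <- function(fit, table, marginalize_over = c("sex", "age")) {
  stopifnot(inherits(fit, "posterior_draws"))
  bad <- setdiff(marginalize_over, c("sex", "age"))
  if (length(bad)) stop("cannot marginalize over: ", paste(bad, collapse = ", "))
  des <- fit$design
  out <- sapply(fit$groups, function(g) {
    rows <- fit$obs_group == g
    if (!any(rows)) stop("no observations for group ", g)
    x <- numeric(ncol(des$X))
    day_m <- mean(table$day_of_year[rows]) - des$centers[["day_of_year"]]
    hour_m <- mean(table$decimal_hour[rows]) - des$centers[["hour"]]
    for (j in seq_along(x)) {
      tn <- des$term[j]; tg <- des$group[j]
      if (!is.na(tg) && tg != g) next      # other group's column
      x[j] <- switch(tn,
        intercept = 1,
        sex = if ("sex" %in% marginalize_over) 0.5 else 0,
        age = if ("age" %in% marginalize_over) 0.5 else 0,
        day_of_year = day_m,
        hour = hour_m,
        hour2 = hour_m^2,
        assay_rank = 0,
        protocol = 1,                      # reference: current protocol
        0)
    }
    as.vector(fit$draws[, colnames(des$X), drop = FALSE] %*% x)
  })
  matrix(out, ncol = length(fit$groups),
         dimnames = list(NULL, fit$groups))
}

#' Assemble per-draw variance components and CV summary
#'
#' Combines variance-component draws, fixed-effect variance and marginal
#' means into the full decomposition: per draw and group, `V_p = V_i + V_y +
#' V_f + V_r` (an exact identity by construction), coefficients of variation
#' `CV_x = sqrt(V_x)/mean` for x in \{P, I, R\}, and adjusted repeatability
#' `rpt = V_i / V_p`.  `CV_R` is omitted (all `NA`) for the ordinal family,
#' whose residual variance is fixed rather than estimated.
#'
#' @param fit a `posterior_draws` object.
#' @param v_f matrix from [fixed_effect_variance()].
#' @param means matrix from [marginal_mean()].
#' @return Object of class `cv_summary`: list of `n_kept x n_groups`
#'   matrices `V_i`, `V_y`, `V_f`, `V_r`, `V_o`, `V_p`, `mean`, `CV_P`,
#'   `CV_I`, `CV_R`, `rpt`, plus `family` and `groups`.
#' @export
assemble <- function(fit, v_f, means) {
  stopifnot(inherits(fit, "posterior_draws"))
  n_kept <- nrow(fit$draws)
  if (nrow(v_f) != n_kept || nrow(means) != n_kept)
    stop("draw indices of v_f / means are not aligned with the fit")
  V_i <- component_draws(fit, "V_i")
  V_y <- component_draws(fit, "V_y")
  V_r <- component_draws(fit, "V_r")
  V_o <- component_draws(fit, "V_o")
  V_p <- V_i + V_y + v_f + V_r
  if (any(means <= 0)) {
    bad <- which(means <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("undefined CV: non-positive marginal mean in draw %d, group %s",
                 bad[1], fit$groups[bad[2]]))
  }
  cv <- function(V) sqrt(V) / means
  rpt <- V_i / V_p
  if (any(rpt >= 1 - 1e-12))
    warning("repeatability at the rpt = 1 boundary in some draws ",
            "(all variance among individuals)")
  out <- list(V_i = V_i, V_y = V_y, V_f = v_f, V_r = V_r, V_o = V_o,
              V_p = V_p, mean = means,
              CV_P = cv(V_p), CV_I = cv(V_i),
              CV_R = if (fit$family == "ordinal")
                       matrix(NA_real_, n_kept, length(fit$groups),
                              dimnames = list(NULL, fit$groups))
                     else cv(V_r),
              rpt = rpt,
              family = fit$family, groups = fit$groups)
  class(out) <- "cv_summary"
  out
}

#' Decompose a fitted model in one call
#'
#' Convenience wrapper: [fixed_effect_variance()] + [marginal_mean()] +
#' [assemble()].
#'
#' @inheritParams fixed_effect_variance
#' @param selected_terms passed to [fixed_effect_variance()]; terms absent
#'   from the fitted model are dropped with a message (e.g. `hour` when the
#'   model was fitted without the hour polynomial).
#' @return A `cv_summary`.
#' @export
decompose_variance <- function(fit, table,
                               selected_terms = c("sex", "hour", "hour2")) {
  have <- intersect(selected_terms, unique(fit$design$term))
  if (length(have) < length(selected_terms))
    message("dropping fixed-effect terms not in the model: ",
            paste(setdiff(selected_terms, have), collapse = ", "))
  v_f <- if (length(have)) fixed_effect_variance(fit, table, have)
         else matrix(0, nrow(fit$draws), length(fit$groups),
                     dimnames = list(NULL, fit$groups))
  assemble(fit, v_f, marginal_mean(fit, table))
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("<cv_summary> %s family, %d draws x %d group(s)\n",
              x$family, nrow(x$V_p), length(x$groups)))
  print(summarize_components(x))
  invisible(x)
}

#' Posterior summary table of a decomposition
#'
#' @param cvs a `cv_summary`.
#' @param level credible level for the equal-tailed interval.
#' @return data.frame (group, component, median, ci_low, ci_high).
#' @export
summarize_components <- function(cvs, level = 0.95) {
  comps <- c("V_i", "V_y", "V_f", "V_r", "V_o", "V_p", "mean",
             "CV_P", "CV_I", "CV_R", "rpt")
  rows <- list()
  for (cc in comps) {
    m <- cvs[[cc]]
    for (g in cvs$groups) {
      v <- m[, g]
      if (all(is.na(v))) next
      s <- ci_summary(v, level)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, component = cc, median = s$median,
        ci_low = s$ci_low, ci_high = s$ci_high, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Tidy per-draw export of a decomposition
#'
#' @param cvs a `cv_summary`.
#' @return Long data.frame (draw, group, component, value).
#' @export
tidy_components <- function(cvs) {
  comps <- c("V_i", "V_y", "V_f", "V_r", "V_o", "V_p", "mean",
             "CV_P", "CV_I", "CV_R", "rpt")
  n <- nrow(cvs$V_p)
  do.call(rbind, lapply(comps, function(cc)
    do.call(rbind, lapply(cvs$groups, function(g)
      data.frame(draw = seq_len(n), group = g, component = cc,
                 value = cvs[[cc]][, g], stringsAsFactors = FALSE)))))
}
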