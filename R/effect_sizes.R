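# Pairwise comparative effect sizes between two groups, computed draw by
# draw so posterior correlation between numerator and denominator is
# preserved:
#
#   lnCVR_x = log(CV_x,num / CV_x,den)   per variance component x
#   lnRR    = log(mean_num / mean_den)
#   lnRPT   = log(rpt_num / rpt_den)
#
# Positive values mean "more" in the numerator group (conventionally urban).

#' Element-wise log-ratio of paired posterior draws
#'
#' @param numerator_draws,denominator_draws strictly positive numeric vectors
#'   of equal length, paired by draw index.
#' @return Numeric vector `log(numerator/denominator)`.
#' @export
ln_ratio <- function(numerator_draws, denominator_draws) {
  if (length(numerator_draws) != length(denominator_draws))
    stop("draw streams must have equal length")
  bad <- which(!(numerator_draws > 0) | !(denominator_draws > 0))
  if (length(bad))
    stop("non-positive draw at index ", bad[1],
         "; log-ratios require strictly positive streams")
  log(numerator_draws) - log(denominator_draws)
}

#' Summarize a per-draw effect stream
#'
#' Median, equal-tailed credible interval (or highest-posterior-density with
#' `hpd = TRUE`), posterior sign probability, and an evidence flag set when
#' the interval excludes zero.
#'
#' @param x per-draw effect values (>= 100 draws).
#' @param level credible level, default 0.95.
#' @param name optional effect label.
#' @param hpd use the HPD interval instead of equal-tailed quantiles.
#' @return Object of class `effect_size`.
#' @export
summarize_effect <- function(x, level = 0.95, name = NULL, hpd = FALSE) {
  if (length(x) < 100L)
    stop("insufficient draws (", length(x), "); need >= 100")
  if (hpd) {
    xs <- sort(x)
    k <- max(1L, floor(level * length(xs)))
    width <- xs[seq(k, length(xs))] - xs[seq_len(length(xs) - k + 1L)]
    i <- which.min(width)
    ci_low <- xs[i]; ci_high <- xs[i + k - 1L]
    med <- stats::median(x)
  } else {
    s <- ci_summary(x, level)
    ci_low <- s$ci_low; ci_high <- s$ci_high; med <- s$median
  }
  structure(list(name = name, median = med,
                 ci_low = ci_low, ci_high = ci_high, level = level,
                 p_positive = mean(x > 0),
                 evidence = ci_low > 0 || ci_high < 0,
                 draws = x),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  f <- fold_ratio(x$median)
  cat(sprintf("%s = %.3g [%.3g; %.3g]%s, P(>0) = %.2f, fold = %s%s\n",
              x$name %||% "effect", x$median, x$ci_low, x$ci_high,
              if (x$evidence) "*" else "", x$p_positive, f$label,
              if (nzchar(f$direction)) paste0(" (", f$direction, ")") else ""))
  invisible(x)
}

#' Fold change implied by a log-ratio effect
#'
#' Converts a log-ratio into the "x times more/less" phrasing: fold =
#' `exp(|ln_effect|)`, direction "more" for positive, "less" for negative
#' effects.
#'
#' @param ln_effect finite numeric scalar (a log ratio).
#' @param digits significant digits for the reporting label (default 3).
#' @return List with `fold` (unrounded), `direction` (`"more"`, `"less"` or
#'   `""` at exactly zero) and `label` (rounded for reporting).
#' @export
fold_ratio <- function(ln_effect, digits = 3) {
  stop_if_not_scalar_number(ln_effect, "ln_effect")
  fold <- exp(abs(ln_effect))
  list(fold = fold,
       direction = if (ln_effect > 0) "more" else if (ln_effect < 0) "less" else "",
       label = format(signif(fold, digits)))
}

#' All pairwise effect sizes from a two-group decomposition
#'
#' Computes lnCVR for the total phenotypic, among-individual, residual, year
#' and observer components, lnRR for marginal means, and lnRPT for adjusted
#' repeatability, each summarized via [summarize_effect()].  The residual
#' lnCVR is skipped for the ordinal family (no estimated residual variance);
#' year and observer lnCVR use `sqrt(V)/mean` with the shared variance when
#' the component is homogeneous.
#'
#' @param cvs a `cv_summary` with exactly the two groups of interest.
#' @param numerator,denominator group labels (default urban vs forest).
#' @param level credible level.
#' @return Named list of `effect_size` objects.
#' @export
effect_sizes <- function(cvs, numerator = "urban", denominator = "forest",
                         level = 0.95) {
  stopifnot(inherits(cvs, "cv_summary"))
  if (!all(c(numerator, denominator) %in% cvs$groups))
    stop("groups must include '", numerator, "' and '", denominator, "'")
  mu_n <- cvs$mean[, numerator]; mu_d <- cvs$mean[, denominator]
  out <- list()
  add <- function(nm, num, den) {
    out[[nm]] <<- summarize_effect(ln_ratio(num, den), level, name = nm)
  }
  cv_of <- function(V, g, mu) sqrt(V[, g]) / mu
  add("lnCVR_P", cv_of(cvs$V_p, numerator, mu_n),
                 cv_of(cvs$V_p, denominator, mu_d))
  add("lnCVR_I", cv_of(cvs$V_i, numerator, mu_n),
                 cv_of(cvs$V_i, denominator, mu_d))
  if (cvs$family != "ordinal")
    add("lnCVR_R", cv_of(cvs$V_r, numerator, mu_n),
                   cv_of(cvs$V_r, denominator, mu_d))
  add("lnCVR_Y", cv_of(cvs$V_y, numerator, mu_n),
                 cv_of(cvs$V_y, denominator, mu_d))
  if (any(cvs$V_o > 0))
    add("lnCVR_O", cv_of(cvs$V_o, numerator, mu_n),
                   cv_of(cvs$V_o, denominator, mu_d))
  add("lnRR", mu_n, mu_d)
  add("lnRPT", cvs$rpt[, numerator], cvs$rpt[, denominator])
  out
}

#' Flat report of a set of effect sizes
#'
#' @param effects named list from [effect_sizes()].
#' @return data.frame ready for JSON/CSV export (one row per effect).
#' @export
effects_report <- function(effects) {
  do.call(rbind, lapply(names(effects), function(nm) {
    e <- effects[[nm]]
    f <- fold_ratio(e$median)
    data.frame(effect = nm, median = e$median,
               ci_low = e$ci_low, ci_high = e$ci_high,
               p_positive = e$p_positive, evidence = e$evidence,
               fold = f$fold, direction = f$direction,
               stringsAsFactors = FALSE)
  }))
}
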