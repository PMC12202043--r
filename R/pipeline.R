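# Orchestration: typed I/O for observation tables, an end-to-end runner
# (simulate -> habitat model -> location model -> decomposition -> effect
# sizes -> gradient -> scale of effect) driven by a JSON config, and a small
# CLI front end.  Every artifact is CSV or JSON; a manifest records stage,
# seed and input hashes so any output can be regenerated.

OBS_COLUMNS <- c("individual_id", "location_id", "habitat", "year",
                 "observer_id", "sex", "age_class", "day_of_year",
                 "decimal_hour", "assay_rank", "value")

# shared validation for read and simulated tables
validate_observations <- function(table, family = NULL) {
  miss <- setdiff(OBS_COLUMNS, names(table))
  if (length(miss))
    stop("observation table missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!all(table$habitat %in% c("forest", "urban")))
    stop("habitat must be 'forest' or 'urban'")
  if (!all(table$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (!all(table$age_class %in% c("adult", "juvenile")))
    stop("age_class must be 'adult' or 'juvenile'")
  hb <- tapply(table$habitat, table$individual_id,
               function(h) length(unique(h)))
  if (any(hb > 1L)) stop("an individual maps to more than one habitat")
  if (!is.null(family)) {
    if (family == "ordinal") {
      bad <- which(!(table$value %in% ORDINAL_SCORES))
      if (length(bad))
        stop("ordinal value outside {0, 0.5, ..., 3} at row ", bad[1],
             " (value ", table$value[bad[1]], ")")
    }
    if (family == "poisson") {
      bad <- which(table$value < 0 | table$value != floor(table$value))
      if (length(bad))
        stop("count value must be a non-negative integer at row ", bad[1])
    }
  }
  table
}

#' Read an observation table from CSV
#'
#' Validates the documented schema, drops rows with missing trait values
#' (reporting how many), and checks family-specific value constraints.
#'
#' @param path CSV path.
#' @param family optional: `"gaussian"`, `"ordinal"` or `"poisson"` to
#'   enforce value constraints.
#' @return A validated `observation_table`.
#' @export
read_observations <- function(path, family = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(OBS_COLUMNS, names(df))
  if (length(miss))
    stop("observation CSV missing required column(s): ",
         paste(miss, collapse = ", "))
  n_na <- sum(is.na(df$value))
  if (n_na > 0L) {
    message("dropping ", n_na, " row(s) with missing trait values")
    df <- df[!is.na(df$value), , drop = FALSE]
  }
  df <- validate_observations(df, family)
  class(df) <- c("observation_table", "data.frame")
  attr(df, "family") <- family
  df
}

default_run_config <- function() {
  list(
    trait = "synthetic_trait",
    family = "gaussian",
    seed = 1L,
    out_dir = "urbanvar_run",
    stages = list(simulate = TRUE, quantify_isa = TRUE, fit = TRUE,
                  decompose = TRUE, effects = TRUE, gradient = TRUE,
                  scale_of_effect = TRUE),
    simulate = list(n_individuals = c(120, 320), V_i = c(1, 2), V_r = 1,
                    V_y = 0.1, V_o = 0.1, intercept = 10,
                    n_urban_locations = 8),
    observations_csv = NULL,
    raster = list(width_px = 260, height_px = 200, pattern = "blocks",
                  p = 0.5, resolution_m = 10),
    nest_boxes_csv = NULL,
    mcmc = list(n_iter = 1500, burn_in = 500, thin = 2),
    gradient = list(scales = c(100, 250, 1000), min_obs = 30,
                    responses = c("CV_P", "CV_I"),
                    n_iterations_used = 200, draws_per_iteration = 20,
                    with_and_without_forest = TRUE)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a pipeline run configuration
#'
#' @param path JSON file of overrides, or `NULL` for the bundled demo
#'   defaults (a small synthetic end-to-end run).
#' @return Config list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, jsonlite::read_json(path, simplifyVector = TRUE))
  }
  cfg
}

manifest_add <- function(manifest, stage, files, seed) {
  for (f in files)
    manifest[[length(manifest) + 1L]] <- list(
      stage = stage, file = basename(f),
      md5 = unname(tools::md5sum(f)), seed = seed)
  manifest
}

#' Run the full pipeline
#'
#' Executes the enabled stages end to end on synthetic (or user-supplied)
#' data and writes every artifact plus a provenance manifest into
#' `config$out_dir`.  Deterministic for a fixed config and master seed.
#'
#' @param config list from [load_run_config()] (or a path to a JSON config).
#' @param quiet suppress stage messages.
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config = NULL, quiet = FALSE) {
  if (is.character(config)) config <- load_run_config(config)
  if (is.null(config)) config <- default_run_config()
  cfg <- merge_config(default_run_config(), config)
  seed <- as.integer(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  manifest <- list()
  out <- function(f) file.path(cfg$out_dir, f)

  # --- stage: landscape ------------------------------------------------------
  site_tabs <- NULL
  if (isTRUE(cfg$stages$quantify_isa)) {
    say("stage quantify-isa (seed ", seed, ")")
    r <- cfg$raster
    raster <- generate_synthetic_isa_raster(r$width_px, r$height_px,
                                            resolution_m = r$resolution_m,
                                            pattern = r$pattern, p = r$p,
                                            seed = substream_seed(seed, "raster"))
    boxes <- if (!is.null(cfg$nest_boxes_csv)) read_nest_boxes(cfg$nest_boxes_csv)
             else synthetic_nest_boxes(raster, cfg$simulate$n_urban_locations,
                                       seed = substream_seed(seed, "boxes"))
    site_tabs <- lapply(cfg$gradient$scales, function(sc)
      site_isa_summary(raster, boxes, sc))
    site_df <- do.call(rbind, site_tabs)
    utils::write.csv(site_df, out("site_isa.csv"), row.names = FALSE)
    manifest <- manifest_add(manifest, "quantify-isa", out("site_isa.csv"), seed)
  }

  # --- stage: data -----------------------------------------------------------
  if (!is.null(cfg$observations_csv)) {
    table <- read_observations(cfg$observations_csv, cfg$family)
  } else if (isTRUE(cfg$stages$simulate)) {
    say("stage simulate")
    s <- cfg$simulate
    spec <- variance_spec(family = cfg$family,
                          V_i = s$V_i, V_r = s$V_r, V_y = s$V_y, V_o = s$V_o,
                          intercept = s$intercept,
                          n_individuals = s$n_individuals,
                          locations_per_group = c(1, s$n_urban_locations))
    table <- simulate_observations(spec, seed = substream_seed(seed, "sim"))
    write_observations(table, out("observations.csv"))
    manifest <- manifest_add(manifest, "simulate", out("observations.csv"), seed)
  } else stop("no data: provide observations_csv or enable the simulate stage")

  fit_a <- fit_b <- NULL
  if (isTRUE(cfg$stages$fit)) {
    say("stage fit: habitat model (model a)")
    m <- cfg$mcmc
    cfg_a <- model_config(cfg$family, "by_habitat", n_iter = m$n_iter,
                          burn_in = m$burn_in, thin = m$thin,
                          seed = substream_seed(seed, "fit_a"))
    fit_a <- fit_hetvar(table, cfg_a)
    say("stage fit: location model (model b)")
    cfg_b <- model_config(cfg$family, "by_location", n_iter = m$n_iter,
                          burn_in = m$burn_in, thin = m$thin,
                          seed = substream_seed(seed, "fit_b"))
    fit_b <- fit_hetvar(table, cfg_b)
    for (nm in c("fit_a", "fit_b")) {
      ft <- get(nm)
      utils::write.csv(as.data.frame(ft$draws), out(paste0(nm, "_draws.csv")),
                       row.names = FALSE)
      conv <- convergence_check(ft$draws,
                                ess_min = min(1000, nrow(ft$draws) / 2))
      jsonlite::write_json(conv, out(paste0(nm, "_convergence.json")),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
      manifest <- manifest_add(manifest, "fit",
                               c(out(paste0(nm, "_draws.csv")),
                                 out(paste0(nm, "_convergence.json"))), seed)
    }
  }

  cvs_a <- cvs_b <- NULL
  if (isTRUE(cfg$stages$decompose) && !is.null(fit_a)) {
    say("stage decompose")
    cvs_a <- decompose_variance(fit_a, table)
    cvs_b <- decompose_variance(fit_b, table)
    utils::write.csv(summarize_components(cvs_a),
                     out("components_habitat.csv"), row.names = FALSE)
    utils::write.csv(summarize_components(cvs_b),
                     out("components_location.csv"), row.names = FALSE)
    manifest <- manifest_add(manifest, "decompose",
                             c(out("components_habitat.csv"),
                               out("components_location.csv")), seed)
  }

  if (isTRUE(cfg$stages$effects) && !is.null(cvs_a)) {
    say("stage effects")
    eff <- effect_sizes(cvs_a)
    jsonlite::write_json(effects_report(eff), out("effect_sizes.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = 10)
    manifest <- manifest_add(manifest, "effects", out("effect_sizes.json"), seed)
  }

  if (isTRUE(cfg$stages$gradient) && !is.null(cvs_b) && !is.null(site_tabs)) {
    say("stage gradient")
    counts <- table(table$location_id)
    kept <- tryCatch(filter_locations(c(counts), cfg$gradient$min_obs),
                     error = function(e) stop("gradient: ", conditionMessage(e)))
    g <- cfg$gradient
    r2_rows <- list(); fits <- list()
    for (resp in g$responses) {
      cvm <- t(cvs_b[[resp]])                       # locations x draws
      cvm <- cvm[intersect(rownames(cvm), kept), , drop = FALSE]
      for (si in seq_along(g$scales)) {
        st <- site_tabs[[si]]
        mi <- stats::setNames(st$mean_isa, st$location_id)
        vi <- stats::setNames(st$var_isa, st$location_id)
        locs_use <- intersect(rownames(cvm), st$location_id)
        fit_g <- per_iteration_regression(
          cvm[locs_use, , drop = FALSE], mi, vi,
          n_iterations_used = min(g$n_iterations_used, ncol(cvm)),
          draws_per_iteration = g$draws_per_iteration,
          scale_m = g$scales[si], response = resp, with_forest = TRUE,
          seed = substream_seed(seed, paste0("grad_", resp, "_", si)))
        fits[[paste(resp, g$scales[si], sep = "_")]] <- fit_g
        r2_rows[[length(r2_rows) + 1L]] <- data.frame(
          response = resp, scale_m = g$scales[si], r2 = fit_g$r2_mean,
          with_forest = TRUE)
        if (isTRUE(g$with_and_without_forest)) {
          urb <- grep("forest", locs_use, invert = TRUE, value = TRUE)
          if (length(urb) >= 4L) {
            fit_u <- per_iteration_regression(
              cvm[urb, , drop = FALSE], mi, vi,
              n_iterations_used = min(g$n_iterations_used, ncol(cvm)),
              draws_per_iteration = g$draws_per_iteration,
              scale_m = g$scales[si], response = resp, with_forest = FALSE,
              seed = substream_seed(seed, paste0("gradu_", resp, "_", si)))
            r2_rows[[length(r2_rows) + 1L]] <- data.frame(
              response = resp, scale_m = g$scales[si], r2 = fit_u$r2_mean,
              with_forest = FALSE)
          }
        }
      }
    }
    r2_tab <- do.call(rbind, r2_rows)
    utils::write.csv(r2_tab, out("r2_by_scale.csv"), row.names = FALSE)
    grad_sum <- lapply(fits, function(f) list(
      response = f$response, scale_m = f$scale_m,
      beta_meanISA = unclass(f$summaries$beta_meanISA)[
        c("median", "ci_low", "ci_high", "p_positive", "evidence")],
      beta_varISA = unclass(f$summaries$beta_varISA)[
        c("median", "ci_low", "ci_high", "p_positive", "evidence")],
      r2_mean = f$r2_mean,
      included_locations = f$included_locations))
    jsonlite::write_json(grad_sum, out("gradient_fits.json"),
                         auto_unbox = TRUE, digits = 10)
    manifest <- manifest_add(manifest, "gradient",
                             c(out("r2_by_scale.csv"),
                               out("gradient_fits.json")), seed)

    if (isTRUE(cfg$stages$scale_of_effect)) {
      say("stage scale-of-effect")
      soe <- lapply(split(r2_tab[r2_tab$with_forest, ],
                          r2_tab$response[r2_tab$with_forest]),
                    function(d) scale_of_effect(
                      stats::setNames(d$r2, d$scale_m)))
      jsonlite::write_json(soe, out("scale_of_effect.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest <- manifest_add(manifest, "scale-of-effect",
                               out("scale_of_effect.json"), seed)
    }
  } else if (isTRUE(cfg$stages$gradient)) {
    say("stage gradient skipped (needs fit + decompose + quantify-isa)")
  }

  jsonlite::write_json(list(trait = cfg$trait, family = cfg$family,
                            seed = seed, outputs = manifest),
                       out("manifest.json"), auto_unbox = TRUE, digits = NA)
  say("done: ", cfg$out_dir)
  invisible(cfg$out_dir)
}

# nest boxes laid out on the synthetic raster: one forest location in the
# low-ISA west edge convention is not assumed -- boxes are placed uniformly
# at random within the raster extent, grouped into 1 forest + n urban
# locations to mirror the study design shape.
synthetic_nest_boxes <- function(raster, n_urban_locations = 8,
                                 boxes_per_location = 12, seed = 1L) {
  local_rng(seed)
  res <- raster$resolution_m
  W <- ncol(raster$values) * res; H <- nrow(raster$values) * res
  locs <- c("forest_1", paste0("urban_", seq_len(n_urban_locations)))
  rows <- lapply(seq_along(locs), function(i) {
    cx <- stats::runif(1, 0.15 * W, 0.85 * W)
    cy <- stats::runif(1, 0.15 * H, 0.85 * H)
    data.frame(
      box_id = paste0(locs[i], "_box", seq_len(boxes_per_location)),
      location_id = locs[i],
      x_m = raster$origin[1] + pmin(pmax(
        cx + stats::rnorm(boxes_per_location, 0, 0.05 * W), res), W - res),
      y_m = raster$origin[2] + pmin(pmax(
        cy + stats::rnorm(boxes_per_location, 0, 0.05 * H), res), H - res),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `quantify-isa`, `fit`, `decompose`, `effects`,
#' `gradient`, `scale-of-effect`, `run-all`.  Each runs the pipeline with
#' the matching stages enabled; `--config <file.json>` supplies overrides,
#' `--seed` and `--out` override the config.  Invoke from a shell via the
#' script installed at `system.file("cli", "urbanvar", package = "urbanvar")`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Invisibly, the output directory.
#' @export
urbanvar_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: urbanvar <simulate|quantify-isa|fit|decompose|effects|",
         "gradient|scale-of-effect|run-all> [--config f.json] ",
         "[--seed n] [--out dir]", call. = FALSE)
  cmd <- args[1]; rest <- args[-1]
  opt <- list()
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!startsWith(rest[i], "--") || i == length(rest))
      stop("malformed option: ", rest[i])
    opt[[key]] <- rest[i + 1L]; i <- i + 2L
  }
  cfg <- load_run_config(opt$config)
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  if (!is.null(opt$out)) cfg$out_dir <- opt$out
  stage_sets <- list(
    "simulate" = "simulate",
    "quantify-isa" = "quantify_isa",
    "fit" = c("simulate", "fit"),
    "decompose" = c("simulate", "fit", "decompose"),
    "effects" = c("simulate", "fit", "decompose", "effects"),
    "gradient" = c("simulate", "quantify_isa", "fit", "decompose", "gradient"),
    "scale-of-effect" = c("simulate", "quantify_isa", "fit", "decompose",
                          "gradient", "scale_of_effect"),
    "run-all" = names(default_run_config()$stages))
  if (!cmd %in% names(stage_sets)) stop("unknown subcommand: ", cmd)
  for (s in names(cfg$stages)) cfg$stages[[s]] <- s %in% stage_sets[[cmd]]
  run_pipeline(cfg)
}
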