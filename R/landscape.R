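# Impervious-surface (ISA) quantification around nest boxes.
#
# Rasters are planar (projected, meters), stored row-major with row 1 the TOP
# row (as in Esri ASCII grids); `origin` is the (x, y) of the LOWER-LEFT corner
# of the grid.  Pixel (r, c) has its center at
#   x = origin_x + (c - 0.5) * res,  y = origin_y + (nrow - r + 0.5) * res.

#' Construct an impervious-surface raster
#'
#' @param values numeric matrix of imperviousness in `[0, 1]`; row 1 is the
#'   northernmost (top) row.
#' @param resolution_m pixel edge length in meters (default 10, matching
#'   typical imperviousness-density products).
#' @param origin numeric length-2, planar (x, y) of the grid's lower-left
#'   corner in meters.
#' @return An object of class `isa_raster`.
#' @export
isa_raster <- function(values, resolution_m = 10, origin = c(0, 0)) {
  values <- as.matrix(values)
  if (length(values) == 0L) stop("raster grid must be non-empty")
  if (!is.numeric(values)) stop("raster values must be numeric")
  if (anyNA(values) || any(values < 0 | values > 1))
    stop("raster values must lie in [0, 1]")
  if (!is.numeric(resolution_m) || length(resolution_m) != 1L || resolution_m <= 0)
    stop("resolution_m must be a single positive number")
  if (length(origin) != 2L || !is.numeric(origin))
    stop("origin must be numeric (x, y)")
  structure(
    list(values = values, resolution_m = as.numeric(resolution_m),
         origin = as.numeric(origin)),
    class = "isa_raster"
  )
}

#' @export
print.isa_raster <- function(x, ...) {
  cat(sprintf("<isa_raster> %d x %d pixels @ %g m, origin (%g, %g), mean %.3f\n",
              nrow(x$values), ncol(x$values), x$resolution_m,
              x$origin[1], x$origin[2], mean(x$values)))
  invisible(x)
}

#' Generate a synthetic imperviousness raster
#'
#' Stand-in for real imperviousness-density products when exercising the
#' pipeline on simulated data.  Patterns:
#' \describe{
#'   \item{uniform_p}{each cell is Bernoulli(p) (binary) or constant p
#'     (`fractional = TRUE`).}
#'   \item{blocks}{rectangular blocks of side `block_px` pixels, each block
#'     all-sealed with probability `p` (emulates building footprints).}
#'   \item{gradient}{sealing probability ramps linearly 0 to 1 left to right.}
#' }
#'
#' @param width_px,height_px grid dimensions in pixels (>= 1).
#' @param resolution_m pixel size in meters.
#' @param pattern one of `"uniform_p"`, `"blocks"`, `"gradient"`.
#' @param p sealing probability (uniform_p, blocks).
#' @param block_px block edge length in pixels (blocks pattern).
#' @param fractional if `TRUE`, cells carry continuous densities instead of
#'   the default binary 0/1 values.
#' @param origin lower-left corner (x, y) in meters.
#' @param seed integer seed; identical seeds give identical rasters.
#' @return An [isa_raster].
#' @export
generate_synthetic_isa_raster <- function(width_px, height_px,
                                          resolution_m = 10,
                                          pattern = c("uniform_p", "blocks", "gradient"),
                                          p = 0.5, block_px = 5,
                                          fractional = FALSE,
                                          origin = c(0, 0), seed = 1L) {
  pattern <- match.arg(pattern)
  if (width_px < 1 || height_px < 1) stop("raster dimensions must be >= 1")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  rng <- local_rng(seed)
  m <- switch(pattern,
    uniform_p = {
      if (fractional) matrix(p, height_px, width_px)
      else matrix(as.numeric(rng$runif(width_px * height_px) < p),
                  height_px, width_px)
    },
    blocks = {
      nbr <- ceiling(height_px / block_px)
      nbc <- ceiling(width_px / block_px)
      bv <- if (fractional) rng$runif(nbr * nbc)
            else as.numeric(rng$runif(nbr * nbc) < p)
      bm <- matrix(bv, nbr, nbc)
      ri <- ceiling(seq_len(height_px) / block_px)
      ci <- ceiling(seq_len(width_px) / block_px)
      bm[ri, ci, drop = FALSE]
    },
    gradient = {
      px <- (seq_len(width_px) - 0.5) / width_px
      if (fractional) matrix(px, height_px, width_px, byrow = TRUE)
      else matrix(as.numeric(rng$runif(width_px * height_px) <
                               rep(px, each = height_px)),
                  height_px, width_px)
    })
  isa_raster(m, resolution_m = resolution_m, origin = origin)
}

# planar centers of every pixel, in raster storage order
pixel_centers <- function(raster) {
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  res <- raster$resolution_m
  cx <- raster$origin[1] + (seq_len(nc) - 0.5) * res
  cy <- raster$origin[2] + (nr - seq_len(nr) + 0.5) * res
  list(x = matrix(cx, nr, nc, byrow = TRUE),
       y = matrix(cy, nr, nc))
}

#' ISA proportion inside a circular buffer
#'
#' Averages raster values over all pixels whose CENTERS lie within Euclidean
#' distance `radius_m` (inclusive) of `point`.  For a binary raster this is
#' the proportion of sealed pixels in the buffer.
#'
#' @param raster an [isa_raster].
#' @param point numeric (x, y) in meters.
#' @param radius_m buffer radius in meters (> 0).
#' @return Proportion in `[0, 1]`.
#' @export
isa_proportion_in_buffer <- function(raster, point, radius_m) {
  stopifnot(inherits(raster, "isa_raster"))
  if (!is.numeric(point) || length(point) != 2L) stop("point must be (x, y)")
  if (radius_m <= 0) stop("radius_m must be > 0")
  ctr <- pixel_centers(raster)
  d2 <- (ctr$x - point[1])^2 + (ctr$y - point[2])^2
  inside <- d2 <= radius_m^2
  n <- sum(inside)
  if (n == 0L)
    stop(sprintf("empty buffer: no pixel center within %g m of (%g, %g)",
                 radius_m, point[1], point[2]))
  sum(raster$values[inside]) / n
}

point_in_extent <- function(raster, x, y) {
  res <- raster$resolution_m
  xmax <- raster$origin[1] + ncol(raster$values) * res
  ymax <- raster$origin[2] + nrow(raster$values) * res
  x >= raster$origin[1] & x <= xmax & y >= raster$origin[2] & y <= ymax
}

#' Per-location summary of ISA around nest boxes
#'
#' Computes, for each sampling location, the mean and the within-site variance
#' (denominator n - 1; 0 for a single box) of the per-box ISA proportions at
#' one buffer radius.
#'
#' @param raster an [isa_raster].
#' @param boxes data.frame with columns `box_id`, `location_id`, `x_m`, `y_m`.
#' @param radius_m buffer radius in meters.
#' @return data.frame with columns `location_id`, `scale_m`, `mean_isa`,
#'   `var_isa`, `n_boxes`.
#' @export
site_isa_summary <- function(raster, boxes, radius_m) {
  req <- c("box_id", "location_id", "x_m", "y_m")
  miss <- setdiff(req, names(boxes))
  if (length(miss)) stop("nest-box table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(boxes) == 0L) stop("nest-box table is empty")
  out_ext <- !point_in_extent(raster, boxes$x_m, boxes$y_m)
  if (any(out_ext))
    stop("nest box outside raster extent: ",
         paste(boxes$box_id[out_ext], collapse = ", "))
  prop <- vapply(seq_len(nrow(boxes)), function(i)
    isa_proportion_in_buffer(raster, c(boxes$x_m[i], boxes$y_m[i]), radius_m),
    numeric(1))
  locs <- unique(as.character(boxes$location_id))
  res <- lapply(locs, function(L) {
    p <- prop[as.character(boxes$location_id) == L]
    data.frame(location_id = L, scale_m = radius_m,
               mean_isa = mean(p),
               var_isa = if (length(p) > 1L) stats::var(p) else 0,
               n_boxes = length(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Classify a location as forest or urban
#'
#' A location is forest when its mean ISA proportion within the 1000 m buffer
#' is strictly below 5%; otherwise (including exactly 5%) urban.
#'
#' @param mean_isa_at_1000m proportion in `[0, 1]`.
#' @return `"forest"` or `"urban"` (vectorized).
#' @export
classify_habitat <- function(mean_isa_at_1000m) {
  if (!is.numeric(mean_isa_at_1000m) || anyNA(mean_isa_at_1000m) ||
      any(mean_isa_at_1000m < 0 | mean_isa_at_1000m > 1))
    stop("mean ISA must lie in [0, 1]")
  ifelse(mean_isa_at_1000m < 0.05, "forest", "urban")
}

#' Read / write rasters as Esri ASCII grids
#'
#' Plain-text single-band raster interchange.  Only square cells are
#' supported; `NODATA_value` cells are rejected (imperviousness grids used
#' here are complete).
#'
#' @param path file path.
#' @return For the reader, an [isa_raster].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2L && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2]); i <- i + 1L
    } else break
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]])) stop("ASCII grid header missing ", k)
  if (!is.null(hdr$xllcenter) || !is.null(hdr$yllcenter))
    stop("xllcenter/yllcenter headers not supported; use corner registration")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid value count does not match header dimensions")
  if (!is.null(hdr$nodata_value) && any(vals == hdr$nodata_value))
    stop("NODATA cells are not supported")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  isa_raster(m, resolution_m = hdr$cellsize,
             origin = c(hdr$xllcorner %||% 0, hdr$yllcorner %||% 0))
}

#' @rdname read_ascii_grid
#' @param raster an [isa_raster] to write.
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "isa_raster"))
  hdr <- c(sprintf("ncols %d", ncol(raster$values)),
           sprintf("nrows %d", nrow(raster$values)),
           sprintf("xllcorner %.10g", raster$origin[1]),
           sprintf("yllcorner %.10g", raster$origin[2]),
           sprintf("cellsize %.10g", raster$resolution_m))
  body <- apply(raster$values, 1, function(r) paste(format(r, trim = TRUE),
                                                    collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a nest-box table
#'
#' @param path CSV with columns `box_id`, `location_id`, `x_m`, `y_m`.
#' @return data.frame.
#' @export
read_nest_boxes <- function(path) {
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("box_id", "location_id", "x_m", "y_m"), names(b))
  if (length(miss)) stop("nest-box CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  b
}

`%||%` <- function(a, b) if (is.null(a)) b else a
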