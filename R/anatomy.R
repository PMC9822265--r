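# Volumetric puncta-density profiles and laminar fluorescence-intensity
# profiles. Coordinates are um, 0-based, with the mediolateral origin at the
# parasubiculum border (x), laminar depth from the pia (y) and slice depth
# (z). All bins and boxes are half-open [a, b).

#' Define slice geometry for puncta analyses
#'
#' @param layer_widths_um named numeric vector of laminar slab widths, um, in
#'   order from the pia (must cover L1, L2, L3, L5a, L5b for the layer
#'   profile).
#' @param ml_extent_um mediolateral span from the parasubiculum border, um.
#' @param z_depth_um imaged depth, um.
#' @return an object of class `slice_geometry` with slab boundaries.
#' @export
slice_geometry <- function(layer_widths_um = c(L1 = 100, L2 = 150, L3 = 250,
                                               L5a = 150, L5b = 200),
                           ml_extent_um = 900, z_depth_um = 400) {
  if (any(layer_widths_um <= 0)) stop("slab widths must be > 0")
  y1 <- cumsum(layer_widths_um)
  layers <- data.frame(layer = names(layer_widths_um),
                       y0 = c(0, head(y1, -1)), y1 = y1,
                       stringsAsFactors = FALSE)
  structure(list(layers = layers, ml_extent_um = ml_extent_um,
                 z_depth_um = z_depth_um),
            class = "slice_geometry")
}

#' Volumetric puncta density in a box
#'
#' Count of puncta inside the half-open axis-aligned box divided by its volume
#' in cubic millimetres.
#'
#' @param puncta data frame with `x_um`, `y_um`, `z_um` columns.
#' @param roi numeric `c(x0, x1, y0, y1, z0, z1)`, um.
#' @return density, mm^-3.
#' @export
puncta_density <- function(puncta, roi) {
  stopifnot(length(roi) == 6)
  vol_um3 <- (roi[2] - roi[1]) * (roi[4] - roi[3]) * (roi[6] - roi[5])
  if (vol_um3 <= 0) stop("argument error: zero-volume roi")
  n <- if (!nrow(puncta)) 0L else sum(
    puncta$x_um >= roi[1] & puncta$x_um < roi[2] &
      puncta$y_um >= roi[3] & puncta$y_um < roi[4] &
      puncta$z_um >= roi[5] & puncta$z_um < roi[6])
  n / (vol_um3 / 1e9)
}

#' Per-layer puncta density from 150 um-wide extracts
#'
#' For each laminar slab, a rectangular extract of the given width (centred
#' mediolaterally unless `extract_x0` is supplied) spanning the slab and the
#' full imaged depth is taken, and the volumetric density computed within it.
#'
#' @param puncta puncta table (`x_um`, `y_um`, `z_um`).
#' @param geometry a [slice_geometry()] defining all five layers.
#' @param extract_width_um extract width, um.
#' @param extract_x0 left edge of the extract, um; default centres it.
#' @return data frame `layer`, `density_mm3`.
#' @export
layer_density_profile <- function(puncta, geometry, extract_width_um = 150,
                                  extract_x0 = NULL) {
  need <- c("L1", "L2", "L3", "L5a", "L5b")
  miss <- setdiff(need, geometry$layers$layer)
  if (length(miss))
    stop("argument error: geometry missing layer ",
         paste(miss, collapse = ", "))
  if (is.null(extract_x0))
    extract_x0 <- (geometry$ml_extent_um - extract_width_um) / 2
  dens <- vapply(seq_len(nrow(geometry$layers)), function(i) {
    ly <- geometry$layers[i, ]
    puncta_density(puncta, c(extract_x0, extract_x0 + extract_width_um,
                             ly$y0, ly$y1, 0, geometry$z_depth_um))
  }, 0)
  data.frame(layer = geometry$layers$layer, density_mm3 = dens,
             stringsAsFactors = FALSE)
}

#' Mediolateral puncta-density profile in layer 1
#'
#' Six sequential 150 um-wide bins starting at the parasubiculum border:
#' `[0,150), [150,300), ..., [750,900)` um.
#'
#' @param puncta puncta table.
#' @param geometry a [slice_geometry()] spanning at least 900 um
#'   mediolaterally.
#' @param layer layer whose slab is profiled (default `"L1"`).
#' @param bin_width_um,n_bins binning parameters.
#' @return data frame `bin_start_um`, `density_mm3`.
#' @export
mediolateral_profile <- function(puncta, geometry, layer = "L1",
                                 bin_width_um = 150, n_bins = 6) {
  if (geometry$ml_extent_um < bin_width_um * n_bins)
    stop("argument error: geometry spans less than ",
         bin_width_um * n_bins, " um mediolaterally")
  ly <- geometry$layers[geometry$layers$layer == layer, ]
  if (!nrow(ly)) stop("argument error: layer ", layer, " not in geometry")
  starts <- (seq_len(n_bins) - 1L) * bin_width_um
  dens <- vapply(starts, function(x0)
    puncta_density(puncta, c(x0, x0 + bin_width_um, ly$y0, ly$y1,
                             0, geometry$z_depth_um)), 0)
  data.frame(bin_start_um = starts, density_mm3 = dens)
}

#' Baseline-subtracted mean intensity
#'
#' Mean gray value of a region minus the mean of a baseline region of the same
#' size; may be negative and is reported as-is.
#'
#' @param region,baseline_region numeric vectors of gray values (same length).
#' @return baseline-subtracted mean, gray.
#' @export
roi_mean_intensity <- function(region, baseline_region) {
  if (!length(region) || !length(baseline_region))
    stop("argument error: empty region")
  if (length(region) != length(baseline_region))
    stop("argument error: regions must be the same size")
  mean(region) - mean(baseline_region)
}

#' Min-max normalise an intensity profile
#'
#' `(x - min) / (max - min)`; invariant under positive affine transforms of
#' the input, with minimum exactly 0 and maximum exactly 1.
#'
#' @param raw numeric vector, length >= 2.
#' @return normalised vector in `[0, 1]`.
#' @export
normalize_profile <- function(raw) {
  if (length(raw) < 2L) stop("argument error: need at least 2 values")
  rng <- range(raw)
  if (rng[1] == rng[2])
    stop("degenerate-profile error: constant input (max = min)")
  (raw - rng[1]) / (rng[2] - rng[1])
}

# ---- generators (synthetic anatomy) ---------------------------------------

#' Generate a synthetic puncta field
#'
#' Homogeneous Poisson point process within each layer-slab x mediolateral-bin
#' cell, with per-layer intensity rates optionally modulated by a
#' mediolateral gradient. Emulates terminal-labelling fields that peak in
#' layer 1 and near the medial border.
#'
#' @param geometry a [slice_geometry()].
#' @param rates_mm3 named per-layer intensity, mm^-3 (>= 0).
#' @param ml_gradient multiplicative profile over mediolateral bins (recycled
#'   per layer); length defines the number of bins.
#' @param seed integer seed.
#' @param intensity_range gray-value range for simulated puncta intensities.
#' @return list with `puncta` (data frame `x_um`, `y_um`, `z_um`,
#'   `intensity`) and `ground_truth` (per cell expected rates).
#' @export
generate_puncta <- function(geometry, rates_mm3, ml_gradient = rep(1, 6),
                            seed = 1L, intensity_range = c(80, 255)) {
  if (any(rates_mm3 < 0)) stop("argument error: negative rate")
  set.seed(seed %% .Machine$integer.max)
  n_bins <- length(ml_gradient)
  bw <- geometry$ml_extent_um / n_bins
  rows <- list(); gt <- list()
  for (i in seq_len(nrow(geometry$layers))) {
    ly <- geometry$layers[i, ]
    rate <- rates_mm3[[ly$layer]]
    for (b in seq_len(n_bins)) {
      lambda_eff <- rate * ml_gradient[b]
      vol_mm3 <- bw * (ly$y1 - ly$y0) * geometry$z_depth_um / 1e9
      n <- rpois(1, lambda_eff * vol_mm3)
      gt[[length(gt) + 1L]] <- data.frame(
        layer = ly$layer, bin_start_um = (b - 1) * bw,
        rate_mm3 = lambda_eff, volume_mm3 = vol_mm3, n = n)
      if (n > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          x_um = runif(n, (b - 1) * bw, b * bw),
          y_um = runif(n, ly$y0, ly$y1),
          z_um = runif(n, 0, geometry$z_depth_um),
          intensity = runif(n, intensity_range[1], intensity_range[2]))
    }
  }
  puncta <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x_um = numeric(), y_um = numeric(), z_um = numeric(),
               intensity = numeric())
  list(puncta = puncta, ground_truth = do.call(rbind, gt))
}

#' Generate a synthetic laminar intensity profile
#'
#' A Gaussian bump over a flat baseline with additive Gaussian noise, clipped
#' to the 8-bit gray range; emulates normalised fluorescence profiles sampled
#' across layers.
#'
#' @param peak_pos_um bump centre, um.
#' @param width_um bump standard deviation, um.
#' @param baseline,amplitude gray values (amplitude >= 0).
#' @param noise_sd gray value noise sd.
#' @param n_points samples along the axis (>= 3).
#' @param extent_um profile span, um.
#' @param seed integer seed.
#' @return list with `profile` (data frame `position_um`, `raw`) and
#'   `ground_truth` (peak location, width, baseline, amplitude).
#' @export
generate_intensity_profile <- function(peak_pos_um, width_um, baseline = 40,
                                       amplitude = 120, noise_sd = 0,
                                       n_points = 200, extent_um = 850,
                                       seed = 1L) {
  if (n_points < 3) stop("argument error: n_points < 3")
  if (amplitude < 0) stop("argument error: amplitude must be >= 0")
  set.seed(seed %% .Machine$integer.max)
  pos <- seq(0, extent_um, length.out = n_points)
  raw <- baseline + amplitude * exp(-(pos - peak_pos_um)^2 / (2 * width_um^2))
  if (noise_sd > 0) raw <- raw + rnorm(n_points, 0, noise_sd)
  raw <- pmin(pmax(raw, 0), 255)
  list(profile = data.frame(position_um = pos, raw = raw),
       ground_truth = list(peak_pos_um = peak_pos_um, width_um = width_um,
                           baseline = baseline, amplitude = amplitude))
}
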