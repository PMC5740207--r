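#' Configuration of the synthetic left-ventricle phantom
#'
#' The phantom is a stack of short-axis slices, each a concentric annulus:
#' blood pool inside the endocardial radius, myocardium between the
#' endocardial and epicardial radii, background outside. Scar is inserted as
#' angular wedges growing from the endocardium outward to a transmurality
#' fraction of the wall, mirroring the subendocardial-to-transmural pattern
#' of ischaemic scar. Post-gadolinium T1 defaults place scar well below
#' remote myocardium (scar retains more gadolinium, hence shorter T1).
#'
#' Angles are measured counterclockwise from the ray pointing at the
#' reference point, which sits below the inferior wall; pixel coordinates
#' are 1-based (row, col) matrix indices.
#'
#' @param image_size pixels per axis (square images).
#' @param pixel_spacing in-plane pixel size, mm.
#' @param slice_thickness mm.
#' @param n_slices number of short-axis slices; the default 5 is 2 basal,
#'   2 mid, 1 apical.
#' @param slice_levels character vector of levels, recycled/truncated to
#'   `n_slices`.
#' @param t1_myocardium,t1_scar,t1_blood,t1_background post-gadolinium T1
#'   defaults in ms (literature-informed; scar < myocardium always required).
#' @param r_endo_mm,r_epi_mm endocardial/epicardial radii, mm.
#' @param scar_specs list of [scar_spec()] wedges.
#' @param noise_sd image-noise SD in signal units, consumed by the
#'   simulation stages (the T1 maps themselves are exact ground truth).
#' @param density myocardial density, g/ml.
#' @param seed integer seed for all phantom randomness.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 128L, pixel_spacing = 1.65,
                           slice_thickness = 8, n_slices = 5L,
                           slice_levels = c("basal", "basal", "mid", "mid", "apical"),
                           t1_myocardium = 500, t1_scar = 300,
                           t1_blood = 350, t1_background = 1000,
                           r_endo_mm = 15, r_epi_mm = 25,
                           scar_specs = list(), noise_sd = 0.02,
                           density = 1.05, seed = 1L) {
  n_slices <- as.integer(n_slices)
  slice_levels <- rep_len(slice_levels, n_slices)
  if (!all(slice_levels %in% c("basal", "mid", "apical"))) {
    abort("slice_levels must be 'basal', 'mid' or 'apical'.")
  }
  if (any(c(t1_myocardium, t1_scar, t1_blood, t1_background) <= 0)) {
    abort("all T1 values must be strictly positive.")
  }
  if (t1_scar >= t1_myocardium) {
    abort("t1_scar must be shorter than t1_myocardium (post-gadolinium scar).")
  }
  stopifnot(r_endo_mm > 0, r_epi_mm > r_endo_mm, image_size > 0,
            pixel_spacing > 0, slice_thickness > 0, noise_sd >= 0, density > 0)
  for (s in scar_specs) {
    if (!inherits(s, "scar_spec")) abort("scar_specs must be a list of scar_spec().")
    if (s$slice < 1 || s$slice > n_slices) {
      abort(sprintf("scar spec references slice %d but the phantom has %d slices.",
                    s$slice, n_slices))
    }
  }
  structure(
    list(image_size = as.integer(image_size), pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness, n_slices = n_slices,
         slice_levels = slice_levels, t1_myocardium = t1_myocardium,
         t1_scar = t1_scar, t1_blood = t1_blood, t1_background = t1_background,
         r_endo_mm = r_endo_mm, r_epi_mm = r_epi_mm, scar_specs = scar_specs,
         noise_sd = noise_sd, density = density, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' @rdname phantom_config
#' @param slice 1-based slice index the wedge belongs to.
#' @param start_deg wedge start angle, degrees counterclockwise from the
#'   reference direction (inferior).
#' @param span_deg angular width of the wedge, degrees.
#' @param transmurality fraction of the wall thickness covered, measured
#'   from the endocardium; in (0, 1].
#' @export
scar_spec <- function(slice, start_deg, span_deg, transmurality) {
  stopifnot(span_deg > 0, span_deg <= 360,
            transmurality > 0, transmurality <= 1)
  structure(list(slice = as.integer(slice), start_deg = start_deg,
                 span_deg = span_deg, transmurality = transmurality),
            class = "scar_spec")
}

# polar coordinates of every pixel center relative to the LV axis:
# radius in pixels and angle (radians, in [0, 2pi)) counterclockwise from
# the reference direction (+row, i.e. inferior)
pixel_polar <- function(image_size) {
  c0 <- (image_size + 1) / 2
  row <- matrix(seq_len(image_size), image_size, image_size)
  col <- t(row)
  dy <- row - c0
  dx <- col - c0
  list(radius = sqrt(dx^2 + dy^2),
       theta = (atan2(dx, dy) + 2 * pi) %% (2 * pi),
       center = c0)
}

in_angular_span <- function(theta, start_deg, span_deg) {
  a0 <- (start_deg %% 360) * pi / 180
  sp <- span_deg * pi / 180
  rel <- (theta - a0) %% (2 * pi)
  rel < sp
}

circle_contour <- function(center, radius_px, n = 360) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(row = center + radius_px * cos(th), col = center + radius_px * sin(th))
}

#' Generate a synthetic short-axis left-ventricle phantom
#'
#' Builds `n_slices` T1 maps with scar wedges inserted per the
#' configuration, together with the exact ground truth: per-slice scar
#' masks, scar mass in grams (pixel count x pixel area x thickness x
#' density), AHA subsegment label images (6 sectors on basal/mid slices, 4
#' on the apical slice, numbered consecutively across slices), endo- and
#' epicardial contours and the reference point.
#'
#' @param config a [phantom_config()].
#' @return a list with components `t1_maps` (list of [t1_map]) and
#'   `ground_truth` (class `lv_ground_truth`): fields `scar_mask`,
#'   `subsegment_labels` (lists of matrices), `scar_mass_g` (per slice),
#'   `endo_contour`, `epi_contour`, `reference_point`, `geometry` (list of
#'   [lv_geometry()] per slice), `annulus` (list of logical matrices).
#' @export
make_lv_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$image_size
  pol <- pixel_polar(n)
  r_endo <- config$r_endo_mm / config$pixel_spacing
  r_epi <- config$r_epi_mm / config$pixel_spacing
  blood <- pol$radius < r_endo
  annulus <- pol$radius >= r_endo & pol$radius <= r_epi

  endo <- circle_contour(pol$center, r_endo)
  epi <- circle_contour(pol$center, r_epi)
  ref_pt <- c(row = pol$center + r_epi + 5, col = pol$center)

  t1_maps <- vector("list", config$n_slices)
  scar_masks <- vector("list", config$n_slices)
  labels <- vector("list", config$n_slices)
  geoms <- vector("list", config$n_slices)
  mass <- numeric(config$n_slices)
  label_offset <- 0L

  for (k in seq_len(config$n_slices)) {
    level <- config$slice_levels[k]
    vals <- matrix(config$t1_background, n, n)
    vals[blood] <- config$t1_blood
    vals[annulus] <- config$t1_myocardium

    scar <- matrix(FALSE, n, n)
    for (s in config$scar_specs) {
      if (s$slice != k) next
      wedge <- annulus &
        in_angular_span(pol$theta, s$start_deg, s$span_deg) &
        pol$radius <= r_endo + s$transmurality * (r_epi - r_endo)
      scar <- scar | wedge
    }
    vals[scar] <- config$t1_scar
    mass[k] <- mass_from_pixels(sum(scar), config$pixel_spacing,
                                config$slice_thickness, config$density)

    n_seg <- if (level == "apical") 4L else 6L
    sector <- pmin(floor(pol$theta / (2 * pi / n_seg)) + 1L, n_seg)
    lab <- matrix(0L, n, n)
    lab[annulus] <- sector[annulus] + label_offset
    label_offset <- label_offset + n_seg

    t1_maps[[k]] <- t1_map(vals, pixel_spacing = config$pixel_spacing,
                           slice_thickness = config$slice_thickness,
                           slice_level = level)
    scar_masks[[k]] <- scar
    labels[[k]] <- lab
    geoms[[k]] <- lv_geometry(endo, epi, ref_pt, slice_level = level,
                              pixel_spacing = config$pixel_spacing,
                              slice_thickness = config$slice_thickness,
                              image_dim = c(n, n))
  }

  gt <- structure(
    list(scar_mask = scar_masks, scar_mass_g = mass,
         subsegment_labels = labels, endo_contour = endo, epi_contour = epi,
         reference_point = ref_pt, geometry = geoms,
         annulus = rep(list(annulus), config$n_slices),
         config = config),
    class = "lv_ground_truth"
  )
  list(t1_maps = t1_maps, ground_truth = gt)
}

#' @export
print.lv_ground_truth <- function(x, ...) {
  cat(sprintf("<lv_ground_truth> %d slices, scar mass %s g (total %.3f g)\n",
              length(x$scar_mask),
              paste(sprintf("%.2f", x$scar_mass_g), collapse = "/"),
              sum(x$scar_mass_g)))
  invisible(x)
}

#' Simulate a MOLLI acquisition from a T1 map
#'
#' Samples the signed inversion-recovery curve S(t) = A - B exp(-t/T1*) at
#' the scheme's effective inversion times at every pixel, adds zero-mean
#' Gaussian noise to the signed signal, then takes the magnitude (a
#' Rician-like noise model). Ground-truth curve parameters are A = 1 and
#' B = A (1 + inversion_efficiency); the apparent T1* follows the
#' Look-Locker relation T1* = T1 A / (B - A), so that ideal inversion
#' (efficiency 1) gives T1* = T1.
#'
#' @param t1map a [t1_map]; every pixel must have positive (or `NA`) T1.
#' @param scheme a [sampling_scheme()].
#' @param noise_sd Gaussian noise SD in signal units (equilibrium signal is 1).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param inversion_efficiency 1 for ideal inversion (B = 2A).
#' @return an object of class `molli_series`: 3-D array `images`
#'   (row, col, image) of magnitudes, sorted `tis` (ms), the provenance
#'   tibble `ti_table` from [effective_tis()], and the map's geometry.
#' @export
simulate_molli <- function(t1map, scheme = sampling_scheme(), noise_sd = 0,
                           seed = NULL, inversion_efficiency = 1) {
  stopifnot(inherits(t1map, "t1_map"), inherits(scheme, "sampling_scheme"),
            noise_sd >= 0, inversion_efficiency > 0)
  v <- t1map$values
  bad <- which(!is.na(v) & v <= 0)
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(v))
    abort(sprintf("non-positive T1 at pixel (%d, %d).", rc[1], rc[2]))
  }
  tt <- effective_tis(scheme)
  tis <- tt$ti
  A <- 1
  B <- A * (1 + inversion_efficiency)
  t1_star <- v * A / (B - A)

  images <- array(NA_real_, c(dim(v), length(tis)))
  with_seed(seed, {
    for (i in seq_along(tis)) {
      s <- ir_model(tis[i], A, B, t1_star)
      if (noise_sd > 0) s <- s + rnorm(length(s), 0, noise_sd)
      m <- abs(s)
      m[is.na(v)] <- NA_real_
      images[, , i] <- m
    }
  })
  structure(
    list(images = images, tis = tis, ti_table = tt, scheme = scheme,
         noise_sd = noise_sd,
         pixel_spacing = t1map$pixel_spacing,
         slice_thickness = t1map$slice_thickness,
         slice_level = t1map$slice_level),
    class = "molli_series"
  )
}

#' @export
print.molli_series <- function(x, ...) {
  cat(sprintf("<molli_series> %d magnitude images, %d x %d px, TIs %s ms\n",
              length(x$tis), dim(x$images)[1], dim(x$images)[2],
              paste(round(x$tis), collapse = ", ")))
  invisible(x)
}
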