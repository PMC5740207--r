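#' Left-ventricle slice geometry
#'
#' Manual-style geometry for one short-axis slice: closed endo- and
#' epicardial contours, plus the reference point placed outside and below
#' the inferior wall, from which the AHA segment angles are measured.
#'
#' @param endo_contour,epi_contour two-column matrices (columns `row`,
#'   `col`, 1-based pixel coordinates) tracing closed polygons; the
#'   endocardial contour must lie strictly inside the epicardial one.
#' @param reference_point length-2 numeric `c(row, col)`, outside the
#'   epicardial contour.
#' @param slice_level `"basal"`, `"mid"` or `"apical"`.
#' @param pixel_spacing mm per pixel.
#' @param slice_thickness mm.
#' @param image_dim `c(nrow, ncol)` of the images this geometry refers to.
#' @return an object of class `lv_geometry`.
#' @export
lv_geometry <- function(endo_contour, epi_contour, reference_point,
                        slice_level = c("mid", "basal", "apical"),
                        pixel_spacing = 1.65, slice_thickness = 8,
                        image_dim) {
  slice_level <- match.arg(slice_level)
  endo_contour <- as.matrix(endo_contour)
  epi_contour <- as.matrix(epi_contour)
  stopifnot(ncol(endo_contour) == 2, ncol(epi_contour) == 2,
            length(reference_point) == 2, length(image_dim) == 2,
            pixel_spacing > 0, slice_thickness > 0)
  inside <- pracma::inpolygon(endo_contour[, 1], endo_contour[, 2],
                              epi_contour[, 1], epi_contour[, 2])
  if (!all(inside)) {
    abort("contours intersect: the endocardial contour must lie inside the epicardial contour.")
  }
  ref_in <- pracma::inpolygon(reference_point[1], reference_point[2],
                              epi_contour[, 1], epi_contour[, 2])
  if (ref_in) abort("the reference point must lie outside the epicardial contour.")
  structure(
    list(endo_contour = endo_contour, epi_contour = epi_contour,
         reference_point = as.numeric(reference_point),
         slice_level = slice_level, pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness, image_dim = as.integer(image_dim)),
    class = "lv_geometry"
  )
}

contour_mask <- function(contour, image_dim) {
  rows <- matrix(seq_len(image_dim[1]), image_dim[1], image_dim[2])
  cols <- t(matrix(seq_len(image_dim[2]), image_dim[2], image_dim[1]))
  m <- pracma::inpolygon(as.vector(rows), as.vector(cols),
                         contour[, 1], contour[, 2])
  matrix(m, image_dim[1], image_dim[2])
}

#' Myocardial annulus mask from an LV geometry
#'
#' @param geometry an [lv_geometry()].
#' @return logical matrix: pixels between the contours.
#' @export
annulus_mask <- function(geometry) {
  stopifnot(inherits(geometry, "lv_geometry"))
  contour_mask(geometry$epi_contour, geometry$image_dim) &
    !contour_mask(geometry$endo_contour, geometry$image_dim)
}

#' Divide the myocardium into AHA segments
#'
#' Labels the myocardial annulus by equal angular sectors: 6 sectors of 60
#' degrees on basal and mid-ventricular slices, 4 sectors of 90 degrees on
#' the apical slice. Segment 1 starts at the ray from the LV center through
#' the reference point (the inferior direction), numbering counterclockwise.
#'
#' @param geometry an [lv_geometry()].
#' @return an object of class `segment_map`: integer matrix `labels`
#'   (0 = non-myocardium), `n_segments`, and the annulus mask.
#' @export
build_segment_map <- function(geometry) {
  stopifnot(inherits(geometry, "lv_geometry"))
  ann <- annulus_mask(geometry)
  n_seg <- if (geometry$slice_level == "apical") 4L else 6L
  ctr <- c(mean(geometry$endo_contour[, 1]), mean(geometry$endo_contour[, 2]))
  ref_dir <- atan2(geometry$reference_point[2] - ctr[2],
                   geometry$reference_point[1] - ctr[1])
  d <- geometry$image_dim
  rows <- matrix(seq_len(d[1]), d[1], d[2])
  cols <- t(matrix(seq_len(d[2]), d[2], d[1]))
  theta <- (atan2(cols - ctr[2], rows - ctr[1]) - ref_dir + 4 * pi) %% (2 * pi)
  sector <- pmin(floor(theta / (2 * pi / n_seg)) + 1L, n_seg)
  labels <- matrix(0L, d[1], d[2])
  labels[ann] <- as.integer(sector[ann])
  structure(list(labels = labels, n_segments = n_seg, annulus = ann,
                 slice_level = geometry$slice_level),
            class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("<segment_map> %s slice, %d segments, %d annulus px\n",
              x$slice_level, x$n_segments, sum(x$annulus)))
  invisible(x)
}

#' Total subsegment count for a set of slice levels
#'
#' Basal and mid slices contribute 6 segments each, apical slices 4; the
#' standard 5-slice set (2 basal, 2 mid, 1 apical) gives 28 subsegments per
#' left ventricle.
#'
#' @param slice_levels character vector of `"basal"`, `"mid"`, `"apical"`.
#' @return integer count.
#' @examples
#' subsegment_count(c("basal", "basal", "mid", "mid", "apical"))  # 28
#' @export
subsegment_count <- function(slice_levels) {
  if (length(slice_levels) == 0) abort("`slice_levels` must be nonempty.")
  if (!all(slice_levels %in% c("basal", "mid", "apical"))) {
    abort("slice levels must be 'basal', 'mid' or 'apical'.")
  }
  sum(ifelse(slice_levels == "apical", 4L, 6L))
}

#' Reference-ROI statistics in normal myocardium
#'
#' Sample mean and SD (n - 1 denominator) of the signal inside a region of
#' interest drawn in normal myocardium. The ROI must contain at least
#' `min_pixels` pixels (100, following standard practice for the 5-SD rule).
#'
#' @param image numeric matrix.
#' @param roi_mask logical matrix selecting the ROI.
#' @param min_pixels minimum ROI size.
#' @return a list `(mean, sd, npixels)` of class `roi_stats`.
#' @export
reference_roi_stats <- function(image, roi_mask, min_pixels = 100L) {
  stopifnot(all(dim(image) == dim(roi_mask)))
  vals <- image[which(roi_mask)]
  if (length(vals) < min_pixels) {
    abort(sprintf("reference ROI has %d pixels; at least %d are required (%d short).",
                  length(vals), min_pixels, min_pixels - length(vals)))
  }
  structure(list(mean = mean(vals), sd = sd(vals), npixels = length(vals)),
            class = "roi_stats")
}

#' Automatic reference ROI in remote myocardium
#'
#' Emulates the reader's placement of a normal-myocardium ROI: segments are
#' ranked by mean signal intensity and accumulated, dimmest first, until at
#' least `min_pixels` pixels are collected. On a nulled-myocardium IR image
#' enhancement is bright, so the dimmest segments are remote myocardium.
#'
#' @param image numeric matrix.
#' @param segment_map a [build_segment_map()] result.
#' @param min_pixels minimum ROI size.
#' @return logical ROI mask.
#' @export
auto_reference_roi <- function(image, segment_map, min_pixels = 100L) {
  stopifnot(inherits(segment_map, "segment_map"))
  labs <- segment_map$labels
  seg_mean <- vapply(seq_len(segment_map$n_segments),
                     function(s) mean(image[labs == s]), numeric(1))
  roi <- matrix(FALSE, nrow(image), ncol(image))
  for (s in order(seg_mean)) {
    roi <- roi | (labs == s)
    if (sum(roi) >= min_pixels) break
  }
  roi
}

#' Threshold enhancement at n SD above normal myocardium
#'
#' The binary threshold rule: a myocardial pixel is called enhanced
#' (infarcted) when its signal is strictly greater than the reference-ROI
#' mean plus `n_sd` reference SDs. No morphological filtering is applied by
#' default; `min_island` optionally removes 4-connected islands smaller
#' than the given pixel count.
#'
#' @param image numeric matrix (the IR image used for quantification).
#' @param segment_map a [build_segment_map()] result for the slice.
#' @param roi_stats a [reference_roi_stats()] result.
#' @param n_sd threshold multiplier (5 for the standard rule).
#' @param pixel_spacing,slice_thickness,density geometry for mass.
#' @param min_island minimum connected-island size kept (0 = no filtering).
#' @return an object of class `scar_slice`: `threshold`, `scar_mask`,
#'   per-segment tibble `segments` (`segment`, `pixels`, `mass_g`), totals.
#' @export
segment_scar <- function(image, segment_map, roi_stats, n_sd = 5,
                         pixel_spacing = 1.65, slice_thickness = 8,
                         density = 1.05, min_island = 0L) {
  stopifnot(inherits(segment_map, "segment_map"),
            inherits(roi_stats, "roi_stats"),
            all(dim(image) == dim(segment_map$labels)))
  threshold <- roi_stats$mean + n_sd * roi_stats$sd
  mask <- segment_map$annulus & (image > threshold)
  if (min_island > 0) mask <- drop_small_islands(mask, min_island)
  seg_pixels <- vapply(seq_len(segment_map$n_segments),
                       function(s) sum(mask & segment_map$labels == s),
                       numeric(1))
  segments <- tibble(
    segment = seq_len(segment_map$n_segments),
    pixels = as.integer(seg_pixels),
    mass_g = mass_from_pixels(seg_pixels, pixel_spacing, slice_thickness, density)
  )
  structure(
    list(threshold = threshold, ref_roi_mean = roi_stats$mean,
         ref_roi_sd = roi_stats$sd, ref_roi_npixels = roi_stats$npixels,
         n_sd = n_sd, scar_mask = mask, segments = segments,
         scar_pixels = sum(mask),
         scar_mass_g = mass_from_pixels(sum(mask), pixel_spacing,
                                        slice_thickness, density),
         slice_level = segment_map$slice_level),
    class = "scar_slice"
  )
}

# remove 4-connected TRUE components smaller than min_px (flood fill)
drop_small_islands <- function(mask, min_px) {
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    cur <- cur + 1L
    stack <- start
    while (length(stack) > 0) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- cur
      rc <- arrayInd(p, d)
      nb <- rbind(rc + c(1L, 0L), rc - c(1L, 0L), rc + c(0L, 1L), rc - c(0L, 1L))
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2]
      nbi <- nb[ok, , drop = FALSE]
      idx <- (nbi[, 2] - 1L) * d[1] + nbi[, 1]
      stack <- c(stack, idx[mask[idx] & lab[idx] == 0L])
    }
  }
  if (cur == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = cur)
  keep <- which(sizes >= min_px)
  mask & matrix(lab %in% keep, d[1], d[2])
}

#' @export
print.scar_slice <- function(x, ...) {
  cat(sprintf("<scar_slice> %s, threshold %.4g (%g SD rule), %d scar px, %.3f g\n",
              x$slice_level, x$threshold, x$n_sd, x$scar_pixels, x$scar_mass_g))
  invisible(x)
}

#' Convert a pixel count to tissue mass
#'
#' mass (g) = npixels x pixel_spacing^2 (mm^2) x thickness (mm) x
#' density (g/ml) / 1000 (mm^3 per ml).
#'
#' @param npixels pixel count (vectorized).
#' @param pixel_spacing mm.
#' @param thickness mm.
#' @param density g/ml; 1.05 is the standard myocardial density.
#' @return grams.
#' @examples
#' mass_from_pixels(1000, 1.65, 8, 1.05)  # 22.87 g
#' @export
mass_from_pixels <- function(npixels, pixel_spacing = 1.65, thickness = 8,
                             density = 1.05) {
  stopifnot(pixel_spacing > 0, thickness > 0, density > 0, all(npixels >= 0))
  npixels * pixel_spacing^2 * thickness * density / 1000
}

#' Per-subsegment positivity calls for one slice
#'
#' A subsegment is called positive when it contains at least `min_pixels`
#' supra-threshold pixels (default 1).
#'
#' @param scar_slice a [segment_scar()] result.
#' @param min_pixels minimum pixel count for a positive call.
#' @return logical vector, one call per segment of the slice.
#' @export
call_subsegments <- function(scar_slice, min_pixels = 1L) {
  stopifnot(inherits(scar_slice, "scar_slice"), min_pixels >= 1)
  scar_slice$segments$pixels >= min_pixels
}

#' Quantify scar across a multi-slice study
#'
#' Convenience wrapper running ROI selection, thresholding and subsegment
#' calls for every slice of one examination. Subsegment ids are numbered
#' consecutively across slices (1..28 for the standard 5-slice set).
#'
#' @param images list of numeric matrices, one per slice.
#' @param geometries list of [lv_geometry()], same length.
#' @param n_sd threshold multiplier.
#' @param roi_masks optional list of logical ROI masks; when `NULL`,
#'   [auto_reference_roi()] picks remote myocardium per slice.
#' @param min_call_pixels minimum pixels for a positive subsegment call.
#' @param min_island island filter size (0 = off).
#' @param density g/ml.
#' @return an object of class `scar_quant`: tibble `subsegments`
#'   (`slice`, `slice_level`, `segment`, `subsegment_id`, `pixels`,
#'   `mass_g`, `call`), tibble `slices` (per-slice threshold, ROI stats,
#'   mass), `total_mass_g`, and the per-slice `scar_slice` objects.
#' @export
quantify_scar <- function(images, geometries, n_sd = 5, roi_masks = NULL,
                          min_call_pixels = 1L, min_island = 0L,
                          density = 1.05) {
  stopifnot(length(images) == length(geometries))
  sub_rows <- list()
  slice_rows <- list()
  slices <- list()
  offset <- 0L
  for (k in seq_along(images)) {
    g <- geometries[[k]]
    sm <- build_segment_map(g)
    roi <- if (is.null(roi_masks)) auto_reference_roi(images[[k]], sm)
           else roi_masks[[k]]
    rs <- reference_roi_stats(images[[k]], roi)
    sl <- segment_scar(images[[k]], sm, rs, n_sd = n_sd,
                       pixel_spacing = g$pixel_spacing,
                       slice_thickness = g$slice_thickness,
                       density = density, min_island = min_island)
    calls <- call_subsegments(sl, min_pixels = min_call_pixels)
    sub_rows[[k]] <- dplyr::mutate(sl$segments,
                                   slice = k, slice_level = g$slice_level,
                                   subsegment_id = .data$segment + offset,
                                   call = calls)
    slice_rows[[k]] <- tibble(slice = k, slice_level = g$slice_level,
                              threshold = sl$threshold,
                              ref_roi_mean = sl$ref_roi_mean,
                              ref_roi_sd = sl$ref_roi_sd,
                              ref_roi_npixels = sl$ref_roi_npixels,
                              scar_pixels = sl$scar_pixels,
                              scar_mass_g = sl$scar_mass_g)
    slices[[k]] <- sl
    offset <- offset + sm$n_segments
  }
  subsegments <- dplyr::select(dplyr::bind_rows(sub_rows),
                               "slice", "slice_level", "segment",
                               "subsegment_id", "pixels", "mass_g", "call")
  structure(
    list(subsegments = subsegments, slices = dplyr::bind_rows(slice_rows),
         total_mass_g = sum(subsegments$mass_g), n_sd = n_sd,
         slice_results = slices),
    class = "scar_quant"
  )
}

#' @export
print.scar_quant <- function(x, ...) {
  cat(sprintf("<scar_quant> %d slices, %d subsegments (%d positive), total %.3f g at %g SD\n",
              nrow(x$slices), nrow(x$subsegments), sum(x$subsegments$call),
              x$total_mass_g, x$n_sd))
  invisible(x)
}

#' @export
tidy.scar_quant <- function(x, ...) x$subsegments

#' @export
glance.scar_quant <- function(x, ...) {
  tibble(n_slices = nrow(x$slices), n_subsegments = nrow(x$subsegments),
         n_positive = sum(x$subsegments$call),
         total_mass_g = x$total_mass_g, n_sd = x$n_sd)
}
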