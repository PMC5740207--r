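#' Read and write T1 maps and image series
#'
#' T1 maps and IR series are stored as NIfTI (with pixel spacing and slice
#' thickness in the header's pixdim) alongside a JSON sidecar for the
#' inversion times of a series; plain delimited-text matrices are supported
#' as a secondary, inspection-friendly format.
#'
#' @param x a [t1_map].
#' @param path output file path (`.nii`/`.nii.gz` or `.txt`/`.tsv`).
#' @return `write_t1_map()` returns `path` invisibly; `read_t1_map()`
#'   returns a [t1_map].
#' @name t1_map_io
NULL

#' @rdname t1_map_io
#' @export
write_t1_map <- function(x, path) {
  stopifnot(inherits(x, "t1_map"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(x$values)
    RNifti::pixdim(img) <- c(x$pixel_spacing, x$pixel_spacing)
    RNifti::writeNifti(img, path)
    # slice thickness and level ride in a sidecar: a 2-D NIfTI has no z pixdim
    jsonlite::write_json(list(slice_thickness_mm = x$slice_thickness,
                              slice_level = x$slice_level),
                         sub("\\.nii(\\.gz)?$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(x$values, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' @rdname t1_map_io
#' @param pixel_spacing,slice_thickness,slice_level metadata used when
#'   reading text matrices (NIfTI carries spacing in its header).
#' @export
read_t1_map <- function(path, pixel_spacing = 1.65, slice_thickness = 8,
                        slice_level = "mid") {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      slice_thickness <- meta$slice_thickness_mm %||% slice_thickness
      slice_level <- meta$slice_level %||% slice_level
    }
    vals <- unclass(img)
    attributes(vals) <- list(dim = dim(vals))
    if (length(dim(vals)) == 3) vals <- vals[, , 1]
    t1_map(as.matrix(vals), pixel_spacing = pd[1],
           slice_thickness = slice_thickness, slice_level = slice_level)
  } else {
    vals <- as.matrix(utils::read.table(path, sep = "\t"))
    dimnames(vals) <- NULL
    t1_map(vals, pixel_spacing = pixel_spacing,
           slice_thickness = slice_thickness, slice_level = slice_level)
  }
}

#' Write an IR series as a NIfTI stack plus a TI sidecar
#'
#' @param series a `synthetic_ir_series` or `molli_series`.
#' @param path `.nii`/`.nii.gz` path; the TI sidecar is written next to it
#'   with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_ir_series <- function(series, path) {
  stopifnot(!is.null(series$images), !is.null(series$tis))
  img <- RNifti::asNifti(series$images)
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(tis_ms = series$tis,
                            mode = series$mode %||% "magnitude"),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an IR stack and its TI sidecar
#'
#' @param path `.nii`/`.nii.gz` path written by [write_ir_series()].
#' @return a list with `images` (3-D array), `tis`, `mode`.
#' @export
read_ir_series <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  list(images = unclass(img)[, , , drop = FALSE], tis = meta$tis_ms,
       mode = meta$mode)
}

#' Serialize phantom ground truth to JSON plus mask images
#'
#' Masses, contours and the reference point go into one JSON file; the
#' per-slice scar masks and subsegment label images are written as
#' delimited-text matrices next to it.
#'
#' @param gt an `lv_ground_truth` from [make_lv_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(gt, dir) {
  stopifnot(inherits(gt, "lv_ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(scar_mass_g = gt$scar_mass_g,
         reference_point = gt$reference_point,
         endo_contour = unname(as.data.frame(gt$endo_contour)),
         epi_contour = unname(as.data.frame(gt$epi_contour)),
         n_slices = length(gt$scar_mask)),
    file.path(dir, "ground_truth.json"), digits = NA
  )
  for (k in seq_along(gt$scar_mask)) {
    utils::write.table(gt$scar_mask[[k]] * 1L,
                       file.path(dir, sprintf("scar_mask_%02d.txt", k)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(gt$subsegment_labels[[k]],
                       file.path(dir, sprintf("subsegment_labels_%02d.txt", k)),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
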