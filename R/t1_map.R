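#' Per-pixel T1 map for one short-axis slice
#'
#' A matrix of longitudinal relaxation times (ms) plus the geometry metadata
#' needed to turn pixel counts into tissue mass: in-plane pixel spacing and
#' slice thickness.
#'
#' @param values numeric matrix of T1 values in ms (`NA` allowed for pixels
#'   outside the field of view or failed fits).
#' @param pixel_spacing in-plane pixel size (mm); the study protocol's
#'   reconstructed resolution, 1.65 mm, is the default.
#' @param slice_thickness slice thickness (mm).
#' @param slice_level one of `"basal"`, `"mid"`, `"apical"`.
#' @param quality optional logical matrix flagging converged fits.
#' @return an object of class `t1_map`.
#' @export
t1_map <- function(values, pixel_spacing = 1.65, slice_thickness = 8,
                   slice_level = c("mid", "basal", "apical"), quality = NULL) {
  slice_level <- match.arg(slice_level)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(values <= 0, na.rm = TRUE)) {
    abort("T1 values must be strictly positive (use NA outside the object).")
  }
  stopifnot(pixel_spacing > 0, slice_thickness > 0)
  structure(
    list(values = values, pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness, slice_level = slice_level,
         quality = quality),
    class = "t1_map"
  )
}

#' @export
print.t1_map <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<t1_map> %d x %d px, %.3g mm/px, %.3g mm thick, %s slice\n",
              nrow(x$values), ncol(x$values), x$pixel_spacing,
              x$slice_thickness, x$slice_level))
  cat(sprintf("  T1 range %.1f-%.1f ms, %d NA px\n", rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.t1_map <- function(x) dim(x$values)

#' Tidy a T1 map into a pixel-level tibble
#'
#' @param x a [t1_map].
#' @param ... unused.
#' @return a tibble with `row`, `col` (1-based pixel indices) and `t1` (ms).
#' @export
tidy.t1_map <- function(x, ...) {
  d <- dim(x$values)
  tibble(row = rep(seq_len(d[1]), times = d[2]),
         col = rep(seq_len(d[2]), each = d[1]),
         t1 = as.vector(x$values))
}

#' @export
autoplot.t1_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$t1)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "T1 (ms)", na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Post-contrast T1 map (%s slice)", object$slice_level)) +
    ggplot2::theme_minimal()
}
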