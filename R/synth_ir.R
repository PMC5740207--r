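#' Inversion-time grid for synthetic IR series
#'
#' The default grid reproduces the synthetic series used clinically: 40
#' images with 25-ms TI increments starting at 200 ms (TIs 200 ... 1175 ms).
#'
#' @param start first inversion time (ms).
#' @param increment TI increment between images (ms).
#' @param count number of images.
#' @return an object of class `ti_grid`.
#' @export
ti_grid <- function(start = 200, increment = 25, count = 40L) {
  stopifnot(start > 0, increment > 0, count >= 1)
  structure(list(start = start, increment = increment, count = as.integer(count)),
            class = "ti_grid")
}

#' @rdname ti_grid
#' @param grid a `ti_grid`.
#' @return `grid_tis()`: numeric vector of the grid's inversion times (ms).
#' @export
grid_tis <- function(grid) {
  stopifnot(inherits(grid, "ti_grid"))
  grid$start + (seq_len(grid$count) - 1) * grid$increment
}

#' @export
print.ti_grid <- function(x, ...) {
  tis <- grid_tis(x)
  cat(sprintf("<ti_grid> %d TIs: %g ... %g ms (step %g)\n",
              x$count, tis[1], tis[length(tis)], x$increment))
  invisible(x)
}

#' Ideal phase-sensitive inversion-recovery signal
#'
#' The full-recovery, ideal-inversion closed form S = 1 - 2 exp(-TI/T1) for
#' unit equilibrium magnetization. The signal is -1 at TI = 0, crosses zero
#' at the null point TI = T1 ln 2, and approaches 1 as TI grows; at a fixed
#' TI below both tissues' null points, shorter T1 gives the larger (less
#' negative) signal, which is why gadolinium-rich scar appears hyperintense.
#'
#' @param t1 longitudinal relaxation time(s), ms; strictly positive.
#' @param ti inversion time(s), ms; non-negative. Recycled against `t1`.
#' @return signed signal in \[-1, 1\].
#' @examples
#' ir_signal(500, 500 * log(2))  # 0 at the null point
#' @export
ir_signal <- function(t1, ti) {
  if (any(t1 <= 0, na.rm = TRUE)) abort("`t1` must be strictly positive.")
  if (any(ti < 0, na.rm = TRUE)) abort("`ti` must be non-negative.")
  1 - 2 * exp(-ti / t1)
}

#' Synthesize a phase-sensitive IR image series from a T1 map
#'
#' Applies [ir_signal()] pixel-wise at every inversion time of `grid`. With
#' `mode = "magnitude"` the absolute value is taken, emulating
#' magnitude-reconstructed IR images; the default signed mode matches PSIR
#' reconstruction.
#'
#' @param t1map a [t1_map].
#' @param grid a [ti_grid()]; the default yields the standard 40-image series.
#' @param mode `"signed"` (PSIR, default) or `"magnitude"`.
#' @return an object of class `synthetic_ir_series`: a 3-D array `images`
#'   (row, col, TI), the vector `tis`, `mode`, and the source map. Pixels
#'   with missing T1 are `NA` in every image (a warning reports how many).
#' @export
synthesize_series <- function(t1map, grid = ti_grid(),
                              mode = c("signed", "magnitude")) {
  stopifnot(inherits(t1map, "t1_map"), inherits(grid, "ti_grid"))
  mode <- match.arg(mode)
  tis <- grid_tis(grid)
  v <- t1map$values
  n_bad <- sum(is.na(v))
  if (n_bad > 0) {
    warn(sprintf("%d pixels have missing T1 and are masked out of the series.", n_bad))
  }
  images <- array(NA_real_, c(dim(v), length(tis)))
  for (i in seq_along(tis)) {
    s <- ir_signal(pmax(v, .Machine$double.eps), tis[i])
    s[is.na(v)] <- NA_real_
    images[, , i] <- if (mode == "magnitude") abs(s) else s
  }
  structure(
    list(images = images, tis = tis, mode = mode, source_t1map = t1map),
    class = "synthetic_ir_series"
  )
}

#' @export
print.synthetic_ir_series <- function(x, ...) {
  cat(sprintf("<synthetic_ir_series> %d %s images, %d x %d px, TI %g ... %g ms\n",
              length(x$tis), x$mode, dim(x$images)[1], dim(x$images)[2],
              x$tis[1], x$tis[length(x$tis)]))
  invisible(x)
}

#' Extract one image of an IR series at (or nearest to) a TI
#'
#' @param series a `synthetic_ir_series` or `molli_series`.
#' @param ti requested inversion time (ms); the nearest available TI is used.
#' @return a numeric matrix.
#' @export
series_image <- function(series, ti) {
  i <- which.min(abs(series$tis - ti))
  series$images[, , i]
}

#' Inversion time that nulls normal myocardium
#'
#' The signed IR signal of tissue with relaxation time T1 crosses zero at
#' TI = T1 ln 2; the display TI conventionally nulls remote myocardium so
#' that scar appears bright. Returns ln 2 times the mean T1 within the mask,
#' snapped to the nearest grid TI when a grid is supplied.
#'
#' @param t1map a [t1_map].
#' @param mask logical matrix selecting myocardial pixels; must be nonempty.
#' @param grid optional [ti_grid()] to snap to.
#' @return TI in ms.
#' @examples
#' m <- t1_map(matrix(500, 4, 4))
#' optimal_ti(m, matrix(TRUE, 4, 4))            # 500 * log(2) = 346.57
#' optimal_ti(m, matrix(TRUE, 4, 4), ti_grid()) # 350
#' @export
optimal_ti <- function(t1map, mask, grid = NULL) {
  stopifnot(inherits(t1map, "t1_map"))
  mask <- as.logical(mask)
  if (!any(mask, na.rm = TRUE)) abort("`mask` must contain at least one pixel.")
  ti <- log(2) * mean(t1map$values[mask], na.rm = TRUE)
  if (!is.null(grid)) {
    tis <- grid_tis(grid)
    ti <- tis[which.min(abs(tis - ti))]
  }
  ti
}

#' @export
autoplot.synthetic_ir_series <- function(object, tis = NULL, ...) {
  if (is.null(tis)) {
    tis <- object$tis[unique(round(seq(1, length(object$tis), length.out = 6)))]
  }
  dfs <- purrr::map(tis, function(t) {
    img <- series_image(object, t)
    d <- dim(img)
    tibble(row = rep(seq_len(d[1]), times = d[2]),
           col = rep(seq_len(d[2]), each = d[1]),
           signal = as.vector(img),
           ti = object$tis[which.min(abs(object$tis - t))])
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$signal)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~ti, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "black", mid = "grey40", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = "Synthetic IR series") +
    ggplot2::theme_minimal()
}
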