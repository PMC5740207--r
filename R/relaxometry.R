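#' MOLLI sampling scheme
#'
#' Describes a Modified Look-Locker Inversion recovery (MOLLI) acquisition as
#' a sequence of inversion blocks. The default `blocks` encode the 4(1)3(1)2
#' scheme: blocks of 4, 3 and 2 single-shot images, separated by 1-beat
#' recovery periods, giving 9 images in 11 heartbeats. Each block starts with
#' its own inversion pulse; the k-th block (k = 0, 1, 2, ...) uses inversion
#' delay `initial_ti + k * ti_increment`, and successive images within a
#' block are one heart period (`rr_interval`) apart.
#'
#' @param blocks list of length-2 integer vectors `c(images, recovery_beats)`;
#'   `recovery_beats` is the number of recovery heartbeats after the block.
#' @param initial_ti first inversion delay (ms).
#' @param ti_increment increment of the inversion delay between blocks (ms).
#' @param rr_interval heart period (ms); 857 ms is about 70 bpm.
#' @return an object of class `sampling_scheme`.
#' @examples
#' sch <- sampling_scheme()
#' n_images(sch)      # 9
#' n_heartbeats(sch)  # 11
#' @export
sampling_scheme <- function(blocks = list(c(4L, 1L), c(3L, 1L), c(2L, 0L)),
                            initial_ti = 100, ti_increment = 80,
                            rr_interval = 857) {
  if (length(blocks) == 0) {
    abort("`blocks` must contain at least one inversion block.")
  }
  blocks <- lapply(blocks, function(b) {
    b <- as.integer(b)
    if (length(b) == 1) b <- c(b, 0L)
    if (length(b) != 2 || b[1] < 1L || b[2] < 0L) {
      abort("each block must be c(images >= 1, recovery_beats >= 0)")
    }
    b
  })
  stopifnot(initial_ti > 0, ti_increment >= 0, rr_interval > 0)
  structure(
    list(blocks = blocks, initial_ti = initial_ti,
         ti_increment = ti_increment, rr_interval = rr_interval),
    class = "sampling_scheme"
  )
}

#' @rdname sampling_scheme
#' @param scheme a [sampling_scheme()].
#' @export
n_images <- function(scheme) sum(vapply(scheme$blocks, `[`, integer(1), 1L))

#' @rdname sampling_scheme
#' @export
n_heartbeats <- function(scheme) {
  sum(vapply(scheme$blocks, `[`, integer(1), 1L)) +
    sum(vapply(scheme$blocks, `[`, integer(1), 2L))
}

#' @export
print.sampling_scheme <- function(x, ...) {
  lab <- paste(vapply(x$blocks, function(b) {
    paste0(b[1], if (b[2] > 0) paste0("(", b[2], ")") else "")
  }, character(1)), collapse = "")
  cat("<sampling_scheme> ", lab, ": ", n_images(x), " images in ",
      n_heartbeats(x), " heartbeats\n", sep = "")
  cat("  initial TI ", x$initial_ti, " ms, increment ", x$ti_increment,
      " ms, RR ", x$rr_interval, " ms\n", sep = "")
  invisible(x)
}

#' Effective inversion times of a MOLLI scheme
#'
#' One inversion time per acquired image: the k-th block's images are read
#' out at `initial_ti + k * ti_increment + j * rr_interval` after that
#' block's inversion pulse (j = 0, 1, ... within the block).
#'
#' @param scheme a [sampling_scheme()].
#' @return a tibble with one row per image, sorted by ascending `ti` (ms),
#'   retaining `block` and `image_in_block` provenance (both 1-based).
#' @examples
#' effective_tis(sampling_scheme(rr_interval = 1000))$ti
#' @export
effective_tis <- function(scheme) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  rows <- purrr::imap(scheme$blocks, function(b, k) {
    delay <- scheme$initial_ti + (k - 1) * scheme$ti_increment
    tibble(
      ti = delay + (seq_len(b[1]) - 1) * scheme$rr_interval,
      block = k,
      image_in_block = seq_len(b[1])
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$ti)
}

ir_model <- function(ti, A, B, t1_star) A - B * exp(-ti / t1_star)

new_ir_fit <- function(A = NA_real_, B = NA_real_, t1_star = NA_real_,
                       residual_rms = NA_real_, converged = FALSE,
                       n = NA_integer_, n_flipped = NA_integer_) {
  t1 <- if (converged) t1_star * (B / A - 1) else NA_real_
  structure(
    list(A = A, B = B, t1_star = t1_star, t1 = t1,
         residual_rms = residual_rms, converged = converged,
         n = n, n_flipped = n_flipped),
    class = "ir_fit"
  )
}

#' Fit the three-parameter inversion-recovery model to MOLLI samples
#'
#' Fits S(t) = A - B exp(-t / T1*) to magnitude samples by
#' Levenberg-Marquardt least squares, with polarity restoration: the m
#' earliest samples are sign-flipped for m = 0, ..., n-1, the signed model is
#' fitted to each hypothesis, and the fit with the lowest residual sum of
#' squares is kept. The apparent T1* is then corrected with the Look-Locker
#' relation T1 = T1* (B/A - 1).
#'
#' Initial values are A = max|S|, B = 2A, T1* = median TI; T1* is bounded to
#' (1, 5000) ms. When the optimizer fails for every polarity hypothesis the
#' fit is returned with `converged = FALSE` rather than an error.
#'
#' @param samples a data frame with numeric columns `ti` (ms) and
#'   `magnitude` (signal units); at least 4 rows with distinct TIs.
#' @param t1_star_bounds length-2 bounds for T1* in ms.
#' @param control a [minpack.lm::nls.lm.control()] list.
#' @return an object of class `ir_fit` with fields `A`, `B`, `t1_star`,
#'   `t1`, `residual_rms`, `converged`. Use [tidy()] / [glance()] for tibbles.
#' @examples
#' sam <- data.frame(ti = c(100, 300, 600, 1200, 2400),
#'                   magnitude = abs(1 - 2 * exp(-c(100, 300, 600, 1200, 2400) / 400)))
#' fit_molli(sam)$t1  # 400
#' @export
fit_molli <- function(samples, t1_star_bounds = c(1, 5000),
                      control = minpack.lm::nls.lm.control(maxiter = 200,
                                                           ftol = 1e-13,
                                                           ptol = 1e-13)) {
  if (!is.data.frame(samples) || !all(c("ti", "magnitude") %in% names(samples))) {
    abort("`samples` must be a data frame with columns `ti` and `magnitude`.")
  }
  ti <- as.numeric(samples$ti)
  mag <- as.numeric(samples$magnitude)
  n <- length(ti)
  if (n < 4) abort("at least 4 samples are required for a 3-parameter fit.")
  if (anyDuplicated(ti)) abort("inversion times must be distinct.")
  if (diff(range(mag)) == 0) {
    return(new_ir_fit(n = n))
  }
  ord <- order(ti)
  ti_s <- ti[ord]
  mag_s <- mag[ord]

  A0 <- max(abs(mag_s))
  # T1* start ladder: the LM fit can hit a singular gradient from one start,
  # so fall through a few scales of the median TI until the optimizer runs
  t1_starts <- pmin(pmax(median(ti_s) * c(1, 0.5, 2, 0.25),
                         t1_star_bounds[1] * 1.01),
                    t1_star_bounds[2] * 0.99)
  lower <- c(A = -Inf, B = 0, t1_star = t1_star_bounds[1])
  upper <- c(A = Inf, B = Inf, t1_star = t1_star_bounds[2])

  best <- NULL
  best_ssr <- Inf
  best_m <- NA_integer_
  for (m in 0:(n - 1)) {
    s <- mag_s
    if (m > 0) s[seq_len(m)] <- -s[seq_len(m)]
    fit <- NULL
    for (t1s0 in t1_starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(s ~ A - B * exp(-ti_s / t1_star),
                          start = list(A = A0, B = 2 * A0, t1_star = t1s0),
                          lower = lower, upper = upper, control = control),
        error = function(e) NULL
      )
      if (!is.null(fit)) break
    }
    if (is.null(fit)) next
    ssr <- sum(resid(fit)^2)
    if (ssr < best_ssr) {
      best <- fit
      best_ssr <- ssr
      best_m <- m
    }
  }
  if (is.null(best)) {
    return(new_ir_fit(n = n))
  }
  cf <- coef(best)
  new_ir_fit(A = unname(cf["A"]), B = unname(cf["B"]),
             t1_star = unname(cf["t1_star"]),
             residual_rms = sqrt(best_ssr / n), converged = TRUE,
             n = n, n_flipped = best_m)
}

#' @export
print.ir_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<ir_fit> T1 = %.2f ms (T1* = %.2f, A = %.4g, B = %.4g, rms = %.3g)\n",
                x$t1, x$t1_star, x$A, x$B, x$residual_rms))
  } else {
    cat("<ir_fit> not converged\n")
  }
  invisible(x)
}

#' @export
tidy.ir_fit <- function(x, ...) {
  tibble(term = c("A", "B", "t1_star", "t1"),
         estimate = c(x$A, x$B, x$t1_star, x$t1))
}

#' @export
glance.ir_fit <- function(x, ...) {
  tibble(t1 = x$t1, t1_star = x$t1_star, residual_rms = x$residual_rms,
         converged = x$converged, nobs = x$n, n_flipped = x$n_flipped)
}

#' Fit a pixel-wise T1 map from a MOLLI series
#'
#' Runs [fit_molli()] at every pixel of a [molli_series] (optionally within a
#' mask) and assembles the Look-Locker-corrected T1 values into a [t1_map].
#' Pixels whose fit does not converge are flagged in the map's quality mask
#' and set to `NA`.
#'
#' @param series a `molli_series` (see [simulate_molli()]).
#' @param mask optional logical matrix; only `TRUE` pixels are fitted.
#' @param ... passed to [fit_molli()].
#' @return a [t1_map] with attribute field `quality` (logical matrix, `TRUE`
#'   where the fit converged among fitted pixels).
#' @export
fit_t1_map <- function(series, mask = NULL, ...) {
  stopifnot(inherits(series, "molli_series"))
  dims <- dim(series$images)
  if (length(dims) != 3) abort("series images must form a 3-D array (row, col, TI).")
  if (dims[3] != length(series$tis)) {
    abort("number of images does not match the number of inversion times.")
  }
  if (is.null(mask)) mask <- matrix(TRUE, dims[1], dims[2])
  if (!all(dim(mask) == dims[1:2])) abort("mask dimensions must match the images.")

  values <- matrix(NA_real_, dims[1], dims[2])
  quality <- matrix(NA, dims[1], dims[2])
  idx <- which(mask)
  tis <- series$tis
  for (p in idx) {
    rc <- arrayInd(p, dims[1:2])
    f <- fit_molli(data.frame(ti = tis, magnitude = series$images[rc[1], rc[2], ]), ...)
    quality[p] <- f$converged
    if (f$converged) values[p] <- f$t1
  }
  t1_map(values,
         pixel_spacing = series$pixel_spacing,
         slice_thickness = series$slice_thickness,
         slice_level = series$slice_level,
         quality = quality)
}
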