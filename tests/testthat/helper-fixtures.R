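# shared fixtures: small phantoms and ideal IR samples, built in code

small_phantom_config <- function(..., image_size = 64L, seed = 1L) {
  phantom_config(image_size = image_size, seed = seed, ...)
}

# ideal inversion-recovery magnitude samples at the scheme's TIs
ideal_molli_samples <- function(t1, A = 1, B = 2,
                                scheme = sampling_scheme(), noise_sd = 0) {
  ti <- effective_tis(scheme)$ti
  t1_star <- t1 * A / (B - A)
  s <- A - B * exp(-ti / t1_star)
  if (noise_sd > 0) s <- s + rnorm(length(s), 0, noise_sd)
  data.frame(ti = ti, magnitude = abs(s))
}

circle_contour_for_tests <- function(center, radius, n = 180) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(row = center + radius * cos(th), col = center + radius * sin(th))
}

noisy_esge_image_noiseless <- function(phantom, slice) {
  gt <- phantom$ground_truth
  remote <- gt$annulus[[slice]] & !gt$scar_mask[[slice]]
  ti <- optimal_ti(phantom$t1_maps[[slice]], remote, ti_grid())
  series_image(synthesize_series(phantom$t1_maps[[slice]], ti_grid()), ti)
}

# a nulled-myocardium IR image with additive Gaussian noise for one slice
noisy_esge_image <- function(phantom, slice, noise_sd) {
  gt <- phantom$ground_truth
  remote <- gt$annulus[[slice]] & !gt$scar_mask[[slice]]
  ti <- optimal_ti(phantom$t1_maps[[slice]], remote, ti_grid())
  img <- series_image(synthesize_series(phantom$t1_maps[[slice]], ti_grid()), ti)
  img + matrix(rnorm(length(img), 0, noise_sd), nrow(img))
}
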