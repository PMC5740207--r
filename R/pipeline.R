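#' Pipeline run configuration
#'
#' Bundles every stage's parameters. All randomness derives from the single
#' root `seed`, split deterministically per stage, so that re-running a
#' configuration is bit-identical. The configuration round-trips through
#' YAML via [read_run_config()] / [write_run_config()].
#'
#' @param phantom a [phantom_config()].
#' @param scheme a [sampling_scheme()].
#' @param grid a [ti_grid()].
#' @param n_sd scar threshold multiplier.
#' @param density myocardial density, g/ml.
#' @param cohort a [cohort_spec()] for the evaluate stage, or `NULL`.
#' @param molli_noise_sd noise SD for the MOLLI simulation.
#' @param image_noise_sd noise SD added to the quantification images.
#' @param seed root integer seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(
                         scar_specs = list(scar_spec(3, 20, 70, 0.6),
                                           scar_spec(4, 200, 50, 0.4))),
                       scheme = sampling_scheme(), grid = ti_grid(),
                       n_sd = 5, density = 1.05,
                       cohort = cohort_spec(), molli_noise_sd = 0.005,
                       image_noise_sd = 0.01, seed = 1L) {
  stopifnot(inherits(phantom, "phantom_config"),
            inherits(scheme, "sampling_scheme"), inherits(grid, "ti_grid"),
            n_sd > 0, density > 0, molli_noise_sd >= 0, image_noise_sd >= 0)
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_spec"))
  structure(
    list(phantom = phantom, scheme = scheme, grid = grid, n_sd = n_sd,
         density = density, cohort = cohort,
         molli_noise_sd = molli_noise_sd, image_noise_sd = image_noise_sd,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

config_to_list <- function(config) {
  ph <- config$phantom
  list(
    phantom = list(
      image_size = ph$image_size, pixel_spacing = ph$pixel_spacing,
      slice_thickness = ph$slice_thickness, n_slices = ph$n_slices,
      slice_levels = ph$slice_levels, t1_myocardium = ph$t1_myocardium,
      t1_scar = ph$t1_scar, t1_blood = ph$t1_blood,
      t1_background = ph$t1_background, r_endo_mm = ph$r_endo_mm,
      r_epi_mm = ph$r_epi_mm, noise_sd = ph$noise_sd, density = ph$density,
      seed = ph$seed,
      scar_specs = lapply(ph$scar_specs, function(s) {
        list(slice = s$slice, start_deg = s$start_deg,
             span_deg = s$span_deg, transmurality = s$transmurality)
      })
    ),
    scheme = list(blocks = lapply(config$scheme$blocks, as.integer),
                  initial_ti = config$scheme$initial_ti,
                  ti_increment = config$scheme$ti_increment,
                  rr_interval = config$scheme$rr_interval),
    grid = list(start = config$grid$start, increment = config$grid$increment,
                count = config$grid$count),
    n_sd = config$n_sd, density = config$density,
    cohort = if (is.null(config$cohort)) NULL else {
      sp <- config$cohort
      list(n_patients = sp$n_patients, n_positive = sp$n_positive,
           wedges_per_patient = sp$wedges_per_patient,
           span_deg_range = sp$span_deg_range,
           transmurality_range = sp$transmurality_range,
           reader_jitter_sd = sp$reader_jitter_sd,
           discordance = sp$discordance, fp_mass_g = sp$fp_mass_g,
           seed = sp$seed)
    },
    molli_noise_sd = config$molli_noise_sd,
    image_noise_sd = config$image_noise_sd,
    seed = config$seed
  )
}

config_from_list <- function(x) {
  ph <- x$phantom
  run_config(
    phantom = phantom_config(
      image_size = ph$image_size, pixel_spacing = ph$pixel_spacing,
      slice_thickness = ph$slice_thickness, n_slices = ph$n_slices,
      slice_levels = unlist(ph$slice_levels),
      t1_myocardium = ph$t1_myocardium, t1_scar = ph$t1_scar,
      t1_blood = ph$t1_blood, t1_background = ph$t1_background,
      r_endo_mm = ph$r_endo_mm, r_epi_mm = ph$r_epi_mm,
      noise_sd = ph$noise_sd, density = ph$density, seed = ph$seed,
      scar_specs = lapply(ph$scar_specs, function(s) {
        scar_spec(s$slice, s$start_deg, s$span_deg, s$transmurality)
      })
    ),
    scheme = sampling_scheme(blocks = x$scheme$blocks,
                             initial_ti = x$scheme$initial_ti,
                             ti_increment = x$scheme$ti_increment,
                             rr_interval = x$scheme$rr_interval),
    grid = ti_grid(x$grid$start, x$grid$increment, x$grid$count),
    n_sd = x$n_sd, density = x$density,
    cohort = if (is.null(x$cohort)) NULL else {
      cohort_spec(n_patients = x$cohort$n_patients,
                  n_positive = x$cohort$n_positive,
                  wedges_per_patient = unlist(x$cohort$wedges_per_patient),
                  span_deg_range = unlist(x$cohort$span_deg_range),
                  transmurality_range = unlist(x$cohort$transmurality_range),
                  reader_jitter_sd = x$cohort$reader_jitter_sd,
                  discordance = x$cohort$discordance,
                  fp_mass_g = x$cohort$fp_mass_g, seed = x$cohort$seed)
    },
    molli_noise_sd = x$molli_noise_sd, image_noise_sd = x$image_noise_sd,
    seed = x$seed
  )
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  config_from_list(yaml::read_yaml(path))
}

#' Run the full simulate-fit-synthesize-quantify-evaluate pipeline
#'
#' Mirrors the study's two-channel protocol on phantom data: the phantom's
#' true T1 maps stand in for the tissue; a MOLLI acquisition is simulated
#' and fitted to produce the measured T1 maps; synthetic PSIR images are
#' computed from the fitted maps (the synthetic early-enhancement channel)
#' and from the true maps (the conventional-LGE stand-in channel) at the TI
#' nulling remote myocardium; both channels are quantified with the n-SD
#' threshold rule; finally a cohort-level agreement study is run. Stage
#' outputs are written under `out_dir`; a stage whose output already exists
#' is skipped unless `overwrite = TRUE`, so an interrupted run resumes from
#' the last completed stage.
#'
#' @param config a [run_config()].
#' @param out_dir writable output directory.
#' @param overwrite rerun stages whose outputs exist.
#' @param fit_maps fit the measured T1 maps per pixel (the slow stage); when
#'   `FALSE` the true maps are used for both channels.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with `report` (the parsed `report.json`
#'   content), `study` (the [run_study()] result or `NULL`), and the paths
#'   written.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         overwrite = FALSE, fit_maps = TRUE, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  ph <- config$phantom

  # stage 1: phantom ---------------------------------------------------
  gt_dir <- file.path(out_dir, "ground_truth")
  phantom_done <- file.path(gt_dir, "ground_truth.json")
  obj <- make_lv_phantom(ph)
  if (overwrite || !file.exists(phantom_done)) {
    say("simulate: phantom with %d slices", ph$n_slices)
    write_ground_truth(obj$ground_truth, gt_dir)
    for (k in seq_along(obj$t1_maps)) {
      write_t1_map(obj$t1_maps[[k]],
                   file.path(out_dir, sprintf("t1_true_%02d.nii.gz", k)))
    }
  }

  # stage 2: MOLLI simulation + fit ------------------------------------
  fitted <- obj$t1_maps
  if (fit_maps) {
    for (k in seq_along(obj$t1_maps)) {
      fit_path <- file.path(out_dir, sprintf("t1_fit_%02d.nii.gz", k))
      if (!overwrite && file.exists(fit_path)) {
        fitted[[k]] <- read_t1_map(fit_path, slice_level = ph$slice_levels[k])
        next
      }
      say("fit: slice %d", k)
      series <- simulate_molli(obj$t1_maps[[k]], config$scheme,
                               noise_sd = config$molli_noise_sd,
                               seed = stage_seed(config$seed, paste0("molli", k)))
      mask <- obj$ground_truth$annulus[[k]] |
        contour_mask(obj$ground_truth$endo_contour, dim(obj$t1_maps[[k]]$values))
      fm <- fit_t1_map(series, mask = mask)
      # unfitted background pixels fall back to truth for display purposes
      fm$values[!mask] <- obj$t1_maps[[k]]$values[!mask]
      fitted[[k]] <- fm
      write_t1_map(fm, fit_path)
    }
  }

  # stage 3: synthesize + stage 4: quantify -----------------------------
  geoms <- obj$ground_truth$geometry
  esge_imgs <- vector("list", ph$n_slices)
  lge_imgs <- vector("list", ph$n_slices)
  for (k in seq_len(ph$n_slices)) {
    ann <- obj$ground_truth$annulus[[k]]
    remote <- ann & !obj$ground_truth$scar_mask[[k]]
    ti_esge <- optimal_ti(fitted[[k]], remote, config$grid)
    ti_lge <- optimal_ti(obj$t1_maps[[k]], remote, config$grid)
    s_esge <- synthesize_series(fitted[[k]], config$grid)
    s_lge <- synthesize_series(obj$t1_maps[[k]], config$grid)
    if (overwrite || !file.exists(file.path(out_dir, sprintf("esge_%02d.nii.gz", k)))) {
      write_ir_series(s_esge, file.path(out_dir, sprintf("esge_%02d.nii.gz", k)))
    }
    e_img <- series_image(s_esge, ti_esge)
    l_img <- series_image(s_lge, ti_lge)
    if (config$image_noise_sd > 0) {
      e_img <- e_img + with_seed(stage_seed(config$seed, paste0("esge_noise", k)),
                                 matrix(rnorm(length(e_img), 0, config$image_noise_sd),
                                        nrow(e_img)))
      l_img <- l_img + with_seed(stage_seed(config$seed, paste0("lge_noise", k)),
                                 matrix(rnorm(length(l_img), 0, config$image_noise_sd),
                                        nrow(l_img)))
    }
    esge_imgs[[k]] <- e_img
    lge_imgs[[k]] <- l_img
  }
  say("quantify: %g SD threshold", config$n_sd)
  q_esge <- quantify_scar(esge_imgs, geoms, n_sd = config$n_sd,
                          density = config$density)
  q_lge <- quantify_scar(lge_imgs, geoms, n_sd = config$n_sd,
                         density = config$density)

  # stage 5: evaluate ----------------------------------------------------
  study <- NULL
  if (!is.null(config$cohort)) {
    say("evaluate: cohort of %d patients", config$cohort$n_patients)
    cohort <- make_cohort(config$cohort, phantom = ph)
    study <- run_study(cohort)
  }

  report <- list(
    seed = config$seed,
    n_sd = config$n_sd,
    ground_truth_mass_g = obj$ground_truth$scar_mass_g,
    esge = list(total_mass_g = q_esge$total_mass_g,
                per_slice_mass_g = q_esge$slices$scar_mass_g,
                subsegment_calls = q_esge$subsegments$call),
    lge = list(total_mass_g = q_lge$total_mass_g,
               per_slice_mass_g = q_lge$slices$scar_mass_g,
               subsegment_calls = q_lge$subsegments$call),
    study = if (is.null(study)) NULL else list(
      patient = unclass(study$patient_table)[c("tp", "fp", "fn", "tn")],
      subsegment = unclass(study$subsegment_table)[c("tp", "fp", "fn", "tn")],
      prevalence_pct = study$prevalence_pct,
      n_quantitative = study$n_quantitative,
      pearson_r = if (is.null(study$paired)) NULL else study$paired$pearson_r,
      mean_difference_g = if (is.null(study$bland_altman)) NULL else
        study$bland_altman$mean_difference,
      sd_difference_g = if (is.null(study$bland_altman)) NULL else
        study$bland_altman$sd_difference,
      icc = if (is.null(study$icc)) NULL else study$icc$icc
    )
  )
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("report written to %s", report_path)
  invisible(list(report = report, study = study,
                 quant_esge = q_esge, quant_lge = q_lge,
                 report_path = report_path))
}
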