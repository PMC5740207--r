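#' Cohort specification for the synthetic agreement study
#'
#' Describes a cohort with the structure of the clinical study the analysis
#' emulates: 214 patients of whom 23 carry myocardial scar, each patient
#' contributing 28 subsegments (5 slices: 2 basal, 2 mid, 1 apical), and two
#' quantification channels — synthetic early enhancement (index) and
#' conventional LGE (reference) — whose per-patient masses are the phantom
#' ground truth perturbed by independent reader jitter.
#'
#' An optional `discordance` block plants the study's disagreement pattern:
#' one scar patient whose single positive subsegment the index channel
#' misses (false negative) and one scar-free patient in whom the index
#' channel calls `fp_subsegments` subsegments (false positive).
#'
#' @param n_patients cohort size.
#' @param n_positive number of scar-positive patients.
#' @param wedges_per_patient integer range; the number of scar wedges per
#'   positive patient is drawn uniformly from it (the study found 39
#'   enhancement areas in 23 patients, about 1.7 per patient).
#' @param span_deg_range,transmurality_range uniform ranges for wedge
#'   geometry (degrees; fraction of wall thickness).
#' @param reader_jitter_sd SD (grams) of the zero-mean Gaussian jitter added
#'   independently to each channel's per-patient mass.
#' @param discordance `NULL` for fully concordant channels, or a list
#'   `list(fn_subsegments = 1, fp_subsegments = 3)`.
#' @param fp_mass_g nominal mass reported by the index channel in the
#'   false-positive patient.
#' @param seed integer seed for all cohort randomness.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 214L, n_positive = 23L,
                        wedges_per_patient = c(1L, 3L),
                        span_deg_range = c(40, 80),
                        transmurality_range = c(0.3, 0.8),
                        reader_jitter_sd = 0.11,
                        discordance = NULL, fp_mass_g = 0.5,
                        seed = 1L) {
  n_patients <- as.integer(n_patients)
  n_positive <- as.integer(n_positive)
  if (n_positive > n_patients) {
    abort("`n_positive` cannot exceed `n_patients`.")
  }
  stopifnot(n_patients >= 1, n_positive >= 0, reader_jitter_sd >= 0,
            length(wedges_per_patient) == 2,
            wedges_per_patient[1] >= 1,
            wedges_per_patient[2] >= wedges_per_patient[1],
            all(transmurality_range > 0), all(transmurality_range <= 1))
  if (!is.null(discordance)) {
    discordance <- modifyList(list(fn_subsegments = 1L, fp_subsegments = 3L),
                              discordance)
    if (n_positive < 1 || n_patients - n_positive < 1) {
      abort("a discordance pattern needs at least one positive and one negative patient.")
    }
  }
  structure(
    list(n_patients = n_patients, n_positive = n_positive,
         wedges_per_patient = as.integer(wedges_per_patient),
         span_deg_range = span_deg_range,
         transmurality_range = transmurality_range,
         reader_jitter_sd = reader_jitter_sd,
         discordance = discordance, fp_mass_g = fp_mass_g,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort with two quantification channels
#'
#' Draws per-patient scar wedges on the shared phantom geometry, computes
#' exact per-subsegment scar pixel counts and masses from the wedge masks,
#' and derives the two channels: the reference (conventional LGE) channel
#' carries the ground-truth subsegment calls, the index (synthetic
#' enhancement) channel is identical except for the optional discordance
#' pattern; both channels' per-patient masses receive independent Gaussian
#' reader jitter. Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param phantom a [phantom_config()] defining the shared slice geometry
#'   (scar specs in it are ignored; the cohort draws its own).
#' @return an object of class `lv_cohort`: tibbles `patients`
#'   (`patient_id`, `scar_positive`, `n_wedges`, `truth_mass_g`,
#'   `esge_mass_g`, `lge_mass_g`) and `subsegments` (`patient_id`, `slice`,
#'   `slice_level`, `segment`, `subsegment_id`, `truth_mass_g`, `esge_call`,
#'   `lge_call`), plus `spec` and the per-patient wedge lists.
#' @export
make_cohort <- function(spec = cohort_spec(), phantom = phantom_config()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(phantom, "phantom_config"))
  base <- make_lv_phantom(
    phantom_config(image_size = phantom$image_size,
                   pixel_spacing = phantom$pixel_spacing,
                   slice_thickness = phantom$slice_thickness,
                   n_slices = phantom$n_slices,
                   slice_levels = phantom$slice_levels,
                   t1_myocardium = phantom$t1_myocardium,
                   t1_scar = phantom$t1_scar, t1_blood = phantom$t1_blood,
                   t1_background = phantom$t1_background,
                   r_endo_mm = phantom$r_endo_mm, r_epi_mm = phantom$r_epi_mm,
                   noise_sd = phantom$noise_sd, density = phantom$density,
                   seed = phantom$seed)
  )
  labels <- base$ground_truth$subsegment_labels
  n_slices <- phantom$n_slices
  n_sub <- subsegment_count(phantom$slice_levels)
  pol <- pixel_polar(phantom$image_size)
  r_endo <- phantom$r_endo_mm / phantom$pixel_spacing
  r_epi <- phantom$r_epi_mm / phantom$pixel_spacing
  annulus <- base$ground_truth$annulus[[1]]
  px_mass <- mass_from_pixels(1, phantom$pixel_spacing,
                              phantom$slice_thickness, phantom$density)

  sub_levels <- rep(phantom$slice_levels,
                    ifelse(phantom$slice_levels == "apical", 4L, 6L))
  sub_slice <- rep(seq_len(n_slices),
                   ifelse(phantom$slice_levels == "apical", 4L, 6L))
  sub_segment <- unlist(lapply(phantom$slice_levels, function(lv) {
    seq_len(if (lv == "apical") 4L else 6L)
  }))

  wedge_subseg_pixels <- function(wedges) {
    counts <- integer(n_sub)
    for (w in wedges) {
      mask <- annulus &
        in_angular_span(pol$theta, w$start_deg, w$span_deg) &
        pol$radius <= r_endo + w$transmurality * (r_epi - r_endo)
      ids <- labels[[w$slice]][mask]
      ids <- ids[ids > 0]
      counts <- counts + tabulate(ids, nbins = n_sub)
    }
    counts
  }

  out <- with_seed(spec$seed, {
    pos_ids <- seq_len(spec$n_positive)
    fn_patient <- NA_integer_
    fp_patient <- NA_integer_
    if (!is.null(spec$discordance)) {
      fn_patient <- 1L
      fp_patient <- spec$n_positive + 1L
    }

    patient_rows <- vector("list", spec$n_patients)
    subseg_rows <- vector("list", spec$n_patients)
    wedge_list <- vector("list", spec$n_patients)

    for (p in seq_len(spec$n_patients)) {
      positive <- p %in% pos_ids
      wedges <- list()
      if (positive) {
        if (!is.na(fn_patient) && p == fn_patient) {
          # single small wedge confined to one mid-ventricular subsegment
          wedges <- list(scar_spec(3L, start_deg = 15, span_deg = 28,
                                   transmurality = 0.45))
        } else {
          nw <- sample(spec$wedges_per_patient[1]:spec$wedges_per_patient[2], 1)
          wedges <- lapply(seq_len(nw), function(i) {
            scar_spec(sample.int(n_slices, 1),
                      start_deg = stats::runif(1, 0, 360),
                      span_deg = stats::runif(1, spec$span_deg_range[1],
                                              spec$span_deg_range[2]),
                      transmurality = stats::runif(1,
                                                   spec$transmurality_range[1],
                                                   spec$transmurality_range[2]))
          })
        }
      }
      wedge_list[[p]] <- wedges
      counts <- if (positive) wedge_subseg_pixels(wedges) else integer(n_sub)
      truth_calls <- counts > 0
      truth_mass <- sum(counts) * px_mass

      lge_call <- truth_calls
      esge_call <- truth_calls
      if (!is.na(fn_patient) && p == fn_patient) esge_call[] <- FALSE
      if (!is.na(fp_patient) && p == fp_patient) {
        esge_call[13:(12 + spec$discordance$fp_subsegments)] <- TRUE
      }

      esge_pos <- any(esge_call)
      lge_pos <- any(lge_call)
      esge_mass <- if (esge_pos) {
        base_mass <- if (positive) truth_mass else spec$fp_mass_g
        base_mass + rnorm(1, 0, spec$reader_jitter_sd)
      } else 0
      lge_mass <- if (lge_pos) truth_mass + rnorm(1, 0, spec$reader_jitter_sd) else 0

      patient_rows[[p]] <- tibble(
        patient_id = p, scar_positive = positive, n_wedges = length(wedges),
        truth_mass_g = truth_mass, esge_mass_g = esge_mass,
        lge_mass_g = lge_mass
      )
      subseg_rows[[p]] <- tibble(
        patient_id = p, slice = sub_slice, slice_level = sub_levels,
        segment = sub_segment, subsegment_id = seq_len(n_sub),
        truth_mass_g = counts * px_mass,
        esge_call = esge_call, lge_call = lge_call
      )
    }
    list(patients = dplyr::bind_rows(patient_rows),
         subsegments = dplyr::bind_rows(subseg_rows),
         wedges = wedge_list)
  })

  structure(
    list(patients = out$patients, subsegments = out$subsegments,
         wedges = out$wedges, spec = spec, phantom = phantom),
    class = "lv_cohort"
  )
}

#' @export
print.lv_cohort <- function(x, ...) {
  cat(sprintf("<lv_cohort> %d patients (%d scar-positive), %d subsegments\n",
              nrow(x$patients), sum(x$patients$scar_positive),
              nrow(x$subsegments)))
  if (!is.null(x$spec$discordance)) {
    cat(sprintf("  discordance pattern: 1 FN patient (%d subsegment), 1 FP patient (%d subsegments)\n",
                x$spec$discordance$fn_subsegments,
                x$spec$discordance$fp_subsegments))
  }
  invisible(x)
}

#' @export
tidy.lv_cohort <- function(x, ...) x$subsegments

#' @export
glance.lv_cohort <- function(x, ...) {
  tibble(n_patients = nrow(x$patients),
         n_positive = sum(x$patients$scar_positive),
         n_subsegments = nrow(x$subsegments),
         total_truth_mass_g = sum(x$patients$truth_mass_g),
         reader_jitter_sd = x$spec$reader_jitter_sd)
}
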