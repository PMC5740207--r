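small_cohort_phantom <- phantom_config(image_size = 64L)

test_that("the cohort has the specified positive/negative structure", {
  co <- make_cohort(cohort_spec(n_patients = 214, n_positive = 23, seed = 2),
                    phantom = small_cohort_phantom)
  expect_equal(nrow(co$patients), 214L)
  expect_equal(sum(co$patients$scar_positive), 23L)
  expect_equal(sum(!co$patients$scar_positive), 191L)
  expect_equal(nrow(co$subsegments), 214L * 28L)
  expect_true(all(co$patients$truth_mass_g[co$patients$scar_positive] > 0))
  expect_true(all(co$patients$truth_mass_g[!co$patients$scar_positive] == 0))
  # negatives contribute 191 x 28 reference-negative subsegments
  neg <- co$subsegments[!co$subsegments$patient_id %in%
                          which(co$patients$scar_positive), ]
  expect_equal(nrow(neg), 5348L)
  expect_true(all(!neg$lge_call))
})

test_that("cohort generation is deterministic for a fixed seed", {
  a <- make_cohort(cohort_spec(n_patients = 20, n_positive = 4, seed = 9),
                   phantom = small_cohort_phantom)
  b <- make_cohort(cohort_spec(n_patients = 20, n_positive = 4, seed = 9),
                   phantom = small_cohort_phantom)
  expect_identical(a$patients, b$patients)
  expect_identical(a$subsegments, b$subsegments)
})

test_that("zero jitter makes the two channels identical", {
  co <- make_cohort(cohort_spec(n_patients = 30, n_positive = 6,
                                reader_jitter_sd = 0, seed = 3),
                    phantom = small_cohort_phantom)
  expect_equal(co$patients$esge_mass_g, co$patients$lge_mass_g)
  expect_equal(co$subsegments$esge_call, co$subsegments$lge_call)
})

test_that("Bland-Altman SD of differences approaches jitter * sqrt(2)", {
  sds <- vapply(1:100, function(s) {
    co <- make_cohort(cohort_spec(n_patients = 21, n_positive = 21,
                                  reader_jitter_sd = 0.1, seed = 1000 + s),
                      phantom = small_cohort_phantom)
    bland_altman(co$patients$esge_mass_g, co$patients$lge_mass_g)$sd_difference
  }, numeric(1))
  # E[sd(d)] for d ~ N(0, 0.1^2 * 2); Monte-Carlo tolerance over 100 seeds
  expect_equal(mean(sds), 0.1 * sqrt(2), tolerance = 0.05)
})

test_that("the discordance pattern plants exactly one FN and one FP patient", {
  co <- make_cohort(cohort_spec(discordance = list(fp_subsegments = 3), seed = 4),
                    phantom = small_cohort_phantom)
  tab <- with(
    dplyr::summarise(dplyr::group_by(co$subsegments, patient_id),
                     esge = any(esge_call), lge = any(lge_call)),
    build_contingency(esge, lge, level = "patient")
  )
  expect_equal(tab$tp, 22L)
  expect_equal(tab$fn, 1L)
  expect_equal(tab$fp, 1L)
  expect_equal(tab$tn, 190L)
  # the FN patient's scar occupies exactly one subsegment
  fn_sub <- co$subsegments[co$subsegments$patient_id == 1, ]
  expect_equal(sum(fn_sub$lge_call), 1L)
  expect_equal(sum(fn_sub$esge_call), 0L)
  # the FP patient has 3 index-only subsegments
  fp_sub <- co$subsegments[co$subsegments$patient_id == 24, ]
  expect_equal(sum(fp_sub$esge_call), 3L)
  expect_equal(sum(fp_sub$lge_call), 0L)
})

test_that("run_study on a zero-jitter cohort is perfect everywhere", {
  co <- make_cohort(cohort_spec(n_patients = 40, n_positive = 8,
                                reader_jitter_sd = 0, seed = 6),
                    phantom = small_cohort_phantom)
  st <- run_study(co)
  expect_equal(st$patient_accuracy$estimate, rep(100, 4))
  expect_equal(st$subsegment_accuracy$estimate, rep(100, 4))
  expect_equal(st$paired$pearson_r, 1)
  expect_equal(st$bland_altman$mean_difference, 0)
  expect_equal(st$icc$icc, 1)
  expect_equal(st$n_quantitative, 8L)
})

test_that("run_study reproduces the study's patient-level pattern", {
  co <- make_cohort(cohort_spec(discordance = list(), seed = 5),
                    phantom = small_cohort_phantom)
  st <- run_study(co, digits = "display")
  pa <- st$patient_accuracy
  expect_equal(pa$estimate[pa$metric == "sensitivity"], 96)
  expect_equal(pa$estimate[pa$metric == "npv"], 99.5)
  expect_equal(round(st$prevalence_pct, 1), 10.7)
  # discordant patients are excluded from quantitative agreement
  expect_equal(length(st$excluded_patients), 2L)
  expect_equal(st$n_quantitative, st$patient_table$tp)
  # count conservation at both levels
  expect_equal(st$patient_table$total, 214L)
  expect_equal(st$subsegment_table$total, 214L * 28L)
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(n_patients = 10, n_positive = 11), "exceed")
  expect_error(cohort_spec(n_positive = 0, discordance = list()), "at least one")
})
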