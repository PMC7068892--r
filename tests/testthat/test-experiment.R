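# Small-cohort study runs keep this file fast; the full default cohort
# is exercised by the acceptance suite.

small_config <- function(seed = 5, ...) {
  study_config(seed = seed,
               cohort = cohort_spec(n_subjects = 5,
                                    seed = lvquant:::derive_seed(seed, 1L)),
               ...)
}

test_that("a study run is deterministic under its master seed", {
  s1 <- run_study(small_config())
  s2 <- run_study(small_config())
  expect_identical(s1$volumetry, s2$volumetry)
  expect_identical(s1$agreement, s2$agreement)
  expect_identical(s1$icc, s2$icc)
  expect_identical(s1$wmsi, s2$wmsi)
  expect_identical(s1$strain, s2$strain)
  s3 <- run_study(small_config(seed = 6))
  expect_false(identical(s1$volumetry, s3$volumetry))
})

test_that("study tables have the documented shapes and identities", {
  s <- run_study(small_config())
  expect_setequal(unique(s$volumetry$modality),
                  c("TRUTH", "CMR", "US4D", "US2D", "MMODE"))
  expect_identical(nrow(s$volumetry), 25L)
  expect_equal(s$volumetry$SV_uL, s$volumetry$EDV_uL - s$volumetry$ESV_uL)
  expect_identical(nrow(s$agreement), 9L) # 3 modalities x 3 endpoints
  expect_true(all(s$agreement$loa_low_pct <= s$agreement$bias_pct))
  expect_true(all(s$agreement$bias_pct <= s$agreement$loa_high_pct))
  expect_identical(nrow(s$icc), 12L)
  expect_true(all(s$icc$icc <= 1))
  expect_identical(nrow(s$wmsi_segments), 5L * 16L)
  expect_true(all(s$wmsi$wmsi >= 1 & s$wmsi$wmsi <= 5))
})

test_that("the emulated CMR reference stays within its quantisation budget", {
  # default-parameter phantom: 1 mm slices within 5% of truth
  ph <- make_phantom(phantom_params())
  tv <- truth_volumes(ph)
  # budget: O(h^2) interior midpoint error plus the basal partial-slab
  # term h * A_base / (2 V), about 6% at h = 1 mm on this anatomy
  cmr <- volumetry_result(sample_short_axis_stack(
    ph, step = 1, thickness = 1, start_z = 0.5, max_slices = 8, tag = "CMR"))
  expect_lt(abs(cmr$edv - tv$edv) / tv$edv, 0.06)
  expect_lt(abs(cmr$esv - tv$esv) / tv$esv, 0.06)
  # jittered cohort: per-subject error bounded by the half-slice volume
  # fraction (a ventricle whose length does not divide the slice step
  # can miss up to ~A_max * h/2 of basal volume at end-diastole)
  s <- run_study(small_config())
  truth <- s$volumetry[s$volumetry$modality == "TRUTH", ]
  cm <- s$volumetry[s$volumetry$modality == "CMR", ]
  expect_true(all(abs(cm$EDV_uL - truth$EDV_uL) / truth$EDV_uL < 0.12))
  expect_true(all(abs(cm$ESV_uL - truth$ESV_uL) / truth$ESV_uL < 0.12))
  # the 0.2 mm stack is several times tighter (same partial-slab bound
  # at a fifth of the step)
  s4 <- s$volumetry[s$volumetry$modality == "US4D", ]
  expect_true(all(abs(s4$EDV_uL - truth$EDV_uL) / truth$EDV_uL < 0.025))
})

test_that("a control cohort shows near-zero biases and flags no dysfunction", {
  # against the truth oracle, so only discretisation remains: slice and
  # disk estimators sit at ~0; the Teichholz EF is approximately
  # unbiased under similarity motion (its volumes carry the formula's
  # own ellipsoid offset and are not constrained here)
  cfg <- study_config(seed = 9,
                      cohort = cohort_spec(n_subjects = 4, infarcted = FALSE,
                                           seed = 99),
                      rater = list(biases = c(0, 0), cv = 0),
                      reference = "TRUTH")
  s <- run_study(cfg)
  ag <- s$agreement
  expect_true(all(abs(ag$bias_pct[ag$modality %in% c("US4D", "US2D")]) < 2.5))
  expect_lt(abs(ag$bias_pct[ag$modality == "MMODE" & ag$endpoint == "EF"]), 3)
  expect_true(all(s$wmsi$wmsi == 1))
  txt <- paste(study_summary(s), collapse = "\n")
  expect_match(txt, "No regional dysfunction detected")
})

test_that("the summary reports the modality ranking and rejects empty bundles", {
  s <- run_study(small_config())
  txt <- paste(study_summary(s), collapse = "\n")
  expect_match(txt, "ranking by \\|EF bias\\|")
  expect_match(txt, "Bland-Altman")
  expect_match(txt, s$config$hash, fixed = TRUE)
  expect_error(study_summary(list()), "bundle")
})

test_that("study outputs serialise to a complete directory", {
  s <- run_study(small_config())
  dir <- withr::local_tempdir()
  write_study(s, dir)
  files <- list.files(dir)
  for (f in c("volumetry.csv", "agreement.csv", "icc.csv", "wmsi.csv",
              "strain.csv", "summary.md", "config.json", "run.log")) {
    expect_true(f %in% files, label = f)
  }
  back <- utils::read.csv(file.path(dir, "volumetry.csv"))
  expect_identical(unique(back$config_hash), s$config$hash)
  # rerun with the same seed writes byte-identical tables
  dir2 <- withr::local_tempdir()
  write_study(run_study(small_config()), dir2)
  expect_identical(readLines(file.path(dir, "volumetry.csv")),
                   readLines(file.path(dir2, "volumetry.csv")))
})
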