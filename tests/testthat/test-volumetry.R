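test_that("Teichholz reproduces hand-evaluated volumes", {
  expect_identical(teichholz_volume(0), 0)
  expect_equal(teichholz_volume(4.0), 7.0 / 6.4 * 64)   # 70 uL
  expect_equal(teichholz_volume(2.4), 7.0 / 4.8 * 2.4^3) # 20.16 uL
  expect_error(teichholz_volume(-0.1), ">= 0")
})

test_that("M-mode volumetry derives EDV/ESV/EF from the trace", {
  tr <- structure(list(lvid = c(4, 2.4), lvid_d = 4, lvid_s = 2.4,
                       ed_phase = 1L, es_phase = 2L, slice_z = 3,
                       beam_azimuth = 0), class = "lv_mmode")
  r <- mmode_result(tr)
  expect_equal(r$edv, 70)
  expect_equal(r$esv, 20.16)
  expect_equal(r$ef, 100 * (70 - 20.16) / 70) # 71.2%
  # no contraction -> EF 0
  tr0 <- tr; tr0$lvid_s <- 4; tr0$lvid <- c(4, 4)
  expect_equal(mmode_result(tr0)$ef, 0)
  # EF is strictly decreasing in lvid_s at fixed lvid_d
  efs <- vapply(c(2, 2.5, 3, 3.5), function(s) {
    t2 <- tr; t2$lvid_s <- s
    mmode_result(t2)$ef
  }, numeric(1))
  expect_true(all(diff(efs) < 0))
  # zero EDV -> EF missing
  trz <- tr; trz$lvid_d <- 0; trz$lvid_s <- 0
  expect_true(is.na(mmode_result(trz)$ef))
})

test_that("monoplane Simpson is near-exact on solids of revolution", {
  ph <- static_ellipsoid(R = 3, L = 6)
  lax <- sample_long_axis(ph, n_points = 400)
  v <- simpson_monoplane(lax, n_disks = 200, phase = 1)
  cf <- closed_form_volume(3, 6)
  expect_lt(abs(v - cf) / cf, 0.005)
  # degenerate flat contour -> zero volume
  flat <- cbind(x = seq(0, 6, length.out = 50), y = rep(0, 50))
  expect_equal(simpson_monoplane_polygon(flat, 20), 0)
  expect_error(simpson_monoplane_polygon(flat, 2), "n_disks")
})

test_that("slice summation is exact arithmetic and second-order in step", {
  # 3 slices, areas 2 mm^2, h = 1 mm -> 6 uL
  sq <- sqrt(2 / pi)
  fake <- structure(list(
    centers = c(0.5, 1.5, 2.5), thickness = 1,
    theta = (0:359), n_phases = 1L, tag = "4D",
    endo = rep(list(matrix(sq, 1, 360)), 3), epi = NULL),
    class = "lv_stack")
  expect_equal(slice_summation(fake, 1), 3 * pi * sq^2, tolerance = 1e-4)
  ph <- static_ellipsoid(R = 3, L = 6)
  cf <- closed_form_volume(3, 6)
  errs <- vapply(c(0.8, 0.4, 0.2), function(h) {
    st <- sample_short_axis_stack(ph, step = h, start_z = h / 2)
    abs(slice_summation(st, 1) - cf) / cf
  }, numeric(1))
  expect_lt(errs[3], 0.01)  # 0.2 mm within 1%
  # observed convergence order >= 2 on the smooth phantom
  order1 <- log2(errs[1] / errs[2])
  order2 <- log2(errs[2] / errs[3])
  expect_gt(order1, 1.8)
  expect_gt(order2, 1.8)
  # CMR protocol: 1 mm / 8 slices within 5%
  cmr <- sample_short_axis_stack(ph, step = 1, thickness = 1, start_z = 0.5,
                                 max_slices = 8, tag = "CMR")
  expect_lt(abs(slice_summation(cmr, 1) - cf) / cf, 0.05)
})

test_that("EF is invariant to uniform spatial rescaling for every estimator", {
  base <- phantom_params(radial_contraction = 0.25,
                         longitudinal_shortening = 0.1,
                         base_hyperkinesis_gain = 1)
  scaled <- phantom_params(base_radius_ed = base$base_radius_ed * 1.5,
                           long_axis_length_ed = base$long_axis_length_ed * 1.5,
                           wall_thickness_ed = base$wall_thickness_ed * 1.5,
                           radial_contraction = 0.25,
                           longitudinal_shortening = 0.1,
                           base_hyperkinesis_gain = 1)
  # the acquisition grid scales with the anatomy (same protocol, bigger
  # heart), so slice estimators are exactly scale-covariant; Teichholz
  # is only approximately so (its 2.4 constant is not homogeneous)
  efs <- lapply(list(c(pp = list(base), k = 1),
                     c(pp = list(scaled), k = 1.5)), function(it) {
    ph <- make_phantom(it$pp); k <- it$k
    list(
      truth = volumetry_result(ph)$ef,
      us4d = volumetry_result(sample_short_axis_stack(
        ph, step = 0.2 * k, start_z = 0.1 * k))$ef,
      cmr = volumetry_result(sample_short_axis_stack(
        ph, step = 1 * k, thickness = 1 * k, start_z = 0.5 * k,
        max_slices = 12, tag = "CMR"))$ef,
      us2d = volumetry_result(sample_long_axis(ph, include_epi = FALSE),
                              n_disks = 100)$ef,
      mmode = volumetry_result(sample_mmode(ph))$ef)
  })
  for (m in c("truth", "us4d", "cmr", "us2d")) {
    expect_equal(efs[[1]][[m]], efs[[2]][[m]], tolerance = 1e-8,
                 label = sprintf("EF of %s (base)", m))
  }
  expect_lt(abs(efs[[1]]$mmode - efs[[2]]$mmode), 2) # percentage points
  # under pure similarity motion every modality recovers the true EF
  true_ef <- efs[[1]]$truth
  for (m in c("us4d", "cmr", "us2d")) {
    expect_equal(efs[[1]][[m]], true_ef, tolerance = 0.05 * true_ef)
  }
})

test_that("zero-motion phantoms report EF 0 across modalities", {
  ph <- static_ellipsoid()
  expect_equal(volumetry_result(ph)$ef, 0)
  expect_equal(volumetry_result(sample_short_axis_stack(ph))$ef, 0)
  expect_equal(volumetry_result(sample_mmode(ph))$ef, 0)
})

test_that("Teichholz mis-measures the akinetic ventricle worse than slice summation", {
  ph <- apical_akinetic_phantom(apex_extent = 0.75, width = 170, center = 0,
                                gain = 1.15)
  tv <- truth_volumes(ph)
  esv_true <- tv$esv
  st <- sample_short_axis_stack(ph)
  esv_4d <- volumetry_result(st)$esv
  esv_mm <- volumetry_result(sample_mmode(ph, beam_azimuth = 0))$esv
  expect_gt(abs(esv_mm - esv_true), abs(esv_4d - esv_true))
})

test_that("volumetry results keep their internal identities", {
  ph <- similarity_phantom()
  for (r in list(volumetry_result(ph),
                 volumetry_result(sample_short_axis_stack(ph)),
                 volumetry_result(sample_mmode(ph)))) {
    expect_equal(r$sv, r$edv - r$esv)
    expect_equal(r$ef, 100 * (r$edv - r$esv) / r$edv)
    expect_gte(r$esv, 0)
  }
  expect_error(volumetry_result(42), "unsupported")
})
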