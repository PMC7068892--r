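test_that("axisymmetric quadrature volume matches the closed-form semi-ellipsoid", {
  ph <- static_ellipsoid(R = 3, L = 6)
  cf <- closed_form_volume(3, 6)
  expect_lt(abs(truth_volume(ph, 1) - cf) / cf, 1e-6)
  # scaling symmetry: radius scaled by k, same L -> volume scales by k^2
  ph2 <- static_ellipsoid(R = 3 * 1.3, L = 6)
  expect_equal(truth_volume(ph2, 1) / truth_volume(ph, 1), 1.3^2,
               tolerance = 1e-8)
})

test_that("a motionless phantom has identical geometry at every phase", {
  ph <- static_ellipsoid()
  theta <- c(0, 45, 123, 300)
  z <- c(0.5, 2, 4.7)
  for (p in c(2, 7, 11, 20)) {
    expect_equal(ph$endo_radius(theta, rep(z, length.out = 4), p),
                 ph$endo_radius(theta, rep(z, length.out = 4), 1))
  }
  v <- truth_volumes(ph)
  expect_equal(max(v$volumes), min(v$volumes))
})

test_that("radius is zero at the apex and epicardium lies outside the endocardium", {
  ph <- make_phantom(phantom_params(infarct = infarct_spec(0.5, 30, 120)))
  expect_equal(ph$endo_radius(c(0, 90, 200), 0, 1), c(0, 0, 0))
  theta <- seq(0, 350, by = 37)
  z <- seq(0.3, 6.5, by = 0.7)
  for (p in c(1, 6, 11)) {
    endo <- ph$endo_radius_grid(theta, z, p)
    epi <- ph$epi_radius_grid(theta, z, p)
    expect_true(all(epi > endo))
    expect_true(all(endo >= 0))
  }
})

test_that("a fully akinetic ventricle neither fills nor ejects", {
  ph <- make_phantom(phantom_params(
    infarct = infarct_spec(1, angular_width = 360, motion_class = "akinetic")))
  tv <- truth_volumes(ph, n_theta = 90L, n_z = 300L)
  expect_equal(max(tv$volumes), min(tv$volumes), tolerance = 1e-10)
  expect_equal(tv$ef, 0, tolerance = 1e-10)
})

test_that("volume decreases monotonically from ED to ES for contracting phantoms", {
  for (ph in list(similarity_phantom(), apical_akinetic_phantom())) {
    tv <- truth_volumes(ph, n_theta = 90L, n_z = 300L)
    first_half <- tv$volumes[tv$ed_phase:tv$es_phase]
    expect_true(all(diff(first_half) < 1e-9))
    expect_equal(tv$ed_phase, which.max(tv$volumes))
  }
})

test_that("an akinetic sector leaves more residual end-systolic volume", {
  healthy <- similarity_phantom(s = 0.3, ell = 0.15)
  infarcted <- make_phantom(phantom_params(
    base_hyperkinesis_gain = 1,
    infarct = infarct_spec(0.6, angular_width = 180,
                           motion_class = "akinetic")))
  es_h <- truth_volumes(healthy, n_theta = 90L, n_z = 300L)$esv
  es_i <- truth_volumes(infarcted, n_theta = 90L, n_z = 300L)$esv
  expect_gt(es_i, es_h)
})

test_that("scar fraction is zero iff no infarct and grows with sector size", {
  expect_identical(truth_scar_fraction(static_ellipsoid()), 0)
  base <- function(width, extent) truth_scar_fraction(
    make_phantom(phantom_params(
      infarct = infarct_spec(extent, 30, width))), n_theta = 120L, n_z = 300L)
  widths <- c(60, 120, 200, 300)
  by_width <- vapply(widths, base, numeric(1), extent = 0.5)
  expect_true(all(diff(by_width) > 0))
  extents <- c(0.2, 0.4, 0.6, 0.78)
  by_extent <- vapply(extents, base, numeric(1), width = 150)
  expect_true(all(diff(by_extent) > 0))
  expect_true(all(c(by_width, by_extent) > 0 & c(by_width, by_extent) < 1))
})

test_that("parameter validation names the offending field", {
  expect_error(phantom_params(base_radius_ed = -1), "base_radius_ed")
  expect_error(phantom_params(long_axis_length_ed = 1), "long_axis_length_ed")
  expect_error(phantom_params(radial_contraction = 1), "radial_contraction")
  expect_error(phantom_params(n_phases = 1), "n_phases")
  expect_error(infarct_spec(0), "apex_extent_fraction")
  expect_error(infarct_spec(0.5, angular_width = 400), "angular_width")
  expect_error(make_phantom(list()), "params")
})

test_that("cohort generation is reproducible and respects the scar envelope", {
  spec <- cohort_spec(n_subjects = 8, seed = 42)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$truth, c2$truth)
  expect_true(all(c1$truth$scar_fraction >= 0.03 &
                    c1$truth$scar_fraction <= 0.58))
  # solved infarcts hit their targets: truth recomputation stays in range
  recomputed <- vapply(c1$phantoms, truth_scar_fraction, numeric(1))
  expect_equal(recomputed, c1$truth$scar_fraction, tolerance = 1e-8)
  expect_error(cohort_spec(n_subjects = 0), "n_subjects")
  expect_error(cohort_spec(scar_distribution = "zipf"), "unsupported")
})

test_that("a control cohort carries no infarcts", {
  co <- generate_cohort(cohort_spec(n_subjects = 3, infarcted = FALSE,
                                    seed = 5))
  expect_true(all(co$truth$scar_fraction == 0))
  expect_true(all(vapply(co$phantoms,
                         function(p) is.null(p$params$infarct), logical(1))))
})

test_that("rater noise honours its identity and pure-bias limits", {
  v <- c(42, 55.5, 61)
  m0 <- apply_rater_noise(v, biases = c(0, 0), cv = 0, seed = 3)
  expect_equal(m0[, "rater1"], v)
  expect_equal(m0[, "rater2"], v)
  m1 <- apply_rater_noise(v, biases = c(0, 0.1), cv = 0, seed = 3)
  expect_equal(m1[, "rater2"], 1.1 * m1[, "rater1"])
  expect_identical(apply_rater_noise(v, cv = 0.05, seed = 9),
                   apply_rater_noise(v, cv = 0.05, seed = 9))
  expect_error(apply_rater_noise(v, cv = -1), "cv")
})
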