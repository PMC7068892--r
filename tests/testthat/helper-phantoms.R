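# Canonical phantoms reused across test files. All are cheap to build;
# quadrature cost is paid only where a test needs truth volumes.

# static truncated semi-ellipsoid R = 3, L = 6 (the closed-form case)
static_ellipsoid <- function(R = 3, L = 6) {
  make_phantom(phantom_params(
    base_radius_ed = R, long_axis_length_ed = L, wall_thickness_ed = 0.8,
    radial_contraction = 0, longitudinal_shortening = 0,
    base_hyperkinesis_gain = 1))
}

# pure similarity contraction: radii x (1 - s), length x (1 - ell)
similarity_phantom <- function(s = 0.25, ell = 0.1, n_phases = 20L) {
  make_phantom(phantom_params(
    radial_contraction = s, longitudinal_shortening = ell,
    n_phases = n_phases, base_hyperkinesis_gain = 1))
}

# apical akinetic infarct on an otherwise default ventricle
apical_akinetic_phantom <- function(apex_extent = 0.6, width = 150,
                                    center = 30, gain = 1) {
  make_phantom(phantom_params(
    base_hyperkinesis_gain = gain,
    infarct = infarct_spec(apex_extent, angular_center = center,
                           angular_width = width,
                           motion_class = "akinetic")))
}

closed_form_volume <- function(R, L) 2 / 3 * pi * R^2 * L

# memoised default study so acceptance blocks share one run
.study_cache <- new.env(parent = emptyenv())
default_study_cached <- function(seed = 1) {
  key <- paste0("seed", seed)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- run_study(study_config(seed = seed))
  .study_cache[[key]]
}
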