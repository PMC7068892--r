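#' Specify a synthetic infarct cohort
#'
#' The default cohort emulates the histology envelope of the 4-week
#' post-ligation mouse study that motivates this package: scar fractions
#' drawn from a truncated normal with mean 21.5% and SD 16.3% (the
#' printed 4.07% is a standard error over 16 hearts), clipped to the
#' printed range 4%-57%. Infarcts grow from the apex with an
#' anterior-lateral angular centre, the pattern of proximal left
#' coronary ligation. Per-subject anatomy is jittered mildly around the
#' default phantom parameters.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param scar_distribution name of the scar-fraction distribution;
#'   `"truncnorm"` (truncated normal, the default) or `"uniform"`.
#' @param scar_mean,scar_sd mean and SD of the untruncated normal.
#' @param scar_range two-element clipping range for scar fractions.
#' @param radius_sd,length_sd,wall_sd SDs of per-subject jitter on the
#'   base radius, long-axis length and wall thickness (mm).
#' @param contraction_sd SD of per-subject jitter on remote radial
#'   contraction.
#' @param angular_center_mean,angular_center_sd infarct sector centre
#'   distribution (degrees; 0 = anterior).
#' @param motion_class dysfunction class of the infarcts: one of the
#'   [infarct_spec()] classes applied to every subject, or `"mixed"`
#'   (the default) where scars larger than `dyskinetic_above` become
#'   dyskinetic — large transmural scars bulge during systole — and the
#'   rest are akinetic.
#' @param dyskinetic_above scar-fraction threshold for the `"mixed"` rule.
#' @param infarcted set `FALSE` for a control cohort with no infarcts
#'   (scar settings are then ignored).
#' @param base_params baseline [phantom_params()] the jitter is applied to.
#' @param seed integer master seed; the cohort is bit-reproducible given
#'   the seed.
#' @return an object of class `lv_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 32L,
                        scar_distribution = "truncnorm",
                        scar_mean = 0.215,
                        scar_sd = 0.163,
                        scar_range = c(0.04, 0.57),
                        radius_sd = 0.10,
                        length_sd = 0.25,
                        wall_sd = 0.05,
                        contraction_sd = 0.02,
                        angular_center_mean = 30,
                        angular_center_sd = 15,
                        motion_class = "mixed",
                        dyskinetic_above = 0.35,
                        infarcted = TRUE,
                        base_params = phantom_params(),
                        seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1 || n_subjects != round(n_subjects))
    stop_param("n_subjects", "must be an integer >= 1")
  if (!scar_distribution %in% c("truncnorm", "uniform"))
    stop(sprintf("unsupported scar distribution '%s'", scar_distribution),
         call. = FALSE)
  stopifnot(length(scar_range) == 2, scar_range[1] >= 0, scar_range[2] < 1,
            scar_range[1] < scar_range[2])
  structure(list(
    n_subjects = as.integer(n_subjects),
    scar_distribution = scar_distribution,
    scar_mean = scar_mean, scar_sd = scar_sd, scar_range = scar_range,
    radius_sd = radius_sd, length_sd = length_sd, wall_sd = wall_sd,
    contraction_sd = contraction_sd,
    angular_center_mean = angular_center_mean,
    angular_center_sd = angular_center_sd,
    motion_class = motion_class,
    dyskinetic_above = dyskinetic_above,
    infarcted = isTRUE(infarcted),
    base_params = base_params,
    seed = as.integer(seed)
  ), class = "lv_cohort_spec")
}

# draw one scar fraction; rejection sampling keeps the draw inside the
# clipping range and is deterministic under the ambient RNG stream
.draw_scar <- function(spec) {
  if (spec$scar_distribution == "uniform")
    return(stats::runif(1, spec$scar_range[1], spec$scar_range[2]))
  for (i in 1:10000) {
    x <- stats::rnorm(1, spec$scar_mean, spec$scar_sd)
    if (x >= spec$scar_range[1] && x <= spec$scar_range[2]) return(x)
  }
  stop("scar-fraction rejection sampling failed; check scar_range", call. = FALSE)
}

# Solve the infarct geometry whose ground-truth scar fraction matches a
# target. A single severity knob `lambda` scales the sector both
# apically (extent = 1.4 * lambda — proximal-ligation scars are long
# wedges reaching from the apex toward the base — capped at 0.78 so the
# scar spares the basal rim: the base stays functional in this model,
# and a scar frozen basal to the end-systolic annulus would degenerate
# the long-axis silhouette) and angularly (width = 170 * lambda deg,
# capped at 360); scar fraction is strictly increasing in lambda, so
# uniroot on a modest integration grid inverts the map.
.infarct_for_scar <- function(target, params, angular_center, motion_class,
                              tol = 1e-3) {
  build <- function(lambda) {
    infarct_spec(apex_extent_fraction = min(0.78, 1.4 * lambda),
                 angular_center = angular_center,
                 angular_width = min(360, 170 * lambda),
                 motion_class = motion_class)
  }
  f <- function(lambda) {
    pp <- params
    pp$infarct <- build(lambda)
    truth_scar_fraction(make_phantom(pp), n_theta = 120L, n_z = 300L) - target
  }
  lo <- 1e-3; hi <- 2.5
  root <- stats::uniroot(f, c(lo, hi), tol = tol)$root
  build(root)
}

#' Generate a cohort of infarcted phantoms
#'
#' Per subject, a target scar fraction is drawn from the configured
#' distribution and the infarct sector is solved (by 1-D root finding on
#' a single severity parameter) so that the phantom's ground-truth scar
#' fraction matches the draw. The same seed yields a bit-identical
#' cohort.
#'
#' @param spec an [cohort_spec()].
#' @return an object of class `lv_cohort`: list with `phantoms` (list of
#'   `lv_phantom`) and `truth` (data.frame with subject id, scar
#'   fraction, true EDV/ESV/SV/EF). The truth table defers volumetric
#'   columns until [cohort_truth_table()] is called with quadrature
#'   settings, so generation stays fast; `truth` here carries subject,
#'   scar_fraction and the per-subject anatomical parameters.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "lv_cohort_spec"))
    stop_param("spec", "must be a cohort_spec() object")
  bp <- spec$base_params
  with_seed(spec$seed, {
    phantoms <- vector("list", spec$n_subjects)
    rows <- vector("list", spec$n_subjects)
    for (i in seq_len(spec$n_subjects)) {
      target <- if (spec$infarcted) .draw_scar(spec) else 0
      R <- max(0.5, stats::rnorm(1, bp$base_radius_ed, spec$radius_sd))
      L <- max(R * 1.5, stats::rnorm(1, bp$long_axis_length_ed, spec$length_sd))
      t_w <- max(0.2, stats::rnorm(1, bp$wall_thickness_ed, spec$wall_sd))
      s <- min(0.6, max(0.05, stats::rnorm(1, bp$radial_contraction,
                                           spec$contraction_sd)))
      ac <- stats::rnorm(1, spec$angular_center_mean, spec$angular_center_sd)
      cls <- if (identical(spec$motion_class, "mixed")) {
        if (target > spec$dyskinetic_above) "dyskinetic" else "akinetic"
      } else spec$motion_class
      pp <- phantom_params(
        base_radius_ed = R, long_axis_length_ed = L, wall_thickness_ed = t_w,
        n_phases = bp$n_phases, radial_contraction = s,
        longitudinal_shortening = bp$longitudinal_shortening,
        infarct = NULL,
        base_hyperkinesis_gain = bp$base_hyperkinesis_gain,
        seed = derive_seed(spec$seed, i))
      if (spec$infarcted)
        pp$infarct <- .infarct_for_scar(target, pp, ac, cls)
      ph <- make_phantom(pp)
      phantoms[[i]] <- ph
      rows[[i]] <- data.frame(
        subject = i,
        scar_fraction = truth_scar_fraction(ph),
        base_radius_ed = R, long_axis_length_ed = L,
        wall_thickness_ed = t_w, radial_contraction = s,
        angular_center = if (spec$infarcted) pp$infarct$angular_center else NA,
        angular_width = if (spec$infarcted) pp$infarct$angular_width else NA,
        apex_extent_fraction = if (spec$infarcted)
          pp$infarct$apex_extent_fraction else NA,
        motion_class = if (spec$infarcted) cls else "none")
    }
    structure(list(phantoms = phantoms, truth = do.call(rbind, rows),
                   spec = spec),
              class = "lv_cohort")
  })
}

#' Cohort ground-truth table including volumetric truth
#'
#' @param cohort an `lv_cohort`.
#' @return data.frame: subject, scar_fraction, EDV_uL, ESV_uL, SV_uL, EF_pct.
#' @export
cohort_truth_table <- function(cohort) {
  stopifnot(inherits(cohort, "lv_cohort"))
  do.call(rbind, lapply(seq_along(cohort$phantoms), function(i) {
    tv <- truth_volumes(cohort$phantoms[[i]])
    data.frame(subject = i,
               scar_fraction = cohort$truth$scar_fraction[i],
               EDV_uL = tv$edv, ESV_uL = tv$esv, SV_uL = tv$sv,
               EF_pct = tv$ef)
  }))
}

#' Apply a two-rater measurement-noise model
#'
#' Rater `r`'s reading of a true value `v` is
#' `v * (1 + bias_r + cv * eps)` with `eps` a standard normal deviate,
#' independent per reading. This is the measurement model behind the
#' inter-rater intraclass-correlation simulations.
#'
#' @param values numeric vector of true values (uL or percent).
#' @param biases length-2 vector of per-rater proportional biases.
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param seed optional integer seed; the output is deterministic given it.
#' @return a numeric matrix with `length(values)` rows and two columns
#'   `rater1`, `rater2`.
#' @export
#' @examples
#' apply_rater_noise(c(50, 60, 70), biases = c(0, 0.05), cv = 0.02, seed = 1)
apply_rater_noise <- function(values, biases = c(0, 0), cv = 0.05, seed = NULL) {
  stopifnot(is.numeric(values), length(biases) == 2)
  if (cv < 0) stop_param("cv", "must be >= 0")
  n <- length(values)
  with_seed(seed, {
    eps <- matrix(stats::rnorm(2 * n), nrow = n, ncol = 2)
    out <- cbind(values * (1 + biases[1] + cv * eps[, 1]),
                 values * (1 + biases[2] + cv * eps[, 2]))
    colnames(out) <- c("rater1", "rater2")
    out
  })
}
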