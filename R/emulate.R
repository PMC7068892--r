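#' Sample an M-mode trace through a phantom
#'
#' Emulates an M-mode cursor line in a short-axis view: at each phase
#' the internal diameter along the beam is the sum of the endocardial
#' radii at the beam azimuth and its antipode. LVID;d and LVID;s are
#' read at the phases of maximal and minimal diameter, mirroring how an
#' operator picks frames on the trace.
#'
#' @param phantom an `lv_phantom`.
#' @param slice_z beam elevation above the apex, mm; the default, 65% of
#'   the end-diastolic long-axis length, is the mid-papillary level of
#'   the semi-ellipsoidal geometry (in a shape widest at the base the
#'   papillary insertion sits basal of the geometric midpoint).
#' @param beam_azimuth beam azimuth in degrees (0 = anterior). M-mode
#'   protocols do not fix an azimuth; results are azimuth-independent
#'   only for axisymmetric ventricles, so it is an explicit parameter.
#' @return an object of class `lv_mmode`: list with `lvid` (mm per
#'   phase), `lvid_d`, `lvid_s`, `ed_phase`, `es_phase`, `slice_z`,
#'   `beam_azimuth`.
#' @export
sample_mmode <- function(phantom,
                         slice_z = 0.65 * phantom$params$long_axis_length_ed,
                         beam_azimuth = 0) {
  stopifnot(inherits(phantom, "lv_phantom"))
  phases <- seq_len(phantom$params$n_phases)
  min_len <- min(phantom$long_axis(phases))
  if (slice_z <= 0 || slice_z >= min_len)
    stop(sprintf(
      "slice_z = %.2f mm is outside the ventricle at some phase (apex-to-base %.2f mm at end-systole)",
      slice_z, min_len), call. = FALSE)
  lvid <- phantom$endo_radius(beam_azimuth, slice_z, phases) +
    phantom$endo_radius(beam_azimuth + 180, slice_z, phases)
  ed <- which.max(lvid); es <- which.min(lvid)
  structure(list(lvid = lvid, lvid_d = lvid[ed], lvid_s = lvid[es],
                 ed_phase = ed, es_phase = es,
                 slice_z = slice_z, beam_azimuth = beam_azimuth %% 360),
            class = "lv_mmode")
}

#' Sample a long-axis endocardial contour
#'
#' Emulates a parasternal long-axis trace: the sampling plane through
#' the long axis at `plane_azimuth` intersects the endocardium in two
#' half-profiles (at the azimuth and its antipode), evaluated on a
#' uniform elevation grid and joined at the apex. The polygon is closed
#' implicitly by the basal chord from the last vertex back to the first.
#' Coordinates: `x` along the long axis (apex at `x = 0`), `y`
#' transverse (positive on the `plane_azimuth` side).
#'
#' @param phantom an `lv_phantom`.
#' @param plane_azimuth plane azimuth in degrees.
#' @param n_points number of sampling stations per half-profile (>= 16).
#' @param include_epi also sample the epicardial boundary (needed for
#'   long-axis radial strain).
#' @return an object of class `lv_laxcontour`: list with `endo` (per
#'   phase, a matrix with columns x, y ordered base -> apex -> base),
#'   optionally `epi`, plus `plane_azimuth` and `n_phases`.
#' @export
sample_long_axis <- function(phantom, plane_azimuth = 0, n_points = 128L,
                             include_epi = TRUE) {
  stopifnot(inherits(phantom, "lv_phantom"))
  if (n_points < 16) stop_param("n_points", "must be >= 16")
  np <- phantom$params$n_phases
  L_ed <- phantom$params$long_axis_length_ed
  inf <- phantom$params$infarct
  az1 <- plane_azimuth; az2 <- plane_azimuth + 180
  # Material station map: a tissue column inside the infarct keeps its
  # end-diastolic elevation (the scar does not shorten), a remote column
  # follows the global longitudinal motion, with a broad blend between
  # them (a functional border zone; tissue motion fields are smooth).
  # Stations therefore track material points, which is what makes the
  # segmental strain of a frozen wall vanish.
  station_w <- function(az, u) {
    if (is.null(inf)) return(rep(0, length(u)))
    a <- inf$apex_extent_fraction
    wz <- if (a >= 1) rep(1, length(u)) else .smoothstep((a - u) / 0.25)
    .w_theta(inf, az) * wz
  }
  station_z <- function(az, u, ze) {
    w <- station_w(az, u)
    cummax(u * ((1 - w) * ze + w * L_ed))
  }
  build <- function(phase, radius_fun) {
    ze <- phantom$extent(phase)
    u <- seq(0, 1, length.out = n_points) # apex -> base
    z1 <- station_z(az1, u, ze)
    z2 <- station_z(az2, u, ze)
    # side 1 runs base -> apex, side 2 apex -> base; shared apex vertex
    cbind(x = c(rev(z1), z2[-1L]),
          y = c(radius_fun(az1, rev(z1), phase),
                -radius_fun(az2, z2[-1L], phase)))
  }
  endo <- lapply(seq_len(np), build, radius_fun = phantom$endo_radius)
  epi <- if (include_epi) lapply(seq_len(np), build,
                                 radius_fun = phantom$epi_radius)
  structure(list(endo = endo, epi = epi,
                 plane_azimuth = plane_azimuth %% 360, n_phases = np),
            class = "lv_laxcontour")
}

#' Sample a short-axis contour stack
#'
#' Emulates stepped short-axis acquisition: slice centres at
#' `start_z + k * step` below the basal limit, each slice a closed
#' polygon of `n_vertices` points at uniform azimuth with radius
#' `endo_radius(theta, center_z, phase)`. The basal limit is the
#' maximal ventricular extent over the cycle (so the stack covers the
#' whole end-diastolic cavity); a slice lying basal to the ventricle at
#' a given phase yields a degenerate zero-area polygon, as a contourer
#' produces when a basal slice shows no cavity at end-systole.
#' `basal_truncation_z`, when set, caps the stack instead — the named
#' scenario for a base that cannot be visualised.
#'
#' Defaults follow the 4D-ultrasound protocol (0.2 mm steps from just
#' below the apex). Use `step = 1, thickness = 1, start_z = 0.5,
#' max_slices = 8, tag = "CMR"` for the cine-CMR protocol of eight
#' gapless 1 mm slices.
#'
#' @param phantom an `lv_phantom`.
#' @param step slice spacing, mm (> 0).
#' @param thickness slice thickness, mm (> 0); defaults to `step`
#'   (gapless).
#' @param start_z centre of the first (apical-most) slice, mm.
#' @param max_slices optional cap on the slice count (apical slices kept).
#' @param basal_truncation_z optional basal cut-off, mm.
#' @param n_vertices polygon vertex count.
#' @param tag acquisition tag, `"4D"` or `"CMR"`.
#' @param include_epi also sample epicardial polygons.
#' @return an object of class `lv_stack`: list with `centers`,
#'   `thickness`, `theta` (vertex azimuths, degrees), `endo` (list over
#'   slices of phase-by-vertex radius matrices), optionally `epi`,
#'   `n_phases`, `tag`.
#' @export
sample_short_axis_stack <- function(phantom, step = 0.2, thickness = step,
                                    start_z = 0.1, max_slices = NULL,
                                    basal_truncation_z = NULL,
                                    n_vertices = 360L, tag = "4D",
                                    include_epi = FALSE) {
  stopifnot(inherits(phantom, "lv_phantom"))
  if (step <= 0) stop_param("step", "must be > 0")
  if (thickness <= 0) stop_param("thickness", "must be > 0")
  phases <- seq_len(phantom$params$n_phases)
  limit <- if (!is.null(basal_truncation_z)) basal_truncation_z
           else max(phantom$extent(phases))
  centers <- if (start_z >= limit) numeric(0) else seq(start_z, limit, by = step)
  centers <- centers[centers < limit]
  if (!is.null(max_slices) && length(centers) > max_slices)
    centers <- centers[seq_len(max_slices)]
  if (length(centers) == 0)
    stop("no slices produced: stack range is empty; check step/start_z/basal limit",
         call. = FALSE)
  theta <- (seq_len(n_vertices) - 1) * 360 / n_vertices
  get <- function(fun) {
    # one (theta x centers) grid evaluation per phase, then split by slice
    per_phase <- lapply(phases, function(p) fun(theta, centers, p))
    lapply(seq_along(centers), function(i) {
      m <- do.call(rbind, lapply(per_phase, function(g) g[, i]))
      dimnames(m) <- NULL
      m # n_phases x n_vertices radii
    })
  }
  endo <- get(phantom$endo_radius_grid)
  epi <- if (include_epi) get(phantom$epi_radius_grid)
  structure(list(centers = centers, thickness = thickness, theta = theta,
                 endo = endo, epi = epi,
                 n_phases = phantom$params$n_phases, tag = tag),
            class = "lv_stack")
}

#' Slice polygon vertices in the imaging plane
#'
#' @param stack an `lv_stack`.
#' @param slice slice index (apical-most = 1).
#' @param phase phase index.
#' @param boundary `"endo"` or `"epi"`.
#' @return matrix with columns x, y (mm).
#' @export
stack_polygon <- function(stack, slice, phase, boundary = c("endo", "epi")) {
  boundary <- match.arg(boundary)
  r <- stack[[boundary]][[slice]][phase, ]
  th <- stack$theta * pi / 180
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Per-slice cavity areas at a phase
#' @param stack an `lv_stack`.
#' @param phase phase index.
#' @return numeric vector of polygon areas (mm^2), one per slice.
#' @export
stack_areas <- function(stack, phase) {
  vapply(seq_along(stack$centers), function(i) {
    xy <- stack_polygon(stack, i, phase)
    if (all(abs(xy) < 1e-12)) return(0) # degenerate basal slice
    shoelace_area(xy[, 1], xy[, 2])
  }, numeric(1))
}
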