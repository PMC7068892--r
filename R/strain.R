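# Strain summaries from emulated boundaries. "Peak" strain is the
# signed extremum of largest magnitude over the cycle; material identity
# along a boundary is carried by the sampling parameter (the
# speckle-tracking surrogate available without image texture).

# signed extremum of largest magnitude (first one on ties)
.peak <- function(x) x[which.max(abs(x))]

# arc length of the open endocardial polyline of a long-axis contour
.lax_arc <- function(xy) polyline_length(xy[, 1], xy[, 2])

#' Longitudinal strain from a long-axis contour
#'
#' Global strain at phase `p` is the percent change of the endocardial
#' boundary arc length relative to end-diastole (the phase of maximal
#' enclosed area); GLS is the signed extremum over the cycle. The ED
#' boundary is split into six segments of equal arc length, each tracked
#' by its vertex-parameter interval, and per-segment peak strains are
#' returned together with their standard deviation (the long-axis
#' dyssynchrony index).
#'
#' @param contour an `lv_laxcontour`.
#' @return list with `gls` (percent), `by_phase` (global strain per
#'   phase), `segment_peaks` (6 values, percent), `dyssynchrony_sd`
#'   (percent) and `ed_phase`.
#' @export
longitudinal_strain <- function(contour) {
  stopifnot(inherits(contour, "lv_laxcontour"))
  np <- contour$n_phases
  if (np < 2) stop("at least 2 phases are required", call. = FALSE)
  areas <- vapply(contour$endo, function(m) shoelace_area(m[, 1], m[, 2]),
                  numeric(1))
  ed <- which.max(areas)
  ed_xy <- contour$endo[[ed]]
  n <- nrow(ed_xy)
  if (n < 8 || all(abs(ed_xy[, 2]) < 1e-12))
    stop("degenerate long-axis contour", call. = FALSE)
  arcs <- vapply(contour$endo, .lax_arc, numeric(1))
  if (arcs[ed] <= 0) stop("degenerate long-axis contour", call. = FALSE)
  by_phase <- 100 * (arcs - arcs[ed]) / arcs[ed]
  # ED-arc-length segmentation into 6 material segments
  seg_len <- sqrt(diff(ed_xy[, 1])^2 + diff(ed_xy[, 2])^2)
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  breaks <- vapply(0:6, function(k) which.min(abs(cum - k * total / 6)),
                   integer(1))
  breaks[1] <- 1L; breaks[7] <- n
  if (any(diff(breaks) < 1)) stop("contour too coarse for 6 segments",
                                  call. = FALSE)
  seg_peaks <- vapply(seq_len(6), function(s) {
    i0 <- breaks[s]; i1 <- breaks[s + 1]
    len <- vapply(contour$endo, function(m)
      polyline_length(m[i0:i1, 1], m[i0:i1, 2]), numeric(1))
    .peak(100 * (len - len[ed]) / len[ed])
  }, numeric(1))
  list(gls = .peak(by_phase), by_phase = by_phase,
       segment_peaks = seg_peaks,
       dyssynchrony_sd = stats::sd(seg_peaks), ed_phase = ed)
}

#' Circumferential strain at a short-axis slice
#'
#' Perimeter-based strain of one slice of a contour stack (the
#' mid-ventricular slice by default), relative to the phase of maximal
#' slice area; the peak signed extremum over the cycle is returned.
#'
#' @param stack an `lv_stack`.
#' @param slice slice index; default the slice nearest mid-ventricle.
#' @return list with `gcs` (percent), `by_phase`, `slice`.
#' @export
circumferential_strain <- function(stack, slice = NULL) {
  stopifnot(inherits(stack, "lv_stack"))
  if (stack$n_phases < 2) stop("at least 2 phases are required", call. = FALSE)
  slice <- slice %||% which.min(abs(stack$centers - stats::median(stack$centers)))
  per <- vapply(seq_len(stack$n_phases), function(p) {
    xy <- stack_polygon(stack, slice, p)
    polygon_perimeter(xy[, 1], xy[, 2])
  }, numeric(1))
  areas <- vapply(seq_len(stack$n_phases), function(p) {
    xy <- stack_polygon(stack, slice, p)
    shoelace_area(xy[, 1], xy[, 2])
  }, numeric(1))
  ed <- which.max(areas)
  if (per[ed] <= 0) stop("degenerate slice perimeter", call. = FALSE)
  by_phase <- 100 * (per - per[ed]) / per[ed]
  list(gcs = .peak(by_phase), by_phase = by_phase, slice = slice)
}

#' Radial strain from paired endo-/epicardial boundaries
#'
#' Mean wall thickness per phase from paired boundaries; radial strain
#' is the percent thickness change relative to end-diastole (positive =
#' systolic thickening), peak signed extremum over the cycle.
#'
#' For a short-axis slice (`lv_stack` sampled with `include_epi = TRUE`)
#' the thickness is the azimuthal mean of `r_epi - r_endo`; for a
#' long-axis contour (`lv_laxcontour` with epicardium) it is the mean
#' transverse wall thickness over the sampling stations.
#'
#' @param x an `lv_stack` or `lv_laxcontour` carrying an epicardium.
#' @param slice slice index for stacks (default mid-ventricular).
#' @return list with `grs` (percent) and `by_phase`.
#' @export
radial_strain <- function(x, slice = NULL) {
  if (inherits(x, "lv_stack")) {
    if (is.null(x$epi)) stop("stack was sampled without the epicardium",
                             call. = FALSE)
    slice <- slice %||% which.min(abs(x$centers - stats::median(x$centers)))
    thick <- vapply(seq_len(x$n_phases), function(p)
      mean(x$epi[[slice]][p, ] - x$endo[[slice]][p, ]), numeric(1))
    areas <- vapply(seq_len(x$n_phases), function(p) {
      xy <- stack_polygon(x, slice, p)
      shoelace_area(xy[, 1], xy[, 2])
    }, numeric(1))
    ed <- which.max(areas)
  } else if (inherits(x, "lv_laxcontour")) {
    if (is.null(x$epi)) stop("contour was sampled without the epicardium",
                             call. = FALSE)
    thick <- vapply(seq_len(x$n_phases), function(p)
      mean(abs(x$epi[[p]][, 2]) - abs(x$endo[[p]][, 2])), numeric(1))
    areas <- vapply(x$endo, function(m) shoelace_area(m[, 1], m[, 2]),
                    numeric(1))
    ed <- which.max(areas)
  } else {
    stop("radial_strain needs an lv_stack or lv_laxcontour", call. = FALSE)
  }
  if (thick[ed] <= 0) stop("non-positive end-diastolic wall thickness",
                           call. = FALSE)
  by_phase <- 100 * (thick - thick[ed]) / thick[ed]
  list(grs = .peak(by_phase), by_phase = by_phase)
}

#' Full strain summary for one phantom
#'
#' Samples the standard long-axis plane (with epicardium) and a 0.2 mm
#' short-axis stack (with epicardium) and assembles GLS, long-axis
#' radial strain, circumferential strain, short-axis radial strain and
#' the SD-based dyssynchrony index.
#'
#' @param phantom an `lv_phantom`.
#' @param plane_azimuth long-axis plane azimuth, degrees.
#' @param lax optional pre-sampled `lv_laxcontour` (with epicardium).
#' @param stack optional pre-sampled `lv_stack` (with epicardium).
#' @return data.frame with gls, grs_long, gcs, grs_short,
#'   dyssynchrony_sd (all percent).
#' @export
strain_result <- function(phantom, plane_azimuth = 0, lax = NULL,
                          stack = NULL) {
  stopifnot(inherits(phantom, "lv_phantom"))
  lax <- lax %||% sample_long_axis(phantom, plane_azimuth = plane_azimuth,
                                   include_epi = TRUE)
  stack <- stack %||% sample_short_axis_stack(phantom, include_epi = TRUE)
  ls <- longitudinal_strain(lax)
  cs <- circumferential_strain(stack)
  data.frame(gls = ls$gls,
             grs_long = radial_strain(lax)$grs,
             gcs = cs$gcs,
             grs_short = radial_strain(stack)$grs,
             dyssynchrony_sd = ls$dyssynchrony_sd)
}
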