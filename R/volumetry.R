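#' Teichholz volume from an internal diameter
#'
#' The cubed-diameter M-mode estimate `7.0 / (2.4 + D) * D^3`, with the
#' diameter in mm and the volume in uL. It assumes an ellipsoid cavity
#' whose long axis is a fixed function of the short-axis diameter; after
#' regional infarction that assumption is the source of the bias this
#' package quantifies.
#'
#' @param lvid internal diameter, mm (>= 0; vectorised).
#' @return volume in uL.
#' @export
#' @examples
#' teichholz_volume(4.0) # 70 uL
teichholz_volume <- function(lvid) {
  if (any(lvid < 0)) stop("lvid must be >= 0", call. = FALSE)
  7.0 / (2.4 + lvid) * lvid^3
}

# assemble a VolumetryResult row
.vol_result <- function(modality, edv, esv, ed_phase = NA, es_phase = NA) {
  ef <- if (is.na(edv) || edv <= 0) NA_real_ else 100 * (edv - esv) / edv
  structure(list(modality = modality, edv = edv, esv = esv,
                 sv = edv - esv, ef = ef,
                 ed_phase = ed_phase, es_phase = es_phase),
            class = "lv_volumetry")
}

#' @export
print.lv_volumetry <- function(x, ...) {
  cat(sprintf("%s: EDV %.2f uL, ESV %.2f uL, SV %.2f uL, EF %s\n",
              x$modality, x$edv, x$esv, x$sv,
              if (is.na(x$ef)) "undefined (EDV = 0)"
              else sprintf("%.1f%%", x$ef)))
  invisible(x)
}

#' M-mode (Teichholz) volumetry from a trace
#'
#' @param trace an `lv_mmode` from [sample_mmode()].
#' @return an `lv_volumetry` with modality `"MMODE"`; EF is reported as
#'   missing when EDV is zero.
#' @export
mmode_result <- function(trace) {
  stopifnot(inherits(trace, "lv_mmode"))
  .vol_result("MMODE",
              edv = teichholz_volume(trace$lvid_d),
              esv = teichholz_volume(trace$lvid_s),
              ed_phase = trace$ed_phase, es_phase = trace$es_phase)
}

#' Monoplane Simpson (method of disks) volume of one contour
#'
#' The long axis runs from the apex vertex (minimal `x`) to the midpoint
#' of the basal chord (the polygon edge whose midpoint lies most basal
#' along the apex-base direction). The axis is divided into `n_disks`
#' equal-height disks; each disk's diameter is the chord of the contour
#' perpendicular to the axis at the disk centre, and
#' `V = sum (pi/4) d_i^2 h`. Exact for solids of revolution up to the
#' disk discretisation.
#'
#' @param xy two-column matrix of contour vertices (closed implicitly).
#' @param n_disks number of disks (>= 4).
#' @return volume in uL.
#' @export
simpson_monoplane_polygon <- function(xy, n_disks = 20L) {
  if (n_disks < 4) stop_param("n_disks", "must be >= 4")
  stopifnot(is.matrix(xy), ncol(xy) == 2, nrow(xy) >= 4)
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  apex <- which.min(x)
  # basal chord: edge whose midpoint is furthest from the apex along x
  nx <- c(2:n, 1L)
  mid_x <- (x + x[nx]) / 2
  be <- which.max(mid_x)
  B <- c((x[be] + x[nx[be]]) / 2, (y[be] + y[nx[be]]) / 2)
  A <- c(x[apex], y[apex])
  u <- B - A
  L_axis <- sqrt(sum(u^2))
  if (L_axis < 1e-12) return(0)
  u <- u / L_axis
  v <- c(-u[2], u[1])
  a <- (x - A[1]) * u[1] + (y - A[2]) * u[2] # axial coordinate
  b <- (x - A[1]) * v[1] + (y - A[2]) * v[2] # transverse coordinate
  h <- L_axis / n_disks
  centers <- (seq_len(n_disks) - 0.5) * h
  a2 <- a[nx]; b2 <- b[nx]
  vol <- 0
  for (t in centers) {
    cross <- which((a - t) * (a2 - t) <= 0 & a != a2)
    if (length(cross) < 2) {
      if (all(abs(b) < 1e-12)) return(0) # degenerate flat contour
      stop(sprintf(
        "no perpendicular chord found at axial position %.3f mm; contour is not disk-decomposable",
        t), call. = FALSE)
    }
    bc <- b[cross] + (t - a[cross]) / (a2[cross] - a[cross]) *
      (b2[cross] - b[cross])
    d <- max(bc) - min(bc)
    vol <- vol + pi / 4 * d^2 * h
  }
  vol
}

#' Monoplane Simpson volumes for a long-axis contour set
#'
#' @param contour an `lv_laxcontour` from [sample_long_axis()].
#' @param n_disks number of disks.
#' @param phase optional phase index; default all phases.
#' @return volume(s) in uL.
#' @export
simpson_monoplane <- function(contour, n_disks = 20L, phase = NULL) {
  stopifnot(inherits(contour, "lv_laxcontour"))
  phase <- phase %||% seq_len(contour$n_phases)
  vapply(phase, function(p) simpson_monoplane_polygon(contour$endo[[p]],
                                                      n_disks), numeric(1))
}

#' Stacked-slice volume by slice summation
#'
#' `V = sum A_i * h_i` with `A_i` the shoelace area of slice `i`'s
#' endocardial polygon at the phase and `h_i` its thickness. This is the
#' shape-assumption-free estimator shared by 4D ultrasound and cine
#' CMR; accuracy is limited only by slice quantisation.
#'
#' @param stack an `lv_stack`.
#' @param phase phase index.
#' @param validate check polygons for self-intersection (slower; meant
#'   for externally supplied stacks).
#' @return volume in uL.
#' @export
slice_summation <- function(stack, phase, validate = FALSE) {
  stopifnot(inherits(stack, "lv_stack"))
  if (length(stack$centers) == 0) stop("empty contour stack", call. = FALSE)
  if (validate) {
    for (i in seq_along(stack$centers)) {
      xy <- stack_polygon(stack, i, phase)
      if (all(abs(xy) < 1e-12)) next
      if (!is_simple_polygon(xy[, 1], xy[, 2]))
        stop(sprintf("slice %d polygon is self-intersecting", i), call. = FALSE)
    }
  }
  sum(stack_areas(stack, phase)) * stack$thickness
}

#' Volumetry result for any acquisition
#'
#' Dispatches on the acquisition object: `lv_stack` (slice summation;
#' modality from the stack tag), `lv_laxcontour` (monoplane Simpson,
#' `"US2D"`), `lv_mmode` (Teichholz, `"MMODE"`), or `lv_phantom`
#' (quadrature oracle, `"TRUTH"`). ED and ES are the phases of maximal
#' and minimal volume as that modality itself estimates them, mirroring
#' operator frame selection; `truth_phases` forces the phantom-truth
#' ED/ES instead (for oracle-aligned comparisons).
#'
#' @param x acquisition object or phantom.
#' @param n_disks disks for the Simpson estimator.
#' @param truth_phases optional list with `ed_phase`, `es_phase` to force
#'   phase alignment (e.g. from [truth_volumes()]).
#' @return an `lv_volumetry`.
#' @export
volumetry_result <- function(x, n_disks = 20L, truth_phases = NULL) {
  pick <- function(vols) {
    if (is.null(truth_phases)) {
      ed <- which.max(vols); es <- which.min(vols)
    } else {
      ed <- truth_phases$ed_phase; es <- truth_phases$es_phase
    }
    list(ed = ed, es = es, edv = vols[ed], esv = vols[es])
  }
  if (inherits(x, "lv_phantom")) {
    tv <- truth_volumes(x)
    k <- pick(tv$volumes)
    return(.vol_result("TRUTH", k$edv, k$esv, k$ed, k$es))
  }
  if (inherits(x, "lv_stack")) {
    vols <- vapply(seq_len(x$n_phases), function(p) slice_summation(x, p),
                   numeric(1))
    k <- pick(vols)
    tag <- if (identical(x$tag, "CMR")) "CMR" else "US4D"
    return(.vol_result(tag, k$edv, k$esv, k$ed, k$es))
  }
  if (inherits(x, "lv_laxcontour")) {
    vols <- simpson_monoplane(x, n_disks = n_disks)
    k <- pick(vols)
    return(.vol_result("US2D", k$edv, k$esv, k$ed, k$es))
  }
  if (inherits(x, "lv_mmode")) {
    if (!is.null(truth_phases)) {
      edv <- teichholz_volume(x$lvid[truth_phases$ed_phase])
      esv <- teichholz_volume(x$lvid[truth_phases$es_phase])
      return(.vol_result("MMODE", edv, esv,
                         truth_phases$ed_phase, truth_phases$es_phase))
    }
    return(mmode_result(x))
  }
  stop("unsupported acquisition object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

#' Bind volumetry results into the standard results table
#'
#' @param results list of `lv_volumetry` objects.
#' @param subject subject id attached to every row.
#' @return data.frame: subject, modality, EDV_uL, ESV_uL, SV_uL, EF_pct.
#' @export
volumetry_table <- function(results, subject = 1L) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(subject = subject, modality = r$modality,
               EDV_uL = r$edv, ESV_uL = r$esv, SV_uL = r$sv, EF_pct = r$ef)
  }))
}
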