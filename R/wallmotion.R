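#' The 16-segment model
#'
#' Three short-axis levels: the apical level is divided into 4 quadrants
#' centred on the anterior (A), lateral (L), inferior (I) and septal (S)
#' walls; the mid and basal levels into 6 sextants in the order A, AL,
#' IL, I, IS, AS (anterior, anterior-lateral, inferior-lateral,
#' inferior, inferior-septal, anterior-septal). Azimuth 0 is anterior,
#' increasing toward lateral.
#'
#' @return data.frame: level, label, theta_center, half_width (degrees).
#' @export
segment_model_16 <- function() {
  rbind(
    data.frame(level = "apical", label = c("A", "L", "I", "S"),
               theta_center = c(0, 90, 180, 270), half_width = 45),
    data.frame(level = "mid",
               label = c("A", "AL", "IL", "I", "IS", "AS"),
               theta_center = c(0, 60, 120, 180, 240, 300), half_width = 30),
    data.frame(level = "basal",
               label = c("A", "AL", "IL", "I", "IS", "AS"),
               theta_center = c(0, 60, 120, 180, 240, 300), half_width = 30)
  )
}

#' Wall-motion scoring thresholds
#'
#' Quantitative surrogates for visual grading, expressed on the relative
#' excursion `q = FE / normal_reference_FE`: normal `q >= normal_min`;
#' hypokinetic `hypo_min <= q < normal_min`; akinetic `|q| < hypo_min`;
#' dyskinetic `q <= -hypo_min`; aneurysmal when the segment's
#' end-diastolic radius exceeds the slice reference radius by more than
#' `bulge_tol`. Chosen so a fully normal phantom scores all 1 and each
#' phantom dysfunction class maps to its nominal grade.
#'
#' @param normal_min,hypo_min,bulge_tol threshold values.
#' @return a named list of thresholds.
#' @export
wmsi_thresholds <- function(normal_min = 0.55, hypo_min = 0.20,
                            bulge_tol = 0.10) {
  list(normal_min = normal_min, hypo_min = hypo_min, bulge_tol = bulge_tol)
}

#' Select the three wall-motion slices from a stack
#'
#' Returns the indices of the slices whose centres are nearest 1, 3 and
#' 5 mm above the apex (the standardised apical/mid/basal levels); ties
#' break toward the apex.
#'
#' @param stack an `lv_stack`.
#' @param levels_mm target elevations, mm.
#' @return integer vector of slice indices (apical, mid, basal).
#' @export
select_wmsi_slices <- function(stack, levels_mm = c(1, 3, 5)) {
  stopifnot(inherits(stack, "lv_stack"))
  ctr <- stack$centers
  if (max(ctr) < max(levels_mm) - 0.5)
    stop(sprintf(
      paste("stack reaches only %.1f mm above the apex but the basal",
            "wall-motion level is at %g mm; extend the acquisition range",
            "(more slices or a more basal stop)"),
      max(ctr), max(levels_mm)), call. = FALSE)
  vapply(levels_mm, function(lv) {
    d <- abs(ctr - lv)
    # tie toward the apex: among equal distances pick the smallest centre
    cand <- which(d < min(d) + 1e-9)
    cand[which.min(ctr[cand])]
  }, integer(1))
}

#' Fractional radial excursion of a segment
#'
#' Mean over the segment's azimuth range of
#' `(r_ED(theta) - r_ES(theta)) / r_ED(theta)`, for two polygons sharing
#' the same vertex azimuths.
#'
#' @param r_ed,r_es vertex radii at end-diastole / end-systole.
#' @param theta vertex azimuths, degrees.
#' @param theta_center,half_width segment angular range.
#' @return dimensionless fractional excursion (positive inward).
#' @export
segment_excursion <- function(r_ed, r_es, theta, theta_center, half_width) {
  stopifnot(length(r_ed) == length(theta), length(r_es) == length(theta))
  sel <- abs(ang_diff(theta, theta_center)) < half_width
  if (!any(sel)) stop("segment angular range contains no vertices", call. = FALSE)
  if (any(r_ed[sel] <= 0))
    stop("end-diastolic radius is zero inside the segment; slice degenerate",
         call. = FALSE)
  mean((r_ed[sel] - r_es[sel]) / r_ed[sel])
}

#' Score one segment
#'
#' Grades 1 (normal), 2 (hypokinetic), 3 (akinetic), 4 (dyskinetic),
#' 5 (aneurysmal) from the relative excursion
#' `q = fe / normal_reference_fe` and the aneurysm flag.
#'
#' @param fe fractional excursion of the segment.
#' @param aneurysm_flag static outward bulge detected at end-diastole.
#' @param normal_reference_fe reference excursion of normally
#'   contracting myocardium (> 0).
#' @param thresholds a [wmsi_thresholds()] list.
#' @return integer score in 1..5.
#' @export
score_segment <- function(fe, aneurysm_flag, normal_reference_fe,
                          thresholds = wmsi_thresholds()) {
  if (!is.numeric(normal_reference_fe) || normal_reference_fe <= 0)
    stop_param("normal_reference_fe", "must be > 0")
  if (aneurysm_flag) return(5L)
  q <- fe / normal_reference_fe
  if (q >= thresholds$normal_min) 1L
  else if (q >= thresholds$hypo_min) 2L
  else if (abs(q) < thresholds$hypo_min) 3L
  else 4L
}

#' Score a contour stack on the 16-segment model
#'
#' Selects the 1/3/5 mm slices, computes each segment's fractional
#' excursion between the stack's own ED and ES phases (maximal and
#' minimal summed volume), flags aneurysmal segments whose ED radius
#' exceeds the slice's median segment radius by more than the bulge
#' tolerance, and grades every segment. The default normal-reference
#' excursion is the mean excursion of the best-moving quartile of
#' segments (the remote zone); pass `normal_reference_fe` to use a
#' cohort-level reference instead.
#'
#' @param stack an `lv_stack`.
#' @param normal_reference_fe optional explicit reference excursion.
#' @param thresholds a [wmsi_thresholds()] list.
#' @param truth_phases optional forced ED/ES phases.
#' @return an object of class `lv_segment_scores`: data.frame with
#'   level, label, fe, aneurysm, score; attribute `wmsi`.
#' @export
score_stack <- function(stack, normal_reference_fe = NULL,
                        thresholds = wmsi_thresholds(), truth_phases = NULL) {
  stopifnot(inherits(stack, "lv_stack"))
  vols <- vapply(seq_len(stack$n_phases), function(p) slice_summation(stack, p),
                 numeric(1))
  ed <- truth_phases$ed_phase %||% which.max(vols)
  es <- truth_phases$es_phase %||% which.min(vols)
  idx <- select_wmsi_slices(stack)
  segs <- segment_model_16()
  level_slice <- c(apical = idx[1], mid = idx[2], basal = idx[3])
  rows <- lapply(seq_len(nrow(segs)), function(k) {
    s <- segs[k, ]
    sl <- level_slice[[s$level]]
    r_ed <- stack$endo[[sl]][ed, ]
    r_es <- stack$endo[[sl]][es, ]
    sel <- abs(ang_diff(stack$theta, s$theta_center)) < s$half_width
    data.frame(level = s$level, label = s$label,
               fe = segment_excursion(r_ed, r_es, stack$theta,
                                      s$theta_center, s$half_width),
               seg_r_ed = mean(r_ed[sel]))
  })
  df <- do.call(rbind, rows)
  # aneurysm: ED radius above the slice's median segment radius
  df$aneurysm <- FALSE
  for (lv in unique(df$level)) {
    i <- df$level == lv
    ref_r <- stats::median(df$seg_r_ed[i])
    df$aneurysm[i] <- df$seg_r_ed[i] > (1 + thresholds$bulge_tol) * ref_r
  }
  ref_fe <- normal_reference_fe %||% {
    top <- sort(df$fe, decreasing = TRUE)[seq_len(max(1L, nrow(df) %/% 4L))]
    mean(top)
  }
  if (!is.numeric(ref_fe) || ref_fe <= 0)
    stop("cannot establish a positive normal-reference excursion; supply normal_reference_fe",
         call. = FALSE)
  df$score <- vapply(seq_len(nrow(df)), function(k)
    score_segment(df$fe[k], df$aneurysm[k], ref_fe, thresholds), integer(1))
  df$seg_r_ed <- NULL
  structure(df, class = c("lv_segment_scores", "data.frame"),
            wmsi = mean(df$score), normal_reference_fe = ref_fe,
            ed_phase = ed, es_phase = es)
}

#' Wall motion score index
#'
#' The unweighted arithmetic mean of the 16 segment scores.
#'
#' @param scores an `lv_segment_scores` from [score_stack()], or a bare
#'   numeric vector of 16 scores in 1..5.
#' @return WMSI, a dimensionless value in [1, 5].
#' @export
#' @examples
#' wmsi(c(5, 4, 4, 3, 3, 2, 2, 2, rep(1, 8))) # 2.0625
wmsi <- function(scores) {
  if (inherits(scores, "lv_segment_scores")) scores <- scores$score
  if (!is.numeric(scores) || length(scores) != 16)
    stop("exactly 16 segment scores are required", call. = FALSE)
  if (any(scores < 1 | scores > 5))
    stop("segment scores must lie in 1..5", call. = FALSE)
  mean(scores)
}
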