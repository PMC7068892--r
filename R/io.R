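# Plain-text serialisation: phantom parameters and study configs as
# JSON, contour stacks and result tables as headed CSV. Readers accept
# externally produced files with the same schema, so measured contour
# stacks can be pushed through the same estimators as emulated ones.

#' Serialise phantom parameters to JSON
#'
#' @param params an [phantom_params()] object.
#' @param path file path; when `NULL` the JSON string is returned.
#' @return the path (invisibly) or a JSON string.
#' @export
write_phantom_params <- function(params, path = NULL) {
  stopifnot(inherits(params, "lv_phantom_params"))
  x <- unclass(params)
  if (!is.null(x$infarct)) x$infarct <- unclass(x$infarct)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read phantom parameters from JSON
#'
#' @param path file path or JSON string.
#' @return an `lv_phantom_params` object.
#' @export
read_phantom_params <- function(path) {
  x <- jsonlite::fromJSON(path)
  inf <- if (!is.null(x$infarct))
    do.call(infarct_spec, x$infarct)
  phantom_params(base_radius_ed = x$base_radius_ed,
                 long_axis_length_ed = x$long_axis_length_ed,
                 wall_thickness_ed = x$wall_thickness_ed,
                 n_phases = x$n_phases,
                 radial_contraction = x$radial_contraction,
                 longitudinal_shortening = x$longitudinal_shortening,
                 infarct = inf,
                 base_hyperkinesis_gain = x$base_hyperkinesis_gain,
                 seed = x$seed)
}

#' Write a contour stack as long-format CSV
#'
#' One row per (slice, phase, vertex) with columns subject, slice,
#' slice_center_z, thickness, phase, vertex, x, y. Only the endocardial
#' boundary is serialised.
#'
#' @param stack an `lv_stack`.
#' @param path output path.
#' @param subject subject id written into every row.
#' @return the path, invisibly.
#' @export
write_contour_stack_csv <- function(stack, path, subject = 1L) {
  stopifnot(inherits(stack, "lv_stack"))
  rows <- list()
  for (i in seq_along(stack$centers)) {
    for (p in seq_len(stack$n_phases)) {
      xy <- stack_polygon(stack, i, p)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, slice = i, slice_center_z = stack$centers[i],
        thickness = stack$thickness, phase = p,
        vertex = seq_len(nrow(xy)), x = xy[, 1], y = xy[, 2])
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a contour stack from long-format CSV
#'
#' Accepts the schema written by [write_contour_stack_csv()]. Vertex
#' azimuths are reconstructed about the end-diastolic slice centroid so
#' wall-motion scoring works on external stacks; polygons are checked
#' for simplicity.
#'
#' @param path CSV path.
#' @param subject subject id to extract (files may hold several).
#' @param tag acquisition tag to attach.
#' @return an `lv_stack`.
#' @export
read_contour_stack_csv <- function(path, subject = NULL, tag = "4D") {
  df <- utils::read.csv(path)
  need <- c("subject", "slice", "slice_center_z", "thickness", "phase",
            "vertex", "x", "y")
  if (!all(need %in% names(df)))
    stop("contour CSV lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  if (!is.null(subject)) df <- df[df$subject == subject, ]
  if (nrow(df) == 0) stop("no rows for the requested subject", call. = FALSE)
  slices <- sort(unique(df$slice))
  centers <- vapply(slices, function(s)
    df$slice_center_z[df$slice == s][1], numeric(1))
  if (any(diff(centers) <= 0))
    stop("slice centers must be strictly increasing", call. = FALSE)
  n_phases <- max(df$phase)
  thickness <- df$thickness[1]
  endo <- lapply(slices, function(s) {
    sub <- df[df$slice == s, ]
    nv <- max(sub$vertex)
    m <- matrix(NA_real_, n_phases, nv)
    ctr <- NULL
    for (p in seq_len(n_phases)) {
      sp <- sub[sub$phase == p, ]
      sp <- sp[order(sp$vertex), ]
      if (nrow(sp) != nv) stop("ragged vertex counts in contour CSV",
                               call. = FALSE)
      if (!all(abs(sp$x) < 1e-12 & abs(sp$y) < 1e-12) &&
          !is_simple_polygon(sp$x, sp$y))
        stop(sprintf("slice %d phase %d polygon is self-intersecting", s, p),
             call. = FALSE)
      if (is.null(ctr)) ctr <- c(mean(sp$x), mean(sp$y))
      m[p, ] <- sqrt((sp$x - ctr[1])^2 + (sp$y - ctr[2])^2)
    }
    m
  })
  # azimuths from the first slice's first phase
  first <- df[df$slice == slices[1] & df$phase == 1, ]
  first <- first[order(first$vertex), ]
  ctr <- c(mean(first$x), mean(first$y))
  theta <- (atan2(first$y - ctr[2], first$x - ctr[1]) * 180 / pi) %% 360
  structure(list(centers = centers, thickness = thickness, theta = theta,
                 endo = endo, epi = NULL, n_phases = n_phases, tag = tag),
            class = "lv_stack")
}

#' Write all study tables to a directory
#'
#' Emits `volumetry.csv`, `truth.csv`, `agreement.csv`, `icc.csv`,
#' `wmsi.csv`, `wmsi_segments.csv`, `strain.csv`, `correlation.csv`,
#' `summary.md`, `config.json` and `run.log`; every table carries the
#' configuration hash in a comment-free companion (`config.json`).
#'
#' @param study an `lv_study`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "lv_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("volumetry", "truth", "agreement", "icc", "wmsi",
            "wmsi_segments", "strain", "correlation")
  for (t in tabs) {
    df <- study[[t]]
    df$config_hash <- study$config$hash
    utils::write.csv(df, file.path(dir, paste0(t, ".csv")), row.names = FALSE)
  }
  writeLines(study_summary(study), file.path(dir, "summary.md"))
  cfg <- study$config
  cfg$cohort$base_params <- unclass(cfg$cohort$base_params)
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              force = TRUE),
             file.path(dir, "config.json"))
  writeLines(study$log, file.path(dir, "run.log"))
  invisible(dir)
}
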