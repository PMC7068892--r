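# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signed angular difference
#'
#' Difference `a - b` wrapped into (-180, 180] degrees.
#' @param a,b angles in degrees.
#' @return numeric vector of wrapped differences.
#' @keywords internal
#' @noRd
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Shoelace area of a closed polygon
#'
#' @param x,y vertex coordinates; the polygon is closed implicitly
#'   (last vertex joins the first). Orientation is normalised away:
#'   the absolute area is returned.
#' @return area in the square of the coordinate unit.
#' @export
shoelace_area <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  xs <- c(x[-1L], x[1L])
  ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

#' Perimeter of a closed polygon
#' @param x,y vertex coordinates (closed implicitly).
#' @return total edge length.
#' @export
polygon_perimeter <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  sum(sqrt(diff(c(x, x[1L]))^2 + diff(c(y, y[1L]))^2))
}

# Open-polyline arc length.
polyline_length <- function(x, y) sum(sqrt(diff(x)^2 + diff(y)^2))

# O(n^2) simplicity test used when validating externally supplied contours;
# adjacent edges sharing a vertex are not counted as intersections.
is_simple_polygon <- function(x, y) {
  n <- length(x)
  if (n < 3) return(FALSE)
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  seg_int <- function(i, j) {
    d1 <- c(x2[i] - x[i], y2[i] - y[i])
    d2 <- c(x2[j] - x[j], y2[j] - y[j])
    den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
    if (abs(den) < 1e-14) return(FALSE) # parallel: ignore (degenerate overlap unhandled)
    t <- ((x[j] - x[i]) * d2[2L] - (y[j] - y[i]) * d2[1L]) / den
    u <- ((x[j] - x[i]) * d1[2L] - (y[j] - y[i]) * d1[1L]) / den
    t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in seq.int(i + 2L, jmax)) {
      if (seg_int(i, j)) return(FALSE)
    }
  }
  TRUE
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used to stamp study outputs with a configuration fingerprint without
# adding a digest dependency.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    # XOR on the low byte only (b < 256), keeping h in double arithmetic
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    # 32-bit modular multiply by 16777619, split to stay within double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Evaluate thunk with a temporary RNG state seeded from `seed`; the caller's
# RNG stream is untouched. NULL seed runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a reproducible child seed below 2^31 from a master seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 69069 + index * 1013904223) %% 2147483647)
}

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}
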