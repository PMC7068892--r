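#' Percentage Bland-Altman agreement
#'
#' Pairwise percentage differences between a test series `b` and a
#' reference series `a`: `d_i = 100 (b_i - a_i) / ((a_i + b_i) / 2)`.
#' The bias is the mean difference and the 95% limits of agreement are
#' `bias +/- 1.96 * SD` (sample SD, n - 1 denominator). The sign
#' convention is test minus reference.
#'
#' @param a reference measurements.
#' @param b test measurements (same length, complete pairs).
#' @return an object of class `lv_blandaltman`: list with `differences`,
#'   `bias`, `loa_low`, `loa_high`, `sd`, `n`, `means`.
#' @export
#' @examples
#' bland_altman_percent(c(50, 60), c(55, 54))
bland_altman_percent <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ", call. = FALSE)
  if (length(a) < 2) stop("at least 2 pairs are required", call. = FALSE)
  if (anyNA(a) || anyNA(b)) {
    keep <- stats::complete.cases(a, b)
    a <- a[keep]; b <- b[keep]
    if (length(a) < 2) stop("fewer than 2 complete pairs", call. = FALSE)
  }
  avg <- (a + b) / 2
  zero <- which(abs(avg) < .Machine$double.eps)
  if (length(zero))
    stop(sprintf("pair %d has zero average; percentage difference undefined",
                 zero[1]), call. = FALSE)
  d <- 100 * (b - a) / avg
  s <- stats::sd(d)
  bias <- mean(d)
  structure(list(differences = d, means = avg, bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d)),
            class = "lv_blandaltman")
}

#' @export
print.lv_blandaltman <- function(x, ...) {
  cat(sprintf("Bland-Altman (%%): bias %.2f%%, 95%% LOA [%.2f, %.2f], n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Single-measure intraclass correlation, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation from the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with `MSR`,
#' `MSC`, `MSE` the subject, rater and residual mean squares. This is
#' the standard form for the reliability of single measurements between
#' raters; negative estimates are reported as computed.
#'
#' @param m numeric matrix, subjects in rows, raters in columns
#'   (complete, `n >= 2`, `k >= 2`).
#' @return an object of class `lv_icc`: list with `icc`, `msr`, `msc`,
#'   `mse`, `n`, `k`.
#' @export
icc_single <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells are not allowed (no imputation)",
                     call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters",
                           call. = FALSE)
  grand <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  structure(list(icc = icc, msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "lv_icc")
}

#' @export
print.lv_icc <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f  (n = %d subjects, k = %d raters)\n",
              x$icc, x$n, x$k))
  invisible(x)
}

# all permutations of 1..n as a matrix (n! rows); n <= 9 in practice
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1L] <- i
    out[rows, -1L] <- ifelse(sub >= i, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with qualitative grading
#'
#' Rank correlation with average ranks for ties. The p-value uses the
#' t approximation for `n >= 10` and exhaustive permutation of the rank
#' vector (two-sided) for `n < 10`. The absolute coefficient is graded
#' on the printed bands: poor below 0.5, moderate 0.5 to below 0.7,
#' strong 0.7 to below 0.9, very strong 0.9 and above (boundary values
#' belong to the higher band).
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return an object of class `lv_correlation`: list with `rho`,
#'   `p_value`, `grade`, `n`, `method`. Constant input yields `rho = NA`
#'   with grade `"undefined"`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("at least 3 complete pairs are required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(rho = NA_real_, p_value = NA_real_,
                          grade = "undefined", n = n, method = "none"),
                     class = "lv_correlation"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n < 10) {
    perms <- .permutations(n)
    rho_null <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  grade <- if (abs(rho) >= 0.9) "very strong"
           else if (abs(rho) >= 0.7) "strong"
           else if (abs(rho) >= 0.5) "moderate"
           else "poor"
  structure(list(rho = rho, p_value = p, grade = grade, n = n,
                 method = method),
            class = "lv_correlation")
}

#' @export
print.lv_correlation <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (%s), p = %.4g (%s), n = %d\n",
              x$rho, x$grade, x$p_value, x$method, x$n))
  invisible(x)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino) and kurtosis
#' (Anscombe-Glynn) into `K2 = z_skew^2 + z_kurt^2`, referred to a
#' chi-square distribution with 2 degrees of freedom. The moment
#' transformations are asymptotic, so the test refuses samples smaller
#' than 20.
#'
#' @param x numeric sample (`n >= 20`).
#' @return list with `statistic` (K2), `z_skew`, `z_kurt`, `p_value`, `n`.
#' @export
dagostino_k2 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 20)
    stop("D'Agostino-Pearson K2 needs n >= 20; the moment approximations are unreliable below that",
         call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("sample is constant", call. = FALSE)
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2
  # skewness transformation (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis transformation (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  den <- 1 + xx * sqrt(2 / (a - 4))
  z2 <- ((1 - 2 / (9 * a)) -
           sign(den) * (abs((1 - 2 / a) / den))^(1 / 3)) / sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, z_skew = z1, z_kurt = z2,
       p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE), n = n)
}
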