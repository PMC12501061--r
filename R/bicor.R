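#' Biweight midcorrelation
#'
#' Robust correlation based on median/MAD standardization: with
#' `u = (x - median) / (9 * MAD)` (MAD unscaled), observations get Tukey
#' biweights `(1 - u^2)^2` inside `|u| < 1` and zero outside; the correlation
#' is the normalized cross-product of the weighted, median-centred vectors.
#' A vector with zero MAD cannot be standardized robustly and falls back to
#' Pearson standardization (mean/sd) with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3, finite values.
#' @return correlation in [-1, 1].
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("bicor needs length >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  crossprod(bicor_standardize(x), bicor_standardize(y))[1]
}

# median/MAD biweight standardization to a unit-norm vector; Pearson
# (mean/sd) fallback when MAD = 0
bicor_standardize <- function(x, warn = TRUE) {
  med <- stats::median(x)
  madx <- stats::mad(x, constant = 1)
  if (madx == 0) {
    if (warn) warning("zero MAD; falling back to Pearson standardization")
    s <- stats::sd(x)
    if (s == 0) return(rep(0, length(x)))
    v <- (x - mean(x))
    return(v / sqrt(sum(v^2)))
  }
  u <- (x - med) / (9 * madx)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  v <- (x - med) * w
  v / sqrt(sum(v^2))
}

#' Biweight midcorrelation matrix
#'
#' Column-wise bicor of one or two matrices (observations in rows). Columns
#' with zero MAD silently use the Pearson fallback.
#'
#' @param x numeric matrix, observations x variables.
#' @param y optional second matrix with the same number of rows.
#' @return correlation matrix, `ncol(x)` x `ncol(y %||% x)`.
#' @export
bicor_matrix <- function(x, y = NULL) {
  sx <- apply(x, 2, bicor_standardize, warn = FALSE)
  if (is.null(y)) {
    r <- crossprod(sx)
  } else {
    if (nrow(x) != nrow(y)) stop("x and y must have the same rows")
    r <- crossprod(sx, apply(y, 2, bicor_standardize, warn = FALSE))
  }
  pmin(pmax(r, -1), 1)
}

# pairwise-complete bicor for vectors with missing values
bicor_pairwise <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(list(r = NA_real_, n = sum(ok)))
  list(r = suppressWarnings(bicor(x[ok], y[ok])), n = sum(ok))
}

#' Student p-value for a correlation
#'
#' Two-sided p from the t statistic `r * sqrt((n-2)/(1-r^2))` on `n - 2`
#' degrees of freedom. `|r| = 1` returns p = 0.
#'
#' @param r correlation value(s).
#' @param n number of observations used.
#' @return p-value(s) in [0, 1].
#' @export
correlation_student_p <- function(r, n) {
  if (any(n < 3, na.rm = TRUE)) stop("need n >= 3")
  p <- rep(NA_real_, length(r))
  exact <- !is.na(r) & abs(r) >= 1
  p[exact] <- 0
  ok <- !is.na(r) & !exact
  nn <- if (length(n) == 1) rep(n, length(r)) else n
  t_ <- r[ok] * sqrt((nn[ok] - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(t_), df = nn[ok] - 2)
  p
}
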