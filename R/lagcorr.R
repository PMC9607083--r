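#' Time-lagged Pearson correlation
#'
#' A lagged correlation curve evaluates the Pearson correlation between
#' two weekly series at every integer lag in `[-max_lag, +max_lag]`. The
#' lag is applied to the *second* series: at positive lag `k` the first
#' series' present is paired with the second series' value `k` weeks
#' earlier, so a peak at `k > 0` means the second series leads (its past
#' predicts the first's present).
#'
#' @name lagcorr
NULL

#' Align two series at a given lag
#'
#' Positive lag `k` pairs `x[t]` with `y[t - k]`; negative lag pairs
#' `x[t]` with `y[t + |k|]`. The overlap is truncated (no wrap-around),
#' leaving `n = N - |lag|` pairs.
#'
#' @param x,y Equal-length numeric vectors or [weekly_series()] on the
#'   same index.
#' @param lag Integer lag in weeks.
#' @return List with components `x`, `y` (aligned values) and `n`.
#' @export
shift_pair <- function(x, y, lag = 0L) {
  xv <- if (inherits(x, "weekly_series")) x$values else as.numeric(x)
  yv <- if (inherits(y, "weekly_series")) y$values else as.numeric(y)
  if (length(xv) != length(yv)) {
    stop("series must share the weekly index", call. = FALSE)
  }
  n <- length(xv)
  k <- as.integer(lag)
  if (abs(k) >= n) {
    stop("|lag| must be smaller than the series length (empty overlap)",
         call. = FALSE)
  }
  if (k >= 0) {
    list(x = xv[(k + 1):n], y = yv[1:(n - k)], n = n - k)
  } else {
    list(x = xv[1:(n + k)], y = yv[(-k + 1):n], n = n + k)
  }
}

#' Pearson correlation with a t-test p-value
#'
#' `r` from the standard product-moment formula; the two-sided p-value
#' comes from the t transform with `n - 2` degrees of freedom. A
#' constant vector has no defined correlation and yields `NA` markers
#' rather than a number.
#'
#' @param xs,ys Equal-length complete numeric vectors.
#' @return List with `r`, `p` and `n`.
#' @export
pearson <- function(xs, ys) {
  n <- length(xs)
  if (length(ys) != n) stop("length mismatch", call. = FALSE)
  if (n < 3 || stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(xs, ys, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Lagged Pearson correlation curve
#'
#' @param x,y [weekly_series()] (or numeric vectors) on a common index.
#' @param max_lag Maximum absolute lag in weeks; the default 10 gives the
#'   standard 21-value curve, 20 the extended screen for slow-response
#'   relations.
#' @return A `lag_corr_curve`: tibble with columns `lag`, `r`, `p`, `n`
#'   (one row per lag, `2 * max_lag + 1` rows) and attributes `pair`.
#' @export
lagged_pearson <- function(x, y, max_lag = 10L) {
  if (max_lag < 0) stop("`max_lag` must be >= 0", call. = FALSE)
  lags <- seq.int(-max_lag, max_lag)
  rows <- lapply(lags, function(k) {
    al <- shift_pair(x, y, k)
    c(pearson(al$x, al$y), list(lag = k))
  })
  out <- tibble::tibble(
    lag = lags,
    r = vapply(rows, `[[`, 0, "r"),
    p = vapply(rows, `[[`, 0, "p"),
    n = vapply(rows, function(z) as.integer(z$n), 0L)
  )
  attr(out, "pair") <- c(
    if (inherits(x, "weekly_series")) x$series_id else "x",
    if (inherits(y, "weekly_series")) y$series_id else "y"
  )
  class(out) <- c("lag_corr_curve", class(out))
  out
}

# ---------------------------------------------------------------------
# Detrended (partial) cross-correlation analysis
# ---------------------------------------------------------------------

#' Cumulative-deviation profile of a series
#'
#' `X[t] = sum_{i<=t} (x[i] - mean(x))`; the integrated object whose
#' local linear detrending defines the DFA/DCCA fluctuation functions.
#' The final profile value is zero up to rounding (the deviations
#' telescope).
#'
#' @param x Complete numeric vector (impute first; missing values are an
#'   error).
#' @return Numeric vector of the same length.
#' @export
build_profile <- function(x) {
  x <- if (inherits(x, "weekly_series")) x$values else as.numeric(x)
  if (anyNA(x)) stop("profile requires a complete series; impute first",
                     call. = FALSE)
  cumsum(x - mean(x))
}

# residual-maker matrix for an OLS line fit on positions 1..s
residual_maker <- function(s) {
  A <- cbind(1, seq_len(s))
  diag(s) - A %*% solve(crossprod(A), t(A))
}

# profile windows of length s as an s x (N - s + 1) matrix
profile_windows <- function(P, s) {
  n <- length(P)
  nwin <- n - s + 1L
  matrix(P[outer(0:(s - 1L), seq_len(nwin), "+")], nrow = s)
}

#' Residuals of the windowed linear fit of a profile
#'
#' OLS line fitted to profile values at positions `j .. j+s-1` against
#' position; returns the residuals (used by [detrended_moments()]).
#'
#' @param P Profile vector (see [build_profile()]).
#' @param s Window size, `>= 3`.
#' @param j Window start, `1 <= j <= length(P) - s + 1`.
#' @return Numeric residual vector of length `s`.
#' @export
window_residuals <- function(P, s, j) {
  n <- length(P)
  if (s > n) stop("`s` exceeds the profile length", call. = FALSE)
  if (s < 3) stop("`s` must be >= 3", call. = FALSE)
  if (j < 1 || j > n - s + 1) stop("window start out of range", call. = FALSE)
  seg <- P[j:(j + s - 1)]
  k <- seq_len(s)
  fit <- stats::lm.fit(cbind(1, k), seg)
  as.numeric(fit$residuals)
}

#' Windowed detrended covariance and variance moments
#'
#' For every overlapping window `j = 1 .. N-s+1` (step 1) of the two
#' series' profiles, fits an OLS line and accumulates the detrended
#' cross moment `f2_dcca(s,j) = sum(res_x * res_y) / (s - 1)` and the
#' detrended variances `f2_dfa(s,j) = sum(res^2) / (s - 1)`. Aggregates
#' divide the window sums by `N - s`. (Some printed statements of the
#' per-window DFA moment omit the square on the residual; the squared
#' form — standard DFA — is what makes `f2_dfa` a variance and is used
#' here.)
#'
#' @param x,y Equal-length complete numeric vectors (or
#'   [weekly_series()]).
#' @param s Window size, `3 <= s <= N`.
#' @return List with per-window vectors `f2_dcca`, `f2_dfa_x`,
#'   `f2_dfa_y` and aggregates `F2_dcca`, `F2_dfa_x`, `F2_dfa_y`
#'   (aggregates are `NA` when `s = N` leaves the `N - s` denominator
#'   empty; the coefficient ratio in [dcca_coefficient()] is still
#'   defined from the window sums).
#' @export
detrended_moments <- function(x, y, s) {
  xv <- if (inherits(x, "weekly_series")) x$values else as.numeric(x)
  yv <- if (inherits(y, "weekly_series")) y$values else as.numeric(y)
  n <- length(xv)
  if (length(yv) != n) stop("series must have equal length", call. = FALSE)
  if (s < 3 || s > n) stop("`s` must satisfy 3 <= s <= N", call. = FALSE)
  Px <- build_profile(xv)
  Py <- build_profile(yv)
  M <- residual_maker(s)
  Rx <- M %*% profile_windows(Px, s)
  Ry <- M %*% profile_windows(Py, s)
  f2_dcca <- colSums(Rx * Ry) / (s - 1)
  f2_dfa_x <- colSums(Rx * Rx) / (s - 1)
  f2_dfa_y <- colSums(Ry * Ry) / (s - 1)
  denom <- n - s
  agg <- function(v) if (denom > 0) sum(v) / denom else NA_real_
  list(s = s, n = n, n_windows = n - s + 1L,
       f2_dcca = f2_dcca, f2_dfa_x = f2_dfa_x, f2_dfa_y = f2_dfa_y,
       F2_dcca = agg(f2_dcca), F2_dfa_x = agg(f2_dfa_x),
       F2_dfa_y = agg(f2_dfa_y))
}

#' DCCA cross-correlation coefficient at scale s
#'
#' `rho(s) = F2_dcca / (F_dfa_x * F_dfa_y)`: the ratio of the aggregate
#' detrended covariance to the two aggregate detrended standard
#' fluctuations, a scale-dependent correlation bounded in \[-1, 1\] by
#' Cauchy-Schwarz. A series whose profile has zero fluctuation at scale
#' `s` (e.g. a constant series) has no defined coefficient and yields
#' `NA`.
#'
#' @inheritParams detrended_moments
#' @return Scalar in \[-1, 1\], or `NA` when undefined.
#' @export
dcca_coefficient <- function(x, y, s) {
  mom <- detrended_moments(x, y, s)
  sx <- sum(mom$f2_dfa_x)
  sy <- sum(mom$f2_dfa_y)
  if (sx <= 0 || sy <= 0) return(NA_real_)
  sum(mom$f2_dcca) / sqrt(sx * sy)
}

#' Pairwise DCCA coefficient matrix
#'
#' @param series Named list of equal-length complete numeric vectors
#'   (at least 2).
#' @param s Window size.
#' @return Symmetric matrix with unit diagonal; an error lists any
#'   series pair whose coefficient is undefined.
#' @export
dcca_matrix <- function(series, s) {
  if (length(series) < 2) stop("need at least 2 series", call. = FALSE)
  ids <- names(series)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("`series` must be a uniquely named list", call. = FALSE)
  }
  m <- length(series)
  rho <- diag(1, m)
  dimnames(rho) <- list(ids, ids)
  bad <- character()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      v <- dcca_coefficient(series[[i]], series[[j]], s)
      if (is.na(v)) bad <- c(bad, paste(ids[i], ids[j], sep = "~"))
      rho[i, j] <- rho[j, i] <- v
    }
  }
  if (length(bad)) {
    stop("undefined DCCA coefficient for pair(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rho
}

#' Detrended partial cross-correlation coefficient
#'
#' Inverts the DCCA coefficient matrix `rho(s)` over the conditioning
#' set and reads the partial coefficient off the precision matrix:
#' `rho_dpcca(x, y; s) = -C[x,y] / sqrt(C[x,x] * C[y,y])` with
#' `C = rho(s)^-1`. With a conditioning set of exactly the pair, this
#' reduces to [dcca_coefficient()].
#'
#' @param series Named list of complete series; must contain both
#'   members of `pair`.
#' @param pair Character vector of the two target series names.
#' @param s Window size.
#' @param max_condition Condition-number guard for the inversion; a
#'   nearly singular matrix (collinear conditioning series) is an error.
#' @return Scalar partial coefficient.
#' @export
dpcca <- function(series, pair, s, max_condition = 1e10) {
  stopifnot(length(pair) == 2, all(pair %in% names(series)))
  rho <- dcca_matrix(series, s)
  kap <- kappa(rho, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition) {
    stop("DCCA matrix is near-singular (condition number ",
         format(kap, digits = 3),
         "); drop collinear conditioning series", call. = FALSE)
  }
  C <- solve(rho)
  -C[pair[1], pair[2]] / sqrt(C[pair[1], pair[1]] * C[pair[2], pair[2]])
}

#' Lagged multi-scale DPCCA curves
#'
#' For each lag the second series is shifted under the [shift_pair()]
#' convention, every series (pair and conditioning set) is truncated to
#' the overlap, and profiles and coefficients are recomputed on that
#' overlap — each lag is a self-contained computation. The default
#' scale set 4, 12, 26, 52 weeks reads as month, trimester, semester
#' and year.
#'
#' @param x,y [weekly_series()] or numeric vectors on a common index;
#'   `y` is the shifted (potentially leading) series.
#' @param conditioning Named list of additional complete series on the
#'   same index (empty for plain pairwise DCCA). Conditioning series
#'   are aligned with `x`'s timeline.
#' @param max_lag Maximum absolute lag in weeks.
#' @param scales Integer vector of window sizes.
#' @return Tibble with columns `lag`, `scale`, `rho` (`NA` where the
#'   overlap is shorter than the scale), attribute `pair`.
#' @export
lagged_dpcca <- function(x, y, conditioning = list(), max_lag = 10L,
                         scales = c(4L, 12L, 26L, 52L)) {
  xv <- if (inherits(x, "weekly_series")) x$values else as.numeric(x)
  yv <- if (inherits(y, "weekly_series")) y$values else as.numeric(y)
  cond <- lapply(conditioning, function(z) {
    if (inherits(z, "weekly_series")) z$values else as.numeric(z)
  })
  n <- length(xv)
  lags <- seq.int(-max_lag, max_lag)
  rows <- list()
  for (k in lags) {
    al <- shift_pair(xv, yv, k)
    x_rows <- if (k >= 0) (k + 1):n else 1:(n + k)
    cond_k <- lapply(cond, `[`, x_rows)
    for (s in scales) {
      rho <- NA_real_
      if (s + 1 <= al$n) {
        sers <- c(list(.x = al$x, .y = al$y), cond_k)
        rho <- if (length(cond_k)) {
          dpcca(sers, c(".x", ".y"), s)
        } else {
          dcca_coefficient(al$x, al$y, s)
        }
      }
      rows[[length(rows) + 1]] <- tibble::tibble(lag = k, scale = s, rho = rho)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "pair") <- c(
    if (inherits(x, "weekly_series")) x$series_id else "x",
    if (inherits(y, "weekly_series")) y$series_id else "y"
  )
  out
}
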