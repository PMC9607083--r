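# Shared fixtures and independent reference implementations.
# The naive_* functions deliberately use explicit loops, lm() fits and
# cofactor matrix inversion so they share no code path with the package.

small_config <- function(seed = 1L, ...) {
  synth_config(seed = seed, n_areas = 4L, south_areas = 1L, pivot_rank = 2L,
               start_date = "2015-01-05", end_date = "2016-12-26", ...)
}

# brute-force windowed detrended moments: one lm() per window
naive_moments <- function(x, y, s) {
  N <- length(x)
  Px <- cumsum(x - mean(x))
  Py <- cumsum(y - mean(y))
  nwin <- N - s + 1
  f2xy <- f2x <- f2y <- numeric(nwin)
  for (j in seq_len(nwin)) {
    k <- j:(j + s - 1)
    rx <- stats::resid(stats::lm(Px[k] ~ k))
    ry <- stats::resid(stats::lm(Py[k] ~ k))
    f2xy[j] <- sum(rx * ry) / (s - 1)
    f2x[j] <- sum(rx^2) / (s - 1)
    f2y[j] <- sum(ry^2) / (s - 1)
  }
  list(f2_dcca = f2xy, f2_dfa_x = f2x, f2_dfa_y = f2y,
       F2_dcca = sum(f2xy) / (N - s), F2_dfa_x = sum(f2x) / (N - s),
       F2_dfa_y = sum(f2y) / (N - s))
}

naive_dcca <- function(x, y, s) {
  m <- naive_moments(x, y, s)
  sum(m$f2_dcca) / sqrt(sum(m$f2_dfa_x) * sum(m$f2_dfa_y))
}

# cofactor inversion, written out for 2x2 and 3x3 only
naive_invert <- function(A) {
  if (nrow(A) == 2) {
    d <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
    matrix(c(A[2, 2], -A[2, 1], -A[1, 2], A[1, 1]), 2) / d
  } else if (nrow(A) == 3) {
    co <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      minor <- A[-i, -j, drop = FALSE]
      co[i, j] <- (-1)^(i + j) * (minor[1, 1] * minor[2, 2] - minor[1, 2] * minor[2, 1])
    }
    d <- sum(A[1, ] * co[1, ])
    t(co) / d
  } else {
    stop("naive_invert handles 2x2 and 3x3 only")
  }
}

naive_dpcca <- function(series, s) {
  m <- length(series)
  rho <- diag(1, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    rho[i, j] <- rho[j, i] <- naive_dcca(series[[i]], series[[j]], s)
  }
  C <- naive_invert(rho)
  -C[1, 2] / sqrt(C[1, 1] * C[2, 2])
}

# toxin pair with an exactly planted lead: both series integrate the same
# bloom pulse train through identical kinetics, but the forcing of the
# first (x) is delayed by `lead` weeks, so y's past predicts x's present
# and the cross-correlation peaks at +lead
planted_lead_pair <- function(seed, lead = 2L, n = 312L, noise_sd = 0.05,
                              elim = 0.4, uptake = 1) {
  set.seed(seed)
  env <- rep_len(1 + 0.8 * sin(2 * pi * seq_len(52) / 52), n + lead)
  P <- rbinom(n + lead, 1, 0.15) * rlnorm(n + lead, 0, 1) * env
  kin <- function(P) {
    T <- numeric(length(P))
    for (t in seq_len(length(P) - 1)) T[t + 1] <- (1 - elim) * T[t] + uptake * P[t]
    T
  }
  y <- kin(P[(lead + 1):(n + lead)])
  x <- kin(P[1:n])
  if (noise_sd > 0) {
    x <- x * exp(rnorm(n, 0, noise_sd))
    y <- y * exp(rnorm(n, 0, noise_sd))
  }
  list(x = x, y = y, lead = lead)
}
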