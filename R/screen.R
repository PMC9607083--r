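#' Correlation screening across pair classes
#'
#' The screen runs lagged correlation curves over every pair in a
#' comparison class — toxicity between production areas, between
#' co-occurring species, and toxicity against phytoplankton abundance or
#' environmental conditions — then applies the surveillance thresholds
#' (0.65 / 0.7 at any lag for Pearson, 0.9 for DPCCA), locates each
#' curve's peak lag and quantifies its asymmetry.
#'
#' @name screen
NULL

curve_value_col <- function(curve) {
  if ("r" %in% names(curve)) "r" else if ("rho" %in% names(curve)) "rho"
  else stop("curve has neither `r` nor `rho`", call. = FALSE)
}

#' Locate the lag at which a correlation curve peaks
#'
#' Returns the lag maximising the curve value. Ties break toward the
#' smallest absolute lag, then toward the negative lag.
#'
#' @param curve A [lagged_pearson()] or [lagged_dpcca()] tibble (for
#'   multi-scale DPCCA curves, filter to one scale first or the maximum
#'   over scales at each lag is used).
#' @return List with `lag` and `value`.
#' @export
peak_lag <- function(curve) {
  col <- curve_value_col(curve)
  df <- curve[!is.na(curve[[col]]), ]
  if (!nrow(df)) stop("curve has no defined entries", call. = FALSE)
  if ("scale" %in% names(df) && length(unique(df$scale)) > 1) {
    df <- dplyr::summarise(dplyr::group_by(df, .data$lag),
                           value = max(.data[[col]]), .groups = "drop")
    col <- "value"
  }
  best <- max(df[[col]])
  cand <- df[df[[col]] == best, ]
  cand <- cand[order(abs(cand$lag), cand$lag), ]
  list(lag = cand$lag[1], value = best)
}

#' Asymmetry of a lagged correlation curve
#'
#' Maximum over strictly positive lags minus maximum over strictly
#' negative lags. A positive index means the second series' past
#' predicts the first series' present better than the reverse — under
#' the species screen, that the second (faster-accumulating) species
#' leads.
#'
#' @inheritParams peak_lag
#' @return Scalar; 0 for an even-symmetric curve.
#' @export
asymmetry_index <- function(curve) {
  col <- curve_value_col(curve)
  df <- curve[!is.na(curve[[col]]), ]
  pos <- df[[col]][df$lag > 0]
  neg <- df[[col]][df$lag < 0]
  max_or <- function(v) if (length(v)) max(v) else 0
  max_or(pos) - max_or(neg)
}

# enumerate the (x, y) series pairs of a comparison class
enumerate_pairs <- function(panel, metadata, class, target_species = "mussel") {
  meta <- panel$meta
  pairs <- list()
  add <- function(x, y) pairs[[length(pairs) + 1]] <<- c(x, y)
  if (class == "area-area") {
    ids <- meta$series_id[meta$variable == "toxin" &
                            !is.na(meta$species) & meta$species == target_species]
    ids <- sort(ids)
    if (length(ids) >= 2) {
      for (i in seq_len(length(ids) - 1)) {
        for (j in (i + 1):length(ids)) add(ids[i], ids[j])
      }
    }
  } else if (class == "species-species") {
    tox <- meta[meta$variable == "toxin" & !is.na(meta$species), ]
    for (a in unique(tox$area)) {
      ids <- sort(tox$series_id[tox$area == a])
      if (length(ids) < 2) next
      for (i in seq_along(ids)) {
        for (j in seq_along(ids)) if (i != j) add(ids[i], ids[j])
      }
    }
  } else if (class == "phyto-toxicity") {
    for (a in unique(meta$area)) {
      tox <- meta$series_id[meta$area == a & meta$variable == "toxin" &
                              !is.na(meta$species) & meta$species == target_species]
      phy <- meta$series_id[meta$area == a & meta$variable == "phyto"]
      if (length(tox) == 1 && length(phy) == 1) add(tox, phy)
    }
  } else if (class == "environment-toxicity") {
    env_vars <- c("sst", "chla", "airtemp", "wind", "rain")
    for (a in unique(meta$area)) {
      tox <- meta$series_id[meta$area == a & meta$variable == "toxin" &
                              !is.na(meta$species) & meta$species == target_species]
      if (length(tox) != 1) next
      for (v in env_vars) {
        ev <- meta$series_id[meta$area == a & meta$variable == v]
        if (length(ev) == 1) add(tox, ev)
      }
    }
  } else {
    stop("unknown comparison class: ", class, call. = FALSE)
  }
  pairs
}

#' Screen every pair of a comparison class
#'
#' Computes the lagged correlation curve for each pair, discards
#' Pearson lag entries with `p >= p_threshold` before locating the
#' peak, flags the threshold passes and sorts by best value. Toxicity
#' is always the first series of each cross-variable pair, so positive
#' peak lags read as "the predictor's past correlates with toxicity's
#' present". No multiplicity correction is applied; `n_tests` is
#' reported so users can apply their own.
#'
#' @param panel A complete [series_panel()].
#' @param metadata Area metadata (used for adjacency annotation of
#'   area-area results; may be `NULL` for other classes).
#' @param class One of `"area-area"`, `"species-species"`,
#'   `"phyto-toxicity"`, `"environment-toxicity"`.
#' @param method `"pearson"` or `"dpcca"`.
#' @param thresholds Numeric vector of pass thresholds to flag; defaults
#'   0.65 and 0.7 for Pearson, 0.9 for DPCCA.
#' @param p_threshold Pearson significance filter (default 0.05).
#' @param max_lag Maximum absolute lag (10 default; 20 for the extended
#'   screen).
#' @param scales DPCCA window sizes.
#' @param target_species Species whose toxicity anchors the area and
#'   cross-variable screens.
#' @return Tibble of screening results, one row per pair, sorted by
#'   `best_value` descending, with attribute `n_tests`.
#' @export
screen_pairs <- function(panel, metadata = NULL,
                         class = c("area-area", "species-species",
                                   "phyto-toxicity", "environment-toxicity"),
                         method = c("pearson", "dpcca"),
                         thresholds = NULL, p_threshold = 0.05,
                         max_lag = 10L, scales = c(4L, 12L, 26L, 52L),
                         target_species = "mussel") {
  class <- match.arg(class)
  method <- match.arg(method)
  if (is.null(thresholds)) {
    thresholds <- if (method == "pearson") c(0.65, 0.7) else 0.9
  }
  pairs <- enumerate_pairs(panel, metadata, class, target_species)
  if (!length(pairs)) {
    warning("no pairs found for class ", class, call. = FALSE)
    return(tibble::tibble())
  }
  adjacency <- NULL
  if (!is.null(metadata)) {
    adjacency <- stats::setNames(metadata$neighbors, metadata$area_id)
  }

  rows <- list()
  for (p in pairs) {
    xs <- panel_series(panel, p[1])
    ys <- panel_series(panel, p[2])
    if (method == "pearson") {
      curve <- lagged_pearson(xs, ys, max_lag)
      keep <- !is.na(curve$p) & curve$p < p_threshold
      usable <- curve[keep, ]
    } else {
      curve <- lagged_dpcca(xs, ys, max_lag = max_lag, scales = scales)
      usable <- curve[!is.na(curve$rho), ]
    }
    if (!nrow(usable)) {
      pk <- list(lag = NA_integer_, value = NA_real_)
      asym <- NA_real_
      p_at_peak <- NA_real_
    } else {
      pk <- peak_lag(usable)
      asym <- asymmetry_index(usable)
      p_at_peak <- if (method == "pearson") {
        min(usable$p[usable$lag == pk$lag])
      } else NA_real_
    }
    ax <- parse_series_id(p[1])$area
    ay <- parse_series_id(p[2])$area
    adj <- if (!is.null(adjacency) && ax %in% names(adjacency)) {
      ay %in% adjacency[[ax]]
    } else NA
    row <- tibble::tibble(
      x = p[1], y = p[2], class = class, method = method,
      best_value = pk$value, peak_lag = pk$lag,
      p_at_peak = p_at_peak, asymmetry = asym, adjacent = adj
    )
    for (th in thresholds) {
      row[[sprintf("pass_%g", th)]] <- !is.na(pk$value) && pk$value >= th
    }
    rows[[length(rows) + 1]] <- row
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(-ifelse(is.na(out$best_value), -Inf, out$best_value)), ]
  attr(out, "n_tests") <- length(pairs) * (2 * max_lag + 1) *
    (if (method == "dpcca") length(scales) else 1L)
  out
}
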