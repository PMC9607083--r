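#' Raw monitoring records to clean weekly panels
#'
#' The preparation chain turns long-format monitoring tables into a
#' complete weekly [series_panel()]: tolerant schema readers, weekly mean
#' resampling onto the common bin grid, optional robust outlier removal,
#' a minimum-coverage filter, and automated imputation-method selection
#' (see [tune_imputer()]).
#'
#' @name prep
NULL

schema_required <- list(
  toxins = c("Date", "Production Area", "Species", "DSP Toxins"),
  phyto = c("Date", "Production Area", "DSP Toxins Producers"),
  environment = c("Date", "Production Area", "Mean SST", "Mean Chlorophyll-a",
                  "Mean Air Temperature", "Mean Wind Intensity", "Rainfall"),
  metadata = c("area_id", "coast", "ns_rank", "region", "neighbors")
)

#' Read a long-format monitoring table
#'
#' Tolerant CSV reader for the four monitoring schemas. Unknown extra
#' columns are ignored with a warning; a missing required column is an
#' error naming it; non-numeric measurement cells become `NA`.
#'
#' @param path CSV file path.
#' @param schema One of `"toxins"`, `"phyto"`, `"environment"`,
#'   `"metadata"`.
#' @return For measurement schemas, a normalised long tibble with columns
#'   `date`, `area`, `variable`, `species` (toxins only) and `value`; for
#'   `"metadata"`, a tibble matching [make_area_metadata()] (with
#'   `neighbors` as a list-column).
#' @export
read_records <- function(path, schema = c("toxins", "phyto", "environment", "metadata")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  req <- schema_required[[schema]]
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop("schema '", schema, "' requires missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), req)
  if (length(extra)) {
    warning("ignoring unknown column(s) in ", basename(path), ": ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, req]

  if (schema == "metadata") {
    return(tibble::tibble(
      area_id = raw$area_id,
      coast = raw$coast,
      ns_rank = as.integer(raw$ns_rank),
      region = raw$region,
      neighbors = lapply(strsplit(raw$neighbors, ";", fixed = TRUE),
                         function(x) x[nzchar(x)])
    ))
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  date <- as.Date(raw$Date)
  area <- raw$`Production Area`
  if (schema == "toxins") {
    out <- tibble::tibble(date = date, area = area, variable = "toxin",
                          species = raw$Species, value = num(raw$`DSP Toxins`))
  } else if (schema == "phyto") {
    out <- tibble::tibble(date = date, area = area, variable = "phyto",
                          species = NA_character_, value = num(raw$`DSP Toxins Producers`))
  } else {
    inv <- stats::setNames(names(env_export_columns), env_export_columns)
    out <- tidyr::pivot_longer(
      dplyr::mutate(raw[, req], date = date, area = area, .keep = "unused"),
      cols = dplyr::all_of(unname(env_export_columns)),
      names_to = "variable", values_to = "value"
    )
    out$variable <- unname(inv[out$variable])
    out$value <- num(out$value)
    out$species <- NA_character_
    out <- out[!is.na(out$value), c("date", "area", "variable", "species", "value")]
  }
  out
}

#' Resample observations onto the weekly bin grid by the mean
#'
#' Observations are assigned to 7-day bins anchored at `start_date`; each
#' bin's value is the arithmetic mean of its observations (so duplicate
#' within-week measurements collapse), and bins without observations are
#' `NA`. Records outside the span are dropped with a message.
#'
#' @param records Tibble with columns `date` and `value` for one series.
#' @param start_date,end_date Span limits (see [weekly_index()]).
#' @param series_id Identifier for the resulting series.
#' @param units Unit string.
#' @return A [weekly_series()] on the full weekly index.
#' @export
resample_weekly <- function(records, start_date, end_date,
                            series_id = "series", units = "") {
  idx <- weekly_index(start_date, end_date)
  d <- as.Date(records$date)
  bin <- as.integer(floor(as.numeric(d - idx[1]) / 7)) + 1L
  inside <- !is.na(bin) & bin >= 1L & bin <= length(idx) & !is.na(records$value)
  dropped <- sum(!inside & !is.na(records$value))
  if (dropped > 0) {
    message(series_id, ": dropped ", dropped, " record(s) outside the span")
  }
  vals <- rep(NA_real_, length(idx))
  if (any(inside)) {
    agg <- tapply(records$value[inside], bin[inside], mean)
    vals[as.integer(names(agg))] <- as.numeric(agg)
  }
  weekly_series(series_id, idx, vals, units = units)
}

#' Mask outlying weekly values
#'
#' Under `rule = "mad_k"`, values farther than `k` median-absolute
#' deviations from the series median are set to missing; a
#' zero-dispersion series is left untouched (no division is involved).
#' `rule = "none"` (the default) returns the series unchanged — the
#' downstream correlation screen is sensitive to removal of genuine
#' toxicity peaks, so masking is opt-in.
#'
#' @param series A [weekly_series()].
#' @param rule `"none"` or `"mad_k"`.
#' @param k Positive multiplier for the MAD rule.
#' @return The series with flagged values set to `NA`; the number removed
#'   is attached as attribute `"n_outliers"`.
#' @export
remove_outliers <- function(series, rule = c("none", "mad_k"), k = 5) {
  rule <- match.arg(rule)
  stopifnot(inherits(series, "weekly_series"))
  if (rule == "none") {
    attr(series, "n_outliers") <- 0L
    return(series)
  }
  if (!is.numeric(k) || k <= 0) stop("`k` must be > 0", call. = FALSE)
  v <- series$values
  med <- stats::median(v, na.rm = TRUE)
  dev <- stats::mad(v, na.rm = TRUE)
  flag <- !is.na(v) & abs(v - med) > k * dev
  series$values[flag] <- NA_real_
  attr(series, "n_outliers") <- sum(flag)
  series
}

#' Drop series with insufficient weekly coverage
#'
#' Retains only series with at least `min_weeks` non-missing weekly
#' values, the inclusion rule that keeps imputation from manufacturing
#' most of a series. Defaults mirror the standard monitoring design:
#' at least 240 observed weeks out of 312.
#'
#' @param panel A [series_panel()].
#' @param min_weeks Inclusive minimum number of observed weeks.
#' @param total_weeks Span length the threshold refers to (validation
#'   only; the panel's own index defines the span).
#' @return The filtered panel; dropped identifiers are attached as
#'   attribute `"dropped_series"`.
#' @export
coverage_filter <- function(panel, min_weeks = 240L, total_weeks = 312L) {
  stopifnot(inherits(panel, "series_panel"))
  if (min_weeks > total_weeks) {
    stop("`min_weeks` must be <= `total_weeks`", call. = FALSE)
  }
  n_obs <- vapply(panel$series, function(v) sum(!is.na(v)), 0L)
  keep <- n_obs >= min_weeks
  dropped <- names(panel$series)[!keep]
  out <- series_panel(panel$index, panel$series[keep],
                      units = stats::setNames(panel$meta$units, panel$meta$series_id))
  attr(out, "dropped_series") <- dropped
  attr(out, "missing_mask") <- attr(panel, "missing_mask")[names(out$series)]
  out
}

#' Root-mean-squared error between a series and its estimate
#'
#' `sqrt(sum((x - xhat)^2) / N)` over aligned complete vectors; the
#' fitness measure used to rank imputation candidates.
#'
#' @param truth,estimate Equal-length numeric vectors without missing
#'   values.
#' @return Non-negative scalar.
#' @export
rmse <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop("`truth` and `estimate` must have equal length", call. = FALSE)
  }
  if (length(truth) < 1) stop("need at least one value", call. = FALSE)
  if (anyNA(truth) || anyNA(estimate)) {
    stop("missing values are not allowed in rmse()", call. = FALSE)
  }
  sqrt(sum((truth - estimate)^2) / length(truth))
}

#' Create artificially-masked copies of a series for imputer evaluation
#'
#' Hides `hide_frac` of the observed positions in each of `n_copies`
#' copies; the hidden subsets are disjoint across copies and never touch
#' originally-missing positions, so each copy's RMSE is computed against
#' genuinely observed truth.
#'
#' @param series A [weekly_series()] with at least 10 observed values.
#' @param n_copies Number of evaluation copies.
#' @param hide_frac Fraction of observed positions hidden per copy, in
#'   (0, 1).
#' @param seed Integer seed.
#' @return List of trials, each `list(copy_id, mask)` where `mask` is a
#'   logical vector over the index (`TRUE` = artificially hidden).
#' @export
make_missing_copies <- function(series, n_copies = 5L, hide_frac = 0.1, seed = 1L) {
  stopifnot(inherits(series, "weekly_series"))
  if (hide_frac <= 0 || hide_frac >= 1) {
    stop("`hide_frac` must be in (0, 1)", call. = FALSE)
  }
  obs <- which(!is.na(series$values))
  if (length(obs) < 10) {
    stop("series ", series$series_id, " has only ", length(obs),
         " observed values; need at least 10", call. = FALSE)
  }
  per_copy <- max(1L, round(hide_frac * length(obs)))
  if (n_copies * per_copy > length(obs)) {
    stop("cannot hide ", n_copies, " disjoint subsets of ", per_copy,
         " from ", length(obs), " observed positions", call. = FALSE)
  }
  set.seed(seed)
  shuffled <- sample(obs)
  lapply(seq_len(n_copies), function(i) {
    hidden <- shuffled[((i - 1) * per_copy + 1):(i * per_copy)]
    mask <- rep(FALSE, length(series$values))
    mask[hidden] <- TRUE
    list(copy_id = i, mask = mask)
  })
}
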