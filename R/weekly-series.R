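#' Weekly time-series containers
#'
#' A `weekly_series` holds one variable's values on a regular 7-day date
#' index with `NA` as the explicit missing marker. A `series_panel` is an
#' aligned collection of such series sharing one common weekly index,
#' together with a metadata table describing each member (production area,
#' variable, species, units).
#'
#' @name weekly-series
NULL

#' Build the weekly bin-start index for a monitoring span
#'
#' Bins are 7-day intervals anchored at `start_date`; only bins fully
#' contained in `[start_date, end_date]` are kept, so a trailing partial
#' week is dropped. The default monitoring span 2015-01-05 to 2020-12-29
#' yields exactly 312 weekly bins.
#'
#' @param start_date,end_date `Date` (or coercible) span limits.
#' @return A `Date` vector of bin-start dates with constant 7-day step.
#' @export
#' @examples
#' length(weekly_index("2015-01-05", "2020-12-29")) # 312
weekly_index <- function(start_date = "2015-01-05", end_date = "2020-12-29") {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (end_date <= start_date) {
    stop("`end_date` must be after `start_date`", call. = FALSE)
  }
  n_weeks <- as.integer((as.numeric(end_date - start_date) + 1) %/% 7)
  if (n_weeks < 1) stop("span shorter than one full week", call. = FALSE)
  start_date + 7 * (seq_len(n_weeks) - 1L)
}

#' Construct a weekly series
#'
#' @param series_id Identifier string, conventionally
#'   `"<area>.<variable>"` or `"<area>.<variable>.<species>"`
#'   (see [make_series_id()]).
#' @param index `Date` vector, strictly increasing with constant 7-day step.
#' @param values Numeric vector, same length as `index`; `NA` marks missing.
#' @param units Unit string (e.g. `"ug OA eq/kg"`).
#' @return A `weekly_series` object.
#' @export
weekly_series <- function(series_id, index, values, units = "") {
  index <- as.Date(index)
  values <- as.numeric(values)
  if (length(index) != length(values)) {
    stop("`index` and `values` must have equal length", call. = FALSE)
  }
  if (length(index) > 1) {
    steps <- as.numeric(diff(index))
    if (any(steps != 7)) {
      stop("`index` must be strictly increasing with a constant 7-day step",
           call. = FALSE)
    }
  }
  structure(
    list(series_id = series_id, index = index, values = values, units = units),
    class = "weekly_series"
  )
}

#' @export
print.weekly_series <- function(x, ...) {
  n <- length(x$values)
  miss <- sum(is.na(x$values))
  cat(sprintf("<weekly_series> %s\n", x$series_id))
  cat(sprintf("  %d weeks (%s to %s), %d missing%s\n",
              n, format(min(x$index)), format(max(x$index)), miss,
              if (nzchar(x$units)) paste0(", units: ", x$units) else ""))
  invisible(x)
}

#' @export
length.weekly_series <- function(x) length(x$values)

#' Compose / parse series identifiers
#'
#' Identifiers concatenate area, variable and (optionally) species with
#' `"."`, e.g. `"RIAV1.toxin.mussel"` or `"L2.sst"`.
#'
#' @param area Production-area code.
#' @param variable Variable name (`"toxin"`, `"phyto"`, `"sst"`, ...).
#' @param species Optional species name for toxin series.
#' @return `make_series_id()`: a string. `parse_series_id()`: a tibble with
#'   columns `series_id`, `area`, `variable`, `species`.
#' @export
make_series_id <- function(area, variable, species = NULL) {
  if (is.null(species) || !nzchar(species)) paste(area, variable, sep = ".")
  else paste(area, variable, species, sep = ".")
}

#' @rdname make_series_id
#' @param series_id Character vector of identifiers to split.
#' @export
parse_series_id <- function(series_id) {
  parts <- strsplit(series_id, ".", fixed = TRUE)
  tibble::tibble(
    series_id = series_id,
    area = vapply(parts, `[`, "", 1L),
    variable = vapply(parts, `[`, "", 2L),
    species = vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_, "")
  )
}

#' Construct a series panel
#'
#' @param index Common weekly `Date` index.
#' @param series Named list of numeric vectors (one per series), each of
#'   `length(index)`, or a list of [weekly_series()] objects sharing `index`.
#' @param units Optional named character vector of units per series_id.
#' @return A `series_panel` object.
#' @export
series_panel <- function(index, series, units = NULL) {
  index <- as.Date(index)
  if (length(series) && inherits(series[[1]], "weekly_series")) {
    ws <- series
    series <- lapply(ws, `[[`, "values")
    names(series) <- vapply(ws, `[[`, "", "series_id")
    if (is.null(units)) {
      units <- vapply(ws, `[[`, "", "units")
      names(units) <- names(series)
    }
    for (w in ws) {
      if (!identical(as.numeric(w$index), as.numeric(index))) {
        stop("series ", w$series_id, " does not share the panel index",
             call. = FALSE)
      }
    }
  }
  if (is.null(names(series)) || anyDuplicated(names(series))) {
    stop("`series` must be a uniquely named list", call. = FALSE)
  }
  bad <- names(series)[vapply(series, length, 0L) != length(index)]
  if (length(bad)) {
    stop("series not on the common index: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  meta <- parse_series_id(names(series))
  meta$units <- if (is.null(units)) "" else unname(units[meta$series_id])
  structure(
    list(index = index, series = lapply(series, as.numeric), meta = meta),
    class = "series_panel"
  )
}

#' @export
print.series_panel <- function(x, ...) {
  cat(sprintf("<series_panel> %d series x %d weeks (%s to %s)\n",
              length(x$series), length(x$index),
              format(min(x$index)), format(max(x$index))))
  miss <- vapply(x$series, function(v) sum(is.na(v)), 0L)
  cat(sprintf("  missing entries: %d total\n", sum(miss)))
  print(utils::head(x$meta, 10))
  if (nrow(x$meta) > 10) cat(sprintf("  ... and %d more series\n", nrow(x$meta) - 10))
  invisible(x)
}

#' Panel accessors
#'
#' @param panel A [series_panel()].
#' @param series_id Identifier of the member to extract.
#' @return `panel_series()` returns the member as a [weekly_series()];
#'   `panel_ids()` the identifiers; `panel_index()` the common date index.
#' @export
panel_series <- function(panel, series_id) {
  stopifnot(inherits(panel, "series_panel"))
  if (!series_id %in% names(panel$series)) {
    stop("no such series in panel: ", series_id, call. = FALSE)
  }
  u <- panel$meta$units[match(series_id, panel$meta$series_id)]
  weekly_series(series_id, panel$index, panel$series[[series_id]], units = u)
}

#' @rdname panel_series
#' @export
panel_ids <- function(panel) names(panel$series)

#' @rdname panel_series
#' @export
panel_index <- function(panel) panel$index

#' Convert a panel to a tidy tibble
#'
#' @param x A `series_panel`.
#' @param ... Unused.
#' @return Long tibble with columns `date`, `series_id`, `value`.
#' @export
as_tibble.series_panel <- function(x, ...) {
  tibble::tibble(
    date = rep(x$index, times = length(x$series)),
    series_id = rep(names(x$series), each = length(x$index)),
    value = unlist(x$series, use.names = FALSE)
  )
}
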