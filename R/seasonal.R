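#' Seasonality and trend profiling
#'
#' Weekly series are summarised by calendar-month means pooled across
#' years (the seasonality profile) and by calendar-year means (the trend
#' profile), in preference to a formal decomposition: the goal is to read
#' off when toxicity peaks and how its overall level drifts, patterns
#' produced by many interacting drivers. A week belongs to the month and
#' year of its bin-start date. Confidence intervals are
#' normal-approximation 95% bands (mean +/- 1.96 sd/sqrt(n)).
#'
#' @name seasonal
NULL

ci_halfwidth <- function(v, level = 0.95) {
  n <- sum(!is.na(v))
  if (n < 2) return(NA_real_)
  stats::qnorm(1 - (1 - level) / 2) * stats::sd(v, na.rm = TRUE) / sqrt(n)
}

profile_rows <- function(values, groups, level) {
  tibble::tibble(
    period = sort(unique(groups)),
    mean = as.numeric(tapply(values, groups, function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })),
    ci_halfwidth = as.numeric(tapply(values, groups, ci_halfwidth, level = level)),
    n = as.integer(tapply(values, groups, function(v) sum(!is.na(v))))
  )
}

#' Monthly (seasonality) profile of a weekly series
#'
#' Month-`m` mean over all weekly values whose bin start falls in
#' calendar month `m`, pooled across years.
#'
#' @param series A [weekly_series()] (prepared; may contain `NA`, which
#'   are excluded from means and counts).
#' @param level Confidence level for the normal-approximation interval.
#' @return Tibble with one row per month 1..12: `series_id`, `month`,
#'   `mean`, `ci_halfwidth`, `n`. Months never observed carry `NA` mean
#'   and zero count.
#' @export
monthly_profile <- function(series, level = 0.95) {
  stopifnot(inherits(series, "weekly_series"))
  if (!length(series$values) || all(is.na(series$values))) {
    stop("empty series: ", series$series_id, call. = FALSE)
  }
  m <- as.POSIXlt(series$index)$mon + 1L
  out <- profile_rows(series$values, factor(m, levels = 1:12), level)
  tibble::tibble(series_id = series$series_id,
                 month = as.integer(as.character(out$period)),
                 mean = out$mean, ci_halfwidth = out$ci_halfwidth, n = out$n)
}

#' Yearly (trend) profile of a weekly series
#'
#' @inheritParams monthly_profile
#' @return Tibble with one row per calendar year in the span:
#'   `series_id`, `year`, `mean`, `ci_halfwidth`, `n`.
#' @export
yearly_profile <- function(series, level = 0.95) {
  stopifnot(inherits(series, "weekly_series"))
  if (!length(series$values) || all(is.na(series$values))) {
    stop("empty series: ", series$series_id, call. = FALSE)
  }
  y <- as.POSIXlt(series$index)$year + 1900L
  out <- profile_rows(series$values, factor(y, levels = sort(unique(y))), level)
  tibble::tibble(series_id = series$series_id,
                 year = as.integer(as.character(out$period)),
                 mean = out$mean, ci_halfwidth = out$ci_halfwidth, n = out$n)
}

#' Month-by-year mean matrix
#'
#' Cell `(m, y)` is the mean weekly value in month `m` of year `y`; `NA`
#' where that month has no data. Weighting the columns by the per-cell
#' counts recovers [monthly_profile()] exactly.
#'
#' @inheritParams monthly_profile
#' @return A 12 x n_years numeric matrix with month rows and year
#'   columns; per-cell counts in attribute `"n"`.
#' @export
monthly_by_year <- function(series) {
  stopifnot(inherits(series, "weekly_series"))
  lt <- as.POSIXlt(series$index)
  m <- factor(lt$mon + 1L, levels = 1:12)
  y <- factor(lt$year + 1900L, levels = sort(unique(lt$year + 1900L)))
  mean_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  mat <- tapply(series$values, list(m, y), mean_na)
  counts <- tapply(!is.na(series$values), list(m, y), sum)
  counts[is.na(counts)] <- 0L
  storage.mode(mat) <- "double"
  attr(mat, "n") <- counts
  mat
}

#' Pooled regional seasonality or trend profiles
#'
#' Pools the weekly values of every member series of each region before
#' averaging (pooled weeks, not mean-of-means), so per-period sample
#' counts drive the confidence bands. Set `pool = FALSE` for the
#' average-of-area-profiles alternative.
#'
#' @param panel A [series_panel()].
#' @param metadata Area metadata with `area_id` and `region` columns.
#' @param kind `"seasonal"` (monthly) or `"trend"` (yearly).
#' @param variable,species Select which member series enter (default:
#'   all toxin series).
#' @param pool Pool weeks across areas (default) or average area
#'   profiles.
#' @param level Confidence level.
#' @return Tibble with `region`, `month` or `year`, `mean`,
#'   `ci_halfwidth`, `n`.
#' @export
regional_profile <- function(panel, metadata, kind = c("seasonal", "trend"),
                             variable = "toxin", species = NULL,
                             pool = TRUE, level = 0.95) {
  kind <- match.arg(kind)
  stopifnot(inherits(panel, "series_panel"))
  meta <- panel$meta
  sel <- meta$variable == variable &
    (is.null(species) | (!is.na(meta$species) & meta$species %in% (species %||% meta$species)))
  ids <- meta$series_id[sel]
  if (!length(ids)) stop("no panel series match the selection", call. = FALSE)
  areas <- meta$area[sel]
  missing_meta <- setdiff(areas, metadata$area_id)
  if (length(missing_meta)) {
    stop("area(s) missing from metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  region_of <- stats::setNames(metadata$region, metadata$area_id)

  profile_one <- function(sid) {
    ws <- panel_series(panel, sid)
    if (kind == "seasonal") monthly_profile(ws, level) else yearly_profile(ws, level)
  }
  period_col <- if (kind == "seasonal") "month" else "year"

  out <- list()
  for (reg in sort(unique(region_of[areas]))) {
    member_ids <- ids[region_of[areas] == reg]
    if (pool) {
      vals <- unlist(panel$series[member_ids], use.names = FALSE)
      lt <- as.POSIXlt(rep(panel$index, times = length(member_ids)))
      groups <- if (kind == "seasonal") {
        factor(lt$mon + 1L, levels = 1:12)
      } else {
        factor(lt$year + 1900L, levels = sort(unique(lt$year + 1900L)))
      }
      pr <- profile_rows(vals, groups, level)
      res <- tibble::tibble(region = reg,
                            period = as.integer(as.character(pr$period)),
                            mean = pr$mean, ci_halfwidth = pr$ci_halfwidth,
                            n = pr$n)
    } else {
      profs <- dplyr::bind_rows(lapply(member_ids, profile_one))
      res <- dplyr::summarise(
        dplyr::group_by(profs, period = .data[[period_col]]),
        mean = mean(.data$mean, na.rm = TRUE),
        ci_halfwidth = NA_real_, n = sum(.data$n), .groups = "drop"
      )
      res <- dplyr::mutate(res, region = reg, .before = 1)
    }
    out[[reg]] <- res
  }
  res <- dplyr::bind_rows(out)
  names(res)[names(res) == "period"] <- period_col
  res
}
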