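#' Imputation-method registry and automated selection
#'
#' Six candidate gap-filling families spanning constant fills,
#' interpolation, local smoothing and a seasonal rule. [tune_imputer()]
#' picks the method (and hyperparameters) minimising mean RMSE over
#' artificially-masked copies of the series ([make_missing_copies()]),
#' so selection adapts to each series' own structure.
#'
#' @name impute
NULL

#' The imputation candidate registry
#'
#' @return Tibble with columns `method`, `n_params` (number of
#'   hyperparameters) and `grid` (list-column of default hyperparameter
#'   grids, each a named list of candidate values).
#' @export
imputer_registry <- function() {
  tibble::tibble(
    method = c("mean_fill", "median_fill", "linear_interp", "spline_interp",
               "moving_average", "seasonal_naive"),
    n_params = c(0L, 0L, 0L, 0L, 1L, 1L),
    grid = list(
      list(), list(), list(), list(),
      list(w = c(3, 5, 7, 9, 11)),
      list(period = c(26, 52))
    )
  )
}

# fill any still-missing leading/trailing positions from the nearest
# observed value (the fallback every interpolating method needs)
fill_edges_nearest <- function(v) {
  if (anyNA(v)) {
    v <- zoo::na.locf(zoo::na.locf(v, na.rm = FALSE), fromLast = TRUE, na.rm = FALSE)
  }
  v
}

#' Fill the missing values of a weekly series
#'
#' Observed values are never altered. Methods that cannot cover leading
#' or trailing gaps (interpolation, moving average, seasonal rule) fall
#' back to nearest-observed extension there, with a message.
#'
#' @param series A [weekly_series()] with at least one observed value.
#' @param method One of the [imputer_registry()] methods.
#' @param params Named list of hyperparameters (`w` for
#'   `moving_average`, `period` for `seasonal_naive`).
#' @return The series with no missing values.
#' @export
impute <- function(series, method, params = list()) {
  stopifnot(inherits(series, "weekly_series"))
  reg <- imputer_registry()
  if (!method %in% reg$method) {
    stop("unknown imputation method: ", method, call. = FALSE)
  }
  v <- series$values
  obs <- !is.na(v)
  if (!any(obs)) {
    stop("series ", series$series_id, " is entirely missing; refusing to impute",
         call. = FALSE)
  }
  if (all(obs)) return(series)

  filled <- switch(
    method,
    mean_fill = {
      v[!obs] <- mean(v[obs])
      v
    },
    median_fill = {
      v[!obs] <- stats::median(v[obs])
      v
    },
    linear_interp = zoo::na.approx(v, na.rm = FALSE),
    spline_interp = {
      out <- v
      interior <- !obs & seq_along(v) > min(which(obs)) & seq_along(v) < max(which(obs))
      if (any(interior)) {
        sp <- zoo::na.spline(v, na.rm = FALSE)
        out[interior] <- sp[interior]
      }
      out
    },
    moving_average = {
      w <- params$w %||% 5
      half <- floor(w / 2)
      out <- v
      for (i in which(!obs)) {
        lo <- max(1, i - half); hi <- min(length(v), i + half)
        window <- v[lo:hi]
        if (any(!is.na(window))) out[i] <- mean(window, na.rm = TRUE)
      }
      out
    },
    seasonal_naive = {
      period <- as.integer(params$period %||% 52)
      out <- v
      phase <- (seq_along(v) - 1L) %% period
      for (i in which(!obs)) {
        same <- which(phase == phase[i] & obs)
        if (length(same)) out[i] <- mean(v[same])
      }
      out
    }
  )
  if (anyNA(filled)) {
    message(series$series_id, " [", method,
            "]: extending nearest observed value over uncovered gap(s)")
    filled <- fill_edges_nearest(filled)
  }
  series$values <- filled
  series
}

# expand a named grid list into a tibble of configurations (one row per
# combination; zero-parameter methods get a single empty configuration)
expand_param_grid <- function(grid) {
  if (!length(grid)) return(tibble::tibble(.config = list(list())))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble::tibble(.config = lapply(seq_len(nrow(combos)),
                                  function(i) as.list(combos[i, , drop = FALSE])))
}

# mean RMSE of one (method, params) candidate over the masked copies
evaluate_candidate <- function(series, method, params, trials) {
  errs <- vapply(trials, function(tr) {
    copy <- series
    copy$values[tr$mask] <- NA_real_
    filled <- suppressMessages(impute(copy, method, params))
    rmse(series$values[tr$mask], filled$values[tr$mask])
  }, 0)
  mean(errs)
}

# ---- sequential model-based search over a discretised 1-D grid --------
# GP with RBF kernel on the normalised parameter, expected-improvement
# acquisition; evaluates the grid ends first, then EI-maximising points.
bo_search <- function(series, method, pname, pvalues, trials, budget) {
  pvalues <- sort(unique(pvalues))
  z <- (pvalues - min(pvalues)) / max(diff(range(pvalues)), 1e-12)
  n <- length(pvalues)
  evaluated <- integer()
  scores <- numeric()
  eval_at <- function(i) {
    evaluate_candidate(series, method, stats::setNames(list(pvalues[i]), pname), trials)
  }
  init <- unique(c(1L, n, ceiling(n / 2)))
  for (i in init[seq_len(min(length(init), budget))]) {
    evaluated <- c(evaluated, i)
    scores <- c(scores, eval_at(i))
  }
  kern <- function(a, b) exp(-0.5 * outer(a, b, "-")^2 / 0.25^2)
  while (length(evaluated) < min(budget, n)) {
    rest <- setdiff(seq_len(n), evaluated)
    K <- kern(z[evaluated], z[evaluated]) + diag(1e-8, length(evaluated))
    ks <- kern(z[rest], z[evaluated])
    mu0 <- mean(scores)
    alpha <- solve(K, scores - mu0)
    mu <- mu0 + as.numeric(ks %*% alpha)
    var <- pmax(1e-12, 1 - rowSums((ks %*% solve(K)) * ks))
    sdv <- sqrt(var) * stats::sd(scores) + 1e-12
    best <- min(scores)
    imp <- best - mu
    zz <- imp / sdv
    ei <- imp * stats::pnorm(zz) + sdv * stats::dnorm(zz)
    pick <- rest[which.max(ei)]
    evaluated <- c(evaluated, pick)
    scores <- c(scores, eval_at(pick))
  }
  tibble::tibble(
    .config = lapply(evaluated, function(i) stats::setNames(list(pvalues[i]), pname)),
    mean_rmse = scores
  )
}

#' Select the best imputation method for a series
#'
#' Hides part of the observed data ([make_missing_copies()]), evaluates
#' every candidate method's mean RMSE at reconstructing the hidden
#' values, and searches each method's hyperparameter grid with the
#' requested strategy. The selected candidate attains the minimal
#' evaluated mean RMSE; ties break toward the method with fewer
#' hyperparameters, then registry order.
#'
#' @param series A [weekly_series()] with missing values to fill.
#' @param candidates Character vector of [imputer_registry()] methods.
#' @param n_copies,hide_frac,seed Passed to [make_missing_copies()].
#' @param budget Maximum hyperparameter evaluations per method (must be
#'   at least 1; grids smaller than the budget are evaluated
#'   exhaustively under every strategy).
#' @param strategy `"bayesian"` (sequential model-based search),
#'   `"grid"` (exhaustive) or `"random"` (uniform subsample of the
#'   grid). All strategies are deterministic given `seed`.
#' @return An `imputation_report`: list with `series_id`, `trials` tibble
#'   (method, params, mean_rmse), `selected` (method + params +
#'   mean_rmse), `budget_used` and `imputed_frac`.
#' @export
tune_imputer <- function(series, candidates = imputer_registry()$method,
                         n_copies = 5L, hide_frac = 0.1, budget = 25L,
                         seed = 1L, strategy = c("bayesian", "grid", "random")) {
  strategy <- match.arg(strategy)
  if (!length(candidates)) stop("empty candidate list", call. = FALSE)
  reg <- imputer_registry()
  unknown <- setdiff(candidates, reg$method)
  if (length(unknown)) {
    stop("unknown candidate(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (budget < 1) stop("`budget` must be >= 1", call. = FALSE)
  trials <- make_missing_copies(series, n_copies, hide_frac, seed)

  rows <- list()
  for (m in candidates) {
    entry <- reg[reg$method == m, ]
    grid <- entry$grid[[1]]
    configs <- expand_param_grid(grid)
    if (nrow(configs) <= budget || strategy == "grid" || !length(grid)) {
      res <- configs
      res$mean_rmse <- vapply(configs$.config, function(p) {
        evaluate_candidate(series, m, p, trials)
      }, 0)
    } else if (strategy == "random") {
      set.seed(seed + 7L)
      take <- sort(sample.int(nrow(configs), budget))
      res <- configs[take, ]
      res$mean_rmse <- vapply(res$.config, function(p) {
        evaluate_candidate(series, m, p, trials)
      }, 0)
    } else {
      pname <- names(grid)[1]
      res <- bo_search(series, m, pname, grid[[pname]], trials, budget)
    }
    res$method <- m
    res$n_params <- entry$n_params
    rows[[m]] <- res
  }
  all_rows <- dplyr::bind_rows(rows)
  reg_order <- match(all_rows$method, reg$method)
  ord <- order(all_rows$mean_rmse, all_rows$n_params, reg_order)
  best <- all_rows[ord[1], ]

  structure(list(
    series_id = series$series_id,
    trials = tibble::tibble(method = all_rows$method,
                            params = all_rows$.config,
                            n_params = all_rows$n_params,
                            mean_rmse = all_rows$mean_rmse),
    selected = list(method = best$method, params = best$.config[[1]],
                    mean_rmse = best$mean_rmse),
    budget_used = nrow(all_rows),
    n_copies = n_copies, hide_frac = hide_frac, strategy = strategy,
    imputed_frac = mean(is.na(series$values))
  ), class = "imputation_report")
}

#' @export
print.imputation_report <- function(x, ...) {
  cat(sprintf("<imputation_report> %s\n", x$series_id))
  cat(sprintf("  selected: %s (mean RMSE %.4g over %d copies, %s search)\n",
              x$selected$method, x$selected$mean_rmse, x$n_copies, x$strategy))
  cat(sprintf("  %d candidate evaluations; %.1f%% of weeks imputed\n",
              x$budget_used, 100 * x$imputed_frac))
  invisible(x)
}

#' Run the full preparation chain on raw monitoring files
#'
#' read -> weekly resample -> outlier rule -> coverage filter ->
#' imputation-method selection -> imputation, per series. Series with no
#' missing values skip tuning; observed values pass through unchanged.
#'
#' @param in_dir Directory containing `toxins.csv`, `phyto.csv`,
#'   `environment.csv` and `areas.csv` (the [export_datasets()] layout).
#' @param config Named list of options: `start_date`, `end_date`,
#'   `min_weeks` (default 240), `outlier_rule` (`"none"`/`"mad_k"`),
#'   `outlier_k`, `n_copies`, `hide_frac`, `budget`, `strategy`, `seed`.
#' @return List with `panel` (complete [series_panel()]), `reports`
#'   (list of `imputation_report`), `areas` metadata and `dropped`
#'   (series removed by the coverage filter).
#' @export
prepare_panel <- function(in_dir, config = list()) {
  cfg <- utils::modifyList(list(
    start_date = "2015-01-05", end_date = "2020-12-29",
    min_weeks = 240L, outlier_rule = "none", outlier_k = 5,
    n_copies = 5L, hide_frac = 0.1, budget = 25L,
    strategy = "grid", seed = 1L
  ), config)

  tox <- read_records(file.path(in_dir, "toxins.csv"), "toxins")
  phy <- read_records(file.path(in_dir, "phyto.csv"), "phyto")
  env <- read_records(file.path(in_dir, "environment.csv"), "environment")
  areas <- read_records(file.path(in_dir, "areas.csv"), "metadata")
  recs <- dplyr::bind_rows(tox, phy, env)

  keys <- dplyr::distinct(recs, .data$area, .data$variable, .data$species)
  idx <- weekly_index(cfg$start_date, cfg$end_date)
  total_weeks <- length(idx)
  series_list <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sub <- recs[recs$area == k$area & recs$variable == k$variable &
                  (is.na(k$species) | (!is.na(recs$species) & recs$species == k$species)), ]
    sid <- make_series_id(k$area, k$variable,
                          if (is.na(k$species)) NULL else k$species)
    ws <- resample_weekly(sub, cfg$start_date, cfg$end_date, series_id = sid)
    ws <- remove_outliers(ws, rule = cfg$outlier_rule, k = cfg$outlier_k)
    series_list[[sid]] <- ws
  }
  panel <- series_panel(idx, series_list)
  panel <- coverage_filter(panel, min_weeks = cfg$min_weeks,
                           total_weeks = total_weeks)

  reports <- list()
  for (sid in panel_ids(panel)) {
    ws <- panel_series(panel, sid)
    if (!anyNA(ws$values)) next
    rep <- tune_imputer(ws, n_copies = cfg$n_copies, hide_frac = cfg$hide_frac,
                        budget = cfg$budget, seed = cfg$seed,
                        strategy = cfg$strategy)
    filled <- suppressMessages(impute(ws, rep$selected$method, rep$selected$params))
    panel$series[[sid]] <- filled$values
    reports[[sid]] <- rep
  }
  list(panel = panel, reports = reports, areas = areas,
       dropped = attr(panel, "dropped_series"))
}
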