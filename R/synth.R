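#' Synthetic shellfish-monitoring data generator
#'
#' Emulates the three weekly monitoring datasets used by DSP (diarrhetic
#' shellfish poisoning) surveillance programmes — shellfish toxin
#' concentrations, toxic-phytoplankton cell counts and
#' oceanographic/meteorological conditions — for a north-to-south chain of
#' production areas. The generator plants the structure the downstream
#' analysis is designed to detect: bimodal within-year seasonality (late
#' spring and late summer bloom peaks), a north-to-south toxicity gradient,
#' spatial correlation that decays with adjacency distance, and
#' species-specific uptake/elimination kinetics that produce asymmetric
#' lead-lag relations between co-occurring species.
#'
#' @name synth
NULL

#' Default species kinetics set
#'
#' Four commercially monitored shellfish species with contrasting
#' uptake/elimination kinetics: mussel and Donax clam eliminate slowly
#' (high burdens, long memory), cockle and surf clam quickly.
#'
#' @return Named list of [species_kinetics()].
#' @export
default_species_kinetics <- function() {
  list(
    mussel    = species_kinetics("mussel",    uptake_rate = 0.9, elimination_rate = 0.30, baseline = 20),
    cockle    = species_kinetics("cockle",    uptake_rate = 0.6, elimination_rate = 0.60, baseline = 10),
    surf_clam = species_kinetics("surf_clam", uptake_rate = 0.3, elimination_rate = 0.70, baseline = 10),
    donax_clam = species_kinetics("donax_clam", uptake_rate = 1.1, elimination_rate = 0.20, baseline = 25)
  )
}

#' Species toxin-kinetics parameters
#'
#' First-order uptake/elimination parameters controlling how fast a species
#' accumulates toxin from the ambient bloom signal and how fast it clears
#' its body burden. Slow eliminators (mussel, Donax clam) reach higher
#' burdens and lag fast ones (cockle, surf clam) under the same forcing.
#'
#' @param species Species name.
#' @param uptake_rate Fraction of the ambient bloom signal accumulated per
#'   week; must be positive.
#' @param elimination_rate Fraction of the body burden cleared per week, in
#'   (0, 1].
#' @param baseline Concentration floor in ug OA eq/kg; non-negative.
#' @return A `species_kinetics` list.
#' @export
species_kinetics <- function(species, uptake_rate, elimination_rate, baseline = 0) {
  if (!is.numeric(uptake_rate) || uptake_rate <= 0) {
    stop("`uptake_rate` must be > 0", call. = FALSE)
  }
  if (!is.numeric(elimination_rate) || elimination_rate <= 0 || elimination_rate > 1) {
    stop("`elimination_rate` must be in (0, 1]", call. = FALSE)
  }
  if (baseline < 0) stop("`baseline` must be >= 0", call. = FALSE)
  structure(
    list(species = species, uptake_rate = uptake_rate,
         elimination_rate = elimination_rate, baseline = baseline),
    class = "species_kinetics"
  )
}

#' Configuration for the synthetic monitoring generator
#'
#' Defaults reproduce the monitoring design the analysis targets: 10
#' production areas on a north-to-south chain (7 west coast, 3 south
#' coast), the 2015-01-05 to 2020-12-29 span (312 weekly bins), four
#' shellfish species with contrasting kinetics, bloom-season peaks in May
#' and September, and roughly 10% missing observations.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_areas Number of production areas (>= 2).
#' @param start_date,end_date Monitoring span (see [weekly_index()]).
#' @param species Named list of [species_kinetics()].
#' @param season_peaks Two-column matrix-like list of bloom peaks: numeric
#'   `month` (1-12) and `amplitude` (>= 0) vectors of equal length.
#' @param spatial_decay Correlation attenuation per adjacency step for the
#'   shared bloom pulses, in \[0, 1\]; 1 = identical pulse trains in all
#'   areas, 0 = independent areas.
#' @param ns_gradient Per-rank multiplicative amplitude factor (< 1 plants
#'   a southward decrease in bloom and toxicity levels), in \[0, 1\].
#' @param missing_frac Marginal probability an observation is missing, in
#'   \[0, 1).
#' @param block_gap_rate Expected number of contiguous multi-week gaps per
#'   series (Poisson rate).
#' @param pivot_rank West-coast rank at which the northwest region ends:
#'   west-coast areas with `ns_rank < pivot_rank` are "northwest", the rest
#'   "southwest" (south-coast areas are always "south").
#' @param south_areas Number of areas on the south coast (the southernmost
#'   of the chain).
#' @param toxin_yield ug OA eq/kg of weekly toxin uptake per ambient cell/L,
#'   converting bloom counts into toxin forcing.
#' @param obs_noise_sd Standard deviation of multiplicative log-normal
#'   observation noise on toxin measurements (0 = noiseless).
#' @param env_noise_sd Additive noise s.d. for the environmental sinusoids,
#'   in each variable's own units (0 = deterministic seasonal cycles).
#' @param pulse_prob Baseline weekly probability of a bloom pulse, before
#'   seasonal modulation.
#' @param mark_meanlog,mark_sdlog Log-normal parameters of bloom pulse
#'   magnitudes (cells/L); heavy right tail emulating observed ranges from
#'   tens to over a million cells per litre.
#' @param season_sd_months Width (s.d., in months) of the Gaussian bloom
#'   season bumps around each peak month.
#' @param pulse_boost Added weekly pulse probability at the height of the
#'   bloom season (scales with the seasonal envelope).
#' @param deterministic_blooms When `TRUE`, pulse trains are replaced by
#'   their expectation (probability times mean magnitude): the noiseless
#'   limit in which the planted structure holds exactly.
#' @param bloom_lead_weeks Weeks by which the bloom season precedes the
#'   toxicity season: `season_peaks` give the months where *toxicity*
#'   peaks, and the bloom envelope is centred this many weeks earlier to
#'   offset the kinetic accumulation delay.
#' @param half_sat Half-saturation cell count (cells/L) of toxin uptake:
#'   the forcing a species sees is `toxin_yield * P / (1 + P / half_sat)`,
#'   saturating for extreme blooms the way filter-feeding uptake does, so
#'   toxin burdens span a far narrower range than cell counts.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(seed = 1L,
                         n_areas = 10L,
                         start_date = "2015-01-05",
                         end_date = "2020-12-29",
                         species = default_species_kinetics(),
                         season_peaks = list(month = c(5, 9), amplitude = c(1, 0.9)),
                         spatial_decay = 0.6,
                         ns_gradient = 0.92,
                         missing_frac = 0.1,
                         block_gap_rate = 2,
                         pivot_rank = 4L,
                         south_areas = 3L,
                         toxin_yield = 0.05,
                         obs_noise_sd = 0.15,
                         env_noise_sd = 0.3,
                         pulse_prob = 0.06,
                         mark_meanlog = 7.7,
                         mark_sdlog = 2.2,
                         season_sd_months = 0.5,
                         pulse_boost = 0.5,
                         deterministic_blooms = FALSE,
                         bloom_lead_weeks = 0L,
                         half_sat = 2e4) {
  cfg <- list(
    seed = as.integer(seed), n_areas = as.integer(n_areas),
    start_date = as.Date(start_date), end_date = as.Date(end_date),
    species = species, season_peaks = season_peaks,
    spatial_decay = spatial_decay, ns_gradient = ns_gradient,
    missing_frac = missing_frac, block_gap_rate = block_gap_rate,
    pivot_rank = as.integer(pivot_rank), south_areas = as.integer(south_areas),
    toxin_yield = toxin_yield, obs_noise_sd = obs_noise_sd,
    env_noise_sd = env_noise_sd, pulse_prob = pulse_prob,
    mark_meanlog = mark_meanlog, mark_sdlog = mark_sdlog,
    season_sd_months = season_sd_months, pulse_boost = pulse_boost,
    deterministic_blooms = isTRUE(deterministic_blooms),
    bloom_lead_weeks = as.integer(bloom_lead_weeks), half_sat = half_sat
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_areas < 2) stop("`n_areas` must be >= 2", call. = FALSE)
  if (cfg$end_date <= cfg$start_date) {
    stop("`end_date` must be after `start_date`", call. = FALSE)
  }
  frac <- c(spatial_decay = cfg$spatial_decay, ns_gradient = cfg$ns_gradient,
            missing_frac = cfg$missing_frac)
  bad <- names(frac)[frac < 0 | frac > 1]
  if (length(bad)) {
    stop("fractions must lie in [0, 1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (cfg$missing_frac >= 1) stop("`missing_frac` must be < 1", call. = FALSE)
  sp <- cfg$season_peaks
  if (length(sp$month) < 1 || length(sp$month) != length(sp$amplitude)) {
    stop("`season_peaks` needs at least one (month, amplitude) pair",
         call. = FALSE)
  }
  if (any(sp$month < 1 | sp$month > 12)) {
    stop("season peak months must be in 1..12", call. = FALSE)
  }
  for (k in cfg$species) {
    if (!inherits(k, "species_kinetics")) {
      stop("`species` must be a list of species_kinetics()", call. = FALSE)
    }
  }
  invisible(cfg)
}

canonical_area_names <- c("L2", "RIAV1", "RIAV2", "LOB", "L5b", "ETJ1",
                          "L7c1", "LAG", "OLH2", "L9")

#' Build the production-area metadata chain
#'
#' Areas form a single north-to-south chain (`ns_rank` 0 = northernmost)
#' with adjacency between consecutive ranks. The southernmost
#' `south_areas` areas sit on the south coast and belong to the "south"
#' region; west-coast areas split into "northwest" (`ns_rank <
#' pivot_rank`) and "southwest".
#'
#' @param config A [synth_config()].
#' @return A tibble with columns `area_id`, `coast`, `ns_rank`, `region`
#'   and a list-column `neighbors`.
#' @export
make_area_metadata <- function(config) {
  n <- config$n_areas
  if (n < 2) stop("`n_areas` must be >= 2", call. = FALSE)
  ids <- if (n == length(canonical_area_names)) {
    canonical_area_names
  } else {
    sprintf("A%02d", seq_len(n))
  }
  rank <- seq_len(n) - 1L
  coast <- ifelse(rank >= n - config$south_areas, "south", "west")
  region <- ifelse(coast == "south", "south",
                   ifelse(rank < config$pivot_rank, "northwest", "southwest"))
  neighbors <- lapply(seq_len(n), function(i) {
    ids[intersect(c(i - 1L, i + 1L), seq_len(n))]
  })
  tibble::tibble(area_id = ids, coast = coast, ns_rank = rank,
                 region = region, neighbors = neighbors)
}

# circular distance between calendar month positions (fractional months)
month_circ_dist <- function(m, peak) {
  d <- abs(m - peak)
  pmin(d, 12 - d)
}

# seasonal bloom envelope in [0, max amplitude]: sum of Gaussian bumps
# (s.d. 0.75 months) centred at the configured peak months
season_envelope <- function(dates, season_peaks, sd_months = 0.75) {
  m <- as.POSIXlt(dates)$mon + 1 + (as.POSIXlt(dates)$mday - 1) / 30.44
  env <- rep(0, length(dates))
  for (i in seq_along(season_peaks$month)) {
    d <- month_circ_dist(m, season_peaks$month[i])
    env <- env + season_peaks$amplitude[i] * exp(-0.5 * (d / sd_months)^2)
  }
  env
}

# annual sinusoid by day-of-year, peaking at `peak_yday`
annual_cycle <- function(dates, peak_yday) {
  yday <- as.POSIXlt(dates)$yday + 1
  cos(2 * pi * (yday - peak_yday) / 365.25)
}

#' Simulate weekly environmental conditions per area
#'
#' Sea-surface temperature (Kelvin, annual sinusoid within the 285-297 K
#' coastal band, late-August peak), chlorophyll-a (mg/L, positive,
#' modulated by the bloom-season envelope), air temperature (Celsius),
#' wind intensity (km/h, non-negative) and rainfall (mm, non-negative,
#' winter-weighted). Reproducible from `config$seed`.
#'
#' @param config A [synth_config()].
#' @param areas Area metadata from [make_area_metadata()].
#' @return A [series_panel()] with series `<area>.{sst,chla,airtemp,wind,rain}`.
#' @export
simulate_environment <- function(config, areas) {
  validate_synth_config(config)
  idx <- weekly_index(config$start_date, config$end_date)
  nw <- length(idx)
  set.seed(config$seed + 1L)
  env <- season_envelope(idx, config$season_peaks,
                         sd_months = config$season_sd_months)
  sst_cycle <- annual_cycle(idx, peak_yday = 233)     # late August
  winter <- (1 - sst_cycle) / 2                        # 0 summer .. 1 winter
  ns <- config$env_noise_sd
  series <- list()
  units <- character()
  for (i in seq_len(nrow(areas))) {
    a <- areas$area_id[i]
    lat_shift <- 0.1 * areas$ns_rank[i]                # slightly warmer south
    sst <- 290.5 + lat_shift + 4 * sst_cycle + rnorm(nw, 0, ns)
    chla <- exp(0.7 + 0.9 * env + rnorm(nw, 0, ns / 2))
    airt <- 16.3 + lat_shift + 6.5 * sst_cycle + rnorm(nw, 0, 2 * ns)
    wind <- pmax(0, 2.8 + 0.5 * winter + rnorm(nw, 0, 2 * ns))
    rain <- pmax(0, 2.5 * winter - 0.4 + rnorm(nw, 0, 3 * ns))
    add <- list(sst, chla, airt, wind, rain)
    vars <- c("sst", "chla", "airtemp", "wind", "rain")
    uu <- c("K", "mg/L", "degC", "km/h", "mm")
    for (j in seq_along(vars)) {
      id <- make_series_id(a, vars[j])
      series[[id]] <- add[[j]]
      units[id] <- uu[j]
    }
  }
  series_panel(idx, series, units = units)
}

#' Simulate toxic-phytoplankton cell counts per area
#'
#' Weekly counts are seasonally modulated random pulses with heavy-tailed
#' log-normal magnitudes. Pulses are shared across the area chain with
#' geometric attenuation `spatial_decay` per adjacency step, so nearby
#' areas see correlated bloom histories; southern areas are scaled down by
#' `ns_gradient` per rank.
#'
#' @inheritParams simulate_environment
#' @param environment Environmental panel from [simulate_environment()]
#'   (defines the weekly index; blooms must cover the same span).
#' @return A [series_panel()] with one `<area>.phyto` series per area
#'   (cells/L, non-negative).
#' @export
simulate_blooms <- function(config, areas, environment) {
  validate_synth_config(config)
  idx <- panel_index(environment)
  nw <- length(idx)
  n <- nrow(areas)
  set.seed(config$seed + 2L)
  # blooms precede the configured toxicity peaks by the phenological lead
  env <- season_envelope(idx + 7 * config$bloom_lead_weeks, config$season_peaks,
                         sd_months = config$season_sd_months)
  env_max <- max(env, 1e-12)
  p <- pmin(0.9, config$pulse_prob + config$pulse_boost * env / max(env_max, 1))
  # raw per-area pulse trains: occurrence * log-normal magnitude (or their
  # expectation in the deterministic noiseless limit)
  raw <- matrix(0, nw, n)
  for (j in seq_len(n)) {
    if (config$deterministic_blooms) {
      raw[, j] <- p * exp(config$mark_meanlog + config$mark_sdlog^2 / 2) *
        (0.3 + env)
    } else {
      occ <- rbinom(nw, 1, p)
      mark <- rlnorm(nw, config$mark_meanlog, config$mark_sdlog)
      raw[, j] <- occ * mark * (0.3 + env)
    }
  }
  # geometric mixing along the chain: area j sees decay^|rank_i - rank_j|
  # of area i's pulses (decay 1 -> identical trains, 0 -> independent)
  d <- abs(outer(areas$ns_rank, areas$ns_rank, "-"))
  w <- config$spatial_decay^d
  if (config$spatial_decay == 0) w <- (d == 0) * 1
  # normalise each area's received mass so chain position does not change
  # the marginal level (decay 1 -> identical trains, 0 -> own train only)
  w <- sweep(w, 2, colSums(w), "/") * 1
  mixed <- raw %*% w
  grad <- config$ns_gradient^areas$ns_rank
  series <- list()
  units <- character()
  for (j in seq_len(n)) {
    id <- make_series_id(areas$area_id[j], "phyto")
    series[[id]] <- 20 + mixed[, j] * grad[j]
    units[id] <- "cells/L"
  }
  series_panel(idx, series, units = units)
}

#' Run the toxin uptake/elimination kinetics over a bloom panel
#'
#' Applies the first-order recursion
#' `T[t+1] = (1 - e) * T[t] + u * P[t] + e * baseline`
#' to every series in `blooms`, where `u` is the uptake rate, `e` the
#' elimination rate and `P` the ambient bloom forcing. Under zero forcing
#' the burden decays geometrically to `baseline`; slow eliminators respond
#' with a longer memory, which is what displaces the cross-correlation
#' peak between species toward the slow species' future.
#'
#' @param blooms A [series_panel()] of bloom forcing series (already scaled
#'   to toxin-uptake units if modelling real magnitudes).
#' @param kinetics A [species_kinetics()].
#' @return A [series_panel()] with one `<area>.toxin.<species>` series per
#'   input series (ug OA eq/kg, non-negative).
#' @export
simulate_toxicity <- function(blooms, kinetics) {
  stopifnot(inherits(blooms, "series_panel"), inherits(kinetics, "species_kinetics"))
  u <- kinetics$uptake_rate
  e <- kinetics$elimination_rate
  b <- kinetics$baseline
  series <- list()
  units <- character()
  for (id in panel_ids(blooms)) {
    P <- blooms$series[[id]]
    if (any(!is.finite(P))) {
      stop("non-finite bloom input in series ", id, call. = FALSE)
    }
    n <- length(P)
    T <- numeric(n)
    T[1] <- b
    for (t in seq_len(n - 1)) {
      T[t + 1] <- (1 - e) * T[t] + u * P[t] + e * b
    }
    area <- parse_series_id(id)$area
    out_id <- make_series_id(area, "toxin", kinetics$species)
    series[[out_id]] <- T
    units[out_id] <- "ug OA eq/kg"
  }
  series_panel(panel_index(blooms), series, units = units)
}

#' Thin a panel with realistic missingness
#'
#' Marks entries missing by i.i.d. thinning at rate `missing_frac` plus a
#' Poisson number of contiguous gap blocks (geometric lengths, mean 3
#' weeks) per series, emulating reporting interruptions. Observed values
#' are never altered; the realised mask is attached as attribute
#' `"missing_mask"` (a named list of logical vectors).
#'
#' @param panel A [series_panel()].
#' @param config A [synth_config()] supplying `missing_frac`,
#'   `block_gap_rate` and the seed.
#' @return The thinned [series_panel()].
#' @export
apply_missingness <- function(panel, config) {
  stopifnot(inherits(panel, "series_panel"))
  if (config$missing_frac >= 1) stop("`missing_frac` must be < 1", call. = FALSE)
  set.seed(config$seed + 3L)
  nw <- length(panel$index)
  masks <- list()
  for (id in panel_ids(panel)) {
    mask <- runif(nw) < config$missing_frac
    n_blocks <- rpois(1, config$block_gap_rate)
    if (n_blocks > 0) {
      for (k in seq_len(n_blocks)) {
        len <- 1 + rgeom(1, 1 / 3)
        start <- sample.int(nw, 1)
        mask[start:min(nw, start + len - 1)] <- TRUE
      }
    }
    masks[[id]] <- mask
    panel$series[[id]][mask] <- NA_real_
  }
  attr(panel, "missing_mask") <- masks
  panel
}

env_export_columns <- c(sst = "Mean SST", chla = "Mean Chlorophyll-a",
                        airtemp = "Mean Air Temperature",
                        wind = "Mean Wind Intensity", rain = "Rainfall")

#' Export synthetic panels as long-format monitoring CSV files
#'
#' Writes the three monitoring tables plus area metadata in the standard
#' long layout: `toxins.csv` (Date, Production Area, Species, DSP Toxins),
#' `phyto.csv` (Date, Production Area, DSP Toxins Producers),
#' `environment.csv` (Date, Production Area and the five environmental
#' variables) and `areas.csv`. Dates are ISO-8601; missing weeks are
#' simply absent rows (toxins/phyto) or empty cells (environment), so the
#' files round-trip losslessly through [read_records()] and
#' [resample_weekly()].
#'
#' @param panels Named list with elements `toxins`, `phyto`, `environment`
#'   ([series_panel()] objects).
#' @param areas Area metadata tibble.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
export_datasets <- function(panels, areas, out_dir) {
  stopifnot(all(c("toxins", "phyto", "environment") %in% names(panels)))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  tox <- as_tibble.series_panel(panels$toxins)
  tox <- dplyr::bind_cols(tox["date"], parse_series_id(tox$series_id)[c("area", "species")],
                          tox["value"])
  tox <- dplyr::filter(tox, !is.na(.data$value))
  tox <- dplyr::arrange(tox, .data$date, .data$area, .data$species)
  tox_out <- tibble::tibble(
    Date = tox$date, `Production Area` = tox$area,
    Species = tox$species, `DSP Toxins` = tox$value
  )

  phy <- as_tibble.series_panel(panels$phyto)
  phy <- dplyr::bind_cols(phy["date"], parse_series_id(phy$series_id)["area"], phy["value"])
  phy <- dplyr::filter(phy, !is.na(.data$value))
  phy <- dplyr::arrange(phy, .data$date, .data$area)
  phy_out <- tibble::tibble(
    Date = phy$date, `Production Area` = phy$area,
    `DSP Toxins Producers` = phy$value
  )

  env <- as_tibble.series_panel(panels$environment)
  env <- dplyr::bind_cols(env["date"], parse_series_id(env$series_id)[c("area", "variable")],
                          env["value"])
  env_wide <- tidyr::pivot_wider(env, id_cols = c("date", "area"),
                                 names_from = "variable", values_from = "value")
  env_wide <- dplyr::arrange(env_wide, .data$date, .data$area)
  keep <- intersect(names(env_export_columns), names(env_wide))
  env_out <- env_wide[, c("date", "area", keep)]
  names(env_out) <- c("Date", "Production Area", unname(env_export_columns[keep]))
  env_out <- env_out[rowSums(!is.na(env_out[, -(1:2), drop = FALSE])) > 0, ]

  meta_out <- tibble::tibble(
    area_id = areas$area_id, coast = areas$coast, ns_rank = areas$ns_rank,
    region = areas$region,
    neighbors = vapply(areas$neighbors, paste, "", collapse = ";")
  )

  paths <- file.path(out_dir, c("toxins.csv", "phyto.csv", "environment.csv", "areas.csv"))
  readr::write_csv(tox_out, paths[1], na = "")
  readr::write_csv(phy_out, paths[2], na = "")
  readr::write_csv(env_out, paths[3], na = "")
  readr::write_csv(meta_out, paths[4], na = "")
  invisible(paths)
}

#' Generate a complete synthetic monitoring study
#'
#' Runs the full generator: area chain, environment, blooms, per-species
#' toxin kinetics (bloom forcing scaled by `toxin_yield`, multiplicative
#' log-normal observation noise `obs_noise_sd`), then missingness on the
#' observed panels. All randomness derives from `config$seed`.
#'
#' @param config A [synth_config()].
#' @param out_dir Optional directory; when given, the thinned datasets are
#'   exported via [export_datasets()].
#' @return List with `areas`, `environment`, `blooms`, `toxins` (complete,
#'   noise-free), `toxins_obs`, `phyto_obs`, `environment_obs` (with
#'   observation noise and missingness applied).
#' @export
simulate_monitoring <- function(config = synth_config(), out_dir = NULL) {
  validate_synth_config(config)
  areas <- make_area_metadata(config)
  env <- simulate_environment(config, areas)
  blooms <- simulate_blooms(config, areas, env)

  forcing <- blooms
  for (id in panel_ids(forcing)) {
    P <- forcing$series[[id]]
    forcing$series[[id]] <- config$toxin_yield * P / (1 + P / config$half_sat)
  }
  tox_list <- lapply(config$species, function(k) simulate_toxicity(forcing, k))
  tox_series <- list()
  tox_units <- character()
  for (p in tox_list) {
    for (id in panel_ids(p)) {
      tox_series[[id]] <- p$series[[id]]
      tox_units[id] <- "ug OA eq/kg"
    }
  }
  toxins <- series_panel(panel_index(blooms), tox_series, units = tox_units)

  tox_obs <- toxins
  if (config$obs_noise_sd > 0) {
    set.seed(config$seed + 4L)
    for (id in panel_ids(tox_obs)) {
      nw <- length(tox_obs$series[[id]])
      tox_obs$series[[id]] <- tox_obs$series[[id]] *
        exp(rnorm(nw, -config$obs_noise_sd^2 / 2, config$obs_noise_sd))
    }
  }

  miss_cfg <- config
  tox_obs <- apply_missingness(tox_obs, miss_cfg)
  miss_cfg$seed <- config$seed + 100L
  phy_obs <- apply_missingness(blooms, miss_cfg)
  miss_cfg$seed <- config$seed + 200L
  env_obs <- apply_missingness(env, miss_cfg)

  out <- list(areas = areas, environment = env, blooms = blooms,
              toxins = toxins, toxins_obs = tox_obs, phyto_obs = phy_obs,
              environment_obs = env_obs)
  if (!is.null(out_dir)) {
    export_datasets(list(toxins = tox_obs, phyto = phy_obs, environment = env_obs),
                    areas, out_dir)
  }
  out
}
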