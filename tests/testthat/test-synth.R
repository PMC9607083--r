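test_that("area chain metadata follows the coast/pivot region rule", {
  cfg <- synth_config(seed = 1)
  areas <- make_area_metadata(cfg)
  expect_equal(nrow(areas), 10)
  expect_false(anyDuplicated(areas$area_id) > 0)
  # west-coast areas above the pivot rank are northwest; south coast is south
  expect_true(all(areas$region[areas$coast == "west" & areas$ns_rank < cfg$pivot_rank] == "northwest"))
  expect_true(all(areas$region[areas$coast == "west" & areas$ns_rank >= cfg$pivot_rank] == "southwest"))
  expect_true(all(areas$region[areas$coast == "south"] == "south"))
  # neighbor relation is a symmetric chain: ends 1 neighbor, middles 2
  n_nb <- vapply(areas$neighbors, length, 0L)
  expect_equal(n_nb, c(1L, rep(2L, 8), 1L))
  for (i in seq_len(nrow(areas))) {
    for (nb in areas$neighbors[[i]]) {
      j <- match(nb, areas$area_id)
      expect_true(areas$area_id[i] %in% areas$neighbors[[j]])
    }
  }
  expect_no_error(make_area_metadata(synth_config(n_areas = 2)))
  expect_error(synth_config(n_areas = 1), "n_areas")
})

test_that("middle area of a 3-chain has two neighbors, ends one", {
  areas <- make_area_metadata(synth_config(n_areas = 3, south_areas = 1))
  expect_equal(vapply(areas$neighbors, length, 0L), c(1L, 2L, 1L))
})

test_that("noiseless environment is a clean annual cycle within physical bands", {
  cfg <- small_config(seed = 3, env_noise_sd = 0)
  areas <- make_area_metadata(cfg)
  env <- simulate_environment(cfg, areas)
  sst <- panel_series(env, "A01.sst")
  # pure sinusoid in day-of-year: peak in late August, plausible Kelvin band
  expect_true(all(sst$values > 285 & sst$values < 297))
  peak_month <- as.POSIXlt(sst$index[which.max(sst$values)])$mon + 1
  expect_true(peak_month %in% c(8, 9))
  rain <- panel_series(env, "A01.rain")
  wind <- panel_series(env, "A01.wind")
  chla <- panel_series(env, "A01.chla")
  expect_true(all(rain$values >= 0))
  expect_true(all(wind$values >= 0))
  expect_true(all(chla$values > 0))
})

test_that("same seed reproduces the environment panel exactly", {
  cfg <- small_config(seed = 11)
  areas <- make_area_metadata(cfg)
  e1 <- simulate_environment(cfg, areas)
  e2 <- simulate_environment(cfg, areas)
  expect_identical(e1$series, e2$series)
})

test_that("bloom pulse sharing collapses and decouples at the decay extremes", {
  # decay 1: all areas receive the identical pulse train (before gradient)
  cfg1 <- small_config(seed = 5, spatial_decay = 1, ns_gradient = 1)
  areas <- make_area_metadata(cfg1)
  env <- simulate_environment(cfg1, areas)
  b1 <- simulate_blooms(cfg1, areas, env)
  expect_equal(b1$series[["A01.phyto"]], b1$series[["A03.phyto"]])

  # decay 0 with flat seasonality: independent trains, sample cor ~ 0
  cfg0 <- synth_config(seed = 5, n_areas = 4, south_areas = 1, pivot_rank = 2,
                       start_date = "2015-01-05", end_date = "2034-03-01",
                       spatial_decay = 0, ns_gradient = 1,
                       season_peaks = list(month = 5, amplitude = 0))
  areas0 <- make_area_metadata(cfg0)
  env0 <- simulate_environment(cfg0, areas0)
  b0 <- simulate_blooms(cfg0, areas0, env0)
  expect_gt(length(panel_index(b0)), 990)
  r <- cor(b0$series[["A01.phyto"]], b0$series[["A02.phyto"]])
  expect_lt(abs(r), 0.1)
})

test_that("bloom counts are non-negative and seasonally concentrated", {
  cfg <- synth_config(seed = 7)
  areas <- make_area_metadata(cfg)
  env <- simulate_environment(cfg, areas)
  b <- simulate_blooms(cfg, areas, env)
  v <- b$series[["RIAV1.phyto"]]
  expect_true(all(v >= 0))
  m <- as.POSIXlt(panel_index(b))$mon + 1
  peak <- v[m %in% c(5, 9)]
  off <- v[m %in% c(1, 2, 12)]
  expect_gt(mean(peak), mean(off))
})

test_that("toxin kinetics follow the uptake/elimination recursion exactly", {
  idx <- weekly_index("2015-01-05", "2015-03-30")
  pulse <- rep(0, length(idx)); pulse[3] <- 1
  blooms <- series_panel(idx, list(X.phyto = pulse))
  kin <- species_kinetics("test", uptake_rate = 1, elimination_rate = 0.5, baseline = 0)
  tox <- simulate_toxicity(blooms, kin)
  v <- tox$series[["X.toxin.test"]]
  # unit pulse at week 3 -> 1, 0.5, 0.25, ... from week 4
  expect_equal(v[1:3], c(0, 0, 0))
  expect_equal(v[4:7], c(1, 0.5, 0.25, 0.125))

  # zero forcing holds the series at baseline
  zero <- series_panel(idx, list(X.phyto = rep(0, length(idx))))
  kin_b <- species_kinetics("test", 1, 0.5, baseline = 8)
  flat <- simulate_toxicity(zero, kin_b)$series[["X.toxin.test"]]
  expect_equal(flat, rep(8, length(idx)))

  expect_error(
    simulate_toxicity(series_panel(idx, list(X.phyto = rep(NaN, length(idx)))), kin),
    "non-finite"
  )
})

test_that("a slower-eliminating species lags and exceeds a faster one", {
  set.seed(9)
  idx <- weekly_index("2015-01-05", "2020-12-29")
  P <- rbinom(length(idx), 1, 0.15) * rlnorm(length(idx), 0, 1)
  blooms <- series_panel(idx, list(X.phyto = P))
  fast <- simulate_toxicity(blooms, species_kinetics("fast", 1, 0.8))
  slow <- simulate_toxicity(blooms, species_kinetics("slow", 1, 0.2))
  vf <- fast$series[["X.toxin.fast"]]
  vs <- slow$series[["X.toxin.slow"]]
  expect_gt(mean(vs), mean(vf))
  # both species respond to the shared forcing in the same week, so the
  # curve peaks at or just after lag 0 but decays asymmetrically: the
  # fast species' past predicts the slow one's present
  cv <- lagged_pearson(vs, vf, 10)
  expect_gte(peak_lag(cv)$lag, 0)
  expect_gt(asymmetry_index(cv), 0)
})

test_that("missingness thinning hits the target rate and never alters values", {
  cfg <- synth_config(seed = 21, missing_frac = 0.2, block_gap_rate = 0)
  idx <- weekly_index(cfg$start_date, cfg$end_date)
  set.seed(1)
  panel <- series_panel(idx, list(A.toxin.m = runif(length(idx), 10, 100)))
  thinned <- apply_missingness(panel, cfg)
  mask <- attr(thinned, "missing_mask")[["A.toxin.m"]]
  expect_equal(mean(mask), 0.2, tolerance = 0.25)
  expect_lt(abs(mean(is.na(thinned$series[[1]])) - 0.2), 0.05)
  expect_identical(thinned$series[[1]][!mask], panel$series[[1]][!mask])

  # no thinning at all is the identity
  cfg0 <- synth_config(seed = 21, missing_frac = 0, block_gap_rate = 0)
  same <- apply_missingness(panel, cfg0)
  expect_identical(same$series[[1]], panel$series[[1]])
})

test_that("exported datasets have the documented shapes and round-trip", {
  cfg <- small_config(seed = 13)
  sim <- simulate_monitoring(cfg, out_dir = file.path(tempdir(), "synthx"))
  out <- file.path(tempdir(), "synthx")
  tox_raw <- readr::read_csv(file.path(out, "toxins.csv"), show_col_types = FALSE)
  env_raw <- readr::read_csv(file.path(out, "environment.csv"), show_col_types = FALSE)
  expect_equal(ncol(tox_raw), 4)
  expect_equal(ncol(env_raw), 7)
  expect_true(all(grepl("^\\d{4}-\\d{2}-\\d{2}$", format(tox_raw$Date))))

  # read back and weekly-resample: observed values reproduce the panel
  recs <- read_records(file.path(out, "toxins.csv"), "toxins")
  sid <- "A01.toxin.mussel"
  sub <- recs[recs$area == "A01" & recs$species == "mussel", ]
  ws <- resample_weekly(sub, cfg$start_date, cfg$end_date, series_id = sid)
  truth <- sim$toxins_obs$series[[sid]]
  obs <- !is.na(truth)
  expect_equal(ws$values[obs], truth[obs], tolerance = 1e-12)
  expect_true(all(is.na(ws$values[!obs])))
})

test_that("identical configs export byte-identical files", {
  cfg <- small_config(seed = 17)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  simulate_monitoring(cfg, out_dir = d1)
  simulate_monitoring(cfg, out_dir = d2)
  for (f in c("toxins.csv", "phyto.csv", "environment.csv", "areas.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("planted gradient decreases toxicity southward when variability is off", {
  cfg <- synth_config(seed = 19, spatial_decay = 1, obs_noise_sd = 0,
                      env_noise_sd = 0, ns_gradient = 0.85)
  sim <- simulate_monitoring(cfg)
  ids <- paste0(sim$areas$area_id, ".toxin.mussel")
  means <- vapply(ids, function(id) mean(sim$toxins$series[[id]]), 0)
  expect_true(all(diff(means) <= 1e-9))
})
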