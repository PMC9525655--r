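# Synthetic test bed: multi-site daily weather with a seasonal cycle,
# nursery trial panels generated from a known log-yield truth, and warming
# scenario trajectories. Every draw is seeded; the generating parameters
# (the "truth") are returned so estimators can be checked against them.

#' Configuration for the synthetic test bed
#'
#' Defaults emulate a winter-wheat-like nursery network: a multi-decade
#' panel of sites across a temperature gradient, September-to-July growing
#' windows, log-yield climate responses dominated by a harmful extreme-heat
#' term and a smaller freeze term, lognormal entry dispersion around the
#' site-season median, and a check variety sitting about 30% below the
#' median advanced line. The thresholds used are the documented placeholders
#' of [default_thresholds()]; none of these values claims to replicate a
#' specific published calibration.
#'
#' @param n_sites Number of sites.
#' @param years Integer vector of harvest years.
#' @param annual_mean_range Range of site annual mean temperature (degrees C).
#' @param amplitude_range Range of site seasonal (annual cycle) amplitude (degrees C).
#' @param diurnal_range Mean daily Tmax - Tmin (degrees C).
#' @param noise_sd Day-to-day temperature noise standard deviation (degrees C);
#'   0 gives the deterministic sinusoid.
#' @param noise_ar Lag-1 autocorrelation of the temperature noise.
#' @param prcp_wet_prob Probability a day is wet.
#' @param prcp_shape,prcp_scale Gamma parameters of wet-day precipitation (mm).
#' @param beta Named true climate coefficients on the log-yield scale
#'   (`fdd`, `gdd`, `edd`, `prcp`, `prcp_sq`).
#' @param log_yield_mean Mean site intercept (log kg/ha).
#' @param alpha_sd Between-site spread of intercepts.
#' @param trend1_mean,trend1_sd Site linear trend (log yield per year).
#' @param trend2_sd Site quadratic trend spread.
#' @param yield_noise_sd Site-season log-yield noise (the regression error term).
#' @param entry_count_range Range of entries per site-season.
#' @param entry_sd_log Lognormal dispersion of entries around the median line.
#' @param check_offset Log offset of the check variety relative to the median
#'   advanced line; the default `log(1/1.3)` puts the median line ~30% above
#'   the check.
#' @param plant_date,harvest_date Season window month-days (wrap December 31).
#' @param phases A [phase_schedule()] used when weather is accumulated.
#' @param seed Integer seed; mandatory, all generators derive their streams
#'   from it.
#'
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_sites = 30L,
                             years = 1979:2018,
                             annual_mean_range = c(5, 13),
                             amplitude_range = c(11, 15),
                             diurnal_range = 10,
                             noise_sd = 3,
                             noise_ar = 0.6,
                             prcp_wet_prob = 0.3,
                             prcp_shape = 0.7,
                             prcp_scale = 8,
                             beta = c(fdd = -1e-3, gdd = 2e-5,
                                      edd = -8e-4, prcp = 1.5e-3, prcp_sq = -7e-7),
                             log_yield_mean = 8,
                             alpha_sd = 0.2,
                             trend1_mean = 0.008,
                             trend1_sd = 0.004,
                             trend2_sd = 5e-5,
                             yield_noise_sd = 0.12,
                             entry_count_range = c(20L, 45L),
                             entry_sd_log = 0.08,
                             check_offset = log(1 / 1.3),
                             plant_date = "09-20",
                             harvest_date = "07-10",
                             phases = single_phase(),
                             seed) {
  if (missing(seed)) abort("seed is mandatory in synthetic_config()")
  stopifnot(
    n_sites >= 2L, length(years) >= 2L,
    noise_sd >= 0, yield_noise_sd >= 0, entry_sd_log >= 0, alpha_sd >= 0,
    all(c("fdd", "gdd", "edd", "prcp", "prcp_sq") %in% names(beta))
  )
  cfg <- list(
    n_sites = as.integer(n_sites), years = as.integer(years),
    annual_mean_range = annual_mean_range, amplitude_range = amplitude_range,
    diurnal_range = diurnal_range, noise_sd = noise_sd, noise_ar = noise_ar,
    prcp_wet_prob = prcp_wet_prob, prcp_shape = prcp_shape, prcp_scale = prcp_scale,
    beta = beta, log_yield_mean = log_yield_mean, alpha_sd = alpha_sd,
    trend1_mean = trend1_mean, trend1_sd = trend1_sd, trend2_sd = trend2_sd,
    yield_noise_sd = yield_noise_sd,
    entry_count_range = as.integer(entry_count_range), entry_sd_log = entry_sd_log,
    check_offset = check_offset,
    plant_date = plant_date, harvest_date = harvest_date, phases = phases,
    seed = as.integer(seed)
  )
  structure(cfg, class = "synthetic_config")
}

site_ids <- function(cfg) sprintf("S%02d", seq_len(cfg$n_sites))

# Deterministic site attributes (temperature climate, fixed-effect truth)
# derived from the config seed; independent of which generator runs first.
site_attributes <- function(cfg) {
  withr_seed(cfg$seed, {
    n <- cfg$n_sites
    tibble::tibble(
      site_id = site_ids(cfg),
      annual_mean = runif(n, cfg$annual_mean_range[1], cfg$annual_mean_range[2]),
      amplitude = runif(n, cfg$amplitude_range[1], cfg$amplitude_range[2]),
      alpha = rnorm(n, cfg$log_yield_mean, cfg$alpha_sd),
      trend1 = rnorm(n, cfg$trend1_mean, cfg$trend1_sd),
      trend2 = rnorm(n, 0, cfg$trend2_sd)
    )
  })
}

# Run code under a local RNG seed without disturbing the caller's stream.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic daily station weather
#'
#' Daily mean temperature follows a site-specific annual sinusoid (peak in
#' mid-July) plus AR(1) day-to-day noise; Tmin/Tmax sit half the diurnal
#' range below/above it. Precipitation is a seeded wet-day/Gamma draw.
#' Weather covers the calendar year before the first harvest year through
#' the last harvest year, so every (possibly wrapping) season window resolves.
#'
#' @param config A [synthetic_config()].
#' @return A daily weather tibble (`site_id`, `date`, `tmin`, `tmax`, `prcp`).
#' @export
gen_weather <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  attrs <- site_attributes(config)
  dates <- seq(as.Date(sprintf("%d-01-01", min(config$years) - 1L)),
               as.Date(sprintf("%d-12-31", max(config$years))), by = "day")
  doy <- as.integer(format(dates, "%j"))
  n_d <- length(dates)

  withr_seed(config$seed + 1L, {
    purrr::map_dfr(seq_len(config$n_sites), function(i) {
      cyc <- attrs$annual_mean[i] - attrs$amplitude[i] * cos(2 * pi * (doy - 15) / 365.25)
      noise <- if (config$noise_sd > 0) {
        as.numeric(stats::arima.sim(list(ar = config$noise_ar), n_d,
                                    sd = config$noise_sd * sqrt(1 - config$noise_ar^2)))
      } else {
        numeric(n_d)
      }
      tavg <- cyc + noise
      half <- config$diurnal_range / 2
      wet <- runif(n_d) < config$prcp_wet_prob
      prcp <- ifelse(wet, rgamma(n_d, config$prcp_shape, scale = config$prcp_scale), 0)
      tibble::tibble(
        site_id = attrs$site_id[i], date = dates,
        tmin = tavg - half, tmax = tavg + half, prcp = prcp
      )
    })
  })
}

#' Season windows implied by a synthetic config
#'
#' @param config A [synthetic_config()].
#' @return A [season_windows()] table for the synthetic sites.
#' @export
gen_windows <- function(config) {
  season_windows(site_ids(config), config$plant_date, config$harvest_date)
}

#' Draw season-climate indices directly (no daily weather)
#'
#' A shortcut for simulation studies where only the regression layer is under
#' test: draws FDD/GDD/EDD/Prcp per site-season from site-level means with a
#' shared warm-year anomaly (so the indices are realistically correlated but
#' not collinear), skipping the daily-weather and accumulation stages.
#'
#' @param config A [synthetic_config()].
#' @return A usable `season_climate`-shaped tibble.
#' @export
gen_season_climates <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  attrs <- site_attributes(config)
  grid <- tidyr::expand_grid(site_id = attrs$site_id, season_year = config$years)
  n <- nrow(grid)
  i <- match(grid$site_id, attrs$site_id)
  withr_seed(config$seed + 2L, {
    warm <- rnorm(n)                                  # shared warm-year anomaly
    gdd <- 1800 + 60 * (attrs$annual_mean[i] - 9) + 45 * warm + rnorm(n, 0, 25)
    edd <- pmax(0, 25 + 5 * (attrs$annual_mean[i] - 9) + 7 * warm + rnorm(n, 0, 4))
    fdd <- pmax(0, 180 - 12 * (attrs$annual_mean[i] - 9) - 20 * warm + rnorm(n, 0, 15))
    prcp <- rgamma(n, shape = 12, scale = 30)
    tibble::tibble(
      site_id = grid$site_id, season_year = grid$season_year,
      fdd = fdd, gdd = gdd, edd = edd, prcp = prcp,
      n_days = 293L, n_days_missing = 0L, usable = TRUE
    )
  })
}

#' Generate nursery trials from a known log-yield truth
#'
#' The site-season median log yield follows the fixed-effects truth
#' `alpha_i + trend1_i t + trend2_i t^2 + sum(beta_k x_k) + noise`; entries
#' are drawn lognormally around the median, and the check yield is the
#' deterministic median times `exp(check_offset)`. Returns the trials along
#' with a truth record (true coefficients, site effects, and offsets) for
#' recovery checks.
#'
#' @param config A [synthetic_config()].
#' @param season_climates A season-climate table ([accumulate_season()] on
#'   [gen_weather()] output, or [gen_season_climates()]).
#' @return A list with elements `trials` (a trial-record tibble) and `truth`.
#' @export
gen_trials <- function(config, season_climates) {
  stopifnot(inherits(config, "synthetic_config"))
  clim <- dplyr::filter(tibble::as_tibble(season_climates), .data$usable)
  attrs <- site_attributes(config)
  clim <- dplyr::inner_join(clim, attrs, by = "site_id")
  t <- clim$season_year - min(clim$season_year)
  b <- config$beta
  mu <- clim$alpha + clim$trend1 * t + clim$trend2 * t^2 +
    b[["fdd"]] * clim$fdd + b[["gdd"]] * clim$gdd + b[["edd"]] * clim$edd +
    b[["prcp"]] * clim$prcp + b[["prcp_sq"]] * clim$prcp^2

  withr_seed(config$seed + 3L, {
    mu <- mu + rnorm(nrow(clim), 0, config$yield_noise_sd)
    n_entries <- sample(seq(config$entry_count_range[1], config$entry_count_range[2]),
                        nrow(clim), replace = TRUE)
    trials <- purrr::map_dfr(seq_len(nrow(clim)), function(r) {
      dev <- rnorm(n_entries[r], 0, config$entry_sd_log)
      dev <- dev - median(dev)   # entries centred so their median is exp(mu)
      tibble::tibble(
        site_id = clim$site_id[r], season_year = clim$season_year[r],
        entry_id = c(sprintf("E%03d", seq_len(n_entries[r])), "CHECK"),
        yield = c(exp(mu[r] + dev), exp(mu[r] + config$check_offset)),
        is_check = c(rep(FALSE, n_entries[r]), TRUE)
      )
    })
    truth <- list(
      beta = b,
      alpha = attrs[c("site_id", "alpha", "trend1", "trend2")],
      check_offset = config$check_offset,
      year0 = min(clim$season_year),
      seed = config$seed
    )
    list(trials = trials, truth = truth)
  })
}

#' Generate warming scenario season-climate trajectories
#'
#' Applies linear-in-year warming to recycled baseline weather years and
#' accumulates the thermal indices, producing one trajectory per scenario and
#' pseudo climate model (models perturb the scenario's warming rate). The
#' generated series exhibit the qualitative structure of warming projections:
#' GDD and EDD increase and FDD decreases over time.
#'
#' @param config A [synthetic_config()].
#' @param weather Baseline daily weather from [gen_weather()].
#' @param rates Named numeric vector of warming rates (degrees C per year) per
#'   scenario.
#' @param years Future harvest years (default 2021:2100).
#' @param n_models Pseudo climate models per scenario.
#' @param model_rate_sd Standard deviation of the per-model rate perturbation
#'   (degrees C per year).
#'
#' @return A scenario season-climate tibble for [project_trajectory()].
#' @export
gen_scenarios <- function(config, weather, rates = c(low = 0.01, high = 0.05),
                          years = 2021:2100, n_models = 3L, model_rate_sd = 0.005) {
  stopifnot(inherits(config, "synthetic_config"))
  weather <- tibble::as_tibble(weather)
  windows <- gen_windows(config)
  base_years <- sort(unique(as.integer(format(weather$date, "%Y"))))
  if (length(base_years) > 2L) base_years <- base_years[-1L]   # first year lacks a full window
  years <- sort(unique(as.integer(years)))
  year_ref <- min(years) - 1L
  wyear <- as.integer(format(weather$date, "%Y"))

  withr_seed(config$seed + 4L, {
    model_rates <- lapply(setNames(names(rates), names(rates)), function(s) {
      r <- rates[[s]] + c(0, rnorm(n_models - 1L, 0, model_rate_sd))
      pmax(r, 0)
    })
    purrr::map_dfr(names(rates), function(s) {
      purrr::map_dfr(seq_len(n_models), function(m) {
        rate <- model_rates[[s]][m]
        purrr::map_dfr(years, function(y) {
          src <- base_years[((y - min(years)) %% length(base_years)) + 1L]
          w <- weather[wyear %in% c(src - 1L, src), , drop = FALSE]
          w <- perturb_weather(w, rate * (y - year_ref))
          clim <- accumulate_season(w, windows, config$phases)
          clim <- dplyr::filter(tibble::as_tibble(clim), .data$usable,
                                .data$season_year == src)
          tibble::tibble(
            scenario_id = s, model_id = sprintf("M%d", m),
            site_id = clim$site_id, season_year = y,
            fdd = clim$fdd, gdd = clim$gdd, edd = clim$edd, prcp = clim$prcp
          )
        })
      })
    })
  })
}
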