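# Thermal exposure indices: FDD / GDD / EDD accumulated from an hourly
# temperature curve reconstructed from daily Tmin/Tmax.

#' Thermal threshold set for one growing phase
#'
#' Bundles the base, optimum, and freeze-injury temperature thresholds that
#' define the degree-day indices. Growing degree-days (GDD) accumulate hourly
#' exceedance of `t_base` capped at `t_opt`; extreme growing degree-days (EDD)
#' accumulate exceedance of `t_opt`; freezing degree-days (FDD) accumulate
#' shortfall below `t_frez`.
#'
#' The package ships no claim about crop-specific values: thresholds are
#' mandatory configuration. [default_thresholds()] provides a documented
#' placeholder set used by the synthetic test bed only.
#'
#' @param t_base Base growing temperature (degrees C).
#' @param t_opt Optimum growing temperature (degrees C); must exceed `t_base`.
#' @param t_frez Freeze-injury temperature (degrees C); must not exceed `t_base`.
#'
#' @return A `thermal_thresholds` list with elements `t_base`, `t_opt`, `t_frez`.
#' @examples
#' thermal_thresholds(t_base = 0, t_opt = 17, t_frez = -5)
#' @export
thermal_thresholds <- function(t_base, t_opt, t_frez) {
  for (x in list(t_base, t_opt, t_frez)) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      abort("thresholds must be finite numeric scalars")
    }
  }
  if (!(t_frez <= t_base && t_base < t_opt)) {
    abort(sprintf(
      "thresholds must satisfy t_frez <= t_base < t_opt (got %g, %g, %g)",
      t_frez, t_base, t_opt
    ))
  }
  structure(list(t_base = t_base, t_opt = t_opt, t_frez = t_frez),
            class = "thermal_thresholds")
}

#' Placeholder thresholds for the synthetic test bed
#'
#' A single-phase threshold set (`t_base` = 0, `t_opt` = 17, `t_frez` = -5 degrees C)
#' used by the synthetic-data generator and examples. These are plausible
#' magnitudes for a cool-season cereal but are explicitly *not* a replication
#' of any published crop-specific calibration; replication runs must supply
#' their own per-phase thresholds.
#'
#' @return A [thermal_thresholds()] object.
#' @export
default_thresholds <- function() {
  thermal_thresholds(t_base = 0, t_opt = 17, t_frez = -5)
}

#' Phase schedule mapping season fractions to thresholds
#'
#' Because per-trial phenology is typically unavailable in long nursery
#' records, growing phases are mapped to fixed fractions of the season
#' window. The fractions must partition `[0, 1]` in order without overlap.
#'
#' @param phases A data frame with columns `phase`, `frac_start`, `frac_end`,
#'   `t_base`, `t_opt`, `t_frez`, one row per phase in chronological order.
#'
#' @return A `phase_schedule` tibble.
#' @seealso [single_phase()] for the common whole-season case.
#' @export
phase_schedule <- function(phases) {
  phases <- tibble::as_tibble(phases)
  need <- c("phase", "frac_start", "frac_end", "t_base", "t_opt", "t_frez")
  missing_cols <- setdiff(need, names(phases))
  if (length(missing_cols)) {
    abort(paste0("phase schedule lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(phases) == 0L) abort("phase schedule must contain at least one phase")
  if (abs(phases$frac_start[1]) > 1e-12 || abs(phases$frac_end[nrow(phases)] - 1) > 1e-12) {
    abort("phase fractions must start at 0 and end at 1")
  }
  if (nrow(phases) > 1L) {
    gaps <- phases$frac_start[-1] - phases$frac_end[-nrow(phases)]
    if (any(abs(gaps) > 1e-12)) abort("phase fractions must partition [0, 1] without gaps or overlap")
  }
  if (any(phases$frac_end <= phases$frac_start)) abort("each phase must span a positive fraction")
  for (i in seq_len(nrow(phases))) {
    thermal_thresholds(phases$t_base[i], phases$t_opt[i], phases$t_frez[i])
  }
  structure(phases, class = c("phase_schedule", class(phases)))
}

#' Single-phase schedule covering the whole season
#'
#' @param thresholds A [thermal_thresholds()] object applied to the entire window.
#' @return A [phase_schedule()] with one phase.
#' @export
single_phase <- function(thresholds = default_thresholds()) {
  stopifnot(inherits(thresholds, "thermal_thresholds"))
  phase_schedule(tibble::tibble(
    phase = "season", frac_start = 0, frac_end = 1,
    t_base = thresholds$t_base, t_opt = thresholds$t_opt, t_frez = thresholds$t_frez
  ))
}

#' Fixed growing-season windows per site
#'
#' Average planting and harvest month-days per site. Fixed calendar windows
#' (rather than year-specific phenology) avoid endogeneity between season
#' length and thermal accumulation. Windows that wrap December 31 (winter
#' crops) are supported; seasons are labelled by harvest year.
#'
#' @param site_id Character vector of site identifiers.
#' @param plant_date,harvest_date Month-day strings (`"mm-dd"`), recycled.
#'
#' @return A `season_window` tibble with one row per site.
#' @examples
#' season_windows("S1", plant_date = "09-20", harvest_date = "07-10")
#' @export
season_windows <- function(site_id, plant_date, harvest_date) {
  out <- tibble::tibble(
    site_id = as.character(site_id),
    plant_date = as.character(plant_date),
    harvest_date = as.character(harvest_date)
  )
  ok <- grepl("^\\d{2}-\\d{2}$", out$plant_date) & grepl("^\\d{2}-\\d{2}$", out$harvest_date)
  if (!all(ok)) abort("plant_date and harvest_date must be 'mm-dd' strings")
  if (anyDuplicated(out$site_id)) abort("one window per site_id")
  structure(out, class = c("season_window", class(out)))
}

#' Hourly temperature from daily extremes
#'
#' Reconstructs the temperature at hour `h` (1-24) of a day from its minimum
#' and maximum via a cosine diurnal cycle peaking at hour 14:
#' `T_h = (t_min + t_max)/2 + (t_max - t_min) * cos(0.2618 * (h - 14)) / 2`.
#' The constant 0.2618 (about 2*pi/24) is used verbatim so the curve is
#' reproducible bit-for-bit.
#'
#' @param t_min,t_max Daily minimum and maximum temperature (degrees C).
#' @param h Hour of day, integer in 1-24. Arguments are recycled to a common
#'   length.
#'
#' @return Temperature at hour `h` (degrees C).
#' @examples
#' hourly_temperature(10, 20, 14) # 20, the daily maximum
#' hourly_temperature(10, 20, 8)  # ~15, the daily mean
#' @export
hourly_temperature <- function(t_min, t_max, h) {
  if (any(!is.na(t_min) & !is.na(t_max) & t_min > t_max)) {
    bad <- which(!is.na(t_min) & !is.na(t_max) & t_min > t_max)[1]
    abort(sprintf("t_min > t_max (record %d: %g > %g)", bad, t_min[bad], t_max[bad]))
  }
  if (any(!is.na(h) & (h < 1 | h > 24 | h != round(h)))) {
    abort("h must be an integer hour in 1..24")
  }
  (t_min + t_max) / 2 + (t_max - t_min) * cos(0.2618 * (h - 14)) / 2
}

# Vectorised daily degree-day increments; thresholds may vary per day.
# Returns a data.frame of gdd/edd/fdd; rows with missing temperatures are NA.
dd_daily <- function(t_min, t_max, t_base, t_opt, t_frez) {
  n <- length(t_min)
  hrs <- matrix(cos(0.2618 * ((1:24) - 14)), nrow = n, ncol = 24, byrow = TRUE)
  th <- (t_min + t_max) / 2 + (t_max - t_min) / 2 * hrs
  gdd <- rowSums(pmin(pmax(th - t_base, 0), t_opt - t_base)) / 24
  edd <- rowSums(pmax(th - t_opt, 0)) / 24
  fdd <- rowSums(pmax(t_frez - th, 0)) / 24
  data.frame(gdd = gdd, edd = edd, fdd = fdd)
}

#' Degree-day increments for one or more days
#'
#' Sums the piecewise hourly increments of the three thermal indices over the
#' 24 reconstructed hours of each day, each increment divided by 24. The GDD
#' increment is capped hourly at `(t_opt - t_base)/24`; EDD accumulates only
#' above `t_opt`; FDD accumulates only at or below `t_frez`. Days with a
#' missing temperature yield `NA` (marked missing, never silently zero).
#'
#' @param t_min,t_max Daily temperature extremes (degrees C), vectors of equal length.
#' @param thresholds A [thermal_thresholds()] object.
#'
#' @return A tibble with columns `gdd`, `edd`, `fdd` (degree-days, one row per day).
#' @examples
#' daily_degree_days(10, 25, thermal_thresholds(0, 17, -5))
#' @export
daily_degree_days <- function(t_min, t_max, thresholds) {
  stopifnot(inherits(thresholds, "thermal_thresholds"))
  if (length(t_min) != length(t_max)) abort("t_min and t_max must have equal length")
  bad <- !is.na(t_min) & !is.na(t_max) & t_min > t_max
  if (any(bad)) {
    abort(sprintf("t_min > t_max (record %d: %g > %g)",
                  which(bad)[1], t_min[which(bad)[1]], t_max[which(bad)[1]]))
  }
  out <- dd_daily(t_min, t_max, thresholds$t_base, thresholds$t_opt, thresholds$t_frez)
  tibble::as_tibble(out)
}

# Resolve one site's window for a given harvest year; returns Date start/end.
resolve_window <- function(plant_date, harvest_date, harvest_year) {
  end <- as.Date(sprintf("%d-%s", harvest_year, harvest_date))
  start <- as.Date(sprintf("%d-%s", harvest_year, plant_date))
  wraps <- start >= end
  start[wraps] <- as.Date(sprintf("%d-%s", harvest_year - 1, plant_date))[wraps]
  len <- as.integer(end - start) + 1L
  if (any(len < 30L | len > 365L)) {
    abort(sprintf("season window length %d days outside 30..365", len[which(len < 30 | len > 365)[1]]))
  }
  list(start = start, end = end, length = len)
}

#' Accumulate thermal indices and precipitation over site-seasons
#'
#' For every site in `windows` and every harvest year whose window is fully
#' covered by the supplied weather span, computes per-day degree-day
#' increments using the thresholds of the day's growing phase (assigned by
#' season fraction) and sums them, together with precipitation, into one row
#' per site-season. Seasons missing more than `gap_tolerance` of their days
#' are flagged unusable and excluded downstream.
#'
#' @param weather A tibble of daily weather with columns `site_id`, `date`
#'   (`Date`), `tmin`, `tmax`, `prcp` (see [read_weather()], [gen_weather()]).
#' @param windows A [season_windows()] table.
#' @param phases A [phase_schedule()]; defaults to a single phase with the
#'   placeholder thresholds.
#' @param gap_tolerance Maximum tolerated fraction of missing days (default 0.05).
#'
#' @return A `season_climate` tibble: `site_id`, `season_year` (harvest year),
#'   `fdd`, `gdd`, `edd`, `prcp`, `n_days`, `n_days_missing`, `usable`.
#' @export
accumulate_season <- function(weather, windows, phases = single_phase(),
                              gap_tolerance = 0.05) {
  stopifnot(inherits(phases, "phase_schedule"))
  weather <- tibble::as_tibble(weather)
  need <- c("site_id", "date", "tmin", "tmax", "prcp")
  if (!all(need %in% names(weather))) {
    abort(paste0("weather lacks columns: ", paste(setdiff(need, names(weather)), collapse = ", ")))
  }
  if (nrow(weather) == 0L) abort("empty weather table")
  windows <- tibble::as_tibble(windows)

  res <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    sid <- windows$site_id[i]
    w <- weather[weather$site_id == sid, , drop = FALSE]
    if (nrow(w) == 0L) next
    span <- range(w$date)
    yrs <- seq(as.integer(format(span[1], "%Y")), as.integer(format(span[2], "%Y")))
    rows <- lapply(yrs, function(y) {
      win <- tryCatch(resolve_window(windows$plant_date[i], windows$harvest_date[i], y),
                      error = function(e) NULL)
      if (is.null(win) || win$start < span[1] || win$end > span[2]) return(NULL)
      season_accumulate_one(w, sid, y, win, phases, gap_tolerance)
    })
    res[[i]] <- dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) abort("no resolvable site-seasons within the weather span")
  structure(out, class = c("season_climate", class(out)))
}

season_accumulate_one <- function(w, sid, year, win, phases, gap_tolerance) {
  days <- seq(win$start, win$end, by = "day")
  n <- length(days)
  idx <- match(days, w$date)
  tmin <- w$tmin[idx]
  tmax <- w$tmax[idx]
  prcp <- w$prcp[idx]
  miss <- is.na(tmin) | is.na(tmax)
  n_missing <- sum(miss)

  # day's phase by mid-day season fraction
  frac <- (seq_len(n) - 0.5) / n
  ph <- findInterval(frac, phases$frac_start, rightmost.closed = TRUE)
  ph[ph < 1L] <- 1L
  ph[ph > nrow(phases)] <- nrow(phases)

  dd <- dd_daily(tmin[!miss], tmax[!miss],
                 phases$t_base[ph[!miss]], phases$t_opt[ph[!miss]], phases$t_frez[ph[!miss]])
  tibble::tibble(
    site_id = sid, season_year = year,
    fdd = sum(dd$fdd), gdd = sum(dd$gdd), edd = sum(dd$edd),
    prcp = sum(prcp, na.rm = TRUE),
    n_days = n, n_days_missing = n_missing,
    usable = n_missing / n <= gap_tolerance
  )
}

#' Apply a uniform temperature perturbation
#'
#' Raises (or lowers) both daily extremes by `delta_t`, which shifts the
#' whole reconstructed hourly curve uniformly. Precipitation is unchanged.
#' This is the warming counterfactual: indices recomputed from the perturbed
#' weather, differenced against the observed indices, quantify how warming
#' moves thermal exposure.
#'
#' @param weather Daily weather tibble (columns `site_id`, `date`, `tmin`,
#'   `tmax`, `prcp`).
#' @param delta_t Temperature increment in degrees C (finite scalar).
#'
#' @return The weather tibble with `tmin` and `tmax` shifted.
#' @export
perturb_weather <- function(weather, delta_t) {
  if (!is.numeric(delta_t) || length(delta_t) != 1L || !is.finite(delta_t)) {
    abort("delta_t must be a finite scalar")
  }
  weather <- tibble::as_tibble(weather)
  weather$tmin <- weather$tmin + delta_t
  weather$tmax <- weather$tmax + delta_t
  weather
}
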