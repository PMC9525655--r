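# Apply fitted genotype models to scenario climate trajectories. Future
# yields are expressed relative to the check variety's baseline-period
# level; non-climate terms (site effects, time trends) are frozen at their
# baseline means so the trajectories isolate the climate signal.

# Climate-term values for a set of rows carrying fdd/gdd/edd/prcp columns.
term_values <- function(rows, terms) {
  m <- sapply(terms, function(term) if (term == "prcp_sq") rows$prcp^2 else rows[[term]])
  matrix(m, nrow = nrow(rows), dimnames = list(NULL, terms))
}

# Frozen non-climate level: baseline mean of alpha_i + a1_i t + a2_i t^2
# over the site-seasons the model was fitted on.
frozen_level <- function(fit) {
  a <- fit$alpha[match(fit$keys$site_id, fit$alpha$site_id), ]
  t <- fit$keys$season_year - fit$year0
  mean(a$intercept + a$trend1 * t + a$trend2 * t^2)
}

# Baseline log level of one fit: frozen non-climate level plus coefficients
# times the baseline mean of each climate term.
baseline_log_level <- function(fit, baseline_panel) {
  rows <- dplyr::inner_join(
    fit$keys,
    dplyr::filter(tibble::as_tibble(baseline_panel),
                  .data$genotype_class == fit$genotype),
    by = c("site_id", "season_year")
  )
  beta <- climate_coefs(fit)
  frozen_level(fit) + sum(beta * colMeans(term_values(rows, names(beta))))
}

#' Project genotype yield trajectories under scenario climate
#'
#' For each scenario, climate model, and future year, computes each
#' genotype's log yield level as its frozen baseline non-climate level plus
#' its climate coefficients applied to the scenario's site-mean climate, and
#' expresses it as a percentage change relative to the check variety's
#' baseline-period level. Summaries across climate models (median and 95%
#' inter-model band) are obtained with [summarize_projection()].
#'
#' @param fits Named list of [fit_panel()] results, one per genotype class,
#'   including `"CK"` — see [fit_all_genotypes()].
#' @param baseline_panel The historical [assemble_panel()] tibble the models
#'   were fitted on; supplies the baseline climate means.
#' @param scenario A tibble of future season climate with columns
#'   `scenario_id`, `model_id`, `site_id`, `season_year`, `fdd`, `gdd`,
#'   `edd`, `prcp` — see [gen_scenarios()] or [scenario_from_deltas()].
#' @param sites Optional declared subset of fitted sites the scenario covers;
#'   by default the scenario must cover exactly the fitted site set.
#'
#' @return A `projection` tibble with one row per scenario, model, year, and
#'   genotype: `log_level` and `pct_vs_ck_baseline`.
#' @export
project_trajectory <- function(fits, baseline_panel, scenario, sites = NULL) {
  if (!"CK" %in% names(fits)) abort("fits must include the check variety 'CK'")
  scenario <- tibble::as_tibble(scenario)
  need <- c("scenario_id", "model_id", "site_id", "season_year", "fdd", "gdd", "edd", "prcp")
  if (!all(need %in% names(scenario))) {
    abort(paste0("scenario lacks columns: ", paste(setdiff(need, names(scenario)), collapse = ", ")))
  }
  fit_sites <- fits[["CK"]]$alpha$site_id
  sc_sites <- unique(scenario$site_id)
  expected <- sites %||% fit_sites
  if (!setequal(sc_sites, expected) || !all(expected %in% fit_sites)) {
    abort("scenario sites do not match the fitted sites (declare a subset via `sites`)")
  }

  ck_base <- baseline_log_level(fits[["CK"]], baseline_panel)
  frozen <- vapply(fits, frozen_level, numeric(1))

  terms_by_fit <- lapply(fits, function(f) climate_coefs(f))
  by_cell <- dplyr::group_by(scenario, .data$scenario_id, .data$model_id, .data$season_year)
  cell_means <- dplyr::summarise(by_cell,
    prcp_sq = mean(.data$prcp^2),   # before prcp is replaced by its mean
    fdd = mean(.data$fdd), gdd = mean(.data$gdd), edd = mean(.data$edd),
    prcp = mean(.data$prcp),
    .groups = "drop"
  )
  out <- purrr::map_dfr(names(fits), function(g) {
    beta <- terms_by_fit[[g]]
    xb <- as.matrix(cell_means[names(beta)]) %*% beta
    tibble::tibble(
      scenario_id = cell_means$scenario_id, model_id = cell_means$model_id,
      season_year = cell_means$season_year, genotype = g,
      log_level = frozen[[g]] + as.numeric(xb)
    )
  })
  out$pct_vs_ck_baseline <- 100 * (exp(out$log_level - ck_base) - 1)
  out <- dplyr::arrange(out, .data$scenario_id, .data$model_id,
                        .data$season_year, .data$genotype)
  attr(out, "ck_baseline_log_level") <- ck_base
  structure(out, class = c("projection", class(out)))
}

#' Summarize a projection across climate models
#'
#' @param projection A [project_trajectory()] result.
#' @return Per scenario, year, and genotype: the median percentage change
#'   across models and the 2.5th/97.5th percentile inter-model band.
#' @export
summarize_projection <- function(projection) {
  by <- dplyr::group_by(tibble::as_tibble(projection),
                        .data$scenario_id, .data$season_year, .data$genotype)
  dplyr::summarise(by,
    median_pct = median(.data$pct_vs_ck_baseline),
    band_low = quantile(.data$pct_vs_ck_baseline, 0.025, names = FALSE),
    band_high = quantile(.data$pct_vs_ck_baseline, 0.975, names = FALSE),
    n_models = dplyr::n_distinct(.data$model_id),
    .groups = "drop"
  )
}

#' Default future periods
#'
#' The 2030s, 2050s, and 2090s as 20-year windows (2021-2040, 2041-2060,
#' 2081-2100). Period boundaries are a reporting convention, not a model
#' input, and are fully configurable.
#'
#' @return Named list of integer year ranges.
#' @export
default_periods <- function() {
  list("2030s" = 2021:2040, "2050s" = 2041:2060, "2090s" = 2081:2100)
}

#' Genotype yield gains over the check variety by future period
#'
#' Within each scenario, climate model, and period, the gain of genotype g is
#' `100 * (exp(mean log-level_g - mean log-level_CK) - 1)` over the period's
#' years. The distribution across climate models is summarized as median,
#' quartiles, and range.
#'
#' @param projection A [project_trajectory()] result.
#' @param periods Named list of integer year vectors (default [default_periods()]).
#'
#' @return A tibble with per-model gains (`gain_pct`) nested in columns
#'   `scenario_id`, `model_id`, `period`, `genotype`, plus an across-model
#'   summary attached as attribute `"summary"` (also returned by
#'   [summarize_gains()]).
#' @export
period_gains <- function(projection, periods = default_periods()) {
  proj <- tibble::as_tibble(projection)
  if (length(periods) == 0L) abort("periods must be non-empty")
  per <- purrr::imap_dfr(periods, function(yrs, label) {
    rows <- dplyr::filter(proj, .data$season_year %in% yrs)
    if (nrow(rows) == 0L) abort(paste0("projection covers no years of period ", label))
    by <- dplyr::group_by(rows, .data$scenario_id, .data$model_id, .data$genotype)
    lev <- dplyr::summarise(by, mean_log = mean(.data$log_level), .groups = "drop")
    ck <- dplyr::filter(lev, .data$genotype == "CK")
    lev <- dplyr::left_join(lev, ck[c("scenario_id", "model_id", "mean_log")],
                            by = c("scenario_id", "model_id"), suffix = c("", "_ck"))
    tibble::tibble(
      period = label, scenario_id = lev$scenario_id, model_id = lev$model_id,
      genotype = lev$genotype,
      gain_pct = 100 * (exp(lev$mean_log - lev$mean_log_ck) - 1)
    )
  })
  structure(per, class = c("period_gains", class(per)))
}

#' Summarize period gains across climate models
#'
#' @param gains A [period_gains()] result.
#' @return Median, quartiles, and range of the per-model gains for each
#'   period, scenario, and genotype.
#' @export
summarize_gains <- function(gains) {
  by <- dplyr::group_by(tibble::as_tibble(gains),
                        .data$period, .data$scenario_id, .data$genotype)
  dplyr::summarise(by,
    median_pct = median(.data$gain_pct),
    q25 = quantile(.data$gain_pct, 0.25, names = FALSE),
    q75 = quantile(.data$gain_pct, 0.75, names = FALSE),
    min_pct = min(.data$gain_pct), max_pct = max(.data$gain_pct),
    n_models = dplyr::n_distinct(.data$model_id),
    .groups = "drop"
  )
}

#' Build scenario season climate from monthly delta factors
#'
#' A delta-change scenario generator: baseline daily weather is shifted by
#' per-month temperature deltas (and precipitation ratios) that grow linearly
#' from the start to the end of the future span, recycling baseline years as
#' the weather template, then accumulated into season climate. This is a
#' deliberately simple stand-in for site-level downscaled model output; it
#' is not a downscaling method.
#'
#' @param weather Baseline daily weather tibble.
#' @param windows [season_windows()] for the sites.
#' @param phases [phase_schedule()].
#' @param delta_table Tibble with columns `scenario_id`, `model_id`, `month`
#'   (1-12), `d_tmin`, `d_tmax`, `prcp_ratio` giving the deltas reached at
#'   `year_end`.
#' @param years Integer vector of future harvest years to generate.
#' @param gap_tolerance Passed to [accumulate_season()].
#'
#' @return Scenario season-climate tibble as consumed by [project_trajectory()].
#' @export
scenario_from_deltas <- function(weather, windows, phases = single_phase(),
                                 delta_table, years, gap_tolerance = 0.05) {
  weather <- tibble::as_tibble(weather)
  delta_table <- tibble::as_tibble(delta_table)
  need <- c("scenario_id", "model_id", "month", "d_tmin", "d_tmax", "prcp_ratio")
  if (!all(need %in% names(delta_table))) {
    abort(paste0("delta table lacks columns: ", paste(setdiff(need, names(delta_table)), collapse = ", ")))
  }
  base_years <- sort(unique(as.integer(format(weather$date, "%Y"))))
  # drop edge years that cannot host a full window
  if (length(base_years) > 2L) base_years <- base_years[-c(1L, length(base_years))]
  years <- sort(unique(as.integer(years)))
  span <- max(years) - min(years)

  cells <- dplyr::distinct(delta_table[c("scenario_id", "model_id")])
  purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    dt <- dplyr::filter(delta_table,
                        .data$scenario_id == cells$scenario_id[i],
                        .data$model_id == cells$model_id[i])
    purrr::map_dfr(years, function(y) {
      frac <- if (span == 0) 1 else (y - min(years)) / span
      src <- base_years[((y - min(years)) %% length(base_years)) + 1L]
      w <- weather[format(weather$date, "%Y") %in% as.character((src - 1):src), , drop = FALSE]
      mo <- as.integer(format(w$date, "%m"))
      j <- match(mo, dt$month)
      w$tmin <- w$tmin + frac * dt$d_tmin[j]
      w$tmax <- w$tmax + frac * dt$d_tmax[j]
      w$prcp <- w$prcp * (1 + frac * (dt$prcp_ratio[j] - 1))
      # accumulate on the template dates, then relabel the season to the
      # future harvest year
      clim <- accumulate_season(w, windows, phases, gap_tolerance)
      clim <- dplyr::filter(tibble::as_tibble(clim), .data$usable,
                            .data$season_year == src)
      clim$season_year <- y
      tibble::tibble(
        scenario_id = cells$scenario_id[i], model_id = cells$model_id[i],
        clim[c("site_id", "season_year", "fdd", "gdd", "edd", "prcp")]
      )
    })
  })
}
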