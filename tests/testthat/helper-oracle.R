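# Independent brute-force oracles, written as plain loops so they share no
# code path with the package internals they check.

# Hour-by-hour degree-day enumeration from daily extremes and thresholds.
dd_oracle <- function(t_min, t_max, t_base, t_opt, t_frez) {
  gdd <- edd <- fdd <- 0
  for (h in 1:24) {
    th <- (t_min + t_max) / 2 + (t_max - t_min) * cos(0.2618 * (h - 14)) / 2
    if (th < t_base) {
      # no growth increment
    } else if (th <= t_opt) {
      gdd <- gdd + (th - t_base) / 24
    } else {
      gdd <- gdd + (t_opt - t_base) / 24
    }
    if (th > t_opt) edd <- edd + (th - t_opt) / 24
    if (th <= t_frez) fdd <- fdd + (t_frez - th) / 24
  }
  c(gdd = gdd, edd = edd, fdd = fdd)
}

# Constant-weather tibble for one site over a date span.
constant_weather <- function(site = "S1", from, to, tmin, tmax, prcp = 0) {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  tibble::tibble(site_id = site, date = dates, tmin = tmin, tmax = tmax, prcp = prcp)
}

# Directly constructed panel for one genotype class from a season-climate
# table and known coefficients (bypasses the trial/entry layer).
panel_from_truth <- function(clim, genotype, alpha, trend1, trend2, beta,
                             noise_sd = 0, year0 = min(clim$season_year)) {
  i <- match(clim$site_id, names(alpha))
  t <- clim$season_year - year0
  mu <- alpha[i] + trend1[i] * t + trend2[i] * t^2 +
    beta[["fdd"]] * clim$fdd + beta[["gdd"]] * clim$gdd + beta[["edd"]] * clim$edd +
    beta[["prcp"]] * clim$prcp + beta[["prcp_sq"]] * clim$prcp^2
  if (noise_sd > 0) mu <- mu + rnorm(nrow(clim), 0, noise_sd)
  tibble::tibble(
    site_id = clim$site_id, season_year = clim$season_year,
    genotype_class = genotype, yield = exp(unname(mu)),
    fdd = clim$fdd, gdd = clim$gdd, edd = clim$edd, prcp = clim$prcp
  )
}

# Small season-climate table with plausible, non-collinear indices.
toy_climates <- function(n_sites = 5, years = 2001:2012, seed = 1) {
  cfg <- synthetic_config(n_sites = n_sites, years = years, seed = seed)
  gen_season_climates(cfg)
}

named_alpha <- function(sites, center = 8, spread = 0.2, seed = 2) {
  set.seed(seed)
  setNames(rnorm(length(sites), center, spread), sites)
}
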