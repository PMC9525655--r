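# Shared small synthetic world for impact tests.
impact_world <- function(seed = 21, n_sites = 4, years = 2000:2009,
                         beta = c(fdd = -0.004, gdd = 3e-4, edd = -0.011,
                                  prcp = 1.2e-3, prcp_sq = -6e-7),
                         noise_sd = 0) {
  cfg <- synthetic_config(n_sites = n_sites, years = years, seed = seed)
  w <- gen_weather(cfg)
  win <- gen_windows(cfg)
  clim <- accumulate_season(w, win, cfg$phases)
  sites <- unique(clim$site_id)
  if (noise_sd > 0) set.seed(seed)
  pan <- panel_from_truth(clim, "MYG", named_alpha(sites, seed = seed),
                          trend1 = setNames(rep(0.01, length(sites)), sites),
                          trend2 = setNames(rep(0, length(sites)), sites),
                          beta = beta, noise_sd = noise_sd)
  list(cfg = cfg, weather = w, windows = win, clim = clim, panel = pan, beta = beta)
}

test_that("warming deltas vanish at zero and match brute-force recomputation", {
  wd <- impact_world()
  d0 <- warming_deltas(wd$weather, wd$windows, wd$cfg$phases, delta_t = 0)
  expect_true(all(abs(c(d0$d_fdd, d0$d_gdd, d0$d_edd)) < 1e-12))

  d1 <- warming_deltas(wd$weather, wd$windows, wd$cfg$phases, delta_t = 1)
  expect_true(all(d1$d_gdd + d1$d_edd >= -1e-9))
  expect_true(all(d1$d_fdd <= 1e-9))
  expect_true(all(d1$d_prcp == 0))

  # brute-force oracle for one site-season: enumerate hours day by day
  key <- d1[1, ]
  win <- wd$windows[wd$windows$site_id == key$site_id, ]
  wr <- resolve <- seq(as.Date(sprintf("%d-%s", key$season_year - 1, win$plant_date)),
                       as.Date(sprintf("%d-%s", key$season_year, win$harvest_date)), by = "day")
  wday <- wd$weather[wd$weather$site_id == key$site_id & wd$weather$date %in% wr, ]
  thr <- default_thresholds()
  acc <- function(tmin, tmax) {
    tot <- c(gdd = 0, edd = 0, fdd = 0)
    for (i in seq_along(tmin)) tot <- tot + dd_oracle(tmin[i], tmax[i], thr$t_base, thr$t_opt, thr$t_frez)
    tot
  }
  base <- acc(wday$tmin, wday$tmax)
  pert <- acc(wday$tmin + 1, wday$tmax + 1)
  expect_equal(key$d_gdd, unname(pert["gdd"] - base["gdd"]), tolerance = 1e-9)
  expect_equal(key$d_edd, unname(pert["edd"] - base["edd"]), tolerance = 1e-9)
  expect_equal(key$d_fdd, unname(pert["fdd"] - base["fdd"]), tolerance = 1e-9)
})

test_that("point impact follows the closed form and is additive on the log scale", {
  wd <- impact_world(beta = c(fdd = 0, gdd = 0, edd = -0.01, prcp = 0, prcp_sq = 0))
  fit <- fit_panel(build_design(wd$panel, "MYG"))
  keys <- fit$keys
  deltas <- tibble::tibble(
    site_id = keys$site_id, season_year = keys$season_year,
    d_fdd = 0, d_gdd = 0, d_edd = 5, d_prcp = 0
  )
  imp <- estimate_impacts(fit, deltas)
  expect_equal(imp$pct[imp$component == "net"], 100 * (exp(-0.05) - 1), tolerance = 1e-6)
  expect_equal(imp$pct[imp$component == "edd"], imp$pct[imp$component == "net"])

  # additivity of log-effects with several nonzero components
  wd2 <- impact_world(seed = 22)
  fit2 <- fit_panel(build_design(wd2$panel, "MYG"))
  d2 <- warming_deltas(wd2$weather, wd2$windows, wd2$cfg$phases, delta_t = 1)
  imp2 <- estimate_impacts(fit2, d2)
  comp <- imp2$log_effect[imp2$component != "net"]
  expect_equal(sum(comp), imp2$log_effect[imp2$component == "net"], tolerance = 1e-12)

  # zero deltas -> zero impact
  d0 <- dplyr::mutate(deltas, d_edd = 0)
  imp0 <- estimate_impacts(fit, d0)
  expect_true(all(imp0$pct == 0))

  # linear transform option
  implin <- estimate_impacts(fit, deltas, transform = "linear")
  expect_equal(implin$pct[implin$component == "net"], -5)
})

test_that("term mismatch between fit and deltas raises an error", {
  wd <- impact_world(seed = 23)
  fit <- fit_panel(build_design(wd$panel, "MYG"))
  bad <- tibble::tibble(site_id = fit$keys$site_id, season_year = fit$keys$season_year,
                        d_gdd = 1, d_prcp = 0)
  expect_error(estimate_impacts(fit, bad), "deltas lack columns")
})

test_that("sign structure: harmful heat and beneficial freeze loss under warming", {
  wd <- impact_world(seed = 24, noise_sd = 0.05)
  fit <- fit_panel(build_design(wd$panel, "MYG"))
  stopifnot(climate_coefs(fit)[["edd"]] < 0, climate_coefs(fit)[["fdd"]] < 0)
  d <- warming_deltas(wd$weather, wd$windows, wd$cfg$phases, delta_t = 1)
  imp <- estimate_impacts(fit, d)
  expect_lte(imp$pct[imp$component == "edd"], 0)
  expect_gte(imp$pct[imp$component == "fdd"], 0)
})

test_that("small-delta impacts scale linearly in the perturbation", {
  wd <- impact_world(seed = 25)
  fit <- fit_panel(build_design(wd$panel, "MYG"))
  slopes <- sapply(c(0.5, 0.25, 0.125), function(dt) {
    d <- warming_deltas(wd$weather, wd$windows, wd$cfg$phases, delta_t = dt)
    estimate_impacts(fit, d)$pct[6] / dt
  })
  # successive halvings converge: differences shrink
  expect_lt(abs(slopes[3] - slopes[2]), abs(slopes[2] - slopes[1]) + 1e-9)
})

test_that("bootstrap is seed-deterministic and degenerate without noise", {
  wd <- impact_world(seed = 26)
  d <- warming_deltas(wd$weather, wd$windows, wd$cfg$phases, delta_t = 1)
  b1 <- bootstrap_impacts(wd$panel, d, n_boot = 30, seed = 99)
  b2 <- bootstrap_impacts(wd$panel, d, n_boot = 30, seed = 99)
  expect_equal(b1, b2)
  b3 <- bootstrap_impacts(wd$panel, d, n_boot = 30, seed = 100)
  expect_false(isTRUE(all.equal(b1$median_pct, b3$median_pct)))

  # noiseless yields: betas have no sampling variance, but resampled delta
  # means still vary; the per-index *coefficients* are exact, so the net CI
  # width reflects only delta-weighting, and a constant-delta table gives a
  # degenerate interval
  const <- dplyr::mutate(d, d_fdd = -2, d_gdd = 3, d_edd = 4)
  bc <- bootstrap_impacts(wd$panel, const, n_boot = 30, seed = 1)
  expect_true(all(bc$ci_high - bc$ci_low < 1e-6))
  expect_equal(bc$estimate_pct, bc$median_pct, tolerance = 1e-6)

  expect_error(bootstrap_impacts(wd$panel, d, n_boot = 30), "seed is mandatory")
  expect_error(bootstrap_impacts(wd$panel, d, n_boot = 1, seed = 1), "at least 2")
})

test_that("all genotype classes share one resampling plan", {
  # two identical genotype series must give identical bootstrap intervals
  wd <- impact_world(seed = 27, noise_sd = 0.1)
  twin <- dplyr::mutate(wd$panel, genotype_class = "CK")
  pan <- dplyr::bind_rows(wd$panel, twin)
  d <- warming_deltas(wd$weather, wd$windows, wd$cfg$phases, delta_t = 1)
  b <- bootstrap_impacts(pan, d, n_boot = 25, seed = 5)
  myg <- dplyr::filter(b, genotype == "MYG")
  ck <- dplyr::filter(b, genotype == "CK")
  expect_equal(myg$median_pct, ck$median_pct)
  expect_equal(myg$ci_low, ck$ci_low)
})
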