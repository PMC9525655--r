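test_that("hourly cosine curve hits its anchors and stays in range", {
  expect_equal(hourly_temperature(10, 20, 14), 20)
  expect_equal(hourly_temperature(10, 20, 2), 10, tolerance = 1e-3)
  expect_equal(hourly_temperature(10, 20, 8), 15, tolerance = 1e-3)

  th <- hourly_temperature(rep(3, 24), rep(19, 24), 1:24)
  expect_equal(max(th), 19)                      # peak exactly at Tmax (h = 14)
  eps <- (19 - 3) * (1 - cos(0.2618 * 12)) / 2   # 0.2618 is not exactly 2*pi/24
  expect_true(all(th >= 3 - eps - 1e-12 & th <= 19 + 1e-12))

  expect_error(hourly_temperature(20, 10, 12), "t_min > t_max")
  expect_error(hourly_temperature(10, 20, 25), "1\\.\\.24")
})

test_that("daily degree-day boundary cases follow the piecewise definitions", {
  thr <- thermal_thresholds(t_base = 5, t_opt = 15, t_frez = 0)
  # constant day at the base threshold: on the boundary every piece is zero
  expect_equal(unlist(daily_degree_days(5, 5, thr)), c(gdd = 0, edd = 0, fdd = 0))
  # constant day above the optimum: capped growth increment plus excess
  expect_equal(unlist(daily_degree_days(20, 20, thr)), c(gdd = 10, edd = 5, fdd = 0))
  # constant freezing day: shortfall below the freeze threshold
  expect_equal(unlist(daily_degree_days(-3, -3, thr)), c(gdd = 0, edd = 0, fdd = 3))
})

test_that("daily degree-days match the brute-force hourly enumeration", {
  thr <- thermal_thresholds(t_base = 5, t_opt = 15, t_frez = 0)
  got <- daily_degree_days(0, 20, thr)
  want <- dd_oracle(0, 20, 5, 15, 0)
  expect_equal(c(gdd = got$gdd, edd = got$edd, fdd = got$fdd), want, tolerance = 1e-12)
})

test_that("missing temperatures yield marked-missing results, not zeros", {
  thr <- default_thresholds()
  out <- daily_degree_days(c(NA, 10), c(5, 20), thr)
  expect_true(all(is.na(out[1, ])))
  expect_false(anyNA(out[2, ]))
})

test_that("thresholds and phase schedules are validated", {
  expect_error(thermal_thresholds(10, 5, 0), "t_frez <= t_base < t_opt")
  expect_error(thermal_thresholds(0, 10, 5), "t_frez <= t_base < t_opt")
  expect_error(
    phase_schedule(tibble::tibble(phase = "a", frac_start = 0.1, frac_end = 1,
                                  t_base = 0, t_opt = 17, t_frez = -5)),
    "start at 0"
  )
  expect_error(
    phase_schedule(tibble::tibble(phase = c("a", "b"),
                                  frac_start = c(0, 0.6), frac_end = c(0.5, 1),
                                  t_base = 0, t_opt = 17, t_frez = -5)),
    "partition"
  )
  ok <- phase_schedule(tibble::tibble(phase = c("veg", "rep"),
                                      frac_start = c(0, 0.5), frac_end = c(0.5, 1),
                                      t_base = c(0, 5), t_opt = c(15, 25),
                                      t_frez = c(-5, 0)))
  expect_s3_class(ok, "phase_schedule")
})

test_that("season accumulation is linear over identical days", {
  thr <- thermal_thresholds(t_base = 5, t_opt = 15, t_frez = 0)
  # 40-day window of constant days 2 degrees above the optimum
  w <- constant_weather(from = "2000-04-01", to = "2000-07-31", tmin = 17, tmax = 17, prcp = 2)
  win <- season_windows("S1", "06-01", "07-10")
  clim <- accumulate_season(w, win, single_phase(thr))
  expect_equal(nrow(clim), 1L)
  expect_equal(clim$gdd, 40 * (15 - 5))
  expect_equal(clim$edd, 40 * 2)
  expect_equal(clim$fdd, 0)
  expect_equal(clim$prcp, 40 * 2)
  expect_equal(clim$n_days_missing, 0L)
})

test_that("seasons wrapping the calendar year are labelled by harvest year", {
  w <- constant_weather(from = "1999-01-01", to = "2001-12-31", tmin = 2, tmax = 12)
  win <- season_windows("S1", "09-20", "07-10")
  clim <- accumulate_season(w, win, single_phase())
  expect_true(all(c(2000L, 2001L) %in% clim$season_year))
  # the 2000 season runs 1999-09-20 .. 2000-07-10
  expect_equal(clim$n_days[clim$season_year == 2000],
               as.integer(as.Date("2000-07-10") - as.Date("1999-09-20")) + 1L)
})

test_that("gap tolerance marks incomplete seasons unusable", {
  w <- constant_weather(from = "2000-01-01", to = "2000-12-31", tmin = 5, tmax = 15)
  w$tmin[w$date >= as.Date("2000-05-01") & w$date <= as.Date("2000-05-20")] <- NA
  win <- season_windows("S1", "04-01", "08-31")
  strict <- accumulate_season(w, win, single_phase(), gap_tolerance = 0.05)
  expect_false(strict$usable)
  expect_equal(strict$n_days_missing, 20L)
  lax <- accumulate_season(w, win, single_phase(), gap_tolerance = 0.2)
  expect_true(lax$usable)
})

test_that("no resolvable window raises an explicit error", {
  w <- constant_weather(from = "2000-06-01", to = "2000-06-05", tmin = 5, tmax = 15)
  win <- season_windows("S1", "04-01", "08-31")
  expect_error(accumulate_season(w, win, single_phase()), "no resolvable site-seasons")
})

test_that("season accumulation is additive over a split window", {
  cfg <- synthetic_config(n_sites = 2, years = 2000:2001, seed = 11)
  w <- gen_weather(cfg)
  full <- accumulate_season(w, season_windows("S01", "04-01", "08-31"), single_phase())
  left <- accumulate_season(w, season_windows("S01", "04-01", "06-15"), single_phase())
  right <- accumulate_season(w, season_windows("S01", "06-16", "08-31"), single_phase())
  for (col in c("fdd", "gdd", "edd", "prcp")) {
    expect_equal(full[[col]], left[[col]] + right[[col]], tolerance = 1e-10)
  }
})

test_that("perturbation shifts the curve uniformly and moves indices monotonically", {
  cfg <- synthetic_config(n_sites = 2, years = 2000:2002, seed = 12)
  w <- gen_weather(cfg)
  expect_equal(perturb_weather(w, 0), w)
  wp <- perturb_weather(w, 1.5)
  expect_equal(wp$tmin, w$tmin + 1.5)
  expect_equal(wp$prcp, w$prcp)

  win <- gen_windows(cfg)
  prev <- accumulate_season(w, win, single_phase())
  for (dt in c(0.5, 1, 2)) {
    cur <- accumulate_season(perturb_weather(w, dt), win, single_phase())
    expect_true(all(cur$gdd + cur$edd >= prev$gdd + prev$edd - 1e-9))
    expect_true(all(cur$fdd <= prev$fdd + 1e-9))
    prev <- cur
  }

  # linear regime: constant day strictly inside (t_base, t_opt - 1)
  thr <- thermal_thresholds(5, 15, 0)
  base <- daily_degree_days(10, 10, thr)
  up <- daily_degree_days(11, 11, thr)
  expect_equal(up$gdd - base$gdd, 1)
  expect_equal(up$edd, base$edd)
})

test_that("per-phase thresholds are applied by season fraction", {
  # two phases with different optima; constant weather makes the split exact
  ph <- phase_schedule(tibble::tibble(
    phase = c("early", "late"), frac_start = c(0, 0.5), frac_end = c(0.5, 1),
    t_base = c(0, 0), t_opt = c(10, 20), t_frez = c(-5, -5)
  ))
  w <- constant_weather(from = "2000-01-01", to = "2000-12-31", tmin = 15, tmax = 15)
  win <- season_windows("S1", "05-01", "06-09")  # 40 days, 20 per phase
  clim <- accumulate_season(w, win, ph)
  # early phase: capped at 10 per day; late phase: 15 per day, no cap
  expect_equal(clim$gdd, 20 * 10 + 20 * 15)
  expect_equal(clim$edd, 20 * 5)
})
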