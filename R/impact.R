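# Warming counterfactual: how a uniform temperature increment shifts the
# thermal indices, and what the fitted coefficients say that shift does to
# yield — net and decomposed by index, with bootstrap confidence intervals.

#' Index changes induced by a temperature perturbation
#'
#' Recomputes the season climate after shifting every day's Tmin/Tmax by
#' `delta_t` and differences against the observed accumulation, giving the
#' per-site-season changes in FDD/GDD/EDD. Precipitation is untouched, so its
#' delta is zero by construction. For warming (`delta_t > 0`) GDD+EDD can
#' only rise and FDD can only fall.
#'
#' @inheritParams accumulate_season
#' @param delta_t Uniform temperature increment in degrees C.
#'
#' @return A tibble keyed by `site_id`, `season_year` with columns `d_fdd`,
#'   `d_gdd`, `d_edd`, `d_prcp` (the last identically 0), restricted to
#'   seasons usable under both the observed and perturbed weather.
#' @export
warming_deltas <- function(weather, windows, phases = single_phase(),
                           delta_t = 1, gap_tolerance = 0.05) {
  base <- accumulate_season(weather, windows, phases, gap_tolerance)
  pert <- accumulate_season(perturb_weather(weather, delta_t), windows, phases, gap_tolerance)
  j <- dplyr::inner_join(
    dplyr::filter(tibble::as_tibble(base), .data$usable),
    dplyr::filter(tibble::as_tibble(pert), .data$usable),
    by = c("site_id", "season_year"), suffix = c("", "_p")
  )
  tibble::tibble(
    site_id = j$site_id, season_year = j$season_year,
    d_fdd = j$fdd_p - j$fdd, d_gdd = j$gdd_p - j$gdd,
    d_edd = j$edd_p - j$edd, d_prcp = 0
  )
}

# Map climate terms to delta columns; precipitation terms are unperturbed.
delta_column <- c(fdd = "d_fdd", gdd = "d_gdd", edd = "d_edd",
                  prcp = "d_prcp", prcp_sq = "d_prcp")

# Per-index log-effects from coefficients and mean deltas (named by term).
impact_components <- function(beta, mean_deltas) {
  log_eff <- beta * mean_deltas[names(beta)]
  tibble::tibble(
    component = c(names(beta), "net"),
    log_effect = c(unname(log_eff), sum(log_eff))
  )
}

pct_from_log <- function(log_effect, transform) {
  if (transform == "exp") 100 * (exp(log_effect) - 1) else 100 * log_effect
}

#' Point estimate of the warming yield impact
#'
#' Averages the per-site-season index changes, multiplies by the fitted
#' climate coefficients to get per-index mean log-yield effects, and converts
#' to percentages. The net percentage is `100 * (exp(L) - 1)` with `L` the
#' summed mean log-effect; per-index log-effects therefore sum exactly to the
#' net log-effect (the percentages themselves are not additive). Deltas are
#' averaged over site-seasons *before* exponentiation, giving one headline
#' number per genotype; `transform = "linear"` (`100 * L`) is available for
#' sensitivity checks and differs by well under a percentage point at typical
#' magnitudes.
#'
#' @param fit A [fit_panel()] result.
#' @param deltas A [warming_deltas()] table; only site-seasons present in the
#'   fitted panel are used.
#' @param transform `"exp"` (default) or `"linear"`.
#'
#' @return A `warming_impact` tibble: `component` (one row per temperature
#'   index plus `"net"`), `log_effect`, `pct`.
#' @export
estimate_impacts <- function(fit, deltas, transform = c("exp", "linear")) {
  transform <- match.arg(transform)
  stopifnot(inherits(fit, "breedclim_fit"))
  deltas <- tibble::as_tibble(deltas)
  beta <- climate_coefs(fit)
  need <- unname(delta_column[names(beta)])
  if (anyNA(need) || !all(need %in% names(deltas))) {
    abort(paste0("deltas lack columns for fitted terms: ",
                 paste(setdiff(need, names(deltas)), collapse = ", ")))
  }
  d <- dplyr::inner_join(fit$keys, deltas, by = c("site_id", "season_year"))
  if (nrow(d) == 0L) abort("no overlap between fitted site-seasons and deltas")
  mean_deltas <- setNames(colMeans(as.matrix(d[need])), names(beta))
  out <- impact_components(beta, setNames(mean_deltas, names(beta)))
  out$pct <- pct_from_log(out$log_effect, transform)
  structure(out, class = c("warming_impact", class(out)))
}

#' Bootstrap distribution of warming impacts
#'
#' Resamples site-seasons with replacement, refits every genotype class on
#' the resampled panel, and recomputes the warming impacts, yielding medians
#' and 2.5th/97.5th percentile (95%) confidence intervals. All genotype
#' classes within one call share the same resampled index sets, so
#' genotype-vs-check contrasts are paired. Replicates whose resampled design
#' is singular (for instance a site left with too few distinct years to
#' identify its quadratic trend) are redrawn and counted.
#'
#' @param panel An [assemble_panel()] tibble.
#' @param deltas A [warming_deltas()] table for the counterfactual of interest.
#' @param spec A [model_spec()].
#' @param n_boot Number of bootstrap replicates (>= 2); published practice is
#'   1000.
#' @param seed Integer seed (mandatory: no hidden global randomness).
#' @param genotypes Genotype classes to fit (default those present).
#' @param transform Percentage transform, as in [estimate_impacts()].
#'
#' @return A tibble with one row per genotype class and component: full-sample
#'   `estimate_pct`, bootstrap `median_pct`, `ci_low`, `ci_high`, `n_boot`,
#'   and the redraw count `n_redrawn` as an attribute.
#' @export
bootstrap_impacts <- function(panel, deltas, spec = model_spec(), n_boot = 1000L,
                              seed, genotypes = NULL, transform = c("exp", "linear")) {
  transform <- match.arg(transform)
  if (missing(seed)) abort("seed is mandatory")
  if (n_boot < 2L) abort("n_boot must be at least 2")
  panel <- tibble::as_tibble(panel)
  deltas <- tibble::as_tibble(deltas)
  genotypes <- genotypes %||% intersect(c("CK", "LYG", "MYG", "HYG"),
                                        unique(panel$genotype_class))

  keys <- dplyr::inner_join(
    dplyr::distinct(panel[c("site_id", "season_year")]),
    deltas, by = c("site_id", "season_year")
  )
  if (nrow(keys) == 0L) abort("no overlap between panel site-seasons and deltas")
  n_keys <- nrow(keys)
  terms <- spec$climate_terms
  dmat <- as.matrix(keys[unname(delta_column[terms])])
  colnames(dmat) <- terms

  # climate columns per (key, genotype) once; per replicate only rows change
  panel_by_g <- lapply(setNames(genotypes, genotypes), function(g) {
    rows <- dplyr::inner_join(keys[c("site_id", "season_year")],
                              dplyr::filter(panel, .data$genotype_class == g),
                              by = c("site_id", "season_year"))
    if (nrow(rows) != n_keys) {
      abort(paste0("genotype ", g, " does not cover every resampled site-season"))
    }
    rows
  })

  boot_betas <- lapply(genotypes, function(g) matrix(NA_real_, n_boot, length(terms),
                                                     dimnames = list(NULL, terms)))
  names(boot_betas) <- genotypes
  boot_mean_deltas <- matrix(NA_real_, n_boot, length(terms), dimnames = list(NULL, terms))

  set.seed(as.integer(seed))
  n_redrawn <- 0L
  b <- 1L
  max_draws <- 50L * n_boot
  draws <- 0L
  while (b <= n_boot) {
    draws <- draws + 1L
    if (draws > max_draws) abort("bootstrap exceeded the redraw budget (degenerate panel?)")
    idx <- sample.int(n_keys, n_keys, replace = TRUE)
    betas <- tryCatch(
      lapply(panel_by_g, function(rows) {
        r <- rows[idx, , drop = FALSE]
        x <- design_matrix(r, spec)
        f <- lm.fit(x, log(r$yield))
        if (f$rank < ncol(x)) stop("singular")
        f$coefficients[terms]
      }),
      error = function(e) NULL
    )
    if (is.null(betas)) {
      n_redrawn <- n_redrawn + 1L
      next
    }
    for (g in genotypes) boot_betas[[g]][b, ] <- betas[[g]]
    boot_mean_deltas[b, ] <- colMeans(dmat[idx, , drop = FALSE])
    b <- b + 1L
  }
  if (n_redrawn > 0L) {
    inform(sprintf("bootstrap_impacts: redrew %d singular replicate(s)", n_redrawn))
  }

  full_fits <- fit_all_genotypes(panel, spec, genotypes)
  components <- c(terms, "net")
  out <- purrr::map_dfr(genotypes, function(g) {
    point <- estimate_impacts(full_fits[[g]], deltas, transform)
    log_eff <- boot_betas[[g]] * boot_mean_deltas          # n_boot x terms
    log_eff <- cbind(log_eff, net = rowSums(log_eff))
    pct <- pct_from_log(log_eff, transform)
    qs <- apply(pct, 2, quantile, probs = c(0.025, 0.5, 0.975), type = 7)
    tibble::tibble(
      genotype = g, component = components,
      estimate_pct = point$pct[match(components, point$component)],
      median_pct = unname(qs[2, components]),
      ci_low = unname(qs[1, components]), ci_high = unname(qs[3, components]),
      n_boot = n_boot
    )
  })
  attr(out, "n_redrawn") <- n_redrawn
  out
}
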