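# Fixed-effects panel regression of log yield on climate indices, with
# per-site intercepts and site-specific linear + quadratic time trends.
#
# log(Y_it) = alpha_i + alpha1_i * t + alpha2_i * t^2 + beta . x_it + e_it
#
# Estimated by explicit dummy-variable OLS: with at most a hundred or so
# sites the design stays small, and the exact per-site alphas are needed as
# projection baselines (a within-transformation would discard them).

#' Model specification for the panel regression
#'
#' @param climate_terms Ordered character vector of climate regressors drawn
#'   from `fdd`, `gdd`, `edd`, `prcp`, `prcp_sq` (`prcp_sq` is the quadratic
#'   precipitation term, built from `prcp`).
#' @param trend_order Site-specific polynomial time-trend order: 0, 1, or 2.
#'
#' @return A `model_spec` list.
#' @export
model_spec <- function(climate_terms = c("fdd", "gdd", "edd", "prcp", "prcp_sq"),
                       trend_order = 2L) {
  allowed <- c("fdd", "gdd", "edd", "prcp", "prcp_sq")
  if (length(climate_terms) == 0L) abort("climate_terms must be non-empty")
  if (!all(climate_terms %in% allowed)) {
    abort(paste0("unknown climate term(s): ",
                 paste(setdiff(climate_terms, allowed), collapse = ", ")))
  }
  if (!trend_order %in% 0:2) abort("trend_order must be 0, 1, or 2")
  structure(list(climate_terms = climate_terms, trend_order = as.integer(trend_order)),
            class = "model_spec")
}

# Assemble the raw design matrix (no rank check): site dummies, site x t,
# site x t^2, then the climate block in specification order.
design_matrix <- function(rows, spec, sites = sort(unique(rows$site_id))) {
  t <- rows$season_year - min(rows$season_year)
  site_f <- factor(rows$site_id, levels = sites)
  fe <- stats::model.matrix(~ 0 + site_f)
  colnames(fe) <- paste0("site:", sites)
  blocks <- list(fe)
  if (spec$trend_order >= 1L) {
    b <- fe * t
    colnames(b) <- paste0("trend1:", sites)
    blocks <- c(blocks, list(b))
  }
  if (spec$trend_order >= 2L) {
    b <- fe * t^2
    colnames(b) <- paste0("trend2:", sites)
    blocks <- c(blocks, list(b))
  }
  clim <- sapply(spec$climate_terms, function(term) {
    if (term == "prcp_sq") rows$prcp^2 else rows[[term]]
  })
  clim <- matrix(clim, nrow = nrow(rows), dimnames = list(NULL, spec$climate_terms))
  do.call(cbind, c(blocks, list(clim)))
}

#' Build the regression design for one genotype class
#'
#' Response is the natural log of yield. Columns are site indicators, then
#' site x t and site x t^2 interactions (per `trend_order`), then the climate
#' terms in specification order. Time `t` is the season year minus the
#' panel's first year; this centering changes trend coefficients and
#' intercepts but never the climate betas.
#'
#' @param panel An [assemble_panel()] tibble (or any tibble with `site_id`,
#'   `season_year`, `genotype_class`, `yield` and climate columns).
#' @param genotype One of `"CK"`, `"LYG"`, `"MYG"`, `"HYG"`.
#' @param spec A [model_spec()].
#'
#' @return A `panel_design` list: response `y`, matrix `x`, indices of the
#'   climate block, and bookkeeping (`sites`, `year0`, row keys).
#' @export
build_design <- function(panel, genotype, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  rows <- dplyr::filter(tibble::as_tibble(panel), .data$genotype_class == genotype)
  if (nrow(rows) == 0L) abort(paste0("no panel rows for genotype class ", genotype))
  need_clim <- setdiff(spec$climate_terms, "prcp_sq")
  if (!all(c(need_clim, "yield", "site_id", "season_year") %in% names(rows))) {
    abort("panel lacks required columns for the requested climate terms")
  }
  if (anyNA(rows[c(need_clim, "yield")])) abort("panel rows must have complete yield and climate")
  if (any(rows$yield <= 0)) abort("yields must be positive to take logs")

  sites <- sort(unique(rows$site_id))
  if (length(sites) < 2L) abort("need at least 2 sites for a fixed-effects panel")
  yrs_per_site <- tapply(rows$season_year, rows$site_id, function(v) length(unique(v)))
  if (min(yrs_per_site) < spec$trend_order + 1L) {
    abort(sprintf(
      "site %s has %d year(s); trend_order %d needs at least %d per site",
      names(which.min(yrs_per_site)), min(yrs_per_site),
      spec$trend_order, spec$trend_order + 1L
    ))
  }

  x <- design_matrix(rows, spec, sites)
  year0 <- min(rows$season_year)

  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1L):ncol(x)]]
    abort(paste0("design is rank deficient; collinear columns: ",
                 paste(dropped, collapse = ", ")))
  }

  structure(list(
    y = log(rows$yield), x = x,
    climate_idx = (ncol(x) - length(spec$climate_terms) + 1L):ncol(x),
    climate_terms = spec$climate_terms, sites = sites, year0 = year0,
    genotype = genotype, spec = spec,
    keys = rows[c("site_id", "season_year")]
  ), class = "panel_design")
}

#' Fit the panel regression by ordinary least squares
#'
#' @param design A [build_design()] object (full rank by construction; a
#'   singular design raises an error rather than a silent pseudo-inverse fit).
#'
#' @return A `breedclim_fit` object: tibble `beta` (climate term, estimate,
#'   classical standard error, t statistic, two-tailed p), tibble `alpha`
#'   (per-site intercept and trend coefficients), `residuals`, `n_obs`,
#'   `r_squared`, plus the design bookkeeping needed downstream.
#' @export
fit_panel <- function(design) {
  stopifnot(inherits(design, "panel_design"))
  x <- design$x
  y <- design$y
  fit <- lm.fit(x, y)
  if (fit$rank < ncol(x)) abort("singular design: refusing to fit by pseudo-inverse")
  coefs <- fit$coefficients
  res <- fit$residuals
  n <- length(y)
  p <- ncol(x)
  sigma2 <- sum(res^2) / (n - p)
  xtx_inv <- chol2inv(chol(crossprod(x)))
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- colnames(x)

  ci <- design$climate_idx
  beta <- tibble::tibble(
    term = design$climate_terms,
    estimate = unname(coefs[ci]),
    std_error = unname(se[ci]),
    statistic = unname(coefs[ci] / se[ci]),
    p_value = 2 * pt(abs(coefs[ci] / se[ci]), df = n - p, lower.tail = FALSE)
  )
  trend1 <- if (design$spec$trend_order >= 1L) unname(coefs[paste0("trend1:", design$sites)]) else rep(0, length(design$sites))
  trend2 <- if (design$spec$trend_order >= 2L) unname(coefs[paste0("trend2:", design$sites)]) else rep(0, length(design$sites))
  alpha <- tibble::tibble(
    site_id = design$sites,
    intercept = unname(coefs[paste0("site:", design$sites)]),
    trend1 = trend1, trend2 = trend2
  )
  tss <- sum((y - mean(y))^2)
  structure(list(
    beta = beta, alpha = alpha, residuals = res,
    n_obs = n, r_squared = 1 - sum(res^2) / tss,
    sigma = sqrt(sigma2), year0 = design$year0, genotype = design$genotype,
    spec = design$spec, keys = design$keys
  ), class = "breedclim_fit")
}

#' @export
print.breedclim_fit <- function(x, ...) {
  cat(sprintf("Fixed-effects log-yield fit, genotype %s (%d obs, %d sites, R^2 = %.3f)\n",
              x$genotype, x$n_obs, nrow(x$alpha), x$r_squared))
  print(x$beta)
  invisible(x)
}

#' Extract climate coefficients as a named vector
#'
#' @param fit A [fit_panel()] result.
#' @return Named numeric vector of climate coefficients in specification order.
#' @export
climate_coefs <- function(fit) {
  stopifnot(inherits(fit, "breedclim_fit"))
  setNames(fit$beta$estimate, fit$beta$term)
}

#' Fit all genotype classes present in a panel
#'
#' @param panel An [assemble_panel()] tibble.
#' @param spec A [model_spec()].
#' @param genotypes Classes to fit (default those present).
#' @return Named list of [fit_panel()] results.
#' @export
fit_all_genotypes <- function(panel, spec = model_spec(), genotypes = NULL) {
  genotypes <- genotypes %||% intersect(c("CK", "LYG", "MYG", "HYG"),
                                        unique(panel$genotype_class))
  setNames(lapply(genotypes, function(g) fit_panel(build_design(panel, g, spec))), genotypes)
}

#' Variance inflation factors for the climate block
#'
#' VIF_k = 1 / (1 - R^2_k), where R^2_k comes from regressing climate term k
#' on the other climate terms. By default the climate columns are first
#' residualized on the fixed-effect and trend columns, so the VIFs describe
#' the collinearity that actually affects the climate coefficients
#' (`partial = FALSE` gives the raw within-block version, with an intercept).
#' Perfect collinearity is reported as `Inf`.
#'
#' @param design A [build_design()] object, or a plain numeric matrix whose
#'   columns are the predictors to diagnose.
#' @param partial Residualize on fixed effects and trends first (default
#'   TRUE; ignored for a plain matrix).
#'
#' @return Tibble with `term` and `vif`.
#' @export
compute_vif <- function(design, partial = TRUE) {
  if (is.matrix(design)) {
    clim <- design
    terms <- colnames(clim) %||% paste0("x", seq_len(ncol(clim)))
    colnames(clim) <- terms
  } else {
    stopifnot(inherits(design, "panel_design"))
    terms <- design$climate_terms
    clim <- design$x[, design$climate_idx, drop = FALSE]
    if (partial) {
      fe <- design$x[, -design$climate_idx, drop = FALSE]
      clim <- qr.resid(qr(fe), clim)
    }
  }
  if (ncol(clim) < 2L) {
    return(tibble::tibble(term = terms, vif = 1))
  }
  vif_one <- function(k) {
    yk <- clim[, k]
    xk <- cbind(1, clim[, -k, drop = FALSE])
    rk <- qr.resid(qr(xk), yk)
    tss <- sum((yk - mean(yk))^2)
    r2 <- 1 - sum(rk^2) / tss
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  tibble::tibble(
    term = terms,
    vif = vapply(seq_len(ncol(clim)), vif_one, numeric(1))
  )
}
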