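# Collapse each site-season's breeding-line entries to percentile genotype
# series (LYG / MYG / HYG) alongside the constant check variety (CK).

#' Percentile of a yield sample
#'
#' Linear-interpolation percentile between order statistics (the "type 7"
#' convention of [stats::quantile()]); pinned explicitly because at the small
#' entry counts typical of a nursery trial the percentile definition matters
#' for the 2.5th and 97.5th tail series.
#'
#' @param values Numeric vector of entry yields (non-empty, no `NA`).
#' @param p Fraction in `[0, 1]` (may be a vector).
#' @param type Quantile algorithm passed to [stats::quantile()] (default 7).
#'
#' @return Percentile yield(s), unnamed.
#' @examples
#' yield_percentile(c(2, 4, 6, 8), 0.5) # 5
#' @export
yield_percentile <- function(values, p, type = 7) {
  if (length(values) == 0L) abort("cannot take a percentile of an empty sample")
  if (anyNA(values)) abort("yield sample contains NA")
  if (any(p < 0 | p > 1)) abort("p must lie in [0, 1]")
  unname(quantile(values, probs = p, type = type, names = FALSE))
}

#' Build the genotype series from trial records
#'
#' For each site-season with at least `min_entries` non-check entries and
#' exactly one check entry, computes the 2.5th (LYG), 50th (MYG), and 97.5th
#' (HYG) percentile of the breeding-line yields and carries the check yield
#' as CK. Site-seasons without a check entry, or with too few entries for the
#' tail percentiles to be stable, are skipped (with a message).
#'
#' @param trials A trial-record tibble (see [read_trials()]): `site_id`,
#'   `season_year`, `entry_id`, `yield`, `is_check`.
#' @param min_entries Minimum number of non-check entries (default 5): the
#'   2.5/97.5 percentiles of fewer entries collapse to the sample extremes.
#' @param probs Percentile fractions for (LYG, MYG, HYG).
#' @param quiet Suppress the skip message.
#'
#' @return A tibble: `site_id`, `season_year`, `ck`, `lyg`, `myg`, `hyg`,
#'   `n_entries`, satisfying `lyg <= myg <= hyg` row-wise.
#' @export
build_series <- function(trials, min_entries = 5L,
                         probs = c(lyg = 0.025, myg = 0.5, hyg = 0.975),
                         quiet = FALSE) {
  trials <- tibble::as_tibble(trials)
  stopifnot(all(c("site_id", "season_year", "yield", "is_check") %in% names(trials)))
  if (anyNA(trials$yield)) {
    trials <- trials[!is.na(trials$yield), , drop = FALSE]
  }

  by_ss <- dplyr::group_by(trials, .data$site_id, .data$season_year)
  out <- dplyr::summarise(by_ss,
    n_check = sum(.data$is_check),
    ck = if (sum(.data$is_check) == 1L) .data$yield[.data$is_check] else NA_real_,
    lyg = yield_percentile_or_na(.data$yield[!.data$is_check], probs[[1]]),
    myg = yield_percentile_or_na(.data$yield[!.data$is_check], probs[[2]]),
    hyg = yield_percentile_or_na(.data$yield[!.data$is_check], probs[[3]]),
    n_entries = sum(!.data$is_check),
    .groups = "drop"
  )
  keep <- out$n_check == 1L & out$n_entries >= min_entries & !is.na(out$lyg)
  n_skip <- sum(!keep)
  if (!quiet && n_skip) {
    inform(sprintf(
      "build_series: skipped %d site-season(s) (no unique check entry or fewer than %d entries)",
      n_skip, min_entries
    ))
  }
  out <- out[keep, c("site_id", "season_year", "ck", "lyg", "myg", "hyg", "n_entries")]
  stopifnot(all(out$lyg <= out$myg & out$myg <= out$hyg))
  out
}

yield_percentile_or_na <- function(values, p) {
  if (length(values) == 0L) return(NA_real_)
  yield_percentile(values, p)
}
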