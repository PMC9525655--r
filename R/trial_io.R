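# Readers for station weather and nursery trial tables, and panel assembly.

#' Read daily station weather
#'
#' Reads delimited text with columns `site_id`, `date` (ISO 8601), `tmin`,
#' `tmax`, `prcp`. Empty fields (or `na_strings`) are treated as missing.
#' Station exports in GHCN-D dialect store temperature and precipitation in
#' tenths of a unit; set `units = "tenths"` to convert to degrees C / mm.
#'
#' @param path Path to a delimited file.
#' @param delim Field delimiter (default `","`).
#' @param units `"si"` (degrees C, mm; default) or `"tenths"` (GHCN-D style).
#' @param na_strings Strings read as missing (default empty field and `"NA"`).
#'
#' @return A tibble with columns `site_id`, `date`, `tmin`, `tmax`, `prcp`,
#'   validated so `tmin <= tmax` where both present and dates are unique per site.
#' @export
read_weather <- function(path, delim = ",", units = c("si", "tenths"),
                         na_strings = c("", "NA")) {
  units <- match.arg(units)
  if (!file.exists(path)) abort(paste0("weather file not found: ", path))
  w <- readr::read_delim(path, delim = delim, na = na_strings,
                         show_col_types = FALSE, progress = FALSE)
  need <- c("site_id", "date", "tmin", "tmax", "prcp")
  missing_cols <- setdiff(need, names(w))
  if (length(missing_cols)) {
    abort(paste0("weather file lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  w <- dplyr::mutate(w,
    site_id = as.character(.data$site_id),
    date = as.Date(.data$date),
    dplyr::across(dplyr::all_of(c("tmin", "tmax", "prcp")), as.numeric)
  )
  if (units == "tenths") {
    w <- dplyr::mutate(w, dplyr::across(dplyr::all_of(c("tmin", "tmax", "prcp")), ~ .x / 10))
  }
  if (anyNA(w$date)) abort("unparseable date in weather file")
  bad <- which(!is.na(w$tmin) & !is.na(w$tmax) & w$tmin > w$tmax)
  if (length(bad)) abort(sprintf("tmin > tmax at row %d of %s", bad[1], path))
  dup <- duplicated(w[c("site_id", "date")])
  if (any(dup)) abort(sprintf("duplicate site/date at row %d of %s", which(dup)[1], path))
  if (any(!is.na(w$prcp) & w$prcp < 0)) abort("negative precipitation in weather file")
  w[need]
}

#' Read a nursery trial yield table
#'
#' Reads delimited text with columns `site_id`, `year`, `entry`, `yield`,
#' `is_check`. Yields must be positive numbers; each site-season may carry at
#' most one check entry. Check entries may alternatively be flagged by name:
#' any entry matching `check_names` case-insensitively is marked as the check.
#'
#' @param path Path to a delimited file.
#' @param delim Field delimiter (default `","`).
#' @param check_names Optional character vector of check-variety names matched
#'   case-insensitively against `entry` (e.g. `"kharkof"`, `"marquis"`).
#'
#' @return A tibble of trial records: `site_id`, `season_year`, `entry_id`,
#'   `yield`, `is_check`.
#' @export
read_trials <- function(path, delim = ",", check_names = NULL) {
  if (!file.exists(path)) abort(paste0("trial file not found: ", path))
  tr <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                          col_types = readr::cols(.default = readr::col_character()),
                          show_col_types = FALSE, progress = FALSE)
  need <- c("site_id", "year", "entry", "yield")
  missing_cols <- setdiff(need, names(tr))
  if (length(missing_cols)) {
    abort(paste0("trial file lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  yield <- suppressWarnings(as.numeric(tr$yield))
  bad <- which(is.na(yield) & !is.na(tr$yield))
  if (length(bad)) {
    abort(sprintf("unparseable yield '%s' at row %d of %s", tr$yield[bad[1]], bad[1], path))
  }
  year <- suppressWarnings(as.integer(tr$year))
  if (anyNA(year)) abort(sprintf("unparseable year at row %d of %s", which(is.na(year))[1], path))
  if (any(!is.na(yield) & yield <= 0)) {
    abort(sprintf("non-positive yield at row %d of %s", which(yield <= 0)[1], path))
  }

  is_check <- if ("is_check" %in% names(tr)) {
    tolower(trimws(tr$is_check)) %in% c("1", "true", "t", "yes", "y")
  } else {
    rep(FALSE, nrow(tr))
  }
  if (!is.null(check_names)) {
    is_check <- is_check | tolower(trimws(tr$entry)) %in% tolower(trimws(check_names))
  }

  out <- tibble::tibble(
    site_id = as.character(tr$site_id), season_year = year,
    entry_id = as.character(tr$entry), yield = yield, is_check = is_check
  )
  dup_ck <- dplyr::filter(
    dplyr::count(dplyr::filter(out, .data$is_check), .data$site_id, .data$season_year),
    .data$n > 1L
  )
  if (nrow(dup_ck)) {
    abort(sprintf("duplicate check entries in site %s, season %d",
                  dup_ck$site_id[1], dup_ck$season_year[1]))
  }
  out
}

#' Assemble the analysis panel
#'
#' Inner-joins the genotype yield series with season climate on
#' `(site_id, season_year)`, keeping only usable seasons (within the missing-day
#' tolerance) — site-seasons must have both yield and climate to enter the
#' panel. One row per site-season and genotype class.
#'
#' @param series A [build_series()] table (`site_id`, `season_year`, `ck`,
#'   `lyg`, `myg`, `hyg`, `n_entries`).
#' @param season_climate An [accumulate_season()] table.
#' @param quiet Suppress the drop-count message.
#'
#' @return A `panel` tibble: `site_id`, `season_year`, `genotype_class`
#'   (CK/LYG/MYG/HYG), `yield`, and climate columns `fdd`, `gdd`, `edd`, `prcp`.
#' @export
assemble_panel <- function(series, season_climate, quiet = FALSE) {
  series <- tibble::as_tibble(series)
  clim <- tibble::as_tibble(season_climate)
  usable <- dplyr::filter(clim, .data$usable)
  n_dropped_clim <- nrow(clim) - nrow(usable)

  long <- tidyr::pivot_longer(
    series[c("site_id", "season_year", "ck", "lyg", "myg", "hyg")],
    cols = dplyr::all_of(c("ck", "lyg", "myg", "hyg")),
    names_to = "genotype_class", values_to = "yield"
  )
  long$genotype_class <- toupper(long$genotype_class)
  panel <- dplyr::inner_join(
    long,
    usable[c("site_id", "season_year", "fdd", "gdd", "edd", "prcp")],
    by = c("site_id", "season_year")
  )
  if (nrow(panel) == 0L) abort("empty panel: no site-season has both yield and usable climate")
  n_dropped_yield <- nrow(long) - nrow(panel)
  if (!quiet && (n_dropped_clim || n_dropped_yield)) {
    inform(sprintf(
      "assemble_panel: dropped %d unusable climate season(s); %d yield row(s) lacked climate",
      n_dropped_clim, n_dropped_yield
    ))
  }
  panel <- dplyr::arrange(panel, .data$site_id, .data$season_year, .data$genotype_class)
  structure(panel, class = c("breedclim_panel", class(panel)))
}
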