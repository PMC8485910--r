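#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr across all_of anti_join arrange bind_rows case_when
#'   distinct filter full_join group_by inner_join left_join mutate n
#'   pull rename row_number select semi_join summarise ungroup
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map2 pmap imap keep
NULL

# Error helpers: every validation error names the offending keys so a data
# preparer can locate the bad row without re-reading the file.

stop_schema <- function(msg, ...) {
  abort(paste0(msg, ...), class = "deltafood_schema_error")
}

stop_validation <- function(msg, ...) {
  abort(paste0(msg, ...), class = "deltafood_validation_error")
}

stop_infeasible <- function(msg, ...) {
  abort(paste0(msg, ...), class = "deltafood_infeasible_error")
}

# Compact "a, b, c" formatting for key lists in error messages, capped so a
# thousand-row failure doesn't produce a thousand-row message.
fmt_keys <- function(x, max = 5L) {
  x <- unique(as.character(x))
  shown <- utils::head(x, max)
  out <- paste(shown, collapse = ", ")
  if (length(x) > max) out <- paste0(out, ", ... (", length(x), " total)")
  out
}

require_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_schema(table, ": missing required column(s): ", fmt_keys(missing))
  }
  invisible(df)
}

check_unique_keys <- function(df, keys, table) {
  dup <- df |>
    group_by(across(all_of(keys))) |>
    filter(n() > 1) |>
    ungroup() |>
    distinct(across(all_of(keys)))
  if (nrow(dup) > 0) {
    labels <- apply(dup, 1, paste, collapse = "/")
    stop_validation(table, ": duplicate key(s) for (",
                    paste(keys, collapse = ", "), "): ", fmt_keys(labels))
  }
  invisible(df)
}

check_finite_nonneg <- function(df, cols, keys, table) {
  for (col in cols) {
    bad <- !is.finite(df[[col]]) | df[[col]] < 0
    if (any(bad)) {
      labels <- apply(df[bad, keys, drop = FALSE], 1, paste, collapse = "/")
      stop_validation(table, ": column ", col,
                      " must be finite and non-negative; offending (",
                      paste(keys, collapse = ", "), "): ", fmt_keys(labels))
    }
  }
  invisible(df)
}

check_in_unit_interval <- function(df, col, keys, table) {
  v <- df[[col]]
  bad <- !is.finite(v) | v < 0 | v > 1
  if (any(bad)) {
    labels <- apply(df[bad, keys, drop = FALSE], 1, paste, collapse = "/")
    stop_validation(table, ": column ", col, " must lie in [0, 1]; offending (",
                    paste(keys, collapse = ", "), "): ", fmt_keys(labels))
  }
  invisible(df)
}

#' Total population at a given year
#'
#' Sums the demographic table over all (region, sex, age-group) strata at
#' `year`, interpolating each stratum linearly between tabulated years when
#' the year itself is not tabulated.
#'
#' @param demographics A demographic tibble as returned by
#'   [read_demographics()].
#' @param year Calendar year, which must lie within the tabulated range.
#' @return Total population (persons) as a single number.
#' @export
population_at <- function(demographics, year) {
  sum(population_strata(demographics, year)$population)
}

#' Per-stratum population at a given year
#'
#' @inheritParams population_at
#' @return A tibble with columns `region_id`, `sex`, `age_group`,
#'   `population`, one row per stratum, linearly interpolated to `year`.
#' @export
population_strata <- function(demographics, year) {
  yrs <- sort(unique(demographics$year))
  if (year < min(yrs) || year > max(yrs)) {
    stop_validation("demographics: year ", year,
                    " outside tabulated range [", min(yrs), ", ", max(yrs), "]")
  }
  demographics |>
    group_by(.data$region_id, .data$sex, .data$age_group) |>
    summarise(
      population = if (length(.data$year) == 1) {
        if (.data$year[1] != !!year) {
          stop_validation("demographics: single tabulated year ",
                          .data$year[1], " cannot be interpolated to ", !!year)
        }
        .data$population[1]
      } else {
        stats::approx(.data$year, .data$population, xout = !!year,
                      rule = 1)$y
      },
      .groups = "drop"
    )
}
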