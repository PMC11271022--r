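# broom-style tidiers for the fitted/assessed objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn classify_criterion_b Per-category threshold outcomes as a tibble.
#' @param x A `redlist_assessment`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.redlist_assessment <- function(x, ...) {
  x$triggered
}

#' @describeIn classify_criterion_b One-row summary (category, criteria string,
#'   inputs).
#' @exportS3Method generics::glance
glance.redlist_assessment <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(category = x$category,
                                  criteria_string = x$criteria_string),
                   x$inputs)
}

#' @describeIn validate_aoh One-row tibble of the test quantities.
#' @param x An `aoh_validation`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.aoh_validation <- function(x, ...) {
  tibble::tibble(N = x$N, K = x$K, n = x$n, k = x$k, p_value = x$p_value,
                 better_than_random = x$better_than_random,
                 n_excluded = x$n_excluded)
}

#' @describeIn scope_kba Per-grid-cell fractions and trigger flags.
#' @param x A `kba_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.kba_result <- function(x, ...) {
  x$cell_fractions
}

#' @describeIn scope_kba One-row scoping summary.
#' @exportS3Method generics::glance
glance.kba_result <- function(x, ...) {
  tibble::tibble(total_area_km2 = x$total_area_km2, pct_of_aoh = x$pct_of_aoh,
                 n_cells_a1 = nrow(x$triggered_cells$A1),
                 n_cells_b1 = nrow(x$triggered_cells$B1),
                 a1_fraction = x$thresholds$a1_fraction,
                 b1_fraction = x$thresholds$b1_fraction)
}

#' @describeIn run_assessment Long tibble of every reported quantity.
#' @param x An `assessment_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.assessment_report <- function(x, ...) {
  num <- function(stage, metric, value) {
    if (is.null(value)) return(NULL)
    tibble::tibble(stage = stage, metric = metric, value = as.numeric(value))
  }
  dplyr::bind_rows(
    num("range", "eoo_km2", x$range$eoo_km2),
    num("range", "aoo_km2", x$range$aoo_km2),
    num("range", "n_localities", x$range$n_localities),
    if (!is.null(x$aoh_areas))
      tibble::tibble(stage = "aoh", metric = paste0("area_km2_", x$aoh_areas$domain),
                     value = x$aoh_areas$area_km2),
    if (!is.null(x$validation)) dplyr::bind_rows(
      num("validation", "k", x$validation$k),
      num("validation", "n", x$validation$n),
      num("validation", "p_value", x$validation$p_value)
    ),
    if (!is.null(x$kba)) dplyr::bind_rows(
      num("kba", "total_area_km2", x$kba$total_area_km2),
      num("kba", "pct_of_aoh", x$kba$pct_of_aoh),
      if ("pa_overlap_pct" %in% names(x$kba))
        num("kba", "pa_overlap_pct", x$kba$pa_overlap_pct)
    )
  )
}

#' @describeIn run_assessment One-row headline summary.
#' @exportS3Method generics::glance
glance.assessment_report <- function(x, ...) {
  tibble::tibble(
    eoo_km2 = x$range$eoo_km2, aoo_km2 = x$range$aoo_km2,
    n_localities = x$range$n_localities,
    category = x$redlist$category, criteria_string = x$redlist$criteria_string,
    aoh_eoo_km2 = if (!is.null(x$aoh_areas)) x$aoh_areas$area_km2[1] else NA_real_,
    validation_p = if (!is.null(x$validation)) x$validation$p_value else NA_real_,
    kba_km2 = if (!is.null(x$kba)) x$kba$total_area_km2 else NA_real_
  )
}
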