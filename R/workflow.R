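# End-to-end assessment driver: read occurrences, compute range metrics,
# classify under criterion B, build and validate AOH maps, scope KBAs,
# measure protected-area coverage, and emit a reproducible report.

#' Read occurrence records from a delimited file
#'
#' Expects a header row with at least `id`, `lat`, `lon`; optional columns
#' `year`, `elevation_m` and `note` are carried through. Coordinates may be
#' decimal degrees or DMS label strings (parsed by [parse_coordinate()]);
#' elevations may be single values or printed ranges like `"25-300"`, which
#' populate `elev_min_m`/`elev_max_m`.
#'
#' @param path CSV file.
#' @return Tibble of records with numeric `lon`, `lat` in decimal degrees.
#' @export
read_occurrences <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(raw) == 0) stop("occurrence file contains no records: ", path, call. = FALSE)
  missing_cols <- setdiff(c("id", "lat", "lon"), names(raw))
  if (length(missing_cols) > 0) {
    stop("occurrence file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_col <- function(col, what) {
    vapply(seq_along(col), function(i) {
      tryCatch(parse_coordinate_one(col[i]),
               error = function(e) stop(sprintf("row %d, %s: %s", i, what,
                                                conditionMessage(e)), call. = FALSE))
    }, numeric(1))
  }
  out <- tibble::tibble(
    id = raw$id,
    lon = parse_col(raw$lon, "lon"),
    lat = parse_col(raw$lat, "lat"),
    year = if ("year" %in% names(raw)) suppressWarnings(as.integer(raw$year)) else NA_integer_,
    note = if ("note" %in% names(raw)) raw$note else ""
  )
  if (any(abs(out$lon) > 180 | abs(out$lat) > 90, na.rm = TRUE)) {
    stop("coordinates outside valid longitude/latitude bounds", call. = FALSE)
  }
  if ("elevation_m" %in% names(raw)) {
    rng <- strsplit(trimws(raw$elevation_m), "\\s*[-–]\\s*")
    out$elev_min_m <- vapply(rng, function(p)
      if (length(p) == 0 || !nzchar(p[1])) NA_real_ else as.numeric(p[1]), numeric(1))
    out$elev_max_m <- vapply(rng, function(p)
      if (length(p) == 0 || !nzchar(p[1])) NA_real_ else as.numeric(p[length(p)]), numeric(1))
    out$elevation_m <- (out$elev_min_m + out$elev_max_m) / 2
  }
  out
}

#' Bundled occurrence records of *Nesodexia corsicana*
#'
#' The seven known Corsican collection sites of the endemic rhinophorine fly
#' *Nesodexia corsicana*, transcribed from specimen labels (mixed DMS and
#' decimal formats, as printed). The 1907 type locality "Campo di Loro" has
#' no published coordinates; it is georeferenced by default to the Campo
#' dell'Oro plain near Ajaccio (41.93 N, 8.79 E) — see the package vignette
#' for the sensitivity of the EOO to this choice.
#'
#' @return Tibble of 7 occurrence records.
#' @export
corsican_occurrences <- function() {
  read_occurrences(system.file("extdata", "nesodexia_corsicana_occurrences.csv",
                               package = "kbascope", mustWork = TRUE))
}

# stable hash of an R object (used for config provenance)
object_hash <- function(x) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

default_config <- function() {
  list(
    occurrences = NULL,        # path or data frame; NULL -> sampled synthetically
    synthetic = NULL,          # list(seed, n_rows, n_cols, n_classes, sea_fraction,
                               #      truth = list(...), n_occurrences, n_outliers,
                               #      pa_coverage)
    linkage_km = 10,
    alpha = 0.05,
    decline_observed = NA,
    severely_fragmented = FALSE,
    a1_fraction = 0.005,
    b1_fraction = 0.10,
    kba_domain = "eoo",        # population denominator: "eoo" or "island"
    include_kba = TRUE,
    seed = 1
  )
}

#' Run the full conservation assessment pipeline
#'
#' Chains all stages: occurrence ingestion, equal-area projection, EOO / AOO /
#' locality metrics, criterion B classification, habitat-model inference, AOH
#' mapping (range-clipped and island-wide), hypergeometric validation, KBA
#' scoping and protected-area overlap. Raster stages run when a landscape is
#' available (synthetic, or passed directly); with occurrences only, the
#' report's AOH/KBA blocks are `NULL`.
#'
#' @param config A named list (see `Details`) or path to a YAML file. Unset
#'   entries take defaults: 10 km locality linkage, alpha 0.05, KBA
#'   thresholds 0.5% (A1) and 10% (B1), EOO-clipped population denominator.
#' @param landscape Optional [generate_island()] landscape overriding the
#'   synthetic block.
#' @param protected_area Optional [generate_protected_area()] object or
#'   polygon rings.
#' @return An `assessment_report`.
#' @export
run_assessment <- function(config = list(), landscape = NULL, protected_area = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  cfg_hash <- object_hash(cfg[setdiff(names(cfg), "occurrences")])

  # --- landscape stage -------------------------------------------------
  truth <- NULL
  if (is.null(landscape) && !is.null(cfg$synthetic)) {
    sy <- cfg$synthetic
    landscape <- generate_island(
      seed = sy$seed %||% cfg$seed,
      n_rows = sy$n_rows %||% 200, n_cols = sy$n_cols %||% 200,
      n_classes = sy$n_classes %||% 8, sea_fraction = sy$sea_fraction %||% 0.35,
      smooth_sigma = sy$smooth_sigma %||% 10
    )
    if (!is.null(sy$truth)) {
      truth <- synthetic_truth(
        suitable_classes = sy$truth$suitable_classes,
        elev_min = sy$truth$elev_min, elev_max = sy$truth$elev_max,
        p_in_habitat = sy$truth$p_in_habitat %||% 1,
        seed = sy$truth$seed %||% (cfg$seed + 1)
      )
    }
    if (is.null(protected_area) && !is.null(sy$pa_coverage)) {
      protected_area <- generate_protected_area(landscape, sy$pa_coverage,
                                                seed = cfg$seed + 2)
    }
  }

  # --- occurrence stage ------------------------------------------------
  occ_path <- NULL
  if (is.data.frame(cfg$occurrences)) {
    records <- tibble::as_tibble(cfg$occurrences)
  } else if (is.character(cfg$occurrences)) {
    occ_path <- cfg$occurrences
    records <- read_occurrences(occ_path)
  } else if (!is.null(landscape) && !is.null(truth)) {
    records <- sample_occurrences(landscape, truth,
                                  n = cfg$synthetic$n_occurrences %||% 50,
                                  n_outliers = cfg$synthetic$n_outliers %||% 0)
  } else {
    stop("config must provide occurrences, or a synthetic block with a truth definition",
         call. = FALSE)
  }

  projection <- if (!is.null(landscape)) landscape$projection else default_projection(records)

  # --- range metrics and classification --------------------------------
  range <- summarize_range(records, projection, linkage_km = cfg$linkage_km)
  redlist <- classify_criterion_b(range$summary$eoo_km2, range$summary$aoo_km2,
                                  range$summary$n_localities,
                                  decline_observed = cfg$decline_observed,
                                  severely_fragmented = cfg$severely_fragmented)

  # --- AOH, validation, KBA --------------------------------------------
  aoh_eoo <- aoh_island <- validation <- kba <- kba_summary <- NULL
  pa_pct <- NULL
  if (!is.null(landscape)) {
    # habitat requirements come from records with reliable modern habitat
    # observations; historical records (pre-1950) are still used for range
    # metrics and validation, where falling outside today's habitat is the
    # signal of habitat decline
    model_records <- records
    if ("year" %in% names(records)) {
      modern <- is.na(records$year) | records$year >= 1950
      if (any(modern)) model_records <- records[modern, ]
    }
    model <- infer_habitat_model(model_records, landscape$landcover,
                                 landscape$elevation, projection)
    hull_ring <- range$eoo$hull[, c("x", "y")]
    aoh_eoo <- build_aoh(landscape$landcover, landscape$elevation, model,
                         boundary = hull_ring, domain_label = "EOO-clipped")
    aoh_island <- build_aoh(landscape$landcover, landscape$elevation, model,
                            domain_label = "island-wide")
    # validation domain: the EOO-clipped domain extended by the records' own
    # cells — cell-centre clipping can otherwise drop the hull-vertex records
    # that define the EOO boundary
    pts <- project_points(records, projection)
    rc <- raster_cell_of(aoh_eoo$header, pts$x, pts$y)
    on_land <- !is.na(rc$row) &
      !is.na(landscape$landcover$values[cbind(rc$row, rc$col)])
    val_aoh <- aoh_eoo
    val_aoh$domain[cbind(rc$row[on_land], rc$col[on_land])] <- TRUE
    val_aoh$mask <- aoh_island$mask & val_aoh$domain
    val_aoh$area_km2 <- sum(val_aoh$mask) * val_aoh$header$cell_size^2 / 1e6
    validation <- validate_aoh(val_aoh, records, projection, alpha = cfg$alpha)
    if (isTRUE(cfg$include_kba)) {
      kba_aoh <- if (identical(cfg$kba_domain, "island")) aoh_island else aoh_eoo
      kba <- scope_kba(kba_aoh,
                       thresholds = kba_thresholds(cfg$a1_fraction, cfg$b1_fraction))
      kba_summary <- summarize_kba(kba, kba_aoh)
      if (!is.null(protected_area)) {
        pa_pct <- pa_overlap(kba, protected_area)
        kba_summary$pa_overlap_pct <- pa_pct
      }
    }
  }

  structure(list(
    range = range$summary,
    redlist = redlist,
    aoh_areas = if (!is.null(aoh_eoo)) {
      tibble::tibble(domain = c("EOO-clipped", "island-wide"),
                     area_km2 = c(aoh_eoo$area_km2, aoh_island$area_km2))
    },
    validation = validation,
    kba = kba_summary,
    provenance = list(
      tool = "kbascope",
      version = as.character(utils::packageVersion("kbascope")),
      seed = cfg$seed,
      config_hash = cfg_hash,
      occurrence_file_md5 = if (!is.null(occ_path)) unname(tools::md5sum(occ_path)),
      n_records = nrow(records),
      config = cfg[setdiff(names(cfg), "occurrences")]
    ),
    layers = list(range_detail = range, aoh_eoo = aoh_eoo, aoh_island = aoh_island,
                  kba = kba, landscape = landscape, protected_area = protected_area,
                  records = records, projection = projection)
  ), class = "assessment_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.assessment_report <- function(x, ...) {
  cat("== Conservation assessment report ==\n")
  cat(sprintf("records: %d | EOO %.1f km2 | AOO %.0f km2 | %d localities\n",
              x$provenance$n_records, x$range$eoo_km2, x$range$aoo_km2,
              x$range$n_localities))
  cat(sprintf("Red List (criterion B): %s %s\n", x$redlist$category,
              x$redlist$criteria_string))
  if (!is.null(x$aoh_areas)) {
    cat(sprintf("AOH: %.1f km2 (EOO-clipped), %.1f km2 (island-wide)\n",
                x$aoh_areas$area_km2[1], x$aoh_areas$area_km2[2]))
    cat(sprintf("validation: k=%d of n=%d occupied cells in habitat, p=%.4g\n",
                x$validation$k, x$validation$n, x$validation$p_value))
  }
  if (!is.null(x$kba)) {
    cat(sprintf("KBA: %.1f km2 (%.1f%% of AOH), A1 cells %d, B1 cells %d%s\n",
                x$kba$total_area_km2, x$kba$pct_of_aoh, x$kba$n_cells_a1,
                x$kba$n_cells_b1,
                if ("pa_overlap_pct" %in% names(x$kba))
                  sprintf(", PA overlap %.1f%%", x$kba$pa_overlap_pct) else ""))
  }
  invisible(x)
}

report_values <- function(report) {
  list(
    range = as.list(report$range),
    redlist = list(category = report$redlist$category,
                   criteria_string = report$redlist$criteria_string,
                   notes = report$redlist$notes),
    aoh_areas = if (!is.null(report$aoh_areas)) {
      stats::setNames(as.list(report$aoh_areas$area_km2), report$aoh_areas$domain)
    },
    validation = if (!is.null(report$validation)) {
      report$validation[c("N", "K", "n", "k", "p_value", "better_than_random",
                          "n_excluded")]
    },
    kba = if (!is.null(report$kba)) as.list(report$kba),
    provenance = report$provenance[c("tool", "version", "seed", "config_hash",
                                     "occurrence_file_md5", "n_records")]
  )
}

#' Write an assessment report to disk
#'
#' Writes `report.json` (machine-readable stage outputs and provenance, no
#' timestamps so identical runs give identical bytes), `summary.txt` (human
#' readable), and — when raster/vector layers were produced — the EOO hull as
#' GeoJSON plus the AOH and KBA masks as ESRI ASCII grids.
#'
#' @param report An [run_assessment()] report.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "assessment_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_values(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con); print(report); sink(); close(con)

  ly <- report$layers
  if (!is.null(ly$range_detail) && nrow(ly$range_detail$eoo$hull) >= 3) {
    write_geojson_polygon(ly$range_detail$eoo$hull, file.path(dir, "eoo_hull.geojson"),
                          ly$projection, properties = list(layer = "EOO hull"))
  }
  mask_raster <- function(m, h) scape_raster(ifelse(m, 1, NA), h, "categorical")
  if (!is.null(ly$aoh_eoo)) {
    write_asc(mask_raster(ly$aoh_eoo$mask, ly$aoh_eoo$header),
              file.path(dir, "aoh_eoo.asc"))
    write_asc(mask_raster(ly$aoh_island$mask, ly$aoh_island$header),
              file.path(dir, "aoh_island.asc"))
  }
  if (!is.null(ly$kba)) {
    write_asc(mask_raster(ly$kba$kba_mask, ly$kba$header), file.path(dir, "kba_mask.asc"))
  }
  if (!is.null(ly$protected_area) && inherits(ly$protected_area, "protected_area")) {
    write_geojson_polygon(ly$protected_area$rings, file.path(dir, "protected_area.geojson"),
                          ly$projection, properties = list(layer = "protected area"))
  }
  invisible(dir)
}

#' Read back a written report
#'
#' @param dir Directory written by [write_report()].
#' @return Parsed `report.json` as a list.
#' @export
read_report <- function(dir) {
  jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
}
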