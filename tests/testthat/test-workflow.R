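# Occurrence I/O, the end-to-end driver, and report round-tripping.

test_that("the bundled occurrence fixture parses to seven georeferenced records", {
  occ <- corsican_occurrences()
  expect_equal(nrow(occ), 7)
  expect_true(all(abs(occ$lon - 9) < 1.5))
  expect_true(all(abs(occ$lat - 42.3) < 1.5))
  # mixed DMS and decimal rows equal hand-computed decimals
  expect_equal(occ$lat[occ$id == "cognocoli"], 41 + 51 / 60 + 4.4 / 3600,
               tolerance = 1e-9)
  expect_equal(occ$lon[occ$id == "chioso"], 9.434145)
  # printed elevation range populates the band columns
  expect_equal(occ$elev_min_m[occ$id == "sisco"], 25)
  expect_equal(occ$elev_max_m[occ$id == "sisco"], 300)
  expect_equal(min(occ$elev_min_m, na.rm = TRUE), 25)
  expect_equal(max(occ$elev_max_m, na.rm = TRUE), 1244)
})

test_that("occurrence files with defects fail with informative errors", {
  empty <- tempfile(fileext = ".csv")
  writeLines("id,lat,lon", empty)
  expect_error(read_occurrences(empty), "no records")

  missing <- tempfile(fileext = ".csv")
  writeLines(c("id,lat", "a,42"), missing)
  expect_error(read_occurrences(missing), "lon")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("id,lat,lon", "a,42,9", "b,4x2,9"), bad)
  expect_error(read_occurrences(bad), "row 2")
})

test_that("the end-to-end synthetic assessment is deterministic and coherent", {
  cfg <- list(seed = 19, decline_observed = TRUE,
              synthetic = list(seed = 19, n_rows = 150, n_cols = 150,
                               truth = list(suitable_classes = c(3, 4, 5),
                                            elev_min = 50, elev_max = 1200),
                               n_occurrences = 60, n_outliers = 0,
                               pa_coverage = 0.4))
  r1 <- run_assessment(cfg)
  r2 <- run_assessment(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  write_report(r1, d1); write_report(r2, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))

  # clean sampling: every occupied cell is habitat, classifier matches oracle
  expect_equal(r1$validation$k, r1$validation$n)
  expect_identical(r1$redlist$category,
                   redlist_oracle(r1$range$eoo_km2, r1$range$aoo_km2,
                                  r1$range$n_localities, TRUE, FALSE))
  # EOO-clipped AOH nests in the island-wide one
  expect_lte(r1$aoh_areas$area_km2[1], r1$aoh_areas$area_km2[2])
  expect_true(r1$kba$pa_overlap_pct >= 0 && r1$kba$pa_overlap_pct <= 100)
})

test_that("reports round-trip through disk with values intact", {
  cfg <- list(seed = 23, decline_observed = TRUE,
              synthetic = list(seed = 23, n_rows = 100, n_cols = 100,
                               truth = list(suitable_classes = c(4, 5),
                                            elev_min = 0, elev_max = 1500),
                               n_occurrences = 40))
  rep <- run_assessment(cfg)
  dir <- tempfile()
  write_report(rep, dir)
  back <- read_report(dir)
  expect_equal(back$range$eoo_km2, rep$range$eoo_km2)
  expect_equal(back$validation$p_value, rep$validation$p_value)
  expect_equal(back$kba$total_area_km2, rep$kba$total_area_km2)
  expect_equal(back$provenance$config_hash, rep$provenance$config_hash)
  expect_true(file.exists(file.path(dir, "aoh_eoo.asc")))

  # the AOH raster round-trips through the ASCII grid format
  asc <- read_asc(file.path(dir, "aoh_eoo.asc"), type = "categorical")
  expect_equal(sum(asc$values == 1, na.rm = TRUE), sum(rep$layers$aoh_eoo$mask))

  # config changes change the echoed hash; reruns do not
  rep2 <- run_assessment(utils::modifyList(cfg, list(linkage_km = 5)))
  expect_false(identical(rep2$provenance$config_hash, rep$provenance$config_hash))
})

test_that("the KBA stage can be switched off and reports null", {
  cfg <- list(seed = 29, decline_observed = TRUE, include_kba = FALSE,
              synthetic = list(seed = 29, n_rows = 100, n_cols = 100,
                               truth = list(suitable_classes = c(4, 5),
                                            elev_min = 0, elev_max = 1500),
                               n_occurrences = 30))
  rep <- run_assessment(cfg)
  expect_null(rep$kba)
  dir <- tempfile()
  write_report(rep, dir)
  expect_match(paste(readLines(file.path(dir, "report.json")), collapse = ""),
               '"kba": *null')
})

test_that("occurrence-only configurations produce the range and Red List block", {
  occ <- corsican_occurrences()
  rep <- run_assessment(list(occurrences = occ, decline_observed = TRUE))
  expect_null(rep$aoh_areas)
  expect_equal(rep$range$aoo_km2, 24)
  expect_equal(rep$redlist$category, "EN")
  g <- glance(rep)
  expect_equal(g$category, "EN")
  td <- tidy(rep)
  expect_true(all(c("eoo_km2", "aoo_km2", "n_localities") %in% td$metric))
})

test_that("yaml configuration files drive the assessment", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    occurrences = system.file("extdata", "nesodexia_corsicana_occurrences.csv",
                              package = "kbascope"),
    decline_observed = TRUE, linkage_km = 10
  ), path)
  rep <- run_assessment(path)
  expect_equal(rep$range$n_localities, 5L)
  expect_false(is.null(rep$provenance$occurrence_file_md5))
})
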