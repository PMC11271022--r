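# Habitat-model inference, AOH construction, hypergeometric validation.

test_that("the habitat model is the observed class set and elevation band", {
  cls <- matrix(c(23, 23, 25,
                  11, 25, 23,
                  11, 11, 25), 3, 3, byrow = TRUE)
  elev <- matrix(seq(100, 900, by = 100), 3, 3)
  ls <- make_flat_landscape(cls, elev)
  rec <- records_at_cells(ls, rows = c(1, 2, 3), cols = c(1, 2, 3))
  m <- infer_habitat_model(rec, ls$landcover, ls$elevation, ls$projection)
  expect_equal(m$suitable_classes, sort(unique(cls[cbind(1:3, 1:3)])))
  # elevation sampled from the raster at those cells
  expect_equal(m$elev_min, min(elev[cbind(1:3, 1:3)]))
  expect_equal(m$elev_max, max(elev[cbind(1:3, 1:3)]))
})

test_that("printed record elevations take precedence over the raster", {
  ls <- make_flat_landscape(matrix(1L, 2, 2), matrix(500, 2, 2))
  rec <- records_at_cells(ls, rows = c(1, 2), cols = c(1, 2),
                          elev_min_m = c(25, 1200), elev_max_m = c(300, 1244))
  m <- infer_habitat_model(rec, ls$landcover, ls$elevation, ls$projection)
  expect_equal(m$elev_min, 25)
  expect_equal(m$elev_max, 1244)
})

test_that("records falling off every land cell raise a listing error", {
  ls <- make_flat_landscape(matrix(NA_integer_, 2, 2), matrix(NA_real_, 2, 2))
  rec <- records_at_cells(ls, rows = 1, cols = 1)
  expect_error(infer_habitat_model(rec, ls$landcover, ls$elevation, ls$projection),
               "r01")
})

test_that("synthetic ground truth is recovered exactly when sampling is clean", {
  isl <- generate_island(seed = 33, n_rows = 150, n_cols = 150)
  tr <- synthetic_truth(c(2, 5, 7), 80, 1100, p_in_habitat = 1, seed = 3)
  occ <- sample_occurrences(isl, tr, 400)   # large n: every class gets sampled
  m <- infer_habitat_model(occ, isl$landcover, isl$elevation, isl$projection)
  expect_equal(m$suitable_classes, tr$suitable_classes)
  expect_gte(m$elev_min, tr$elev_min)
  expect_lte(m$elev_max, tr$elev_max)
})

test_that("AOH masks match a brute-force cell scan and honour the boundary", {
  isl <- generate_island(seed = 17, n_rows = 100, n_cols = 100)
  model <- habitat_model(c(3, 4), 100, 800)
  aoh <- build_aoh(isl$landcover, isl$elevation, model)

  # independent full scan over every cell
  cnt <- 0L
  for (i in seq_len(100)) for (j in seq_len(100)) {
    cl <- isl$landcover$values[i, j]; el <- isl$elevation$values[i, j]
    if (!is.na(cl) && cl %in% c(3, 4) && !is.na(el) && el >= 100 && el <= 800)
      cnt <- cnt + 1L
  }
  expect_equal(sum(aoh$mask), cnt)
  expect_equal(aoh$area_km2, cnt * 0.01)

  # a class absent from the raster gives an empty map
  empty <- build_aoh(isl$landcover, isl$elevation, habitat_model(99))
  expect_equal(empty$area_km2, 0)

  # clipped domain nests inside the island-wide one
  box <- tibble::tibble(x = c(-3000, 3000, 3000, -3000),
                        y = c(-3000, -3000, 3000, 3000))
  clipped <- build_aoh(isl$landcover, isl$elevation, model, boundary = box,
                       domain_label = "EOO-clipped")
  expect_true(all(!clipped$mask | aoh$mask))
  expect_lte(clipped$area_km2, aoh$area_km2)
  expect_true(all(clipped$domain | !clipped$mask))

  h2 <- raster_header(0, 0, 100, 50, 50)
  other <- scape_raster(matrix(0, 50, 50), h2)
  expect_error(build_aoh(isl$landcover, other, model), "header")
})

test_that("hypergeometric validation matches full enumeration for small N", {
  # worked case: N=10 domain cells, K=5 habitat, records in 2 cells, both habitat
  ls <- make_flat_landscape(matrix(c(rep(1L, 5), rep(2L, 5)), 1, 10),
                            matrix(0, 1, 10))
  aoh <- build_aoh(ls$landcover, ls$elevation, habitat_model(1))
  rec <- records_at_cells(ls, rows = c(1, 1), cols = c(1, 2))
  v <- validate_aoh(aoh, rec, ls$projection)
  expect_equal(v$p_value, 10 / 45, tolerance = 1e-12)
  expect_equal(c(v$N, v$K, v$n, v$k), c(10, 5, 2, 2))

  # exhaustive check across the (N <= 12, K, n, k) lattice
  for (N in c(5, 8, 12)) for (K in c(1, 3, N - 1)) for (n in c(1, 3, N)) {
    for (k in 0:min(n, K)) {
      got <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      expect_equal(got, enum_hyper_upper(N, K, n, k), tolerance = 1e-12,
                   label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
    }
  }
})

test_that("the validation p-value behaves as an upper tail should", {
  # all-habitat domain: p = 1 whatever the records hit
  ls <- make_flat_landscape(matrix(1L, 2, 5), matrix(0, 2, 5))
  aoh <- build_aoh(ls$landcover, ls$elevation, habitat_model(1))
  rec <- records_at_cells(ls, rows = c(1, 2, 1), cols = c(1, 3, 5))
  expect_equal(validate_aoh(aoh, rec, ls$projection)$p_value, 1)

  # p is non-increasing in k at fixed (N, K, n)
  p <- stats::phyper(0:4 - 1, 5, 7, 4, lower.tail = FALSE)
  expect_true(all(diff(p) <= 0))

  # duplicate records in one cell count once
  ls2 <- make_flat_landscape(matrix(c(1L, 1L, 2L, 2L), 1, 4), matrix(0, 1, 4))
  aoh2 <- build_aoh(ls2$landcover, ls2$elevation, habitat_model(1))
  dup <- records_at_cells(ls2, rows = c(1, 1, 1), cols = c(1, 1, 2))
  v2 <- validate_aoh(aoh2, dup, ls2$projection)
  expect_equal(v2$n, 2)
  expect_equal(v2$k, 2)
})

test_that("an injected off-habitat record shows up as k = n - 1", {
  isl <- generate_island(seed = 51, n_rows = 120, n_cols = 120)
  tr <- synthetic_truth(c(3, 4, 5), 50, 1300, p_in_habitat = 1, seed = 6)
  occ <- sample_occurrences(isl, tr, 30, n_outliers = 1)
  aoh <- build_aoh(isl$landcover, isl$elevation,
                   habitat_model(tr$suitable_classes, tr$elev_min, tr$elev_max))
  v <- validate_aoh(aoh, occ, isl$projection)
  expect_equal(v$k, v$n - 1)
  expect_true(v$better_than_random)

  off <- records_at_cells(make_flat_landscape(matrix(1L, 2, 2), matrix(0, 2, 2)),
                          rows = 1, cols = 1)
  off$lon <- off$lon + 45   # far off the raster
  expect_warning(validate_aoh(aoh, dplyr::bind_rows(occ, off), isl$projection),
                 "excluded")
})
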