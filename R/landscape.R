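# Synthetic island landscapes: a smoothed Gaussian random field supplies a
# coastline (quantile threshold) and an elevation surface; land-cover classes
# follow elevation bands perturbed by patchy categorical noise, giving a
# CORINE-like 100 m mosaic. Everything is deterministic in the seed, so the
# full assessment pipeline can be exercised with no external geodata.

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# separable Gaussian smoothing with renormalised truncated kernels
# (equivalent to reflection-free boundary handling)
gauss_smooth <- function(m, sigma) {
  smooth_1d_matrix <- function(n) {
    r <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(-r:r, sd = sigma)
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      lo <- max(1, i - r); hi <- min(n, i + r)
      w <- k[(lo - i + r + 1):(hi - i + r + 1)]
      A[i, lo:hi] <- w / sum(w)
    }
    A
  }
  A <- smooth_1d_matrix(nrow(m))
  B <- if (ncol(m) == nrow(m)) A else smooth_1d_matrix(ncol(m))
  A %*% m %*% t(B)
}

#' Generate a synthetic island landscape
#'
#' Builds a smoothed white-noise field, suppresses it towards the grid edges
#' so land concentrates centrally, and thresholds it at the `sea_fraction`
#' quantile: cells above the threshold are land, the rest sea. Elevation is
#' the rescaled field over land (spatially autocorrelated by construction);
#' land-cover classes are elevation bands perturbed with patchy categorical
#' noise from a second smoothed field.
#'
#' @param seed Integer seed; identical seeds give bit-identical landscapes.
#' @param n_rows,n_cols Grid dimensions (default 200 x 200 cells).
#' @param n_classes Number of land-cover classes (>= 2).
#' @param sea_fraction Fraction of cells that are sea, in (0, 1).
#' @param cell_size Cell edge in metres (default 100).
#' @param smooth_sigma Smoothing kernel bandwidth in cells; controls coastline
#'   and relief wavelength.
#' @param max_elev Maximum elevation in metres.
#' @param projection The [laea_projection()] the landscape is georeferenced
#'   in; the raster is centred on the projection origin.
#' @return An `island_landscape` with elements `landcover`, `elevation`
#'   (both [scape_raster()]), `field` (the underlying smooth surface),
#'   `sea_level`, `coastline` (list of rings in metres), `projection`.
#' @export
generate_island <- function(seed, n_rows = 200, n_cols = 200, n_classes = 8,
                            sea_fraction = 0.35, cell_size = 100,
                            smooth_sigma = 10, max_elev = 1500,
                            projection = laea_projection(9.0, 42.0)) {
  stopifnot(n_classes >= 2, sea_fraction > 0, sea_fraction < 1)
  if (n_rows < 8 || n_cols < 8) stop("grid too small to contain land", call. = FALSE)

  header <- raster_header(origin_x = -n_cols * cell_size / 2,
                          origin_y = -n_rows * cell_size / 2,
                          cell_size = cell_size, n_rows = n_rows, n_cols = n_cols)

  with_seed(seed, {
    f <- gauss_smooth(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols),
                      smooth_sigma)
    f <- (f - mean(f)) / stats::sd(f)
    # radial taper keeps land away from the grid edge so the coastline closes
    ri <- (seq_len(n_rows) - (n_rows + 1) / 2) / (n_rows / 2)
    rj <- (seq_len(n_cols) - (n_cols + 1) / 2) / (n_cols / 2)
    r2 <- outer(ri^2, rj^2, `+`)
    f <- f - 2.5 * r2

    sea_level <- stats::quantile(f, sea_fraction, names = FALSE)
    land <- f > sea_level
    if (sum(land) < 16) stop("grid too small to contain land", call. = FALSE)

    elev <- matrix(NA_real_, n_rows, n_cols)
    elev[land] <- (f[land] - sea_level) / (max(f) - sea_level) * max_elev

    # elevation bands -> classes, then patchy perturbation
    breaks <- stats::quantile(elev[land], probs = seq(0, 1, length.out = n_classes + 1),
                              names = FALSE)
    breaks[1] <- -Inf; breaks[n_classes + 1] <- Inf
    cls <- matrix(NA_integer_, n_rows, n_cols)
    cls[land] <- as.integer(cut(elev[land], breaks = breaks, labels = FALSE))
    patch <- gauss_smooth(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols),
                          max(2, smooth_sigma / 2))
    swap <- land & patch > stats::quantile(patch[land], 0.75, names = FALSE)
    cls[swap] <- (cls[swap] %% n_classes) + 1L

    structure(list(
      landcover = scape_raster(cls, header, type = "categorical"),
      elevation = scape_raster(elev, header, type = "continuous"),
      field = f,
      sea_level = sea_level,
      coastline = raster_contour(f, header, sea_level),
      projection = projection,
      seed = seed
    ), class = "island_landscape")
  })
}

#' @export
print.island_landscape <- function(x, ...) {
  h <- x$landcover$header
  land <- sum(!is.na(x$landcover$values))
  cat(sprintf("synthetic island: %d x %d cells of %g m, %d land cells (%.1f km2)\n",
              h$n_rows, h$n_cols, h$cell_size, land, land * h$cell_size^2 / 1e6))
  cat(sprintf("  %d land-cover classes, elevation %.0f-%.0f m, seed %d\n",
              length(stats::na.omit(unique(as.vector(x$landcover$values)))),
              min(x$elevation$values, na.rm = TRUE),
              max(x$elevation$values, na.rm = TRUE), x$seed))
  invisible(x)
}

#' Ground-truth habitat definition for synthetic sampling
#'
#' @param suitable_classes Integer set of suitable land-cover codes.
#' @param elev_min,elev_max Elevation band in metres.
#' @param p_in_habitat Probability that a sampled occurrence respects the
#'   habitat definition (the rest fall uniformly on unsuitable land).
#' @param seed RNG seed for occurrence sampling.
#' @return A `synthetic_truth` object.
#' @export
synthetic_truth <- function(suitable_classes, elev_min, elev_max,
                            p_in_habitat = 1, seed = 1) {
  stopifnot(p_in_habitat >= 0, p_in_habitat <= 1, elev_min <= elev_max,
            length(suitable_classes) >= 1)
  structure(list(suitable_classes = sort(unique(as.integer(suitable_classes))),
                 elev_min = elev_min, elev_max = elev_max,
                 p_in_habitat = p_in_habitat, seed = seed),
            class = "synthetic_truth")
}

# logical habitat mask implied by a truth/model on a landscape
habitat_mask_of <- function(island, suitable_classes, elev_min, elev_max) {
  cls <- island$landcover$values
  elev <- island$elevation$values
  !is.na(cls) & cls %in% suitable_classes &
    !is.na(elev) & elev >= elev_min & elev <= elev_max
}

#' Sample occurrence records on a synthetic landscape
#'
#' Draws `n - n_outliers` records that respect the ground-truth habitat with
#' probability `p_in_habitat` (otherwise they fall uniformly on unsuitable
#' land), plus `n_outliers` records forced outside the habitat and flagged as
#' historical (collection year before 1950) — emulating an old, possibly
#' habitat-loss-affected record in an otherwise habitat-consistent set.
#'
#' @param island An [generate_island()] landscape.
#' @param truth A [synthetic_truth()].
#' @param n Total number of records.
#' @param n_outliers Number of forced off-habitat historical records.
#' @return Tibble of occurrence records: `id`, `lon`, `lat`, `year`,
#'   `elevation_m`, `note`, plus bookkeeping columns `x`, `y`, `in_habitat`.
#' @export
sample_occurrences <- function(island, truth, n, n_outliers = 0) {
  stopifnot(inherits(island, "island_landscape"), inherits(truth, "synthetic_truth"),
            n >= 1, n_outliers >= 0, n_outliers <= n)
  hab <- habitat_mask_of(island, truth$suitable_classes, truth$elev_min, truth$elev_max)
  land <- !is.na(island$landcover$values)
  off <- land & !hab
  if (!any(hab)) stop("habitat is empty on this landscape", call. = FALSE)
  if ((n_outliers > 0 || truth$p_in_habitat < 1) && !any(off)) {
    stop("no unsuitable land available for off-habitat records", call. = FALSE)
  }
  h <- island$landcover$header

  with_seed(truth$seed, {
    n_reg <- n - n_outliers
    respects <- stats::runif(n_reg) < truth$p_in_habitat
    pick <- function(mask, k) {
      cells <- which(mask)
      cells[sample.int(length(cells), k, replace = TRUE)]
    }
    cell <- integer(0)
    if (any(respects)) cell <- c(cell, pick(hab, sum(respects)))
    if (any(!respects)) cell <- c(cell, pick(off, sum(!respects)))
    in_hab <- c(rep(TRUE, sum(respects)), rep(FALSE, sum(!respects)))
    year <- sample(2015:2021, n_reg, replace = TRUE)
    if (n_outliers > 0) {
      cell <- c(cell, pick(off, n_outliers))
      in_hab <- c(in_hab, rep(FALSE, n_outliers))
      year <- c(year, sample(1900:1949, n_outliers, replace = TRUE))
    }
    ij <- arrayInd(cell, dim(hab))
    x <- h$origin_x + (ij[, 2] - 1 + stats::runif(n)) * h$cell_size
    y <- h$origin_y + (ij[, 1] - 1 + stats::runif(n)) * h$cell_size
    ll <- unproject_points(tibble::tibble(x = x, y = y), island$projection)
    tibble::tibble(
      id = sprintf("occ-%04d", seq_len(n)),
      lon = ll$lon, lat = ll$lat,
      year = year,
      elevation_m = island$elevation$values[ij],
      note = ifelse(seq_len(n) > n_reg, "historical outlier", ""),
      x = x, y = y,
      in_habitat = in_hab
    )
  })
}

#' Generate a synthetic protected area inside the coastline
#'
#' The protected area is a superlevel set of the island's smooth surface
#' blended with fresh seed noise that is tapered to zero at the coastline, so
#' the resulting contour polygon is guaranteed to lie inside the coast. The
#' threshold is chosen so the enclosed land area equals
#' `coverage_fraction` x island area (cell-count bookkeeping, within 2%).
#'
#' @param island An [generate_island()] landscape.
#' @param coverage_fraction Target fraction of the island's land area, in
#'   (0, 0.9]; fractions approaching 1 are rejected as infeasible because the
#'   polygon must remain strictly inside the coastline.
#' @param seed RNG seed for the blending noise.
#' @return A `protected_area`: `rings` (list of polygons in metres), `mask`
#'   (logical matrix on the island grid), `header`, `area_km2`,
#'   `coverage_fraction`.
#' @export
generate_protected_area <- function(island, coverage_fraction, seed = 1) {
  stopifnot(inherits(island, "island_landscape"))
  if (coverage_fraction <= 0 || coverage_fraction >= 1) {
    stop("coverage_fraction must be in (0, 1)", call. = FALSE)
  }
  if (coverage_fraction > 0.9) {
    stop("coverage_fraction above 0.9 is infeasible: the protected area must stay inside the coastline",
         call. = FALSE)
  }
  f <- island$field
  q <- island$sea_level
  h <- island$landcover$header
  land <- f > q

  with_seed(seed, {
    noise <- gauss_smooth(matrix(stats::rnorm(length(f)), nrow(f), ncol(f)),
                          max(2, ceiling(nrow(f) / 25)))
    noise <- (noise - mean(noise)) / stats::sd(noise)
    taper <- pmax(0, (f - q) / (max(f) - q))
    H <- f + 0.6 * (max(f) - q) * taper * noise

    target <- round(coverage_fraction * sum(land))
    if (target < 4) stop("coverage_fraction infeasible on this landscape", call. = FALSE)
    level <- sort(H[land], decreasing = TRUE)[target]
    mask <- land & H >= level
    if (abs(sum(mask) - coverage_fraction * sum(land)) > 0.02 * sum(land)) {
      stop("could not achieve coverage_fraction within 2%", call. = FALSE)
    }
    structure(list(
      rings = raster_contour(H, h, level),
      mask = mask,
      header = h,
      area_km2 = sum(mask) * h$cell_size^2 / 1e6,
      coverage_fraction = sum(mask) / sum(land),
      seed = seed
    ), class = "protected_area")
  })
}

#' @export
print.protected_area <- function(x, ...) {
  cat(sprintf("protected area: %.1f km2 (%.1f%% of island), %d ring(s)\n",
              x$area_km2, 100 * x$coverage_fraction, length(x$rings)))
  invisible(x)
}
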