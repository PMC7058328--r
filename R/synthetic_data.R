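# Synthetic landscapes, covariates and detection histories with known
# ground truth. The generator emulates the study conditions of a
# patch-landscape occupancy survey: a few dozen habitat patches embedded in
# a crop/urban matrix with a low overall habitat proportion, a linear river
# feature, two surveys per patch, and occupancy/detection driven by
# logit-linear models with a single known scale of effect.

#' Simulation configuration
#'
#' Defaults describe the reference desk-scale scenario: a 3 x 3 km
#' landscape at 5 m resolution, 40 irregular patches targeting 12% habitat
#' cover, a river crossing the extent, 2 surveys per patch, composition
#' evaluated at the ten standard buffer scales, and occupancy driven by the
#' habitat proportion at a true scale of 250 m plus distance to river.
#'
#' @param extent_m landscape width/height (m), length-2.
#' @param cell_size_m land-cover cell size (m).
#' @param dem_cell_size_m DEM cell size (m).
#' @param n_patches number of habitat patches.
#' @param habitat_fraction_target target proportion of habitat cells, in (0,1\].
#' @param class_table land-cover classes, see [default_class_table()].
#' @param patch_classes habitat classes the generator assigns to patches.
#' @param urban_fraction share of matrix cells turned into urban blocks.
#' @param river draw a river polyline across the landscape?
#' @param scales buffer scale set (m).
#' @param true_scale_m scale (m) at which the composition covariate truly
#'   acts; must be one of `scales`.
#' @param psi_covariates names of occupancy covariates; composition names
#'   (`habitat`, `crop_pas`, `urban`, `prox`) are resolved at `true_scale_m`.
#' @param true_psi_coefs intercept plus one logit-scale coefficient per
#'   occupancy covariate (covariates are z-scored before coefficients apply).
#' @param true_p_coefs logit-scale detection coefficients: intercept,
#'   vegetation structure, day of survey, patch area.
#' @param n_surveys surveys per patch (>= 2).
#' @param seed integer seed governing every random draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(extent_m = c(3000, 3000),
                       cell_size_m = 5,
                       dem_cell_size_m = 30,
                       n_patches = 40,
                       habitat_fraction_target = 0.12,
                       class_table = default_class_table(),
                       patch_classes = c("grass", "dry_grass", "shrubland", "woodland"),
                       urban_fraction = 0.2,
                       river = TRUE,
                       scales = default_scales(),
                       true_scale_m = 250,
                       psi_covariates = c("habitat", "dist_river"),
                       true_psi_coefs = c(0, 1.5, -1),
                       true_p_coefs = c(0.5, -0.5, 0.5, 0.5),
                       n_surveys = 2,
                       seed = 1) {
  stopifnot(
    length(extent_m) == 2, all(extent_m > 0),
    extent_m[1] %% cell_size_m == 0, extent_m[2] %% cell_size_m == 0,
    n_patches >= 1,
    habitat_fraction_target > 0, habitat_fraction_target <= 1,
    true_scale_m %in% scales,
    length(true_psi_coefs) == length(psi_covariates) + 1,
    length(true_p_coefs) == 4,
    n_surveys >= 2
  )
  check_scales(scales)
  structure(
    list(
      extent_m = extent_m, cell_size_m = cell_size_m,
      dem_cell_size_m = dem_cell_size_m,
      n_patches = n_patches,
      habitat_fraction_target = habitat_fraction_target,
      class_table = class_table, patch_classes = patch_classes,
      urban_fraction = urban_fraction, river = river,
      scales = scales, true_scale_m = true_scale_m,
      psi_covariates = psi_covariates,
      true_psi_coefs = true_psi_coefs, true_p_coefs = true_p_coefs,
      n_surveys = n_surveys, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

code_of <- function(class_table, name) class_table$code[match(name, class_table$class)]

#' Generate a synthetic landscape
#'
#' Places `n_patches` disjoint habitat patches (axis-aligned rectangles
#' with random side bumps for shape irregularity) into a crop/urban matrix,
#' rasterizes a 1-cell-wide river polyline, and builds a smooth DEM.
#' Patch polygons are traced from the rasterized cells, so raster and
#' vector representations agree exactly. The same seed gives bit-identical
#' output.
#'
#' @param config a [sim_config()].
#' @return A list of class `occ_landscape`: `land_cover` and `dem`
#'   ([occ_raster()]), `patches` (tibble: `patch_id`, `habitat_type`,
#'   `cells`, `polygon`), `river` (polyline matrix or `NULL`),
#'   `class_table`, `config`, and `habitat_fraction` (realized).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cs <- config$cell_size_m
  nc <- as.integer(config$extent_m[1] / cs)
  nr <- as.integer(config$extent_m[2] / cs)
  ncells <- nr * nc
  ct <- config$class_table

  lc <- matrix(code_of(ct, "crop_pas"), nr, nc)
  occupied <- matrix(FALSE, nr, nc) # patches + exclusion gap
  river_mask <- matrix(FALSE, nr, nc)

  whole_extent <- config$habitat_fraction_target >= 0.999 && config$n_patches == 1

  river_coords <- NULL
  if (config$river && !whole_extent) {
    rv <- draw_river(nr, nc)
    river_coords <- cbind(
      x = (rv$cols - 0.5) * cs,
      y = (nr - rv$rows + 0.5) * cs
    )
    river_mask[cbind(rv$rows, rv$cols)] <- TRUE
    occupied <- occupied | dilate_mask(river_mask, 2L)
  }

  target_cells <- round(config$habitat_fraction_target * ncells)
  patch_cells_list <- vector("list", config$n_patches)
  if (whole_extent) {
    patch_cells_list[[1]] <- as.matrix(expand.grid(row = 1:nr, col = 1:nc))
  } else {
    # budget base rectangles at ~85% of target; side bumps supply the rest
    rel <- exp(stats::rnorm(config$n_patches, 0, 0.6))
    areas <- pmax(9, round(rel / sum(rel) * target_cells * 0.85))
    if (sum(areas) > 0.6 * ncells) {
      stop("habitat target infeasible for the requested patch count and extent")
    }
    for (i in seq_len(config$n_patches)) {
      placed <- FALSE
      for (try in 1:400) {
        aspect <- stats::runif(1, 0.5, 2)
        w <- max(2L, round(sqrt(areas[i] * aspect)))
        h <- max(2L, round(areas[i] / w))
        if (w > nc - 2L || h > nr - 2L) next
        r0 <- sample.int(nr - h - 1L, 1) + 1L
        c0 <- sample.int(nc - w - 1L, 1) + 1L
        rows <- r0:(r0 + h - 1L); cols <- c0:(c0 + w - 1L)
        if (any(occupied[rows, cols])) next
        cells <- as.matrix(expand.grid(row = rows, col = cols))
        cells <- add_bumps(cells, occupied, nr, nc)
        patch_cells_list[[i]] <- cells
        block <- matrix(FALSE, nr, nc)
        block[cells] <- TRUE
        occupied <- occupied | dilate_mask(block, 2L)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(
          "could not place patch ", i, " of ", config$n_patches,
          ": habitat target infeasible for this extent"
        )
      }
    }
  }

  habitat_types <- sample(config$patch_classes, config$n_patches, replace = TRUE)
  for (i in seq_len(config$n_patches)) {
    lc[patch_cells_list[[i]]] <- code_of(ct, habitat_types[i])
  }

  realized <- sum(vapply(patch_cells_list, nrow, integer(1))) / ncells
  if (abs(realized - config$habitat_fraction_target) > 0.03) {
    stop(sprintf(
      "realized habitat fraction %.3f misses target %.3f by more than 3 points",
      realized, config$habitat_fraction_target
    ))
  }

  if (!whole_extent && config$urban_fraction > 0) {
    lc <- place_urban(lc, occupied | river_mask, code_of(ct, "urban"),
      target = config$urban_fraction * ncells
    )
  }
  lc[river_mask] <- code_of(ct, "river")

  raster <- occ_raster(lc, xmin = 0, ymin = 0, cellsize = cs)
  patches <- tibble::tibble(
    patch_id = seq_len(config$n_patches),
    habitat_type = habitat_types,
    cells = patch_cells_list,
    polygon = purrr::map(patch_cells_list, cells_to_polygon, r = raster)
  )

  dem <- make_dem(config)

  structure(
    list(
      land_cover = raster, dem = dem, patches = patches,
      river = river_coords, class_table = ct, config = config,
      habitat_fraction = realized
    ),
    class = "occ_landscape"
  )
}

# meandering 1-cell river from top to bottom
draw_river <- function(nr, nc) {
  col <- round(nc * stats::runif(1, 0.3, 0.7))
  cols <- integer(nr)
  for (r in seq_len(nr)) {
    col <- min(max(col + sample(c(-1L, 0L, 0L, 1L), 1), 3L), nc - 2L)
    cols[r] <- col
  }
  list(rows = seq_len(nr), cols = cols)
}

# grow a boolean mask by k cells (Chebyshev) — cheap via shifted ORs
dilate_mask <- function(m, k) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (dr in -k:k) {
    for (dcol in -k:k) {
      if (dr == 0 && dcol == 0) next
      src_r <- max(1, 1 - dr):min(nr, nr - dr)
      src_c <- max(1, 1 - dcol):min(nc, nc - dcol)
      out[src_r + dr, src_c + dcol] <- out[src_r + dr, src_c + dcol] | m[src_r, src_c]
    }
  }
  out
}

# attach 0-2 rectangular bumps to a rectangle of cells, keeping the patch
# simply connected and clear of other occupied cells
add_bumps <- function(cells, occupied, nr, nc) {
  n_bumps <- sample(0:2, 1, prob = c(0.2, 0.4, 0.4))
  if (n_bumps == 0) return(cells)
  have <- matrix(FALSE, nr, nc)
  have[cells] <- TRUE
  rr <- range(cells[, 1]); cr <- range(cells[, 2])
  for (b in seq_len(n_bumps)) {
    side <- sample(c("N", "S", "E", "W"), 1)
    bw <- max(1L, round((cr[2] - cr[1] + 1L) * stats::runif(1, 0.2, 0.5)))
    bh <- max(1L, round((rr[2] - rr[1] + 1L) * stats::runif(1, 0.2, 0.5)))
    if (side %in% c("N", "S")) {
      c0 <- sample(cr[1]:(max(cr[1], cr[2] - bw + 1L)), 1)
      rows <- if (side == "N") (rr[1] - bh):(rr[1] - 1L) else (rr[2] + 1L):(rr[2] + bh)
      cols <- c0:(c0 + bw - 1L)
    } else {
      r0 <- sample(rr[1]:(max(rr[1], rr[2] - bh + 1L)), 1)
      cols <- if (side == "W") (cr[1] - bw):(cr[1] - 1L) else (cr[2] + 1L):(cr[2] + bw)
      rows <- r0:(r0 + bh - 1L)
    }
    if (min(rows) < 2L || max(rows) > nr - 1L || min(cols) < 2L || max(cols) > nc - 1L) next
    if (any(occupied[rows, cols]) || any(have[rows, cols])) next
    have[as.matrix(expand.grid(row = rows, col = cols))] <- TRUE
  }
  which(have, arr.ind = TRUE)
}

# overlay random urban rectangles on free matrix cells until ~target cells
place_urban <- function(lc, blocked, urban_code, target) {
  nr <- nrow(lc); nc <- ncol(lc)
  placed <- 0
  for (try in 1:500) {
    if (placed >= target) break
    w <- sample(8:40, 1); h <- sample(8:40, 1)
    if (w >= nc || h >= nr) next
    r0 <- sample.int(nr - h, 1); c0 <- sample.int(nc - w, 1)
    rows <- r0:(r0 + h - 1L); cols <- c0:(c0 + w - 1L)
    free <- !blocked[rows, cols]
    idx <- as.matrix(expand.grid(row = rows, col = cols))[as.vector(free), , drop = FALSE]
    if (nrow(idx) == 0) next
    lc[idx] <- urban_code
    placed <- placed + nrow(idx)
  }
  lc
}

# smooth DEM: inclined plane + two long-wavelength sinusoids
make_dem <- function(config) {
  cs <- config$dem_cell_size_m
  nc <- max(4L, ceiling(config$extent_m[1] / cs))
  nr <- max(4L, ceiling(config$extent_m[2] / cs))
  x <- (seq_len(nc) - 0.5) * cs
  y <- ((nr - seq_len(nr)) + 0.5) * cs
  gx <- stats::runif(1, -0.05, 0.05); gy <- stats::runif(1, -0.05, 0.05)
  amp <- stats::runif(1, 5, 25)
  lam <- stats::runif(1, 600, 1500)
  z <- outer(y, x, function(yy, xx) {
    200 + gx * xx + gy * yy +
      amp * sin(2 * pi * xx / lam) * cos(2 * pi * yy / lam)
  })
  occ_raster(z, xmin = 0, ymin = 0, cellsize = cs)
}

#' @export
print.occ_landscape <- function(x, ...) {
  cat(sprintf(
    "<occ_landscape> %d patches, %.1f%% habitat, %s river, seed %d\n",
    nrow(x$patches), 100 * x$habitat_fraction,
    if (is.null(x$river)) "no" else "with", x$config$seed
  ))
  invisible(x)
}

#' Simulate site and survey covariates for a synthetic landscape
#'
#' Computes every covariate family the analysis consumes: buffer
#' composition and proximity at all configured scales, nearest-patch
#' distance, distances to river/crop/urban, patch geometry, vegetation
#' structure (from simulated 25 m^2 plot coverages run through the FHD
#' machinery), DEM slope, a pass-through radiation column, and survey-level
#' day of year. With a single patch `np_dist` is `NA` (no neighbour
#' exists).
#'
#' @param landscape an `occ_landscape` from [generate_landscape()].
#' @param config the matching [sim_config()]; defaults to the one stored in
#'   the landscape.
#' @return List with `site` (one row per patch) and `surveys` (one row per
#'   patch x survey, column `day`) tibbles, plus `plots` (the simulated
#'   vegetation plot table).
#' @export
simulate_covariates <- function(landscape, config = landscape$config) {
  set.seed(config$seed + 1L)
  metrics <- patch_metrics(landscape, scales = config$scales)

  # vegetation plots: 1-3 per patch, coverages from scaled gamma draws with
  # random zero classes so FHD varies between 0 and log(9)
  plots <- purrr::map(seq_len(nrow(landscape$patches)), function(i) {
    np <- sample(1:3, 1)
    purrr::map(seq_len(np), function(k) {
      g <- stats::rgamma(9, shape = 0.7)
      g[stats::runif(9) < 0.3] <- 0
      if (all(g == 0)) g[sample.int(9, 2)] <- 1
      cov <- round(100 * g / max(g), 1)
      tibble::tibble(
        patch_id = landscape$patches$patch_id[i],
        habitat_type = landscape$patches$habitat_type[i],
        !!!stats::setNames(as.list(cov), paste0("cover_", 1:9))
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  # each generated patch is a single habitat type, so the type-area table
  # has one row per patch
  type_areas <- tibble::tibble(
    patch_id = landscape$patches$patch_id,
    habitat_type = landscape$patches$habitat_type,
    area = metrics$area
  )
  veg <- veg_structure_table(plots, type_areas)

  slope <- vapply(
    landscape$patches$polygon,
    function(poly) dem_slope(landscape$dem, poly),
    numeric(1)
  )

  site <- metrics |>
    dplyr::left_join(veg, by = "patch_id") |>
    dplyr::mutate(
      slope = slope,
      radiation = 5200 - 18 * slope + stats::rnorm(dplyr::n(), 0, 40)
    )

  day1 <- sample(110:170, nrow(site), replace = TRUE)
  surveys <- tidyr::expand_grid(
    patch_id = site$patch_id,
    survey = seq_len(config$n_surveys)
  ) |>
    dplyr::arrange(.data$survey, .data$patch_id) |>
    dplyr::mutate(day = rep(day1, config$n_surveys) +
      rep(seq_len(config$n_surveys) - 1L, each = nrow(site)))

  list(site = site, surveys = surveys, plots = plots)
}

#' Simulate detection histories with known truth
#'
#' Occupancy and detection follow logit-linear models on z-scored
#' covariates: `logit(psi_i) = b0 + sum_k b_k x_ik` with the configured
#' occupancy covariates (composition covariates taken at the true scale of
#' effect), and `logit(p_ij) = a0 + a_veg veg_str_i + a_day day_ij +
#' a_area area_i`. Latent occupancy `z_i ~ Bernoulli(psi_i)` and
#' observations `y_ij ~ Bernoulli(z_i p_ij)`.
#'
#' @param covariates output of [simulate_covariates()].
#' @param config the [sim_config()].
#' @return List with `detections` (tibble: `patch_id`, `y_1..y_J`,
#'   `day_1..day_J`, and all site covariates) and `truth` (tibble:
#'   `patch_id`, `psi_true`, `p_true_1..J`, `z`).
#' @export
simulate_detections <- function(covariates, config) {
  set.seed(config$seed + 2L)
  site <- covariates$site
  n <- nrow(site)
  J <- config$n_surveys

  psi_cols <- resolve_composition_names(config$psi_covariates, config$true_scale_m)
  missing <- setdiff(psi_cols, names(site))
  if (length(missing) > 0) {
    stop("occupancy covariate(s) absent from site table: ", paste(missing, collapse = ", "))
  }
  X <- apply(as.matrix(site[psi_cols]), 2, zscore)
  X <- matrix(X, nrow = n)
  eta_psi <- config$true_psi_coefs[1] + drop(X %*% config$true_psi_coefs[-1])

  day_wide <- covariates$surveys |>
    tidyr::pivot_wider(
      id_cols = "patch_id", names_from = "survey",
      values_from = "day", names_prefix = "day_"
    )
  day_mat <- as.matrix(day_wide[paste0("day_", seq_len(J))])
  day_z <- matrix(zscore(as.vector(day_mat)), n, J)
  veg_z <- zscore(site$veg_str)
  area_z <- zscore(site$area)
  a <- config$true_p_coefs
  eta_p <- a[1] + a[2] * veg_z + a[3] * day_z + a[4] * area_z # n x J

  if (any(!is.finite(eta_psi)) || any(!is.finite(eta_p))) {
    stop("non-finite linear predictor in detection simulation")
  }
  psi <- stats::plogis(eta_psi)
  p <- stats::plogis(eta_p)
  z <- stats::rbinom(n, 1, psi)
  y <- matrix(stats::rbinom(n * J, 1, rep(z, J) * as.vector(p)), n, J)

  detections <- dplyr::bind_cols(
    tibble::tibble(patch_id = site$patch_id),
    stats::setNames(as.data.frame(y), paste0("y_", seq_len(J))),
    stats::setNames(as.data.frame(day_mat), paste0("day_", seq_len(J))),
    site[setdiff(names(site), "patch_id")]
  )
  truth <- dplyr::bind_cols(
    tibble::tibble(patch_id = site$patch_id, psi_true = psi, z = z),
    stats::setNames(as.data.frame(p), paste0("p_true_", seq_len(J)))
  )
  list(detections = detections, truth = truth)
}

# z-score that degrades gracefully for constant (or single-value) columns
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

resolve_composition_names <- function(vars, scale) {
  ifelse(
    vars %in% c("habitat", "crop_pas", "urban", "prox"),
    paste0(vars, "_", scale),
    vars
  )
}

#' One-call synthetic region
#'
#' Runs [generate_landscape()], [simulate_covariates()] and
#' [simulate_detections()] for one configuration.
#'
#' @param config a [sim_config()].
#' @return List: `landscape`, `covariates`, `detections`, `truth`.
#' @export
simulate_region <- function(config = sim_config()) {
  landscape <- generate_landscape(config)
  covariates <- simulate_covariates(landscape, config)
  det <- simulate_detections(covariates, config)
  list(
    landscape = landscape, covariates = covariates,
    detections = det$detections, truth = det$truth
  )
}

#' Fast tabular occupancy simulator
#'
#' Generates detection data straight from the model, without rasters:
#' covariates named in `psi_coefs`/`p_coefs` are drawn iid standard normal
#' per site (a `day` detection covariate is drawn per site x survey).
#' Useful for estimator calibration at large n.
#'
#' @param n_sites number of sites.
#' @param n_surveys surveys per site.
#' @param psi_coefs named logit-scale coefficients; first element must be
#'   the intercept `(Intercept)`.
#' @param p_coefs named logit-scale detection coefficients, same convention.
#' @param seed integer seed.
#' @return List with `data` (tibble ready for [fit_occupancy()]) and
#'   `truth` (psi, p, z per site).
#' @export
simulate_occupancy_data <- function(n_sites, n_surveys = 2,
                                    psi_coefs = c("(Intercept)" = 0, x = 1),
                                    p_coefs = c("(Intercept)" = stats::qlogis(0.6)),
                                    seed = 1) {
  set.seed(seed)
  psi_vars <- setdiff(names(psi_coefs), "(Intercept)")
  p_vars <- setdiff(names(p_coefs), "(Intercept)")
  site_vars <- unique(c(psi_vars, setdiff(p_vars, "day")))
  Xs <- matrix(stats::rnorm(n_sites * length(site_vars)), n_sites,
    dimnames = list(NULL, site_vars)
  )
  eta_psi <- psi_coefs[["(Intercept)"]] +
    if (length(psi_vars)) drop(Xs[, psi_vars, drop = FALSE] %*% psi_coefs[psi_vars]) else 0
  eta_p <- matrix(p_coefs[["(Intercept)"]], n_sites, n_surveys)
  day <- NULL
  if ("day" %in% p_vars) {
    day <- matrix(stats::rnorm(n_sites * n_surveys), n_sites, n_surveys)
    eta_p <- eta_p + p_coefs[["day"]] * day
  }
  for (v in setdiff(p_vars, "day")) eta_p <- eta_p + p_coefs[[v]] * Xs[, v]
  psi <- stats::plogis(eta_psi)
  p <- stats::plogis(eta_p)
  z <- stats::rbinom(n_sites, 1, psi)
  y <- matrix(stats::rbinom(n_sites * n_surveys, 1, rep(z, n_surveys) * as.vector(p)),
    n_sites, n_surveys
  )
  data <- dplyr::bind_cols(
    tibble::tibble(patch_id = seq_len(n_sites)),
    stats::setNames(as.data.frame(y), paste0("y_", seq_len(n_surveys))),
    tibble::as_tibble(as.data.frame(Xs))
  )
  if (!is.null(day)) {
    data <- dplyr::bind_cols(
      data,
      stats::setNames(as.data.frame(day), paste0("day_", seq_len(n_surveys)))
    )
  }
  list(
    data = data,
    truth = dplyr::bind_cols(
      tibble::tibble(patch_id = seq_len(n_sites), psi_true = psi, z = z),
      stats::setNames(as.data.frame(p), paste0("p_true_", seq_len(n_surveys)))
    )
  )
}

#' Multi-scale covariate simulator with a known scale of effect
#'
#' Emulates nested buffer composition without rasters: per site, each
#' annulus between consecutive scales gets an iid standard-normal value,
#' and the covariate at scale `s` is the annulus-area-weighted cumulative
#' mean up to `s` — so neighbouring scales are correlated the way nested
#' buffers are. Occupancy responds to the covariate at `true_scale` only;
#' detection uses vegetation structure, day of survey and patch area with
#' the supplied coefficients.
#'
#' @param n_sites number of sites.
#' @param scales buffer scale set (m).
#' @param true_scale the scale (m) whose covariate drives occupancy.
#' @param beta0,beta1 occupancy intercept and slope (logit scale; the
#'   covariate is z-scored before use).
#' @param p_coefs detection coefficients (intercept, veg_str, day, area).
#' @param variable name stem for the per-scale columns.
#' @param n_surveys surveys per site.
#' @param seed integer seed.
#' @return List with `data` (tibble with `<variable>_<scale>` columns,
#'   `veg_str`, `area`, `day_*`, `y_*`) and `truth`.
#' @export
simulate_scale_data <- function(n_sites, scales = default_scales(),
                                true_scale = 250, beta0 = 0, beta1 = 1.5,
                                p_coefs = c(0.5, -0.3, 0.3, 0.2),
                                variable = "habitat", n_surveys = 2, seed = 1) {
  stopifnot(true_scale %in% scales)
  set.seed(seed)
  K <- length(scales)
  ring_area <- diff(c(0, scales^2)) # proportional annulus areas
  rings <- matrix(stats::rnorm(n_sites * K), n_sites, K)
  cum_w <- cumsum(ring_area)
  covs <- sapply(seq_len(K), function(k) {
    drop(rings[, seq_len(k), drop = FALSE] %*% ring_area[seq_len(k)]) / cum_w[k]
  })
  colnames(covs) <- paste0(variable, "_", scales)
  x_true <- drop(scale(covs[, paste0(variable, "_", true_scale)]))
  veg <- stats::rnorm(n_sites)
  area <- stats::rnorm(n_sites)
  day <- matrix(stats::rnorm(n_sites * n_surveys), n_sites, n_surveys)
  psi <- stats::plogis(beta0 + beta1 * x_true)
  eta_p <- p_coefs[1] + p_coefs[2] * veg + p_coefs[3] * day + p_coefs[4] * area
  p <- stats::plogis(eta_p)
  z <- stats::rbinom(n_sites, 1, psi)
  y <- matrix(stats::rbinom(n_sites * n_surveys, 1, rep(z, n_surveys) * as.vector(p)),
    n_sites, n_surveys
  )
  data <- dplyr::bind_cols(
    tibble::tibble(patch_id = seq_len(n_sites)),
    stats::setNames(as.data.frame(y), paste0("y_", seq_len(n_surveys))),
    tibble::as_tibble(as.data.frame(covs)),
    tibble::tibble(veg_str = veg, area = area),
    stats::setNames(as.data.frame(day), paste0("day_", seq_len(n_surveys)))
  )
  list(
    data = data,
    truth = dplyr::bind_cols(
      tibble::tibble(patch_id = seq_len(n_sites), psi_true = psi, z = z),
      stats::setNames(as.data.frame(p), paste0("p_true_", seq_len(n_surveys)))
    )
  )
}

#' Write / read all synthetic-region artifacts
#'
#' Writes the land cover and DEM as ESRI ASCII grids, patches and river as
#' GeoJSON, covariate/detection/truth tables as CSV, and a YAML echo of the
#' configuration for provenance.
#'
#' @param region output of [simulate_region()].
#' @param dir output directory (created if needed).
#' @return `write_region` returns `dir` invisibly; `read_region_tables`
#'   returns the tables read back (`site`, `surveys`, `detections`,
#'   `truth`, `patches`, `land_cover`, `dem`, `river`).
#' @export
write_region <- function(region, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_esri_ascii(region$landscape$land_cover, file.path(dir, "land_cover.asc"))
  write_esri_ascii(region$landscape$dem, file.path(dir, "dem.asc"))
  write_patches_geojson(
    region$landscape$patches[c("patch_id", "habitat_type", "polygon")],
    file.path(dir, "patches.geojson")
  )
  if (!is.null(region$landscape$river)) {
    write_line_geojson(region$landscape$river, file.path(dir, "river.geojson"))
  }
  utils::write.csv(region$covariates$site, file.path(dir, "site_covariates.csv"),
    row.names = FALSE
  )
  utils::write.csv(region$covariates$surveys, file.path(dir, "survey_covariates.csv"),
    row.names = FALSE
  )
  utils::write.csv(region$detections, file.path(dir, "detections.csv"),
    row.names = FALSE
  )
  utils::write.csv(region$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  cfg <- region$landscape$config
  cfg$class_table <- as.data.frame(cfg$class_table)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_region
#' @export
read_region_tables <- function(dir) {
  read1 <- function(f) tibble::as_tibble(utils::read.csv(file.path(dir, f)))
  river_path <- file.path(dir, "river.geojson")
  list(
    site = read1("site_covariates.csv"),
    surveys = read1("survey_covariates.csv"),
    detections = read1("detections.csv"),
    truth = read1("truth.csv"),
    patches = read_patches_geojson(file.path(dir, "patches.geojson")),
    land_cover = read_esri_ascii(file.path(dir, "land_cover.asc")),
    dem = read_esri_ascii(file.path(dir, "dem.asc")),
    river = if (file.exists(river_path)) read_line_geojson(river_path) else NULL
  )
}
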