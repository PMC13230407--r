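#' Moment-matched lognormal parameters
#'
#' Returns the (meanlog, sdlog) pair whose lognormal has the requested
#' arithmetic mean and standard deviation. Used to calibrate the synthetic
#' wood-production field to the observed FAWS-wide moments
#' (mean 1.78, SD 1.73 m3/ha/yr).
#'
#' @param mean,sd Target arithmetic mean and SD (same units).
#' @return Named numeric vector `c(meanlog, sdlog)`.
#' @export
calibrate_lognormal <- function(mean = 1.78, sd = 1.73) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(c(meanlog = log(mean), sdlog = 0))
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Synthetic-scene configuration
#'
#' Parameters of the seeded synthetic landscape generator. The defaults
#' reproduce the statistical structure of the real inputs: an 87/13
#' FAWS/FNAWS split, sparse primary forest (4.4% of forest cells), protected
#' areas of all seven IUCN categories (strict categories nested inside the
#' primary/strict archetype, multi-use categories covering the
#' other-protected archetype and spilling into the wood-production
#' archetypes), and a strongly right-skewed wood-production field calibrated
#' to mean 1.78 and SD 1.73 m3/ha/yr. Class fractions for the passive
#' archetypes and the within-FAWS intensity split default to the published
#' continental shares.
#'
#' @param grid_rows,grid_cols Grid dimensions (>= 10).
#' @param cell_size_m Cell size, m (100 m cells are 1 ha).
#' @param origin_x,origin_y Upper-left corner, m, in the equal-area CRS.
#' @param crs_id CRS identifier.
#' @param forest_fraction Fraction of the grid that is forest.
#' @param faws_fraction Fraction of forest available for wood supply.
#' @param primary_fraction Fraction of forest that is primary / strictly
#'   protected (archetype A).
#' @param b_fraction,c_fraction Forest fractions of the other-protected (B)
#'   and unprotected-FNAWS (C) archetypes.
#' @param dg_weights Relative weights of archetypes D-G within the remaining
#'   FAWS mass.
#' @param protection_fractions Named fractions of forest per IUCN category
#'   Ia..VI; Ia+Ib+II must fit inside `primary_fraction`, III+..+VI must
#'   cover at least `b_fraction`.
#' @param wp_log_mean,wp_log_sd Lognormal parameters of the wood-production
#'   field (defaults moment-matched to mean 1.78 / SD 1.73).
#' @param n_regions Number of biogeographical regions (>= 2); the first two
#'   form the split Alpine pair.
#' @param n_countries Number of country zones.
#' @param blob_scale_cells Spatial-correlation scale (cells) of the smoothed
#'   noise fields that shape all categorical blobs.
#' @param point_share Share of primary-forest features emitted as point
#'   features (proportional circles) rather than polygons.
#' @param point_missing_share Share of point features with a missing
#'   patch-area attribute (imputed at rasterization).
#' @param nest_share Share of strict protected components additionally
#'   wrapped in an enclosing category-V polygon (exercises overlap
#'   precedence).
#' @param seed Integer seed; the whole scene is a deterministic function of
#'   the configuration.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(grid_rows = 256, grid_cols = 256,
                            cell_size_m = 100,
                            origin_x = 4e6, origin_y = 2.8e6,
                            crs_id = "laea_europe",
                            forest_fraction = 0.55,
                            faws_fraction = 0.87,
                            primary_fraction = 0.044,
                            b_fraction = 0.023,
                            c_fraction = 0.0675,
                            dg_weights = c(D = 0.4198, E = 0.2120,
                                           F = 0.2618, G = 0.1065),
                            protection_fractions = c(Ia = 0.010, Ib = 0.005,
                                                     II = 0.015, III = 0.010,
                                                     IV = 0.020, V = 0.020,
                                                     VI = 0.010),
                            wp_log_mean = NULL, wp_log_sd = NULL,
                            n_regions = 4, n_countries = 6,
                            blob_scale_cells = 12,
                            point_share = 0.10, point_missing_share = 0.25,
                            nest_share = 0.2,
                            seed = 1L) {
  lp <- calibrate_lognormal()
  if (is.null(wp_log_mean)) wp_log_mean <- unname(lp["meanlog"])
  if (is.null(wp_log_sd)) wp_log_sd <- unname(lp["sdlog"])
  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              cell_size_m = cell_size_m, origin_x = origin_x,
              origin_y = origin_y, crs_id = crs_id,
              forest_fraction = forest_fraction,
              faws_fraction = faws_fraction,
              primary_fraction = primary_fraction,
              b_fraction = b_fraction, c_fraction = c_fraction,
              dg_weights = dg_weights / sum(dg_weights),
              protection_fractions = protection_fractions,
              wp_log_mean = wp_log_mean, wp_log_sd = wp_log_sd,
              n_regions = as.integer(n_regions),
              n_countries = as.integer(n_countries),
              blob_scale_cells = blob_scale_cells,
              point_share = point_share,
              point_missing_share = point_missing_share,
              nest_share = nest_share, seed = as.integer(seed))
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  fr <- c(cfg$forest_fraction, cfg$faws_fraction, cfg$primary_fraction,
          cfg$b_fraction, cfg$c_fraction, cfg$protection_fractions,
          cfg$point_share, cfg$point_missing_share, cfg$nest_share)
  if (any(fr < 0 | fr > 1))
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  if (sum(cfg$protection_fractions) > 1)
    stop("protection fractions sum to more than 1", call. = FALSE)
  if (cfg$grid_rows < 10 || cfg$grid_cols < 10)
    stop("grid must be at least 10 x 10", call. = FALSE)
  if (cfg$cell_size_m <= 0) stop("cell_size_m must be > 0", call. = FALSE)
  if (cfg$primary_fraction + cfg$b_fraction + cfg$c_fraction >= 1)
    stop("archetype fractions A+B+C must leave room for D-G", call. = FALSE)
  strict <- sum(cfg$protection_fractions[STRICT_CATEGORIES])
  if (strict > cfg$primary_fraction + 1e-9)
    stop("strict protection (Ia+Ib+II) cannot exceed primary_fraction",
         call. = FALSE)
  multi <- sum(cfg$protection_fractions[setdiff(names(cfg$protection_fractions),
                                                STRICT_CATEGORIES)])
  if (multi < cfg$b_fraction - 1e-9)
    stop("multi-use protection (III-VI) must cover at least b_fraction",
         call. = FALSE)
  if (cfg$wp_log_sd < 0)
    stop("wp_log_sd must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Sample the calibrated wood-production distribution
#'
#' I.i.d. draws from the scene's lognormal wood-production model; all values
#' strictly positive (degenerate at `exp(wp_log_mean)` when `wp_log_sd` is 0).
#'
#' @param config A [scenario_config()].
#' @param n Number of draws (>= 1).
#' @return Numeric vector of length `n`, m3/ha/yr.
#' @export
sample_wood_production <- function(config, n) {
  stopifnot(inherits(config, "scenario_config"), n >= 1)
  if (config$wp_log_sd < 0) stop("wp_log_sd must be >= 0", call. = FALSE)
  stats::rlnorm(n, config$wp_log_mean, config$wp_log_sd)
}

# spatially correlated standard field: white noise smoothed with a separable
# gaussian kernel (circular edges), then rescaled to zero mean / unit sd
gaussian_field <- function(n_rows, n_cols, scale) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (scale > 0) {
    half <- max(1L, ceiling(3 * scale))
    k <- stats::dnorm(seq(-half, half), sd = scale)
    k <- k / sum(k)
    z <- stats::filter(z, k, circular = TRUE)        # columns
    z <- t(stats::filter(t(z), k, circular = TRUE))  # rows
    z <- matrix(as.numeric(z), n_rows, n_cols)
  }
  (z - mean(z)) / stats::sd(z)
}

# run-length decomposition of a cell set into axis-aligned rectangles; one
# ring per maximal horizontal run, exact under cell-centre coverage
runs_to_rings <- function(cells_rc, grid) {
  s <- grid$cell_size_m
  rings <- list()
  for (r in unique(cells_rc[, 1])) {
    cs <- sort(cells_rc[cells_rc[, 1] == r, 2])
    brk <- c(0, which(diff(cs) > 1), length(cs))
    for (j in seq_len(length(brk) - 1)) {
      c1 <- cs[brk[j] + 1]; c2 <- cs[brk[j + 1]]
      x1 <- grid$origin_x + (c1 - 1) * s; x2 <- grid$origin_x + c2 * s
      y1 <- grid$origin_y - r * s; y2 <- grid$origin_y - (r - 1) * s
      rings[[length(rings) + 1]] <-
        cbind(x = c(x1, x2, x2, x1), y = c(y1, y1, y2, y2))
    }
  }
  rings
}

voronoi_zones <- function(grid, n_zones, names) {
  ctr_r <- sample(seq_len(grid$n_rows), n_zones, replace = TRUE)
  ctr_c <- sample(seq_len(grid$n_cols), n_zones, replace = TRUE)
  rows <- row(matrix(0, grid$n_rows, grid$n_cols))
  cols <- col(matrix(0, grid$n_rows, grid$n_cols))
  best <- matrix(1L, grid$n_rows, grid$n_cols)
  bestd <- (rows - ctr_r[1])^2 + (cols - ctr_c[1])^2
  for (z in seq_len(n_zones)[-1]) {
    d <- (rows - ctr_r[z])^2 + (cols - ctr_c[z])^2
    upd <- d < bestd
    best[upd] <- z; bestd[upd] <- d[upd]
  }
  matrix(names[best], grid$n_rows, grid$n_cols)
}

#' Region raster
#' @param grid A [grid_spec()].
#' @param region_id Character matrix of region ids on `grid`.
#' @param alpine_pair The two ids forming the split Alpine zone (or NULL).
#' @return A `region_raster` object.
#' @export
region_raster <- function(grid, region_id, alpine_pair = NULL) {
  stopifnot(all(dim(region_id) == c(grid$n_rows, grid$n_cols)))
  structure(list(grid = grid, region_id = region_id,
                 alpine_pair = alpine_pair),
            class = "region_raster")
}

#' Generate a synthetic scene with known ground truth
#'
#' Builds a seeded synthetic landscape with the statistical structure the
#' archetype analysis assumes. Spatial structure comes from smoothed
#' white-noise fields thresholded at quantiles (a neutral-landscape model), so
#' classes form blobs rather than salt-and-pepper. Class labels are drawn
#' first at the configured fractions; layers (FAWS flag, primary forest,
#' protection categories, banded wood production) are then constructed to be
#' consistent with them. Primary forest and protection are emitted as vector
#' features (polygons, plus a share of proportional-circle points for primary
#' forest) and re-rasterized through [rasterize_primary()] /
#' [rasterize_protection()], so the raster layers are exactly the
#' rasterization of the vector inputs. The stored ground truth is finally
#' derived from the assembled layers by the generator's own coding of the
#' decision rules, so every forest cell's truth label is consistent with its
#' layer values by construction.
#'
#' @param config A [scenario_config()].
#' @return A `synthetic_scene`: list with `layers` (a
#'   [layer_stack][assemble_stack()]), `truth` (an `archetype_raster`),
#'   `regions` and `countries` ([region_raster()]s), `features` (list of
#'   `primary` and `protection` feature tibbles) and `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  grid <- grid_spec(config$origin_x, config$origin_y, config$cell_size_m,
                    config$grid_rows, config$grid_cols, config$crs_id)
  nr <- grid$n_rows; nc <- grid$n_cols

  # forest mask and provisional archetype blobs
  f_forest <- gaussian_field(nr, nc, config$blob_scale_cells)
  forest <- f_forest <= stats::quantile(f_forest, config$forest_fraction)
  n_forest <- sum(forest)

  frac <- c(A = config$primary_fraction, B = config$b_fraction,
            C = config$c_fraction,
            (1 - config$primary_fraction - config$b_fraction -
               config$c_fraction) * config$dg_weights)
  f_label <- gaussian_field(nr, nc, config$blob_scale_cells)
  prov <- matrix(NA_character_, nr, nc)
  fidx <- which(forest)
  ord <- fidx[order(f_label[fidx])]
  sizes <- diff(round(cumsum(c(0, frac)) * n_forest))
  prov[ord] <- rep(ARCHETYPES, times = sizes)

  # strict protection nested in the A blob; a share of strict cells is
  # strict-only (not primary) so both A rule paths occur
  strict_fr <- config$protection_fractions[STRICT_CATEGORIES]
  a_idx <- fidx[prov[fidx] == "A"]
  f_sub <- gaussian_field(nr, nc, max(2, config$blob_scale_cells / 2))
  a_ord <- a_idx[order(f_sub[a_idx])]
  n_strict <- round(sum(strict_fr) * n_forest)
  strict_cells <- a_ord[seq_len(min(n_strict, length(a_ord)))]
  strict_cat <- rep(STRICT_CATEGORIES,
                    times = diff(round(cumsum(c(0, strict_fr / sum(strict_fr))) *
                                         length(strict_cells))))
  strict_only <- strict_cells[seq_len(round(0.25 * length(strict_cells)))]
  primary <- matrix(FALSE, nr, nc)
  primary[setdiff(a_idx, strict_only)] <- TRUE

  # multi-use protection: all of B, plus a blobby spill-over into D-G
  multi_cats <- setdiff(PROTECTION_LEVELS, STRICT_CATEGORIES)
  multi_fr <- config$protection_fractions[multi_cats]
  b_idx <- fidx[prov[fidx] == "B"]
  n_multi <- round(sum(multi_fr) * n_forest)
  dg_idx <- fidx[prov[fidx] %in% c("D", "E", "F", "G")]
  spill <- max(0L, n_multi - length(b_idx))
  dg_ord <- dg_idx[order(f_sub[dg_idx])]
  multi_cells <- c(b_idx, dg_ord[seq_len(min(spill, length(dg_ord)))])
  multi_cat <- rep(multi_cats,
                   times = diff(round(cumsum(c(0, multi_fr / sum(multi_fr))) *
                                        length(multi_cells))))

  # vector features: primary patches (some as proportional-circle points),
  # protection polygons as exact run-rectangles, some strict components
  # wrapped in an enclosing category-V polygon
  prim_features <- build_primary_features(primary, grid, config)
  prot_features <- build_protection_features(strict_cells, strict_cat,
                                             multi_cells, multi_cat,
                                             grid, config)

  # zones
  region_names <- c("alpine_scandinavian", "alpine_south",
                    paste0("region_", seq_len(max(0, config$n_regions - 2))))
  regions <- region_raster(grid,
                           voronoi_zones(grid, config$n_regions, region_names),
                           alpine_pair = region_names[1:2])
  countries <- region_raster(grid,
                             voronoi_zones(grid, config$n_countries,
                                           paste0("country_",
                                                  seq_len(config$n_countries))))

  # rasterize features back through the layers module
  primary_final <- rasterize_primary(prim_features, grid, regions$region_id)
  protection_final <- rasterize_protection(prot_features, grid)

  # FAWS flag: all provisional D-G cells, topped up from final-A cells
  faws <- matrix(FALSE, nr, nc)
  faws[dg_idx] <- TRUE
  strict_final <- matrix(protection_final %in% STRICT_CATEGORIES, nr, nc)
  a_final <- (primary_final | strict_final) & forest
  deficit <- round(config$faws_fraction * n_forest) - sum(faws & forest)
  if (deficit > 0) {
    pool <- which(a_final & !faws)
    faws[sample(pool, min(deficit, length(pool)))] <- TRUE
  }

  # banded wood production on FAWS cells
  wp <- matrix(NA_real_, nr, nc)
  bands <- list(D = c(0, 1), E = c(1, 2), F = c(2, 4), G = c(4, Inf))
  for (lab in names(bands)) {
    cells <- intersect(which(faws & forest), fidx[prov[fidx] == lab])
    cells <- setdiff(cells, which(a_final))
    if (length(cells))
      wp[cells] <- rlnorm_band(length(cells), config, bands[[lab]])
  }
  rest <- which(faws & forest & is.na(wp))  # FAWS cells ending up in A
  if (length(rest))
    wp[rest] <- stats::rlnorm(length(rest), config$wp_log_mean, config$wp_log_sd)

  layers <- assemble_stack(forest, faws, primary_final, protection_final,
                           wp, grid)

  # ground truth from the generator's own coding of the decision rules
  truth <- matrix(NA_character_, nr, nc)
  on <- which(layers$forest)
  p <- layers$protection[on]
  is_strict <- p %in% STRICT_CATEGORIES
  is_multi <- p %in% multi_cats
  av <- layers$faws[on]; pr <- layers$primary[on]; w <- layers$wood_production[on]
  lab <- rep(NA_character_, length(on))
  lab[av & !is.na(w) & w > 4] <- "G"
  lab[av & !is.na(w) & w <= 4] <- "F"
  lab[av & !is.na(w) & w < 2] <- "E"
  lab[av & !is.na(w) & w < 1] <- "D"
  lab[!av] <- "C"
  lab[!av & is_multi] <- "B"
  lab[pr | is_strict] <- "A"
  truth[on] <- lab
  truth_raster <- structure(list(labels = truth, grid = grid,
                                 n_unclassified = sum(is.na(lab))),
                            class = "archetype_raster")

  structure(list(layers = layers, truth = truth_raster, regions = regions,
                 countries = countries,
                 features = list(primary = prim_features,
                                 protection = prot_features),
                 config = config),
            class = "synthetic_scene")
}

# truncated lognormal draw via inverse CDF on the band's probability slice
rlnorm_band <- function(n, config, band) {
  plo <- stats::plnorm(band[1], config$wp_log_mean, config$wp_log_sd)
  phi <- stats::plnorm(band[2], config$wp_log_mean, config$wp_log_sd)
  stats::qlnorm(stats::runif(n, plo, phi), config$wp_log_mean, config$wp_log_sd)
}

build_primary_features <- function(primary, grid, config) {
  lab <- matrix(NA_character_, nrow(primary), ncol(primary))
  lab[primary] <- "P"
  comp <- label_components(lab)
  on <- which(!is.na(comp))
  by_id <- split(on, comp[on])
  geom <- list(); fid <- integer(); typ <- character(); pa <- numeric()
  has_attributed <- FALSE
  for (id in as.integer(names(by_id))) {
    cells <- by_id[[as.character(id)]]
    rc <- cbind(((cells - 1L) %% grid$n_rows) + 1L,
                ((cells - 1L) %/% grid$n_rows) + 1L)
    area <- length(cells) * cell_area_ha(grid)
    if (stats::runif(1) < config$point_share) {
      ctr <- c(grid$origin_x + (mean(rc[, 2]) - 0.5) * grid$cell_size_m,
               grid$origin_y - (mean(rc[, 1]) - 0.5) * grid$cell_size_m)
      # the attribute can only go missing once an attributed point exists
      # somewhere, so imputation always has a basis
      if (stats::runif(1) < config$point_missing_share && has_attributed)
        area <- NA_real_
      else has_attributed <- TRUE
      geom[[length(geom) + 1]] <- ctr
      fid <- c(fid, id); typ <- c(typ, "point"); pa <- c(pa, area)
    } else {
      for (ring in runs_to_rings(rc, grid)) {
        geom[[length(geom) + 1]] <- ring
        fid <- c(fid, id); typ <- c(typ, "polygon"); pa <- c(pa, area)
      }
    }
  }
  tibble::tibble(feature_id = fid, type = typ, geometry = geom,
                 patch_area_ha = pa)
}

build_protection_features <- function(strict_cells, strict_cat,
                                      multi_cells, multi_cat, grid, config) {
  geom <- list(); cat_out <- character()
  emit <- function(cells, category) {
    lab <- matrix(NA_character_, grid$n_rows, grid$n_cols)
    lab[cells] <- "x"
    comp <- label_components(lab)
    on <- which(!is.na(comp))
    by_id <- split(on, comp[on])
    for (sub in by_id) {
      src <- cbind(((sub - 1L) %% grid$n_rows) + 1L,
                   ((sub - 1L) %/% grid$n_rows) + 1L)
      for (ring in runs_to_rings(src, grid)) {
        geom[[length(geom) + 1]] <<- ring
        cat_out <<- c(cat_out, category)
      }
      # occasionally wrap a strict component in an enclosing multi-use
      # polygon (one-cell plus-shaped dilation) to exercise nested
      # designations and the most-protective precedence
      if (category %in% STRICT_CATEGORIES &&
          stats::runif(1) < config$nest_share) {
        dil <- rbind(src,
                     cbind(pmin(pmax(src[, 1] + 1L, 1L), grid$n_rows), src[, 2]),
                     cbind(pmin(pmax(src[, 1] - 1L, 1L), grid$n_rows), src[, 2]),
                     cbind(src[, 1], pmin(pmax(src[, 2] + 1L, 1L), grid$n_cols)),
                     cbind(src[, 1], pmin(pmax(src[, 2] - 1L, 1L), grid$n_cols)))
        dil <- unique(dil)
        for (ring in runs_to_rings(dil, grid)) {
          geom[[length(geom) + 1]] <<- ring
          cat_out <<- c(cat_out, "V")
        }
      }
    }
  }
  for (cat in unique(strict_cat))
    emit(strict_cells[strict_cat == cat], cat)
  for (cat in unique(multi_cat))
    emit(multi_cells[multi_cat == cat], cat)
  tibble::tibble(category = cat_out, geometry = geom)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> seed %d\n", x$config$seed))
  print(x$layers)
  print(x$truth)
  invisible(x)
}

#' Write a synthetic scene to disk
#'
#' Layers as ASCII grids, the truth and zone rasters likewise, vector
#' features as GeoJSON and the configuration as YAML.
#'
#' @param scene A `synthetic_scene`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_stack(scene$layers, file.path(dir, "stack"))
  write_archetypes(scene$truth, file.path(dir, "truth.asc"))
  rn <- sort(unique(as.vector(scene$regions$region_id)))
  write_ascii_grid(scene$regions$region_id, scene$regions$grid,
                   file.path(dir, "regions.asc"), levels = rn)
  readr::write_csv(tibble::tibble(code = seq_along(rn), region = rn),
                   file.path(dir, "regions.asc.legend.csv"))
  write_features_geojson(scene$features$primary,
                         file.path(dir, "primary_features.geojson"))
  write_features_geojson(scene$features$protection,
                         file.path(dir, "protected_areas.geojson"))
  cfg <- unclass(scene$config)
  cfg$dg_weights <- as.list(cfg$dg_weights)
  cfg$protection_fractions <- as.list(cfg$protection_fractions)
  yaml::write_yaml(cfg, file.path(dir, "scene.yaml"))
  invisible(dir)
}

#' Write features as GeoJSON
#'
#' Minimal GeoJSON writer for the package's feature tibbles (rings become
#' Polygon features, points Point features; remaining columns become
#' properties).
#'
#' @param features A feature tibble with a `geometry` list-column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_geojson <- function(features, path) {
  feats <- purrr::map(seq_len(nrow(features)), function(i) {
    g <- features$geometry[[i]]
    geom <- if (is.matrix(g)) {
      ring <- rbind(g, g[1, , drop = FALSE])
      list(type = "Polygon",
           coordinates = list(purrr::map(seq_len(nrow(ring)),
                                         function(j) as.numeric(ring[j, ]))))
    } else {
      list(type = "Point", coordinates = as.numeric(g))
    }
    props <- as.list(features[i, setdiff(names(features), "geometry")])
    list(type = "Feature", geometry = geom, properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}
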