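#' IUCN protection categories, most protective first
#' @export
PROTECTION_LEVELS <- c("Ia", "Ib", "II", "III", "IV", "V", "VI")

#' Strictly protected categories (strict nature reserve, wilderness area,
#' national park)
#' @export
STRICT_CATEGORIES <- c("Ia", "Ib", "II")

# even-odd ray-casting point-in-polygon; ring is a 2-col (x, y) matrix,
# implicitly closed
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

# indices (row-major over the grid) of cells whose centre a ring covers;
# restricted to the ring's bounding box for speed
cells_covered_by_ring <- function(ring, grid) {
  s <- grid$cell_size_m
  c1 <- max(1L, floor((min(ring[, 1]) - grid$origin_x) / s) + 1L)
  c2 <- min(grid$n_cols, ceiling((max(ring[, 1]) - grid$origin_x) / s))
  r1 <- max(1L, floor((grid$origin_y - max(ring[, 2])) / s) + 1L)
  r2 <- min(grid$n_rows, ceiling((grid$origin_y - min(ring[, 2])) / s))
  if (c2 < c1 || r2 < r1) return(integer(0))
  rows <- rep(r1:r2, each = c2 - c1 + 1L)
  cols <- rep(c1:c2, times = r2 - r1 + 1L)
  cx <- grid$origin_x + (cols - 0.5) * s
  cy <- grid$origin_y - (rows - 0.5) * s
  keep <- point_in_ring(cx, cy, ring)
  (rows[keep] - 1L) * grid$n_cols + cols[keep]
}

cells_covered_by_disc <- function(x0, y0, radius_m, grid) {
  s <- grid$cell_size_m
  c1 <- max(1L, floor((x0 - radius_m - grid$origin_x) / s) + 1L)
  c2 <- min(grid$n_cols, ceiling((x0 + radius_m - grid$origin_x) / s))
  r1 <- max(1L, floor((grid$origin_y - (y0 + radius_m)) / s) + 1L)
  r2 <- min(grid$n_rows, ceiling((grid$origin_y - (y0 - radius_m)) / s))
  if (c2 < c1 || r2 < r1) return(integer(0))
  rows <- rep(r1:r2, each = c2 - c1 + 1L)
  cols <- rep(c1:c2, times = r2 - r1 + 1L)
  cx <- grid$origin_x + (cols - 0.5) * s
  cy <- grid$origin_y - (rows - 0.5) * s
  keep <- (cx - x0)^2 + (cy - y0)^2 <= radius_m^2
  (rows[keep] - 1L) * grid$n_cols + cols[keep]
}

# row-major indices -> matrix (row, col)
rowmajor_to_rc <- function(idx, grid) {
  cbind(row = (idx - 1L) %/% grid$n_cols + 1L,
        col = (idx - 1L) %% grid$n_cols + 1L)
}

#' Rasterize protected-area polygons to a protection-category layer
#'
#' Each cell takes the most protective IUCN category (Ia highest, VI lowest)
#' among the polygons covering its centre; cells covered by no polygon get
#' `"NONE"`. Overlaps — including fully nested designations — therefore
#' resolve conservatively.
#'
#' @param features A tibble with a `category` column (one of Ia, Ib, II, III,
#'   IV, V, VI) and a `geometry` list-column of two-column (x, y) ring
#'   matrices in grid coordinates.
#' @param grid A [grid_spec()].
#' @return A character matrix over `PROTECTION_LEVELS` plus `"NONE"`.
#' @export
rasterize_protection <- function(features, grid) {
  out_rank <- matrix(length(PROTECTION_LEVELS) + 1L, grid$n_rows, grid$n_cols)
  if (!is.null(features) && nrow(features) > 0) {
    bad <- setdiff(unique(features$category), PROTECTION_LEVELS)
    if (length(bad))
      stop("unknown protection category: ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (i in seq_len(nrow(features))) {
      rank <- match(features$category[[i]], PROTECTION_LEVELS)
      idx <- cells_covered_by_ring(features$geometry[[i]], grid)
      if (length(idx)) {
        rc <- rowmajor_to_rc(idx, grid)
        out_rank[rc] <- pmin(out_rank[rc], rank)
      }
    }
  }
  matrix(c(PROTECTION_LEVELS, "NONE")[out_rank], grid$n_rows, grid$n_cols)
}

#' Rasterize primary-forest features (polygons and proportional circles)
#'
#' Polygon features are burned where they cover cell centres. Point features
#' are burned as proportional circles: a point with patch area `a` ha becomes
#' a disc of radius `sqrt(a * 1e4 / pi)` metres. Points lacking the
#' patch-area attribute are imputed with the mean attributed patch area of
#' points in the same region (falling back to the global mean of attributed
#' points when their region has none).
#'
#' @param features A tibble with columns `type` ("polygon" or "point"),
#'   `geometry` (list-column: ring matrix for polygons, length-2 numeric
#'   `c(x, y)` for points) and `patch_area_ha` (NA allowed for points).
#' @param grid A [grid_spec()].
#' @param regions Optional region-id matrix on `grid`, used only for the
#'   imputation of missing point areas.
#' @return A logical matrix: TRUE where primary forest is mapped.
#' @export
rasterize_primary <- function(features, grid, regions = NULL) {
  out <- matrix(FALSE, grid$n_rows, grid$n_cols)
  if (is.null(features) || nrow(features) == 0) return(out)
  is_pt <- features$type == "point"
  areas <- features$patch_area_ha
  if (any(is_pt & is.na(areas))) {
    attributed <- which(is_pt & !is.na(areas))
    if (!length(attributed))
      stop(paste("point features with missing patch area but no",
                 "area-attributed points to impute from"), call. = FALSE)
    pt_region <- rep(NA_character_, nrow(features))
    if (!is.null(regions)) {
      for (i in which(is_pt)) {
        rc <- locate_cells(grid, features$geometry[[i]][1],
                           features$geometry[[i]][2])
        if (!is.na(rc$row[1])) pt_region[i] <- as.character(
          regions[rc$row[1], rc$col[1]])
      }
    }
    global_mean <- mean(areas[attributed])
    for (i in which(is_pt & is.na(areas))) {
      same <- attributed[!is.na(pt_region[attributed]) &
                           pt_region[attributed] == pt_region[i]]
      areas[i] <- if (length(same)) mean(areas[same]) else global_mean
    }
  }
  for (i in seq_len(nrow(features))) {
    idx <- if (is_pt[i]) {
      r <- sqrt(areas[i] * 1e4 / pi)
      cells_covered_by_disc(features$geometry[[i]][1],
                            features$geometry[[i]][2], r, grid)
    } else {
      cells_covered_by_ring(features$geometry[[i]], grid)
    }
    if (length(idx)) out[rowmajor_to_rc(idx, grid)] <- TRUE
  }
  out
}

#' Resample a coarse continuous raster onto a finer grid
#'
#' Nearest-neighbour (containing-cell) assignment: each destination cell takes
#' the value of the source cell its centre falls in. Used to bring the 1 km
#' wood-production layer onto the 100 m analysis grid without inventing
#' sub-cell detail. Missing source values propagate as missing.
#'
#' @param src Source matrix.
#' @param src_grid,dst_grid [grid_spec()]s sharing a CRS.
#' @return A matrix on `dst_grid`.
#' @export
resample_wood_production <- function(src, src_grid, dst_grid) {
  if (!identical(src_grid$crs, dst_grid$crs))
    stop("source and destination grids use different CRSs", call. = FALSE)
  ctr <- cell_centers(dst_grid)
  loc <- locate_cells(src_grid, ctr$x, ctr$y)
  vals <- rep(NA_real_, nrow(ctr))
  ok <- !is.na(loc$row)
  vals[ok] <- src[cbind(loc$row[ok], loc$col[ok])]
  matrix(vals, dst_grid$n_rows, dst_grid$n_cols, byrow = TRUE)
}

#' Assemble the harmonized layer stack
#'
#' Bundles the five per-cell themes on a shared grid and applies the forest
#' mask: outside forest every other layer is set to no-data. FAWS/FNAWS is a
#' logical flag (TRUE = available for wood supply); protection is one of the
#' seven IUCN categories or `"NONE"`; wood production is in m3/ha/yr and may
#' be missing (FAWS cells with missing wood production are later counted as
#' unclassifiable).
#'
#' @param forest Logical matrix: the forest mask.
#' @param faws Logical matrix: TRUE = FAWS, FALSE = FNAWS.
#' @param primary Logical matrix: mapped primary forest.
#' @param protection Character matrix over categories Ia..VI / NONE.
#' @param wood_production Numeric matrix, m3/ha/yr, NA allowed.
#' @param grid The shared [grid_spec()].
#' @return A `layer_stack` object.
#' @export
assemble_stack <- function(forest, faws, primary, protection,
                           wood_production, grid) {
  dims <- c(grid$n_rows, grid$n_cols)
  for (nm in c("forest", "faws", "primary", "protection", "wood_production")) {
    m <- get(nm)
    if (!all(dim(m) == dims))
      stop(nm, " is not on the stack grid", call. = FALSE)
  }
  bad <- setdiff(unique(protection[!is.na(protection)]),
                 c(PROTECTION_LEVELS, "NONE"))
  if (length(bad))
    stop("invalid protection values: ", paste(bad, collapse = ", "),
         call. = FALSE)
  forest[is.na(forest)] <- FALSE
  off <- !forest
  faws[off] <- NA; primary[off] <- NA
  protection[off] <- NA_character_; wood_production[off] <- NA_real_
  if (any(wood_production < 0, na.rm = TRUE))
    stop("negative wood production", call. = FALSE)
  structure(list(grid = grid, forest = forest, faws = faws, primary = primary,
                 protection = protection, wood_production = wood_production),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  nf <- sum(x$forest)
  cat(sprintf("<layer_stack> %d x %d @ %g m; %d forest cells (%.1f%%)\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_size_m, nf,
              100 * nf / length(x$forest)))
  if (nf > 0)
    cat(sprintf("  FAWS %.1f%% | primary %.2f%% | protected %.2f%% | wp defined %.1f%%\n",
                100 * sum(x$faws, na.rm = TRUE) / nf,
                100 * sum(x$primary, na.rm = TRUE) / nf,
                100 * sum(x$protection != "NONE", na.rm = TRUE) / nf,
                100 * sum(!is.na(x$wood_production)) / nf))
  invisible(x)
}

#' Write / read a layer stack as ASCII grids
#'
#' One `.asc` file per layer plus a small YAML sidecar with the CRS id and
#' the categorical encodings; round-trips exactly.
#'
#' @param stack A `layer_stack`.
#' @param dir Directory to write into (created if needed).
#' @return `write_stack()` the directory invisibly; `read_stack()` a
#'   `layer_stack`.
#' @export
write_stack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- stack$grid
  write_ascii_grid(stack$forest, g, file.path(dir, "forest.asc"))
  write_ascii_grid(stack$faws, g, file.path(dir, "faws.asc"))
  write_ascii_grid(stack$primary, g, file.path(dir, "primary.asc"))
  write_ascii_grid(stack$protection, g, file.path(dir, "protection.asc"),
                   levels = c(PROTECTION_LEVELS, "NONE"))
  write_ascii_grid(stack$wood_production, g,
                   file.path(dir, "wood_production.asc"))
  yaml::write_yaml(list(crs = g$crs,
                        protection_levels = c(PROTECTION_LEVELS, "NONE")),
                   file.path(dir, "stack.yaml"))
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "stack.yaml"))
  rd <- function(f, levels = NULL)
    read_ascii_grid(file.path(dir, f), levels = levels, crs = meta$crs)
  forest <- rd("forest.asc")
  assemble_stack(forest$matrix > 0,
                 rd("faws.asc")$matrix > 0,
                 rd("primary.asc")$matrix > 0,
                 rd("protection.asc", levels = meta$protection_levels)$matrix,
                 rd("wood_production.asc")$matrix,
                 forest$grid)
}
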