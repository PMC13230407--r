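# connected components of a categorical matrix under Moore (8-neighbour)
# connectivity: same-label cells joined through any of the eight surrounding
# cells; NA never joins. Returns an integer matrix of component ids numbered
# 1..K in row-major order of first occurrence, NA off-category.
label_components <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  on <- which(!is.na(lab))
  out <- matrix(NA_integer_, nr, nc)
  if (!length(on)) return(out)
  # vertex ids only for on-category cells keeps the graph small
  vid <- integer(nr * nc)
  vid[on] <- seq_along(on)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  edges <- list()
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq.int(1L - dc, nc)
    a <- as.vector(idx[r1, c1, drop = FALSE])
    b <- as.vector(idx[r1 + dr, c1 + dc, drop = FALSE])
    same <- which(!is.na(lab[a]) & !is.na(lab[b]) & lab[a] == lab[b])
    edges[[length(edges) + 1]] <- cbind(vid[a[same]], vid[b[same]])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(on), directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, t(e))
  memb <- as.integer(igraph::components(g)$membership)
  out[on] <- memb
  # renumber in row-major first-occurrence order for determinism
  rm_order <- as.vector(t(out))
  first <- rm_order[!is.na(rm_order)]
  out[on] <- match(memb, unique(first))
  out
}

#' Delineate archetype patches (Moore neighbourhood)
#'
#' Labels contiguous groups of same-archetype cells using the Moore
#' neighbourhood (the eight surrounding grid cells): two cells belong to the
#' same patch iff they carry the same archetype and are connected through a
#' chain of 8-adjacent same-archetype cells. No-data cells never join a
#' patch.
#'
#' @param labels An `archetype_raster`.
#' @return A `patch_components` object: list with `membership` (integer
#'   matrix of patch ids, NA off forest), `labels`, `grid`.
#' @export
label_patches <- function(labels) {
  stopifnot(inherits(labels, "archetype_raster"))
  structure(list(membership = label_components(labels$labels),
                 labels = labels$labels, grid = labels$grid),
            class = "patch_components")
}

#' Build the patch table
#'
#' Tabulates the labeled components into one row per patch, dropping patches
#' of fewer than `min_cells` cells — the published rule keeps contiguous
#' groups of more than two grid cells, i.e. patches greater than 2 ha on the
#' 100 m grid. Each patch gets the region containing the majority of its
#' cells (ties broken toward the region of the patch's first cell in
#' row-major order) and its cell-centre centroid.
#'
#' @param components A `patch_components` from [label_patches()].
#' @param zones Optional [region_raster()] on the same grid.
#' @param min_cells Minimum patch size in cells (default 3).
#' @return A `patch_table` tibble: `patch_id`, `archetype`, `region_id`,
#'   `cell_count`, `area_ha`, `x`, `y`.
#' @export
build_patch_table <- function(components, zones = NULL, min_cells = 3) {
  stopifnot(inherits(components, "patch_components"))
  grid <- components$grid
  memb <- components$membership
  on <- which(!is.na(memb))
  if (!length(on))
    return(structure(tibble::tibble(patch_id = integer(),
                                    archetype = character(),
                                    region_id = character(),
                                    cell_count = integer(),
                                    area_ha = numeric(),
                                    x = numeric(), y = numeric()),
                     class = c("patch_table", class(tibble::tibble()))))
  rows <- ((on - 1L) %% grid$n_rows) + 1L
  cols <- ((on - 1L) %/% grid$n_rows) + 1L
  d <- tibble::tibble(
    patch_id = memb[on],
    archetype = components$labels[on],
    region_id = if (is.null(zones)) NA_character_
    else as.character(zones$region_id[on]),
    row = rows, col = cols,
    rm_index = (rows - 1L) * grid$n_cols + cols,
    x = grid$origin_x + (cols - 0.5) * grid$cell_size_m,
    y = grid$origin_y - (rows - 0.5) * grid$cell_size_m)
  out <- d |>
    dplyr::group_by(.data$patch_id) |>
    dplyr::summarise(
      archetype = .data$archetype[1],
      region_id = majority_region(.data$region_id, .data$rm_index),
      cell_count = dplyr::n(),
      x = mean(.data$x), y = mean(.data$y), .groups = "drop") |>
    dplyr::filter(.data$cell_count >= min_cells) |>
    dplyr::mutate(area_ha = .data$cell_count * cell_area_ha(grid)) |>
    dplyr::select("patch_id", "archetype", "region_id", "cell_count",
                  "area_ha", "x", "y")
  structure(out, class = c("patch_table", class(out)))
}

# majority region of a patch; ties go to the region of the first member cell
# in row-major order
majority_region <- function(region_id, rm_index) {
  if (all(is.na(region_id))) return(NA_character_)
  tab <- table(region_id)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1) return(winners)
  region_id[order(rm_index)][1]
}

#' Mean patch size by region and archetype
#'
#' Arithmetic mean patch area (ha) per (region, archetype) cell plus a
#' study-area-wide row (`region_id = "All"`). Combinations with no patches
#' are absent, not zero.
#'
#' @param patches A `patch_table`.
#' @return An `mps_matrix` tibble: `region_id`, `archetype`, `n_patches`,
#'   `mps_ha`.
#' @export
mps_matrix <- function(patches) {
  stopifnot(nrow(patches) > 0)
  by_region <- patches |>
    dplyr::group_by(.data$region_id, .data$archetype) |>
    dplyr::summarise(n_patches = dplyr::n(), mps_ha = mean(.data$area_ha),
                     .groups = "drop")
  overall <- patches |>
    dplyr::group_by(.data$archetype) |>
    dplyr::summarise(n_patches = dplyr::n(), mps_ha = mean(.data$area_ha),
                     .groups = "drop") |>
    dplyr::mutate(region_id = "All")
  out <- dplyr::bind_rows(by_region, overall) |>
    dplyr::select("region_id", "archetype", "n_patches", "mps_ha")
  structure(out, class = c("mps_matrix", class(out)))
}

#' Iterative resampled Tukey HSD on log patch sizes
#'
#' The stability-oriented significance rule for patch-size differences: in
#' each of `n_iter` iterations, sample `n_sample` patches per archetype
#' without replacement (capped at group size; optionally spatially thinned on
#' patch centroids), run a Tukey HSD on the transformed areas, and record
#' whether each pair falls below `alpha`. A pair is declared significant when
#' that happens in at least `freq_rule` of the iterations (95% of 1000 at the
#' defaults). Archetypes with fewer than two patches are excluded with a
#' warning. Fully seeded: iteration i uses a seed stream derived from
#' `seed + i`.
#'
#' @param patches A `patch_table`.
#' @param n_iter Number of resampling iterations.
#' @param n_sample Patches sampled per archetype per iteration.
#' @param alpha Per-iteration significance level.
#' @param freq_rule Frequency threshold for the overall decision.
#' @param transform Transformation applied to `area_ha` (default `log`).
#' @param min_separation_m Optional spatial thinning distance between sampled
#'   patch centroids within a group (0 = none).
#' @param seed Integer seed.
#' @return An `iterative_tukey_result`: list with `pairs` (tibble `group1`,
#'   `group2`, `frequency`, `significant`), and the run parameters.
#' @export
iterative_tukey <- function(patches, n_iter = 1000, n_sample = 1000,
                            alpha = 0.05, freq_rule = 0.95, transform = log,
                            min_separation_m = 0, seed = 1L) {
  d <- tibble::tibble(group = as.character(patches$archetype),
                      value = transform(patches$area_ha),
                      x = patches$x, y = patches$y)
  sizes <- table(d$group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("archetypes with < 2 patches excluded: ",
            paste(small, collapse = ", "), call. = FALSE)
    d <- d[!d$group %in% small, , drop = FALSE]
  }
  lv <- sort(unique(d$group))
  if (length(lv) < 2) stop("need at least two archetype groups", call. = FALSE)
  by_g <- split(d, d$group)
  pairs <- utils::combn(lv, 2)
  hits <- numeric(ncol(pairs))
  for (it in seq_len(n_iter)) {
    set.seed(seed + it)
    vals <- list()
    for (g in lv) {
      dg <- by_g[[g]]
      ord <- sample.int(nrow(dg))
      keep <- thin_accept(dg$x[ord], dg$y[ord], n_sample, min_separation_m)
      vals[[g]] <- dg$value[ord][keep]
    }
    gs <- group_stats(unlist(vals), rep(lv, lengths(vals)))
    pw <- tukey_pairwise(gs, alpha)
    key <- match(paste(pw$group1, pw$group2),
                 paste(pairs[1, ], pairs[2, ]))
    hits[key] <- hits[key] + (pw$p_adj < alpha)
  }
  freq <- hits / n_iter
  structure(list(pairs = tibble::tibble(group1 = pairs[1, ],
                                        group2 = pairs[2, ],
                                        frequency = freq,
                                        significant = freq >= freq_rule),
                 n_iter = n_iter, n_sample = n_sample, alpha = alpha,
                 freq_rule = freq_rule, seed = seed),
            class = "iterative_tukey_result")
}

#' @export
print.iterative_tukey_result <- function(x, ...) {
  cat(sprintf("<iterative Tukey HSD> %d iterations, %d per group, alpha %g, rule >= %g\n",
              x$n_iter, x$n_sample, x$alpha, x$freq_rule))
  print(x$pairs, n = nrow(x$pairs))
  invisible(x)
}
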