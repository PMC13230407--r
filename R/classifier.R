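#' Archetype labels
#'
#' The seven forest archetypes, ordered from the most natural (A, primary and
#' strictly protected forests) to the most intensively used (G, very
#' high-intensity wood production). Rank 1-7 follows this order; D < E < F < G
#' is the wood-production intensity ordering.
#' @export
ARCHETYPES <- c("A", "B", "C", "D", "E", "F", "G")

#' Wood-production thresholds separating archetypes D-G
#'
#' The intensity bands are `D = [0, t_low)`, `E = [t_low, t_mid)`,
#' `F = [t_mid, t_high]` and `G = (t_high, Inf)`, in m3/ha/yr. The published
#' bands are printed as "< 1", "1-2", "2-4" and "> 4", which leaves the shared
#' endpoints ambiguous; "> 4" strictly read forces 4 into F, and by the same
#' left-closed convention 1 falls in E and 2 in F. The conventions are fixed
#' here and the cut points configurable.
#'
#' @param t_low,t_mid,t_high Band edges, m3/ha/yr; must be strictly increasing
#'   and positive.
#' @return A `threshold_set` object.
#' @export
threshold_set <- function(t_low = 1, t_mid = 2, t_high = 4) {
  if (!(0 < t_low && t_low < t_mid && t_mid < t_high))
    stop("thresholds must satisfy 0 < t_low < t_mid < t_high", call. = FALSE)
  structure(list(t_low = t_low, t_mid = t_mid, t_high = t_high),
            class = "threshold_set")
}

# vectorised band lookup for FAWS cells; NA wp -> NA label
wp_band <- function(wp, thresholds) {
  dplyr::case_when(
    is.na(wp) ~ NA_character_,
    wp < thresholds$t_low ~ "D",
    wp < thresholds$t_mid ~ "E",
    wp <= thresholds$t_high ~ "F",
    TRUE ~ "G")
}

#' Classify forest cells into archetypes A-G
#'
#' Applies the expert decision rules to per-cell attributes, in order:
#' \enumerate{
#'   \item primary forest OR strictly protected (IUCN Ia, Ib, II) -> A,
#'     regardless of FAWS/FNAWS status;
#'   \item otherwise FNAWS with protection III-VI -> B;
#'   \item otherwise FNAWS -> C;
#'   \item otherwise (FAWS) by wood-production band: D below `t_low`, E in
#'     `[t_low, t_mid)`, F in `[t_mid, t_high]`, G above `t_high`.
#' }
#' Protection categories III-VI never shield a FAWS cell from the intensity
#' path. FAWS cells with missing wood production return NA ("unclassifiable");
#' the caller decides whether to drop or flag them.
#'
#' `classify_cells()` is the vectorised work-horse; [classify_raster()] wraps
#' it over a [layer_stack][assemble_stack()].
#'
#' @param faws Logical: available for wood supply?
#' @param primary Logical: mapped primary forest?
#' @param protection Character: IUCN category Ia..VI or "NONE".
#' @param wood_production Numeric, m3/ha/yr (NA allowed).
#' @param thresholds A [threshold_set()].
#' @return Character vector of labels A-G (NA = unclassifiable FAWS cell).
#' @export
classify_cells <- function(faws, primary, protection, wood_production,
                           thresholds = threshold_set()) {
  strict <- protection %in% STRICT_CATEGORIES
  multi <- protection %in% setdiff(PROTECTION_LEVELS, STRICT_CATEGORIES)
  out <- rep(NA_character_, length(faws))
  a <- (primary %in% TRUE) | strict
  out[a] <- "A"
  b <- !a & !(faws %in% TRUE) & multi
  out[b] <- "B"
  cc <- !a & !b & !(faws %in% TRUE)
  out[cc] <- "C"
  d <- !a & (faws %in% TRUE)
  out[d] <- wp_band(wood_production[d], thresholds)
  out
}

#' Classify a layer stack into an archetype raster
#'
#' @param stack A [layer_stack][assemble_stack()].
#' @param thresholds A [threshold_set()].
#' @return An `archetype_raster`: list with `labels` (character matrix A-G,
#'   NA off forest), `grid`, and `n_unclassified` (forest FAWS cells dropped
#'   for missing wood production).
#' @export
classify_raster <- function(stack, thresholds = threshold_set()) {
  stopifnot(inherits(stack, "layer_stack"))
  f <- as.vector(stack$forest)
  lab <- rep(NA_character_, length(f))
  lab[f] <- classify_cells(as.vector(stack$faws)[f],
                           as.vector(stack$primary)[f],
                           as.vector(stack$protection)[f],
                           as.vector(stack$wood_production)[f],
                           thresholds)
  structure(list(labels = matrix(lab, stack$grid$n_rows, stack$grid$n_cols),
                 grid = stack$grid,
                 n_unclassified = sum(f & is.na(lab))),
            class = "archetype_raster")
}

#' @export
print.archetype_raster <- function(x, ...) {
  tab <- table(factor(x$labels, ARCHETYPES))
  cat(sprintf("<archetype_raster> %d x %d @ %g m; %d classified cells, %d unclassifiable\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_size_m,
              sum(tab), x$n_unclassified))
  print(tab)
  invisible(x)
}

#' Aggregate a fine archetype raster to a coarser presentation raster
#'
#' Majority (modal) aggregation of `factor x factor` blocks, e.g. the 100 m
#' analysis raster to a 1 km presentation map. Ties break toward the lower
#' rank, i.e. the more natural archetype. A coarse cell is no-data only when
#' every fine cell in its block is no-data.
#'
#' @param fine An `archetype_raster`.
#' @param factor Aggregation factor; must divide both grid dimensions.
#' @return An `archetype_raster` on the coarse grid.
#' @export
aggregate_majority <- function(fine, factor = 10) {
  stopifnot(inherits(fine, "archetype_raster"))
  g <- fine$grid
  if (g$n_rows %% factor != 0 || g$n_cols %% factor != 0)
    stop("aggregation factor must divide the grid dimensions", call. = FALSE)
  nr <- g$n_rows %/% factor; nc <- g$n_cols %/% factor
  rank <- matrix(match(fine$labels, ARCHETYPES), g$n_rows, g$n_cols)
  block_r <- (row(rank) - 1L) %/% factor
  block_c <- (col(rank) - 1L) %/% factor
  block <- block_r * nc + block_c + 1L  # 1..nr*nc
  counts <- table(factor(block, seq_len(nr * nc)),
                  factor(rank, seq_along(ARCHETYPES)))
  counts <- as.matrix(counts)
  modal <- apply(counts, 1, function(cnt)
    if (all(cnt == 0)) NA_integer_ else which.max(cnt))  # first max = lower rank
  out <- matrix(ARCHETYPES[modal], nr, nc, byrow = TRUE)
  structure(list(labels = out,
                 grid = grid_spec(g$origin_x, g$origin_y,
                                  g$cell_size_m * factor, nr, nc, g$crs),
                 n_unclassified = fine$n_unclassified),
            class = "archetype_raster")
}

#' Write / read an archetype raster
#'
#' ASCII grid with integer label codes plus a CSV legend sidecar.
#' @param x An `archetype_raster`.
#' @param path Path of the `.asc` file; the legend goes to `<path>.legend.csv`.
#' @return `write_archetypes()` returns `path` invisibly; `read_archetypes()`
#'   an `archetype_raster`.
#' @export
write_archetypes <- function(x, path) {
  write_ascii_grid(x$labels, x$grid, path, levels = ARCHETYPES)
  readr::write_csv(tibble::tibble(code = seq_along(ARCHETYPES),
                                  label = ARCHETYPES),
                   paste0(path, ".legend.csv"))
  invisible(path)
}

#' @rdname write_archetypes
#' @param crs CRS identifier to attach on read.
#' @export
read_archetypes <- function(path, crs = "laea_europe") {
  r <- read_ascii_grid(path, levels = ARCHETYPES, crs = crs)
  structure(list(labels = r$matrix, grid = r$grid, n_unclassified = NA_integer_),
            class = "archetype_raster")
}
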