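#' Regional extent table of archetypes
#'
#' Tabulates the archetype raster by zone into areas in thousands of km2
#' (1 cell on the 100 m grid is 1 ha; 1000 km2 = 1e5 ha). The result carries
#' one row per zone, one column per archetype A-G, a `total` column and a
#' `"Total"` row, mirroring the published regional accounting table.
#'
#' @param labels An `archetype_raster`.
#' @param zones A [region_raster()] on the same grid.
#' @return An `extent_table` tibble: `region`, `A`..`G`, `total`.
#' @export
extent_table <- function(labels, zones) {
  stopifnot(inherits(labels, "archetype_raster"),
            inherits(zones, "region_raster"))
  if (!same_grid(labels$grid, zones$grid))
    stop("archetype and zone rasters are on different grids", call. = FALSE)
  on <- !is.na(labels$labels)
  counts <- table(factor(zones$region_id[on],
                         levels = sort(unique(as.vector(zones$region_id)))),
                  factor(labels$labels[on], levels = ARCHETYPES))
  area <- matrix(as.numeric(counts), nrow(counts), ncol(counts),
                 dimnames = dimnames(counts)) *
    cell_area_ha(labels$grid) / 1e5
  d <- tibble::as_tibble(area, rownames = "region")
  d$total <- unname(rowSums(area))
  tot <- dplyr::summarise(d, region = "Total",
                          dplyr::across(dplyr::where(is.numeric), sum))
  structure(dplyr::bind_rows(d, tot),
            class = c("extent_table", class(d)))
}

#' Read / write extent tables as CSV
#'
#' Header `region, A..G, total`; the bundled transcription of the published
#' continental table is available through [table3_fixture()].
#'
#' @param path CSV path.
#' @return An `extent_table` tibble.
#' @export
read_extent_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(region = "c",
                                               .default = "d"))
  stopifnot(all(c("region", ARCHETYPES) %in% names(d)))
  if (!"total" %in% names(d))
    d$total <- rowSums(d[ARCHETYPES])
  structure(d, class = c("extent_table", class(d)))
}

#' @rdname read_extent_table
#' @param table An `extent_table`.
#' @export
write_extent_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' The published continental extent table
#'
#' The regional archetype extents (1000 km2) of the published European
#' assessment, as transcribed from the printed table; used for in-paper
#' arithmetic checks and as a realistic accounting fixture.
#'
#' @return An `extent_table` tibble.
#' @export
table3_fixture <- function() {
  read_extent_table(system.file("extdata", "extent_table3.csv",
                                package = "forestarch", mustWork = TRUE))
}

#' Archetype shares of an extent table
#'
#' Percentage of area in a set of archetypes (and optionally a set of
#' regions), relative to a configurable denominator:
#' \describe{
#'   \item{`"total"`}{the table's grand total;}
#'   \item{`"regions"`}{the total area of the selected regions (a row
#'     share, e.g. the share of the Mediterranean region in archetype D);}
#'   \item{`"archetypes"`}{the total area of the selected archetypes across
#'     all regions (a column share, e.g. the share of archetype E falling in
#'     the Boreal and Continental regions).}
#' }
#' Denominators use the table's stored `total` column / `"Total"` row (the
#' printed marginals when the table was transcribed from a publication);
#' rounding to a reporting precision is left to the caller.
#'
#' @param table An `extent_table`.
#' @param archetypes Archetype subset (default all).
#' @param regions Region subset (default all data rows).
#' @param denominator One of `"total"`, `"regions"`, `"archetypes"`.
#' @return The share as a percentage (bare numeric).
#' @export
shares <- function(table, archetypes = ARCHETYPES, regions = NULL,
                   denominator = c("total", "regions", "archetypes")) {
  denominator <- match.arg(denominator)
  stopifnot(length(archetypes) > 0, all(archetypes %in% ARCHETYPES))
  body <- table[table$region != "Total", , drop = FALSE]
  tot_row <- table[table$region == "Total", , drop = FALSE]
  if (is.null(regions)) regions <- body$region
  missing_r <- setdiff(regions, body$region)
  if (length(missing_r))
    stop("unknown regions: ", paste(missing_r, collapse = ", "),
         call. = FALSE)
  all_regions <- setequal(regions, body$region)
  # when the selection spans all regions, use the table's stored column
  # totals as the numerator: for transcribed tables these are the printed
  # marginals the published percentages were computed from
  num <- if (all_regions && nrow(tot_row))
    sum(as.matrix(tot_row[, archetypes, drop = FALSE]))
  else sum(as.matrix(body[body$region %in% regions, archetypes,
                          drop = FALSE]))
  den <- switch(denominator,
                total = if (nrow(tot_row)) tot_row$total[1]
                else sum(as.matrix(body[ARCHETYPES])),
                regions = sum(body$total[body$region %in% regions]),
                archetypes = if (nrow(tot_row))
                  sum(as.matrix(tot_row[, archetypes, drop = FALSE]))
                else sum(as.matrix(body[, archetypes, drop = FALSE])))
  if (!isTRUE(den > 0)) stop("zero denominator", call. = FALSE)
  100 * num / den
}

#' Sensitivity of archetype extents to the wood-production thresholds
#'
#' Perturbs each threshold independently by the given relative offsets,
#' reclassifies the intensity bands D-G (archetypes A-C are
#' threshold-independent and never change) and tabulates the extents and
#' their deltas against the baseline. Perturbed triples violating the
#' ordering constraint are skipped with a warning. The band membership is
#' recomputed directly from the wood-production values of the cells on the
#' FAWS intensity path, which is equivalent to a full reclassification.
#'
#' @param stack A [layer_stack][assemble_stack()].
#' @param baseline A [threshold_set()].
#' @param offsets Relative offsets applied to one threshold at a time
#'   (default +/-10% and +/-25%).
#' @return A `sensitivity_result` tibble: `scenario`, `perturbed`, `offset`,
#'   `t_low`, `t_mid`, `t_high`, `archetype`, `extent_1000km2`, `delta`.
#' @export
sensitivity_sweep <- function(stack, baseline = threshold_set(),
                              offsets = c(-0.25, -0.1, 0.1, 0.25)) {
  stopifnot(inherits(stack, "layer_stack"))
  if (any(offsets <= -1)) stop("offsets must be > -100%", call. = FALSE)
  f <- stack$forest
  path <- f & (stack$faws %in% TRUE) & !(stack$primary %in% TRUE) &
    !(stack$protection %in% STRICT_CATEGORIES)
  wp <- stack$wood_production[path]
  wp <- wp[!is.na(wp)]
  to_ext <- cell_area_ha(stack$grid) / 1e5
  band_extents <- function(th) {
    cnt <- c(D = sum(wp < th$t_low),
             E = sum(wp >= th$t_low & wp < th$t_mid),
             F = sum(wp >= th$t_mid & wp <= th$t_high),
             G = sum(wp > th$t_high))
    cnt * to_ext
  }
  base_ext <- band_extents(baseline)
  grid_rows <- list(tibble::tibble(scenario = "baseline", perturbed = "none",
                                   offset = 0, t_low = baseline$t_low,
                                   t_mid = baseline$t_mid,
                                   t_high = baseline$t_high,
                                   archetype = names(base_ext),
                                   extent_1000km2 = as.numeric(base_ext),
                                   delta = 0))
  for (which_t in c("t_low", "t_mid", "t_high")) for (off in offsets) {
    th <- baseline
    th[[which_t]] <- baseline[[which_t]] * (1 + off)
    if (!(0 < th$t_low && th$t_low < th$t_mid && th$t_mid < th$t_high)) {
      warning(sprintf("skipping degenerate triple (%s %+.0f%%)",
                      which_t, 100 * off), call. = FALSE)
      next
    }
    ext <- band_extents(th)
    grid_rows[[length(grid_rows) + 1]] <- tibble::tibble(
      scenario = sprintf("%s%+.0f%%", which_t, 100 * off),
      perturbed = which_t, offset = off,
      t_low = th$t_low, t_mid = th$t_mid, t_high = th$t_high,
      archetype = names(ext), extent_1000km2 = as.numeric(ext),
      delta = as.numeric(ext - base_ext))
  }
  structure(dplyr::bind_rows(grid_rows),
            class = c("sensitivity_result", class(tibble::tibble())))
}

#' Compositional agreement against a reference accounting
#'
#' Compares two stratum-wise composition vectors over the same classes (by
#' default the three-way reserve / extensive / intensive grouping) with the
#' proportion-overlap statistic: per-stratum agreement is the summed
#' class-wise minimum of the two percentage vectors, and the overall
#' agreement the weighted mean over strata. Identical compositions score
#' 100%, disjoint ones 0%.
#'
#' @param ours,reference Long tibbles with columns `stratum`, `class`,
#'   `percent`; each stratum's percentages must sum to 100 within 0.5.
#' @param weights Optional named stratum weights (e.g. forest areas);
#'   default equal.
#' @return An `agreement_report`: list with `per_stratum` (tibble `stratum`,
#'   `agreement`) and `overall`.
#' @export
benchmark_agreement <- function(ours, reference, weights = NULL) {
  for (nm in c("ours", "reference")) {
    d <- get(nm)
    stopifnot(all(c("stratum", "class", "percent") %in% names(d)))
    sums <- tapply(d$percent, d$stratum, sum)
    if (any(abs(sums - 100) > 0.5))
      stop(nm, ": stratum percentages must sum to 100 (+/- 0.5)",
           call. = FALSE)
  }
  if (!setequal(unique(ours$stratum), unique(reference$stratum)))
    stop("strata do not match", call. = FALSE)
  if (!setequal(unique(ours$class), unique(reference$class)))
    stop("classes do not match", call. = FALSE)
  j <- dplyr::inner_join(ours, reference, by = c("stratum", "class"),
                         suffix = c("_ours", "_ref"))
  per <- j |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(agreement = sum(pmin(.data$percent_ours,
                                          .data$percent_ref)),
                     .groups = "drop")
  w <- if (is.null(weights)) stats::setNames(rep(1, nrow(per)), per$stratum)
  else weights[per$stratum]
  overall <- sum(per$agreement * w) / sum(w)
  structure(list(per_stratum = per, overall = overall),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> overall %.1f%%\n", x$overall))
  print(x$per_stratum)
  invisible(x)
}

#' Default archetype grouping for benchmarking
#'
#' Maps the seven archetypes onto the three benchmark classes: strict
#' reserves (A, B), extensively managed (C, D), intensively managed
#' (E, F, G). Configurable because the reference accountings differ in where
#' they draw these lines.
#'
#' @return Named character vector archetype -> class.
#' @export
default_benchmark_grouping <- function() {
  c(A = "reserve", B = "reserve", C = "extensive", D = "extensive",
    E = "intensive", F = "intensive", G = "intensive")
}

#' Stratum composition vectors from an extent table
#'
#' Collapses an extent table onto a benchmark grouping, yielding per-region
#' percentage vectors suitable for [benchmark_agreement()].
#'
#' @param table An `extent_table`.
#' @param grouping Named archetype -> class map
#'   (default [default_benchmark_grouping()]).
#' @return A long tibble `stratum`, `class`, `percent`.
#' @export
composition_by_stratum <- function(table, grouping = default_benchmark_grouping()) {
  body <- table[table$region != "Total", , drop = FALSE]
  body |>
    tidyr::pivot_longer(dplyr::all_of(ARCHETYPES), names_to = "archetype",
                        values_to = "area") |>
    dplyr::mutate(class = grouping[.data$archetype]) |>
    dplyr::group_by(stratum = .data$region, .data$class) |>
    dplyr::summarise(area = sum(.data$area), .groups = "drop_last") |>
    dplyr::mutate(percent = 100 * .data$area / sum(.data$area)) |>
    dplyr::ungroup() |>
    dplyr::select("stratum", "class", "percent")
}
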