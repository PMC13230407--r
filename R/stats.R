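#' Spatially thinned cell sampling
#'
#' Draws up to `n` cells per group (archetype) from an archetype raster,
#' uniformly at random but greedily thinned so that within each group all
#' accepted cells are at least `min_separation_m` apart — the package's
#' reproducible stand-in for "sampled to avoid spatial autocorrelation".
#' Candidates are visited in seeded random order; a candidate is accepted iff
#' it keeps the separation constraint; sampling stops when `n` cells are
#' accepted or candidates run out (the group is then flagged undersized).
#' With `min_separation_m = 0` this reduces to plain sampling without
#' replacement.
#'
#' @param labels An `archetype_raster`.
#' @param wp Numeric matrix of wood production on the same grid.
#' @param groups Archetype subset to sample (default D-G).
#' @param n Target sample size per group.
#' @param min_separation_m Minimum pairwise distance within a group, m.
#' @param seed Integer seed.
#' @return A `sample_set` tibble with columns `group`, `value`, `x`, `y`
#'   and attributes `min_separation_m` and `undersized` (named logical).
#' @export
sample_cells <- function(labels, wp, groups = c("D", "E", "F", "G"),
                         n = 1000, min_separation_m = 2000, seed = 1L) {
  stopifnot(inherits(labels, "archetype_raster"))
  grid <- labels$grid
  set.seed(seed)
  out <- list(); undersized <- logical(0)
  for (g in groups) {
    idx <- which(labels$labels == g & !is.na(wp))
    if (!length(idx)) {
      warning("group ", g, " has no eligible cells; excluded", call. = FALSE)
      next
    }
    cand <- idx[sample.int(length(idx))]
    rows <- ((cand - 1L) %% grid$n_rows) + 1L
    cols <- ((cand - 1L) %/% grid$n_rows) + 1L
    cx <- grid$origin_x + (cols - 0.5) * grid$cell_size_m
    cy <- grid$origin_y - (rows - 0.5) * grid$cell_size_m
    keep <- thin_accept(cx, cy, n, min_separation_m)
    undersized[g] <- sum(keep) < n
    out[[g]] <- tibble::tibble(group = g, value = wp[cand[keep]],
                               x = cx[keep], y = cy[keep])
  }
  res <- dplyr::bind_rows(out)
  res$group <- factor(res$group, levels = intersect(ARCHETYPES, unique(res$group)))
  attr(res, "min_separation_m") <- min_separation_m
  attr(res, "undersized") <- undersized
  class(res) <- c("sample_set", class(res))
  res
}

# greedy thinning with a bucket grid: O(candidates) for fixed density
thin_accept <- function(x, y, n, sep) {
  m <- length(x)
  if (sep <= 0) {
    keep <- logical(m); keep[seq_len(min(n, m))] <- TRUE
    return(keep)
  }
  keep <- logical(m)
  bx <- floor(x / sep); by <- floor(y / sep)
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  accepted <- 0L
  for (i in seq_len(m)) {
    ok <- TRUE
    for (dx in -1:1) for (dy in -1:1) {
      key <- paste(bx[i] + dx, by[i] + dy)
      pts <- buckets[[key]]
      if (!is.null(pts) &&
          any((pts[, 1] - x[i])^2 + (pts[, 2] - y[i])^2 < sep^2)) {
        ok <- FALSE; break
      }
    }
    if (ok) {
      keep[i] <- TRUE
      key <- paste(bx[i], by[i])
      buckets[[key]] <- rbind(buckets[[key]], c(x[i], y[i]))
      accepted <- accepted + 1L
      if (accepted >= n) break
    }
  }
  keep
}

# shared single-shot machinery: group stats from a (value, group) frame
group_stats <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  k <- nlevels(groups)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  ni <- tapply(values, groups, length)
  if (any(ni < 2)) stop("each group needs at least two values", call. = FALSE)
  mi <- tapply(values, groups, mean)
  sse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  N <- length(values)
  list(levels = levels(groups), k = k, ni = ni, mi = mi,
       sse = sse, df_within = N - k,
       ssb = sum(ni * (mi - mean(values))^2), N = N)
}

#' One-way analysis of variance across groups
#'
#' Classical fixed-effects one-way ANOVA of the sampled values across groups
#' (fitted through [stats::aov()]).
#'
#' @param samples A `sample_set` (or any tibble with `group` and `value`).
#' @return A `group_test_result` with elements `F`, `p`, `df`, and group
#'   summaries; see [tidy.group_test_result()].
#' @export
one_way_anova <- function(samples) {
  d <- data.frame(value = samples$value,
                  group = droplevels(as.factor(samples$group)))
  gs <- group_stats(d$value, d$group)
  if (gs$sse == 0 && gs$ssb == 0)
    stop("all values identical: variance is degenerate", call. = FALSE)
  fit <- stats::aov(value ~ group, data = d)
  tab <- summary(fit)[[1]]
  structure(list(method = "one-way ANOVA",
                 F = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
                 df = c(between = tab[["Df"]][1], within = tab[["Df"]][2]),
                 groups = tibble::tibble(group = gs$levels,
                                         n = as.integer(gs$ni),
                                         mean = as.numeric(gs$mi)),
                 pairwise = NULL, alpha = NA_real_),
            class = "group_test_result")
}

# Tukey-Kramer pairwise p-values from group stats via the studentized range
tukey_pairwise <- function(gs, alpha) {
  mse <- gs$sse / gs$df_within
  pairs <- utils::combn(gs$k, 2)
  g1 <- gs$levels[pairs[1, ]]; g2 <- gs$levels[pairs[2, ]]
  diff <- as.numeric(gs$mi[pairs[2, ]] - gs$mi[pairs[1, ]])
  se <- as.numeric(sqrt(mse / 2 * (1 / gs$ni[pairs[1, ]] +
                                     1 / gs$ni[pairs[2, ]])))
  p <- stats::ptukey(abs(diff) / se, gs$k, gs$df_within, lower.tail = FALSE)
  tibble::tibble(group1 = g1, group2 = g2, diff = diff,
                 p_adj = p, significant = p < alpha)
}

#' Tukey HSD post hoc test
#'
#' All-pairs comparison via the studentized range distribution, with the
#' Tukey-Kramer standard error for unequal group sizes; preceded by the
#' one-way ANOVA whose F and p are reported alongside.
#'
#' @inheritParams one_way_anova
#' @param alpha Familywise significance level (default 0.05, i.e. the 95%
#'   confidence level).
#' @return A `group_test_result` whose `pairwise` tibble has columns
#'   `group1`, `group2`, `diff`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(samples, alpha = 0.05) {
  res <- one_way_anova(samples)
  gs <- group_stats(samples$value, samples$group)
  res$pairwise <- tukey_pairwise(gs, alpha)
  res$alpha <- alpha
  res$method <- "one-way ANOVA + Tukey HSD"
  res
}

#' Significance matrix of a pairwise test
#' @param x A `group_test_result` with a `pairwise` component.
#' @return A symmetric logical matrix (NA diagonal).
#' @export
significance_matrix <- function(x) {
  stopifnot(!is.null(x$pairwise))
  lv <- x$groups$group
  m <- matrix(NA, length(lv), length(lv), dimnames = list(lv, lv))
  pw <- x$pairwise
  m[cbind(pw$group1, pw$group2)] <- pw$significant
  m[cbind(pw$group2, pw$group1)] <- pw$significant
  m
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("<%s> F = %.3f (df %d, %d), p = %.3g\n", x$method,
              x$F, x$df[1], x$df[2], x$p))
  if (!is.null(x$pairwise)) {
    sig <- sum(x$pairwise$significant)
    cat(sprintf("  %d of %d pairs significant at alpha = %g\n",
                sig, nrow(x$pairwise), x$alpha))
  }
  invisible(x)
}

#' Latitudinal / longitudinal slice definition
#'
#' Half-open bands of the projected plane used for the gradient assessment;
#' the defaults are the nine 500-km latitudinal slices from 1 000 000 m North
#' (about 32.0 deg N) to 5 500 000 m North (about 72.7 deg N) in the European
#' equal-area grid. A coordinate exactly on a band edge belongs to the upper
#' slice.
#'
#' @param axis `"northing"` (latitudinal slices) or `"easting"`.
#' @param start Lower edge of the first slice, m.
#' @param width Slice width, m.
#' @param count Number of slices.
#' @return A `slice_definition` object.
#' @export
slice_definition <- function(axis = c("northing", "easting"),
                             start = 1e6, width = 5e5, count = 9) {
  axis <- match.arg(axis)
  stopifnot(width > 0, count >= 1)
  structure(list(axis = axis, start = start, width = width,
                 count = as.integer(count)),
            class = "slice_definition")
}

#' Assess forest-use gradients across latitudinal or longitudinal slices
#'
#' Restricts attention to the wood-production archetypes D-G, computes the
#' per-slice composition (shares of D-G summing to 100% within each slice),
#' samples wood production per slice with spatial thinning, and tests for
#' differences across slices with one-way ANOVA plus Tukey HSD.
#'
#' @param labels An `archetype_raster`.
#' @param wp Wood-production matrix on the same grid.
#' @param slices A [slice_definition()].
#' @param n Sample size per slice.
#' @param min_separation_m Thinning distance, m.
#' @param alpha Significance level for the Tukey test.
#' @param seed Integer seed.
#' @return A `slice_assessment`: list with `shares` (tibble slice x archetype
#'   percent), `samples` (a `sample_set` keyed by slice), `test` (a
#'   `group_test_result`) and `slices`.
#' @export
slice_assessment <- function(labels, wp, slices = slice_definition(),
                             n = 1000, min_separation_m = 2000,
                             alpha = 0.05, seed = 1L) {
  stopifnot(inherits(labels, "archetype_raster"),
            inherits(slices, "slice_definition"))
  grid <- labels$grid
  dg <- c("D", "E", "F", "G")
  idx <- which(labels$labels %in% dg)
  rows <- ((idx - 1L) %% grid$n_rows) + 1L
  cols <- ((idx - 1L) %/% grid$n_rows) + 1L
  coord <- if (slices$axis == "northing")
    grid$origin_y - (rows - 0.5) * grid$cell_size_m
  else grid$origin_x + (cols - 0.5) * grid$cell_size_m
  k <- floor((coord - slices$start) / slices$width)
  ok <- k >= 0 & k < slices$count
  slice_id <- k[ok] + 1L
  idx <- idx[ok]

  shares <- tibble::tibble(slice = slice_id,
                           archetype = labels$labels[idx]) |>
    dplyr::count(.data$slice, .data$archetype) |>
    tidyr::complete(slice = seq_len(slices$count), archetype = dg,
                    fill = list(n = 0L)) |>
    dplyr::group_by(.data$slice) |>
    dplyr::mutate(percent = if (sum(.data$n) > 0)
      100 * .data$n / sum(.data$n) else NA_real_) |>
    dplyr::ungroup()

  # per-slice thinned wood-production samples
  set.seed(seed)
  out <- list()
  empty <- setdiff(seq_len(slices$count), unique(slice_id))
  if (length(empty))
    warning("empty slices excluded: ", paste(empty, collapse = ", "),
            call. = FALSE)
  for (s in sort(unique(slice_id))) {
    cand <- idx[slice_id == s]
    cand <- cand[!is.na(wp[cand])]
    if (!length(cand)) next
    cand <- cand[sample.int(length(cand))]
    r <- ((cand - 1L) %% grid$n_rows) + 1L
    cc <- ((cand - 1L) %/% grid$n_rows) + 1L
    cx <- grid$origin_x + (cc - 0.5) * grid$cell_size_m
    cy <- grid$origin_y - (r - 0.5) * grid$cell_size_m
    keep <- thin_accept(cx, cy, n, min_separation_m)
    out[[as.character(s)]] <- tibble::tibble(
      group = sprintf("slice_%02d", s), value = wp[cand[keep]],
      x = cx[keep], y = cy[keep])
  }
  samples <- dplyr::bind_rows(out)
  test <- if (length(unique(samples$group)) >= 2)
    tukey_hsd(samples, alpha = alpha) else NULL
  structure(list(shares = shares, samples = samples, test = test,
                 slices = slices),
            class = "slice_assessment")
}
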