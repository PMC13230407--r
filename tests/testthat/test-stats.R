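test_that("thinned sampling honours the separation constraint exhaustively", {
  set.seed(30)
  m <- matrix(sample(c("D", "E"), 3600, replace = TRUE), 60, 60)
  wp <- matrix(runif(3600, 0.1, 6), 60, 60)
  s <- sample_cells(arch_from_matrix(m), wp, groups = c("D", "E"), n = 50,
                    min_separation_m = 450, seed = 3)
  for (g in unique(s$group)) {
    sub <- s[s$group == g, ]
    d <- as.matrix(dist(cbind(sub$x, sub$y)))
    expect_true(all(d[upper.tri(d)] >= 450))
    expect_equal(nrow(sub), 50)
  }
})

test_that("zero separation reduces to plain sampling without replacement", {
  m <- matrix("D", 10, 10)
  wp <- matrix(runif(100), 10, 10)
  s <- sample_cells(arch_from_matrix(m), wp, groups = "D", n = 100,
                    min_separation_m = 0, seed = 7)
  expect_equal(sort(s$value), sort(as.vector(wp)))
  expect_false(attr(s, "undersized")[["D"]])
})

test_that("exhaustion flags undersized groups and empty groups warn", {
  m <- matrix("D", 6, 6)
  wp <- matrix(1, 6, 6)
  s <- sample_cells(arch_from_matrix(m), wp, groups = "D", n = 1000,
                    min_separation_m = 250, seed = 2)
  expect_true(attr(s, "undersized")[["D"]])
  expect_true(nrow(s) < 36)
  expect_warning(sample_cells(arch_from_matrix(m), wp, groups = c("D", "G"),
                              n = 5, seed = 1),
                 "no eligible cells")
})

test_that("ANOVA matches the direct sum-of-squares decomposition", {
  # identical groups: no between-group variance at all
  s0 <- tibble::tibble(group = rep(c("a", "b", "c"), each = 3),
                       value = rep(c(1, 2, 3), times = 3))
  r0 <- one_way_anova(s0)
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  # seeded data against the textbook formula computed from scratch
  set.seed(8)
  s <- tibble::tibble(group = rep(c("a", "b", "c", "d"), times = c(9, 14, 11, 8)),
                      value = rnorm(42, rep(c(0, 0.4, 1, 2), times = c(9, 14, 11, 8))))
  r <- one_way_anova(s)
  gm <- mean(s$value)
  ssb <- sum(tapply(s$value, s$group, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(s$value, s$group, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ssb / 3) / (ssw / (42 - 4))
  expect_equal(r$F, f_oracle)
  expect_equal(r$p, pf(f_oracle, 3, 38, lower.tail = FALSE))
  # extreme separation at large n
  s2 <- tibble::tibble(group = rep(c("lo", "hi"), each = 1000),
                       value = c(rnorm(1000, 0), rnorm(1000, 5)))
  expect_lt(one_way_anova(s2)$p, 1e-10)
  expect_error(one_way_anova(tibble::tibble(group = rep(c("a", "b"), 2),
                                            value = rep(1, 4))),
               "degenerate")
})

test_that("Tukey HSD agrees with the reference implementation", {
  set.seed(12)
  s <- tibble::tibble(group = rep(c("a", "b", "c", "d"), times = c(20, 15, 25, 18)),
                      value = rnorm(78, rep(c(0, 0.3, 0.8, 0.9), times = c(20, 15, 25, 18))))
  res <- tukey_hsd(s)
  ref <- TukeyHSD(aov(value ~ group, data = s))$group
  key <- paste(res$pairwise$group2, res$pairwise$group1, sep = "-")
  expect_equal(res$pairwise$p_adj, unname(ref[key, "p adj"]), tolerance = 1e-6)
  expect_equal(res$pairwise$diff, unname(ref[key, "diff"]), tolerance = 1e-10)
  # identical groups: all pairwise p near 1
  s0 <- tibble::tibble(group = rep(c("a", "b", "c"), each = 30),
                       value = withr::with_seed(5, rep(rnorm(30), 3)))
  expect_true(all(tukey_hsd(s0)$pairwise$p_adj > 0.99))
  # significance matrix is symmetric with NA diagonal
  sm <- significance_matrix(res)
  expect_true(isSymmetric(sm))
  expect_true(all(is.na(diag(sm))))
})

test_that("two-group Tukey p agrees with a permutation oracle", {
  set.seed(19)
  x <- rnorm(12, 0, 1); y <- rnorm(12, 1.0, 1)
  s <- tibble::tibble(group = rep(c("x", "y"), each = 12), value = c(x, y))
  p_tukey <- tukey_hsd(s)$pairwise$p_adj
  # permutation distribution of |mean difference|, 1e5 resamples
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  perm <- replicate(1e5, {
    idx <- sample.int(24, 12)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  p_perm <- mean(perm >= obs)
  expect_lt(abs(p_tukey - p_perm), 0.02)
})

test_that("Table-4-shaped groups give six strongly significant pairs", {
  set.seed(41)
  means <- c(D = 0.44, E = 1.48, F = 2.86, G = 5.57)
  sds <- c(D = 0.29, E = 0.29, F = 0.55, G = 1.71)
  s <- tibble::tibble(group = rep(names(means), each = 1000),
                      value = rnorm(4000, rep(means, each = 1000),
                                    rep(sds, each = 1000)))
  res <- tukey_hsd(s)
  expect_equal(nrow(res$pairwise), 6)
  expect_true(all(res$pairwise$p_adj < 0.001))
  expect_lt(res$p, 0.001)
})

test_that("slice assessment partitions cells and finds planted gradients", {
  # 90 rows x 40 cols, slices of 30 rows: south low, middle high, north low
  nr <- 90; nc <- 40
  g <- grid_spec(0, nr * 100, 100, nr, nc)
  set.seed(31)
  wp <- matrix(0.5 + runif(nr * nc, 0, 0.2), nr, nc)
  wp[31:60, ] <- 5 + runif(30 * nc, 0, 0.2)  # middle band (rows 31-60)
  lab <- matrix("D", nr, nc); lab[wp > 4] <- "G"
  arch <- structure(list(labels = lab, grid = g, n_unclassified = 0L),
                    class = "archetype_raster")
  sl <- slice_definition("northing", start = 0, width = 3000, count = 3)
  sa <- slice_assessment(arch, wp, sl, n = 200, min_separation_m = 0,
                         seed = 5)
  # compositional closure: D-G shares sum to 100 within each slice
  sums <- tapply(sa$shares$percent, sa$shares$slice, sum)
  expect_equal(as.numeric(sums), rep(100, 3))
  # slice 1 = lowest northings = north rows? no: slice k from start upward;
  # rows 61-90 have northing < 3000 -> slice 1; middle rows -> slice 2
  td <- tidy(sa$test)
  mid_pairs <- td[td$group1 == "slice_01" & td$group2 == "slice_02" |
                    td$group1 == "slice_02" & td$group2 == "slice_03", ]
  ext_pair <- td[td$group1 == "slice_01" & td$group2 == "slice_03", ]
  expect_true(all(mid_pairs$significant))
  expect_false(ext_pair$significant)
  # shares reflect the planted composition
  sh <- sa$shares
  expect_equal(sh$percent[sh$slice == 2 & sh$archetype == "G"], 100)
  expect_equal(sh$percent[sh$slice == 1 & sh$archetype == "D"], 100)
})

test_that("homogeneous fields produce no significant slice differences", {
  nr <- 60; nc <- 30
  g <- grid_spec(0, nr * 100, 100, nr, nc)
  set.seed(23)
  wp <- matrix(rlnorm(nr * nc, 0.3, 0.4), nr, nc)
  arch <- structure(list(labels = matrix("E", nr, nc), grid = g,
                         n_unclassified = 0L), class = "archetype_raster")
  sl <- slice_definition("northing", start = 0, width = 2000, count = 3)
  sa <- slice_assessment(arch, wp, sl, n = 150, min_separation_m = 0, seed = 2)
  expect_false(any(tidy(sa$test)$significant))
  # empty slices warn and are excluded
  sl_far <- slice_definition("northing", start = 0, width = 2000, count = 9)
  expect_warning(slice_assessment(arch, wp, sl_far, n = 50,
                                  min_separation_m = 0, seed = 2),
                 "empty slices")
})

test_that("boundary coordinates belong to the upper slice", {
  # a single row of cells whose centres sit exactly on a slice edge
  g <- grid_spec(0, 1050, 100, 10, 2)    # centres at northing 1000, 900, ...
  lab <- matrix("D", 10, 2)
  wp <- matrix(withr::with_seed(6, runif(20, 1, 2)), 10, 2)
  arch <- structure(list(labels = lab, grid = g, n_unclassified = 0L),
                    class = "archetype_raster")
  sl <- slice_definition("northing", start = 0, width = 500, count = 2)
  sa <- suppressWarnings(slice_assessment(arch, wp, sl, n = 5,
                                          min_separation_m = 0, seed = 1))
  # centres at 100-400 m -> slice 1 (4 rows); 500 m sits exactly on the edge
  # and goes to slice 2 with 600-900 m (5 rows); 1000 m is past the span
  counts <- tapply(sa$shares$n, sa$shares$slice, sum)
  expect_equal(as.numeric(counts), c(8, 10))
})
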