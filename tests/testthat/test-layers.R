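test_that("protection rasterization keeps the most protective category", {
  g <- tiny_grid(10, 10)
  feats <- tibble::tibble(
    category = c("V", "Ia"),
    geometry = list(rect_ring(g, 2, 6, 2, 6), rect_ring(g, 4, 8, 4, 8)))
  m <- rasterize_protection(feats, g)
  expect_equal(m[5, 5], "Ia")      # overlap -> strict wins
  expect_equal(m[2, 2], "V")
  expect_equal(m[8, 8], "Ia")
  expect_equal(m[1, 1], "NONE")
  # feature order must not matter
  expect_identical(rasterize_protection(feats[2:1, ], g), m)
})

test_that("empty and invalid protection inputs are handled", {
  g <- tiny_grid(4, 4)
  expect_true(all(rasterize_protection(tibble::tibble(category = character(),
                                                      geometry = list()),
                                       g) == "NONE"))
  expect_error(rasterize_protection(
    tibble::tibble(category = "VII", geometry = list(rect_ring(g, 1, 2, 1, 2))),
    g), "unknown protection category")
})

test_that("polygon coverage matches a brute-force point-in-polygon oracle", {
  g <- tiny_grid(20, 20)
  set.seed(11)
  # an irregular convex-ish pentagon
  ring <- cbind(x = c(300, 1500, 1900, 1100, 200),
                y = c(300, 150, 1200, 1900, 1400))
  m <- rasterize_protection(tibble::tibble(category = "II",
                                           geometry = list(ring)), g)
  ctr <- cell_centers(g)
  # oracle: even-odd crossing count, written independently with sp-style loop
  inside <- vapply(seq_len(nrow(ctr)), function(i) {
    px <- ctr$x[i]; py <- ctr$y[i]
    n <- nrow(ring); cnt <- 0L
    for (j in seq_len(n)) {
      k <- if (j == n) 1L else j + 1L
      y1 <- ring[j, 2]; y2 <- ring[k, 2]
      if ((y1 > py) != (y2 > py)) {
        xint <- ring[j, 1] + (py - y1) / (y2 - y1) * (ring[k, 1] - ring[j, 1])
        if (px < xint) cnt <- cnt + 1L
      }
    }
    cnt %% 2L == 1L
  }, logical(1))
  got <- as.vector(t(m == "II"))  # row-major like cell_centers
  expect_identical(got, inside)
  expect_equal(sum(m == "II"), sum(inside))
})

test_that("a k-cell rectangle burns exactly k cells", {
  g <- tiny_grid(12, 12)
  feats <- tibble::tibble(feature_id = 1L, type = "polygon",
                          geometry = list(rect_ring(g, 4, 6, 5, 7)),
                          patch_area_ha = 9)
  m <- rasterize_primary(feats, g)
  expect_equal(sum(m), 9)
  expect_true(all(m[4:6, 5:7]))
})

test_that("proportional circles burn the attributed patch area within 5%", {
  # 315 ha (the mean patch area of the point features) on a 100 m grid
  g <- tiny_grid(60, 60)
  feats <- tibble::tibble(feature_id = 1L, type = "point",
                          geometry = list(c(3000, 3000)),
                          patch_area_ha = 315)
  m <- rasterize_primary(feats, g)
  expect_lt(abs(sum(m) - 315) / 315, 0.05)
})

test_that("missing point areas impute from regional then global means", {
  g <- tiny_grid(40, 40)
  regions <- matrix("west", 40, 40); regions[, 21:40] <- "east"
  feats <- tibble::tibble(
    feature_id = 1:4, type = "point",
    geometry = list(c(500, 2000), c(900, 2000), c(1500, 2000), c(3500, 2000)),
    patch_area_ha = c(100, 300, NA, NA))
  m <- rasterize_primary(feats, g, regions)
  # western missing point -> regional mean of {100, 300} = 200 ha; eastern
  # region has no attributed points -> global mean, also 200 ha here
  explicit <- feats
  explicit$patch_area_ha[3:4] <- 200
  expect_identical(m, rasterize_primary(explicit, g, regions))
  # no attributed points at all -> no imputation basis
  expect_error(rasterize_primary(
    tibble::tibble(feature_id = 1L, type = "point",
                   geometry = list(c(1000, 1000)), patch_area_ha = NA_real_),
    g, regions), "impute")
})

test_that("disc discretization error vanishes for large radii", {
  g <- tiny_grid(80, 80)
  for (a in c(100, 500, 1200)) {  # radii >= 5.6 cells
    m <- rasterize_primary(tibble::tibble(feature_id = 1L, type = "point",
                                          geometry = list(c(4000, 4000)),
                                          patch_area_ha = a), g)
    expect_lt(abs(sum(m) - a) / a, 0.05)
  }
})

test_that("wood-production resampling equals the containing-cell lookup", {
  src_g <- grid_spec(0, 5000, 1000, 5, 5)
  dst_g <- grid_spec(0, 5000, 100, 50, 50)
  # constant field passes through
  const <- resample_wood_production(matrix(2.5, 5, 5), src_g, dst_g)
  expect_true(all(const == 2.5))
  # one source cell covers exactly 100 fine cells
  src <- matrix(0, 5, 5); src[2, 3] <- 7
  dst <- resample_wood_production(src, src_g, dst_g)
  expect_equal(sum(dst == 7), 100)
  # randomized oracle incl. missing propagation
  set.seed(4)
  src <- matrix(rlnorm(25), 5, 5); src[3, 1] <- NA
  dst <- resample_wood_production(src, src_g, dst_g)
  for (i in sample.int(2500, 200)) {
    r <- (i - 1) %/% 50 + 1; c <- (i - 1) %% 50 + 1
    x <- (c - 0.5) * 100; y <- 5000 - (r - 0.5) * 100
    expect_identical(dst[r, c], src[ceiling((5000 - y) / 1000),
                                    ceiling(x / 1000)])
  }
  expect_error(resample_wood_production(src, src_g,
                                        grid_spec(0, 5000, 100, 50, 50,
                                                  crs = "other")),
               "CRS")
})

test_that("stack assembly masks non-forest and is idempotent", {
  nr <- 4; nc <- 4
  forest <- matrix(TRUE, nr, nc); forest[1, 1] <- FALSE
  prot <- matrix("Ia", nr, nc)
  st <- assemble_stack(forest, matrix(TRUE, nr, nc), matrix(FALSE, nr, nc),
                       prot, matrix(1, nr, nc), tiny_grid(nr, nc))
  expect_true(is.na(st$protection[1, 1]))
  expect_true(is.na(st$wood_production[1, 1]))
  expect_equal(st$protection[2, 2], "Ia")
  st2 <- assemble_stack(st$forest, st$faws, st$primary, st$protection,
                        st$wood_production, st$grid)
  expect_identical(st2[names(st2) != "grid"], st[names(st) != "grid"])
  expect_error(assemble_stack(forest, matrix(TRUE, 5, 5),
                              matrix(FALSE, nr, nc), prot,
                              matrix(1, nr, nc), tiny_grid(nr, nc)),
               "not on the stack grid")
})

test_that("layer stacks round-trip through disk exactly", {
  set.seed(9)
  sc <- generate_scene(scenario_config(grid_rows = 32, grid_cols = 32,
                                       blob_scale_cells = 3, seed = 5))
  dir <- withr::local_tempdir()
  write_stack(sc$layers, dir)
  back <- read_stack(dir)
  for (nm in c("forest", "faws", "primary", "protection", "wood_production"))
    expect_identical(back[[nm]], sc$layers[[nm]], info = nm)
})
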