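test_that("simple shapes label as single Moore-connected components", {
  # L-shaped tromino
  m <- matrix(NA_character_, 4, 4)
  m[2, 2] <- m[3, 2] <- m[3, 3] <- "D"
  comp <- label_patches(arch_from_matrix(m))$membership
  expect_equal(sort(unique(comp[!is.na(comp)])), 1L)
  expect_equal(sum(!is.na(comp)), 3)
  # diagonal touch joins under Moore connectivity (4-connectivity would not)
  m2 <- matrix(NA_character_, 3, 3)
  m2[1, 1] <- m2[2, 2] <- "E"
  comp2 <- label_patches(arch_from_matrix(m2))$membership
  expect_equal(comp2[1, 1], comp2[2, 2])
  # different archetypes never join even when adjacent
  m3 <- matrix(c("D", "E"), 1, 2)
  comp3 <- label_patches(arch_from_matrix(m3))$membership
  expect_false(comp3[1, 1] == comp3[1, 2])
})

test_that("labeling matches the flood-fill oracle exhaustively on small grids", {
  # every two-class raster up to 9 cells, both as two labels and as
  # label-vs-nodata
  for (dims in list(c(2, 2), c(2, 4), c(3, 3))) {
    nr <- dims[1]; nc <- dims[2]
    for (code in 0:(2^(nr * nc) - 1)) {
      m <- bits_to_matrix(code, nr, nc)
      expect_identical(label_components(m), flood_fill_components(m))
      m_na <- bits_to_matrix(code, nr, nc, classes = c("A", NA))
      expect_identical(label_components(m_na), flood_fill_components(m_na))
    }
  }
})

test_that("labeling matches the flood-fill oracle on random rasters", {
  set.seed(14)
  for (rep in 1:20) {
    m <- matrix(sample(c("A", "B", NA), 64, replace = TRUE,
                       prob = c(0.4, 0.4, 0.2)), 8, 8)
    expect_identical(label_components(m), flood_fill_components(m))
  }
  for (rep in 1:100) {
    m <- matrix(sample(c("A", "B"), 2500, replace = TRUE), 50, 50)
    expect_identical(label_components(m), flood_fill_components(m))
  }
})

test_that("cell counts are conserved and the >2-cell filter is literal", {
  set.seed(3)
  m <- matrix(sample(c("D", "E", NA), 900, replace = TRUE), 30, 30)
  lp <- label_patches(arch_from_matrix(m))
  full <- build_patch_table(lp, min_cells = 1)
  expect_equal(sum(full$cell_count), sum(!is.na(m)))
  filtered <- build_patch_table(lp, min_cells = 3)
  expect_identical(filtered$patch_id,
                   full$patch_id[full$cell_count >= 3])
  # a 2-cell patch is excluded, a 3-cell patch kept with area 3 ha
  m2 <- matrix(NA_character_, 6, 6)
  m2[1, 1:2] <- "F"           # 2 cells
  m2[4, 2:4] <- "G"           # 3 cells
  t2 <- build_patch_table(label_patches(arch_from_matrix(m2)))
  expect_equal(nrow(t2), 1)
  expect_equal(t2$archetype, "G")
  expect_equal(t2$area_ha, 3)
})

test_that("planted patches are recovered with exact areas and regions", {
  m <- matrix(NA_character_, 24, 24)
  m[2:4, 2] <- "D"                       # 3 cells
  m[8:10, 8:10] <- "E"                   # 9 cells
  m[14:23, 14:23] <- "G"                 # 100 cells
  zones <- matrix("west", 24, 24); zones[, 13:24] <- "east"
  t <- build_patch_table(label_patches(arch_from_matrix(m)),
                         region_from_matrix(zones))
  expect_setequal(t$area_ha, c(3, 9, 100))
  expect_equal(t$region_id[t$archetype == "G"], "east")
  expect_equal(t$region_id[t$archetype == "D"], "west")
})

test_that("patch region ties break to the first cell in row-major order", {
  zones <- matrix(c("n", "s"), 2, 2, byrow = TRUE)  # row 1 = n, row 2 = s
  m <- matrix("A", 2, 2)
  t <- build_patch_table(label_patches(arch_from_matrix(m)),
                         region_from_matrix(zones), min_cells = 1)
  expect_equal(t$region_id, "n")
})

test_that("MPS aggregates are plain group means", {
  pt <- tibble::tibble(patch_id = 1:4, archetype = c("B", "B", "B", "G"),
                       region_id = c("r1", "r1", "r2", "r1"),
                       cell_count = c(10, 20, 30, 9),
                       area_ha = c(10, 20, 30, 9),
                       x = 0, y = 0)
  mm <- mps_matrix(pt)
  expect_equal(mm$mps_ha[mm$region_id == "r1" & mm$archetype == "B"], 15)
  expect_equal(mm$mps_ha[mm$region_id == "All" & mm$archetype == "B"], 20)
  expect_equal(mm$mps_ha[mm$region_id == "r1" & mm$archetype == "G"], 9)
  # empty combinations are absent, not zero
  expect_false(any(mm$region_id == "r2" & mm$archetype == "G"))
  # random table against an independent aggregate oracle
  set.seed(5)
  pt2 <- tibble::tibble(patch_id = 1:200,
                        archetype = sample(ARCHETYPES, 200, replace = TRUE),
                        region_id = sample(c("u", "v"), 200, replace = TRUE),
                        cell_count = sample(3:50, 200, replace = TRUE),
                        x = 0, y = 0) |>
    dplyr::mutate(area_ha = cell_count)
  mm2 <- mps_matrix(pt2)
  ora <- stats::aggregate(area_ha ~ region_id + archetype, pt2, mean)
  for (i in seq_len(nrow(ora)))
    expect_equal(mm2$mps_ha[mm2$region_id == ora$region_id[i] &
                              mm2$archetype == ora$archetype[i]],
                 ora$area_ha[i])
})

test_that("MPS increases along planted blob-size gradients", {
  # archetypes with systematically larger blobs show larger mean patch size
  m <- matrix(NA_character_, 40, 40)
  for (i in 0:7) m[(i %/% 2) * 10 + 1:3, (i %% 2) * 20 + 1:3] <- "B"
  m[31:40, 1:20] <- "G"
  mm <- mps_matrix(build_patch_table(label_patches(arch_from_matrix(m))))
  expect_lt(mm$mps_ha[which(mm$region_id == "All" & mm$archetype == "B")],
            mm$mps_ha[which(mm$region_id == "All" & mm$archetype == "G")])
})

test_that("iterative Tukey separates shifted groups and is reproducible", {
  set.seed(60)
  pt <- tibble::tibble(
    patch_id = 1:300,
    archetype = rep(c("B", "G"), each = 150),
    region_id = "r",
    cell_count = 3L,
    area_ha = exp(c(rnorm(150, 2, 0.5), rnorm(150, 3.5, 0.5))),
    x = runif(300, 0, 1e5), y = runif(300, 0, 1e5))
  res <- iterative_tukey(pt, n_iter = 50, n_sample = 100, seed = 4)
  expect_equal(res$pairs$frequency, 1)
  expect_true(res$pairs$significant)
  res2 <- iterative_tukey(pt, n_iter = 50, n_sample = 100, seed = 4)
  expect_identical(res$pairs, res2$pairs)
})

test_that("iterative Tukey stays near alpha under the null", {
  set.seed(61)
  pt <- tibble::tibble(
    patch_id = 1:400,
    archetype = rep(c("C", "D"), each = 200),
    region_id = "r",
    cell_count = 3L,
    area_ha = exp(rnorm(400, 2.5, 0.6)),
    x = runif(400, 0, 1e5), y = runif(400, 0, 1e5))
  res <- iterative_tukey(pt, n_iter = 200, n_sample = 100, seed = 9)
  expect_lt(abs(res$pairs$frequency - 0.05), 0.05)
  expect_false(res$pairs$significant)
  # groups with too few patches are excluded with a warning
  pt3 <- dplyr::bind_rows(pt, dplyr::mutate(pt[1, ], patch_id = 401L,
                                            archetype = "A"))
  expect_warning(iterative_tukey(pt3, n_iter = 5, n_sample = 50, seed = 1),
                 "excluded")
})
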