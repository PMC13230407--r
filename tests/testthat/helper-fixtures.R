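# shared builders and independent oracles for the test suite

# small grid with easy coordinates: UL corner (0, nr*s)
tiny_grid <- function(nr = 10, nc = 10, s = 100) {
  grid_spec(origin_x = 0, origin_y = nr * s, cell_size_m = s,
            n_rows = nr, n_cols = nc)
}

# a uniform layer stack: every forest cell shares the given attributes
uniform_stack <- function(nr = 6, nc = 6, forest = TRUE, faws = TRUE,
                          primary = FALSE, protection = "NONE", wp = 1.5) {
  g <- tiny_grid(nr, nc)
  m <- function(v) matrix(v, nr, nc)
  assemble_stack(m(forest), m(faws), m(primary), m(protection), m(wp), g)
}

# archetype raster straight from a character matrix
arch_from_matrix <- function(lab, s = 100) {
  g <- grid_spec(0, nrow(lab) * s, s, nrow(lab), ncol(lab))
  structure(list(labels = lab, grid = g, n_unclassified = 0L),
            class = "archetype_raster")
}

region_from_matrix <- function(ids, s = 100) {
  region_raster(grid_spec(0, nrow(ids) * s, s, nrow(ids), ncol(ids)), ids)
}

# independent Moore-neighbourhood flood fill (BFS), components numbered in
# row-major order of first occurrence -- the oracle for patch labeling
flood_fill_components <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  comp <- matrix(NA_integer_, nr, nc)
  k <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(lab[r, c]) || !is.na(comp[r, c])) next
    k <- k + 1L
    queue <- list(c(r, c)); comp[r, c] <- k
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- cur[1] + dr; cc <- cur[2] + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            is.na(comp[rr, cc]) && !is.na(lab[rr, cc]) &&
            lab[rr, cc] == lab[cur[1], cur[2]]) {
          comp[rr, cc] <- k
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  comp
}

# integer -> two-class label matrix from the bits of `code`
bits_to_matrix <- function(code, nr, nc, classes = c("A", "B")) {
  bits <- as.integer(intToBits(code))[seq_len(nr * nc)]
  matrix(classes[bits + 1], nr, nc)
}

# closed rectangle ring covering cell rows r1..r2, cols c1..c2 of a grid
rect_ring <- function(grid, r1, r2, c1, c2) {
  s <- grid$cell_size_m
  x1 <- grid$origin_x + (c1 - 1) * s; x2 <- grid$origin_x + c2 * s
  y1 <- grid$origin_y - r2 * s; y2 <- grid$origin_y - (r1 - 1) * s
  cbind(x = c(x1, x2, x2, x1), y = c(y1, y1, y2, y2))
}
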