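# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the labeler is a plain-R breadth-first search,
# the area oracle rasterizes nearest-neighbor assignment.

# BFS flood-fill labeling of zero cells; returns list(labels, n_spots)
bfs_label_oracle <- function(cells, connectivity) {
  nr <- nrow(cells)
  nc <- ncol(cells)
  labels <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  lab <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (cells[i, j] != 0L || labels[i, j] != 0L) next
      lab <- lab + 1L
      queue <- list(c(i, j))
      labels[i, j] <- lab
      while (length(queue) > 0L) {
        cur <- queue[[1L]]
        queue <- queue[-1L]
        for (d in seq_len(nrow(offs))) {
          ni <- cur[1] + offs[d, 1]
          nj <- cur[2] + offs[d, 2]
          if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
              cells[ni, nj] == 0L && labels[ni, nj] == 0L) {
            labels[ni, nj] <- lab
            queue <- c(queue, list(c(ni, nj)))
          }
        }
      }
    }
  }
  list(labels = labels, n_spots = lab)
}

# Discrete nearest-neighbor nutrition areas: each grid cell is cut into
# k x k subpixels whose centers are assigned to the closest emerged plant.
# Exact partition of the field; per-plant error O(perimeter * subpixel).
nn_area_oracle <- function(cells, row_sp, plant_sp, k = 24) {
  nr <- nrow(cells)
  nc <- ncol(cells)
  px <- py <- numeric(0)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (cells[i, j] == 1L) {
        px <- c(px, (j - 0.5) * plant_sp)
        py <- c(py, (i - 0.5) * row_sp)
      }
    }
  }
  sx <- (seq_len(nc * k) - 0.5) * plant_sp / k
  sy <- (seq_len(nr * k) - 0.5) * row_sp / k
  counts <- numeric(length(px))
  for (yy in sy) {
    d2 <- outer(px, sx, function(a, b) (a - b)^2) + (py - yy)^2
    nearest <- apply(d2, 2, which.min)
    tab <- tabulate(nearest, nbins = length(px))
    counts <- counts + tab
  }
  counts * (plant_sp / k) * (row_sp / k)
}

poly_area_shoelace <- function(poly) {
  n <- length(poly$x)
  if (n < 3) return(0)
  k2 <- c(seq_len(n)[-1], 1L)
  0.5 * abs(sum(poly$x * poly$y[k2] - poly$x[k2] * poly$y))
}

# random 0/1 matrix with at least `min_ones` emerged cells
random_cells <- function(nr, nc, rate, min_ones = 0L) {
  repeat {
    m <- matrix(rbinom(nr * nc, 1L, rate), nr, nc)
    if (sum(m) >= min_ones) return(m)
  }
}

# canonical form of a labeling: relabel by first occurrence in column-major
# order so two labelings of the same partition compare equal
canonical_labels <- function(labels) {
  ids <- unique(labels[labels > 0])
  out <- labels
  for (k in seq_along(ids)) out[labels == ids[k]] <- k
  out
}
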