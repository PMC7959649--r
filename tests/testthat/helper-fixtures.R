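# Small systems and independent oracles shared across test files.

# A consistent system with non-negative truth: limited-angle geometry on a
# small grid, projections synthesized from the rasterized phantom.
tiny_system <- function(n = 8, pkt = 6, phantom = phantom_f1()) {
  grid <- build_grid(n)
  truth <- rasterize(phantom, grid)
  A <- build_system(make_one_by_one(pkt), grid)
  list(grid = grid, truth = truth, A = A, B = forward_project(A, truth))
}

# Dense random consistent system with non-negative truth (full column rank
# with probability 1).
random_consistent_system <- function(m, n, seed) {
  set.seed(seed)
  A <- matrix(stats::runif(m * n, 0.1, 1), m, n)
  x <- stats::runif(n)
  list(A = A, x = x, b = as.numeric(A %*% x))
}

# Brute-force ray/pixel intersection lengths: midpoint sampling of the
# segment against pixel membership.  Independent of the tracer.
sampled_ray_lengths <- function(src, det, grid, samples = 1e5) {
  tt <- (seq_len(samples) - 0.5) / samples
  xs <- src[1] + tt * (det[1] - src[1])
  ys <- src[2] + tt * (det[2] - src[2])
  seg_len <- sqrt(sum((det - src)^2))
  idx <- pixel_at(grid, xs, ys)
  counts <- tabulate(idx, nbins = grid$N)
  counts / samples * seg_len
}

# Dense reference for one relaxed projection sweep over given rows (ascending
# order), clamping after each step when nonneg = TRUE.  Mirrors the update
# formula directly on dense vectors.
dense_sweep <- function(A, b, x, rows, lam, nonneg) {
  for (i in rows) {
    a <- A[i, ]
    x <- x + lam * ((b[i] - sum(a * x)) / sum(a * a)) * a
    if (nonneg) x <- pmax(x, 0)
  }
  x
}

# Independent dense evaluation of one parallel-block iteration: every block
# sweeps its rows from the shared x, results recombined with the diagonal
# weighting matrices.
dense_pb_iteration <- function(A, b, x, starts, W, lam, nonneg) {
  M <- nrow(W)
  acc <- NULL
  for (i in seq_len(M)) {
    rows <- seq.int(starts[i] + 1L, starts[i + 1L])
    y <- dense_sweep(A, b, x, rows, lam, nonneg)
    contrib <- W[i, ] * y
    acc <- if (is.null(acc)) contrib else acc + contrib
  }
  acc
}

# Analytic line integral of a piecewise-constant rectangle phantom along a
# segment: per region, the length of the parameter range where the segment
# is inside the rectangle.
analytic_line_integral <- function(phantom, src, det) {
  seg_len <- sqrt(sum((det - src)^2))
  total <- 0
  r <- phantom$regions
  for (i in seq_len(nrow(r))) {
    t_lo <- 0
    t_hi <- 1
    for (axis in 1:2) {
      p0 <- src[axis]
      d <- det[axis] - src[axis]
      lo <- c(r$x_lo[i], r$y_lo[i])[axis]
      hi <- c(r$x_hi[i], r$y_hi[i])[axis]
      if (d == 0) {
        if (p0 < lo || p0 > hi) {
          t_lo <- 1
          t_hi <- 0
        }
      } else {
        t1 <- (lo - p0) / d
        t2 <- (hi - p0) / d
        t_lo <- max(t_lo, min(t1, t2))
        t_hi <- min(t_hi, max(t1, t2))
      }
    }
    if (t_hi > t_lo) total <- total + r$density[i] * (t_hi - t_lo) * seg_len
  }
  total
}

random_boundary_ray <- function() {
  # two distinct points on different edges of E
  repeat {
    e <- sample(4L, 2L)
    pt <- function(edge) {
      t <- stats::runif(1, -1, 1)
      switch(edge, c(-1, t), c(1, t), c(t, -1), c(t, 1))
    }
    p1 <- pt(e[1])
    p2 <- pt(e[2])
    if (e[1] != e[2] && sqrt(sum((p1 - p2)^2)) > 1e-3) {
      return(list(source_x = p1[1], source_y = p1[2],
                  detector_x = p2[1], detector_y = p2[2],
                  src = p1, det = p2))
    }
  }
}
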