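#' Construct a piecewise-constant rectangular phantom
#'
#' A phantom models a discrete, high-contrast density distribution — e.g. a
#' coal seam containing rock inclusions or compressed-gas pockets — as a set
#' of axis-aligned rectangles \eqn{D_i \subset E} with constant densities
#' \eqn{c_i} over a constant background. Region interiors must be pairwise
#' disjoint (shared edges are allowed: their common area is zero).
#'
#' @param regions Data frame with columns \code{x_lo}, \code{x_hi},
#'   \code{y_lo}, \code{y_hi}, \code{density}.
#' @param background Background density outside all regions (default 0).
#' @return An object of class \code{phantom}.
#' @seealso [phantom_f1()], [phantom_f2()], [rasterize()]
#' @export
phantom_regions <- function(regions, background = 0) {
  req <- c("x_lo", "x_hi", "y_lo", "y_hi", "density")
  if (!is.data.frame(regions) || !all(req %in% names(regions))) {
    stop("`regions` must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  regions <- regions[, req]
  with(regions, {
    if (any(x_lo >= x_hi) || any(y_lo >= y_hi)) {
      stop("each region needs x_lo < x_hi and y_lo < y_hi", call. = FALSE)
    }
    if (any(x_lo < -1) || any(x_hi > 1) || any(y_lo < -1) || any(y_hi > 1)) {
      stop("regions must lie inside E = [-1,1]^2", call. = FALSE)
    }
    if (any(density < 0)) {
      stop("densities must be non-negative", call. = FALSE)
    }
  })
  s <- nrow(regions)
  if (s > 1L) {
    for (a in seq_len(s - 1L)) {
      for (b in seq.int(a + 1L, s)) {
        ox <- min(regions$x_hi[a], regions$x_hi[b]) -
          max(regions$x_lo[a], regions$x_lo[b])
        oy <- min(regions$y_hi[a], regions$y_hi[b]) -
          max(regions$y_lo[a], regions$y_lo[b])
        if (ox > 0 && oy > 0) {
          stop(sprintf("regions %d and %d have overlapping interiors", a, b),
               call. = FALSE)
        }
      }
    }
  }
  structure(list(regions = regions, background = background),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d rectangular region(s), background %g\n",
              nrow(x$regions), x$background))
  print(x$regions)
  invisible(x)
}

#' Built-in four-rectangle test phantoms
#'
#' `phantom_f1()` and `phantom_f2()` are the two reference density
#' distributions used throughout the package's convergence experiments:
#' four rectangles of densities 1–4 on a zero background.
#'
#' @return A \code{phantom}.
#' @examples
#' f1 <- phantom_f1()
#' phantom_eval(f1, 0, 0)      # 2
#' phantom_eval(f1, 0.5, 0.5)  # 4
#' @export
phantom_f1 <- function() {
  phantom_regions(data.frame(
    x_lo = c(-0.7, -0.2, -0.2, 0.4),
    x_hi = c(-0.4,  0.2,  0.2, 0.7),
    y_lo = c(-0.5, -0.1,  0.3, 0.4),
    y_hi = c( 0.2,  0.1,  0.5, 0.7),
    density = c(1, 2, 3, 4)
  ))
}

#' @rdname phantom_f1
#' @export
phantom_f2 <- function() {
  phantom_regions(data.frame(
    x_lo = c( 0.0, -0.4, -0.6, 0.0),
    x_hi = c( 0.5,  0.0, -0.4, 0.3),
    y_lo = c( 0.3, -0.6, -0.1, -0.5),
    y_hi = c( 0.5,  0.7,  0.1, -0.3),
    density = c(1, 2, 3, 4)
  ))
}

#' Evaluate a phantom's density at points
#'
#' Points inside a region (closed rectangle) take the region density; points
#' in no region take the background. On a shared edge the earlier region in
#' the phantom's list wins (a zero-area set; the choice never affects
#' area-weighted rasterization).
#'
#' @param phantom A \code{phantom}.
#' @param x,y Coordinate vectors (recycled to common length).
#' @return Numeric density values.
#' @export
phantom_eval <- function(phantom, x, y) {
  stopifnot(inherits(phantom, "phantom"))
  k <- max(length(x), length(y))
  x <- rep_len(x, k)
  y <- rep_len(y, k)
  out <- rep(phantom$background, k)
  done <- logical(k)
  r <- phantom$regions
  for (i in seq_len(nrow(r))) {
    inside <- !done &
      x >= r$x_lo[i] & x <= r$x_hi[i] &
      y >= r$y_lo[i] & y <= r$y_hi[i]
    out[inside] <- r$density[i]
    done <- done | inside
  }
  out
}

#' Rasterize a phantom to a pixel-indexed density vector
#'
#' The default (\code{method = "area"}) sets each pixel to the exact
#' area-weighted mean of the density over the pixel, computed from
#' rectangle-overlap areas — a pixel half covered by a density-4 region over
#' zero background gets 2. This makes the truth vector independent of how
#' points exactly on region edges are classified. \code{method = "center"}
#' instead samples the density at the pixel centre, giving a strictly
#' piecewise-constant-per-pixel truth.
#'
#' @param phantom A \code{phantom}.
#' @param grid A \code{pixel_grid}.
#' @param method \code{"area"} (exact area averaging, default) or
#'   \code{"center"} (pixel-centre sampling).
#' @return Numeric vector of length \code{grid$N} in the grid's row-major
#'   pixel order.
#' @examples
#' x <- rasterize(phantom_f1(), build_grid(40))
#' range(x)  # 0 to 4
#' @export
rasterize <- function(phantom, grid, method = c("area", "center")) {
  stopifnot(inherits(phantom, "phantom"), inherits(grid, "pixel_grid"))
  method <- match.arg(method)
  n <- grid$n
  h <- grid$pixel_size

  if (method == "center") {
    centers <- -1 + (seq_len(n) - 0.5) * h
    xs <- rep(centers, times = n)          # column index varies fastest
    ys <- rep(rev(centers), each = n)      # row 0 at top
    return(phantom_eval(phantom, xs, ys))
  }

  img <- matrix(phantom$background, nrow = n, ncol = n)
  # Overlaps are computed in pixel units (u = (x+1) n/2, v = (1-y) n/2, so
  # pixel (r, c) is the unit square [c, c+1] x [r, r+1]).  Region edges
  # within 1e-9 pixel of a mesh line are snapped onto it, so pixels fully
  # inside a region get exactly that region's density.
  snap <- function(u) {
    r <- round(u)
    ifelse(abs(u - r) < 1e-9, r, u)
  }
  col_lo <- seq_len(n) - 1
  row_lo <- seq_len(n) - 1
  r <- phantom$regions
  for (i in seq_len(nrow(r))) {
    ux <- snap((c(r$x_lo[i], r$x_hi[i]) + 1) * n / 2)
    vy <- snap((1 - c(r$y_hi[i], r$y_lo[i])) * n / 2)
    ox <- pmax(0, pmin(ux[2], col_lo + 1) - pmax(ux[1], col_lo))
    oy <- pmax(0, pmin(vy[2], row_lo + 1) - pmax(vy[1], row_lo))
    img <- img + (r$density[i] - phantom$background) * outer(oy, ox)
  }
  as.vector(t(img))
}

#' Forward-project a density vector through a system matrix
#'
#' Computes \eqn{B = A x}: each entry is the discrete line integral of the
#' density along one ray, i.e. the noiseless projection the scanner would
#' measure for that ray.
#'
#' @param A System matrix from [build_system()].
#' @param x Density vector of length \code{ncol(A)}.
#' @return Numeric projection vector of length \code{nrow(A)}.
#' @export
forward_project <- function(A, x) {
  if (length(x) != ncol(A)) {
    stop(sprintf("length(x) = %d but ncol(A) = %d", length(x), ncol(A)),
         call. = FALSE)
  }
  as.numeric(A %*% x)
}

#' Projection value from beam intensities
#'
#' The measured projection along a path is the log-attenuation
#' \eqn{p = \ln(I_0 / I)} of the initial intensity \eqn{I_0} to the final
#' intensity \eqn{I}.
#'
#' @param I0 Initial beam intensity (> 0).
#' @param I Final beam intensity (> 0, at most \code{I0}).
#' @return The projection \eqn{\ln(I_0/I)} (non-negative).
#' @examples
#' projection_from_intensities(exp(1), 1)  # 1
#' @export
projection_from_intensities <- function(I0, I) {
  if (any(I0 <= 0) || any(I <= 0)) {
    stop("intensities must be positive", call. = FALSE)
  }
  if (any(I > I0)) {
    stop("final intensity cannot exceed initial intensity", call. = FALSE)
  }
  log(I0 / I)
}

#' Add Gaussian noise to a projection vector
#'
#' Optional measurement-noise hook for robustness experiments; the package's
#' reference experiments use noiseless projections.
#'
#' @param B Projection vector.
#' @param sd Noise standard deviation (in projection units).
#' @param seed Optional integer seed for reproducibility.
#' @return \code{B} plus i.i.d. \eqn{N(0, sd^2)} noise.
#' @export
add_projection_noise <- function(B, sd, seed = NULL) {
  stopifnot(is.numeric(B), sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  B + stats::rnorm(length(B), mean = 0, sd = sd)
}
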