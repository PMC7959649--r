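new_scan_geometry <- function(rays, kind, ...) {
  structure(
    c(list(rays = rays, kind = kind), list(...)),
    class = "scan_geometry"
  )
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> kind = %s, %d rays\n", x$kind, nrow(x$rays)))
  invisible(x)
}

#' Opposite-walls (1 x 1) limited-angle scanning geometry
#'
#' Sources sit on the wall \eqn{x = -1} and detectors on the opposite wall
#' \eqn{x = +1} of the domain square, so every usable view direction lies
#' within a right angle — the severely incomplete acquisition that arises
#' when only two opposite faces of an object (e.g. a coal seam between two
#' headings) are accessible. Each of the \code{pkt} sources is paired with
#' each of the \code{pkt} detectors; positions are equally spaced including
#' the corners, \eqn{y_k = -1 + 2k/(pkt-1)}. The two pairs whose segment
#' runs along the horizontal edges \eqn{y = \pm 1} — and hence along the
#' pixel mesh — are rejected, leaving exactly \eqn{pkt^2 - 2} rays.
#'
#' Ray order is source-major, detector-minor, ascending position, so two
#' calls with the same \code{pkt} produce identical geometries.
#'
#' @param pkt Number of sources (= number of detectors); integer, at least 2.
#' @return A \code{scan_geometry} whose \code{rays} data frame has columns
#'   \code{id}, \code{source_x}, \code{source_y}, \code{detector_x},
#'   \code{detector_y}.
#' @examples
#' g <- make_one_by_one(50)
#' nrow(g$rays)  # 2498 = 50^2 - 2
#' @export
make_one_by_one <- function(pkt) {
  if (length(pkt) != 1L || !is.numeric(pkt) || is.na(pkt) || pkt != as.integer(pkt)) {
    stop("`pkt` must be a single integer", call. = FALSE)
  }
  pkt <- as.integer(pkt)
  if (pkt < 2L) stop("`pkt` must be at least 2", call. = FALSE)

  y <- -1 + 2 * (seq_len(pkt) - 1L) / (pkt - 1L)
  src <- rep(seq_len(pkt), each = pkt)   # source index, major
  det <- rep(seq_len(pkt), times = pkt)  # detector index, minor
  # reject the two edge-aligned pairs: bottom (first source, first detector)
  # and top (last source, last detector)
  drop <- (src == 1L & det == 1L) | (src == pkt & det == pkt)
  src <- src[!drop]
  det <- det[!drop]
  rays <- data.frame(
    id = seq_along(src),
    source_x = -1, source_y = y[src],
    detector_x = 1, detector_y = y[det]
  )
  new_scan_geometry(rays, "one_by_one", pkt = pkt)
}

#' Complete-data parallel-beam scanning geometry
#'
#' For each of \code{num_angles} view directions, equally spaced over
#' \eqn{[0, 180)} degrees, a fan of \code{rays_per_angle} parallel rays is
#' generated. Perpendicular ray offsets are placed at the centres of
#' \code{rays_per_angle} equal cells spanning the circumscribed extent
#' \eqn{[-\sqrt{2}, \sqrt{2}]} of the domain square, so every direction uses
#' the same offset pattern. Each ray is clipped to the square; rays whose
#' chord is empty (offsets beyond the square at that angle) are dropped.
#' Order is angle-major, then ascending offset.
#'
#' @param num_angles Number of view directions over 0–180 degrees.
#' @param rays_per_angle Number of parallel rays per direction.
#' @return A \code{scan_geometry} (kind \code{"parallel_beam"}).
#' @examples
#' g <- make_parallel_beam(100, 121)
#' nrow(g$rays) <= 12100
#' @export
make_parallel_beam <- function(num_angles, rays_per_angle) {
  for (v in list(num_angles, rays_per_angle)) {
    if (length(v) != 1L || !is.numeric(v) || is.na(v) || v != as.integer(v) || v < 1) {
      stop("`num_angles` and `rays_per_angle` must be positive integers",
           call. = FALSE)
    }
  }
  num_angles <- as.integer(num_angles)
  rays_per_angle <- as.integer(rays_per_angle)

  half <- sqrt(2)
  offs <- -half + (seq_len(rays_per_angle) - 0.5) * (2 * half / rays_per_angle)

  out <- vector("list", num_angles)
  for (a in seq_len(num_angles)) {
    theta <- (a - 1L) * pi / num_angles
    d <- c(cos(theta), sin(theta))   # ray direction
    u <- c(-sin(theta), cos(theta))  # offset direction (perpendicular)
    seg <- lapply(offs, function(t) clip_line_to_square(t * u, d))
    keep <- !vapply(seg, is.null, logical(1))
    if (!any(keep)) next
    ep <- do.call(rbind, seg[keep])
    out[[a]] <- data.frame(
      source_x = ep[, 1], source_y = ep[, 2],
      detector_x = ep[, 3], detector_y = ep[, 4]
    )
  }
  rays <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rays <- cbind(id = seq_len(nrow(rays)), rays)
  rownames(rays) <- NULL
  new_scan_geometry(rays, "parallel_beam",
                    num_angles = num_angles, rays_per_angle = rays_per_angle)
}

# Clip the line {point + s * dir} to E = [-1,1]^2 (Liang-Barsky).
# Returns c(x0, y0, x1, y1) with both endpoints on the boundary of E,
# or NULL when the chord is empty.
clip_line_to_square <- function(point, dir) {
  s_lo <- -Inf
  s_hi <- Inf
  for (axis in 1:2) {
    p <- point[axis]
    d <- dir[axis]
    if (d == 0) {
      if (p < -1 || p > 1) return(NULL)
    } else {
      s1 <- (-1 - p) / d
      s2 <- (1 - p) / d
      s_lo <- max(s_lo, min(s1, s2))
      s_hi <- min(s_hi, max(s1, s2))
    }
  }
  if (!is.finite(s_lo) || !is.finite(s_hi) || s_hi - s_lo <= 1e-12) return(NULL)
  c(point + s_lo * dir, point + s_hi * dir)
}

#' Intersection lengths of one ray with every pixel of a grid
#'
#' Traces the segment through the grid by sorted parametric boundary
#' crossings and returns, for each pixel traversed, the Euclidean length of
#' the intersection. A segment crossing at most \eqn{n - 1} interior vertical
#' and \eqn{n - 1} interior horizontal mesh lines touches at most
#' \eqn{2n - 1} pixels.
#'
#' @param ray One row of a geometry's \code{rays} data frame (or any list
#'   with \code{source_x}, \code{source_y}, \code{detector_x},
#'   \code{detector_y}), with the segment intersecting the domain square.
#' @param grid A \code{pixel_grid}.
#' @return A \code{\link[Matrix]{sparseVector}} of length \code{grid$N};
#'   entry \eqn{j} is the length of the ray's path through pixel \eqn{j}.
#' @examples
#' g <- build_grid(2)
#' r <- list(source_x = -1, source_y = -1, detector_x = 1, detector_y = 1)
#' ray_row(r, g)  # two entries of sqrt(2)
#' @export
ray_row <- function(ray, grid) {
  stopifnot(inherits(grid, "pixel_grid"))
  tr <- trace_ray_cpp(ray$source_x, ray$source_y,
                      ray$detector_x, ray$detector_y, grid$n)
  if (length(tr$j) == 0L) {
    stop("degenerate ray: zero-length chord through E", call. = FALSE)
  }
  Matrix::sparseVector(x = tr$x, i = tr$j + 1L, length = grid$N)
}

#' Assemble the sparse system matrix of the discretized scanning problem
#'
#' Row \eqn{i} of the returned matrix holds the intersection lengths of ray
#' \eqn{i} with every pixel, so that for a density vector \eqn{x} the product
#' \eqn{Ax} is the vector of line integrals (projections). The matrix is
#' non-negative, sparse (at most \eqn{2n - 1} nonzeros per row), and each
#' row sums to the chord length of its ray through the domain square.
#'
#' @param geometry A \code{scan_geometry}.
#' @param grid A \code{pixel_grid}.
#' @return A \code{\link[Matrix]{dgRMatrix-class}} (row-compressed sparse)
#'   of dimension \code{nrow(geometry$rays)} by \code{grid$N}.
#' @examples
#' A <- build_system(make_one_by_one(10), build_grid(8))
#' dim(A)  # 98 x 64
#' @export
build_system <- function(geometry, grid) {
  stopifnot(inherits(geometry, "scan_geometry"), inherits(grid, "pixel_grid"))
  rays <- as.matrix(geometry$rays[, c("source_x", "source_y",
                                      "detector_x", "detector_y")])
  parts <- build_system_cpp(rays, grid$n)
  methods::new("dgRMatrix",
               p = parts$p, j = parts$j, x = parts$x,
               Dim = c(nrow(rays), grid$N))
}

#' Chord lengths of a geometry's rays through the domain square
#'
#' @param geometry A \code{scan_geometry} whose ray endpoints lie on the
#'   boundary of the domain square (true for generated geometries).
#' @return Numeric vector of Euclidean source-to-detector distances.
#' @export
chord_lengths <- function(geometry) {
  r <- geometry$rays
  sqrt((r$detector_x - r$source_x)^2 + (r$detector_y - r$source_y)^2)
}
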