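#' Discretize the reconstruction domain into a square pixel grid
#'
#' The reconstruction domain is the fixed square \eqn{E = [-1, 1]^2}. It is
#' divided into \eqn{N = n^2} congruent square pixels of side \eqn{2/n}, and
#' the unknown density is assumed constant within each pixel.
#'
#' Pixels are indexed 0-based, row-major, with row 0 at the top of the image
#' (image convention): pixel \eqn{(r, c)} covers
#' \eqn{[-1 + c\,h,\ -1 + (c+1)h] \times [1 - (r+1)h,\ 1 - r\,h]} with
#' \eqn{h = 2/n}. The corresponding 1-based position in a density vector is
#' \code{r * n + c + 1}.
#'
#' @param n Number of pixels per side; integer, at least 2.
#' @return An object of class \code{pixel_grid} with fields \code{n},
#'   \code{N} (\eqn{= n^2}) and \code{pixel_size} (\eqn{= 2/n}).
#' @examples
#' g <- build_grid(40)
#' g$N          # 1600
#' g$pixel_size # 0.05
#' @export
build_grid <- function(n) {
  if (length(n) != 1L || !is.numeric(n) || is.na(n) || n != as.integer(n)) {
    stop("`n` must be a single integer", call. = FALSE)
  }
  n <- as.integer(n)
  if (n < 2L) {
    stop("`n` must be at least 2 (a 1-pixel grid cannot resolve structure)",
         call. = FALSE)
  }
  structure(
    list(n = n, N = n * n, pixel_size = 2 / n),
    class = "pixel_grid"
  )
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("<pixel_grid> %d x %d pixels (N = %d) on E = [-1,1]^2, pixel size %g\n",
              x$n, x$n, x$N, x$pixel_size))
  invisible(x)
}

#' Map pixel (row, column) coordinates to density-vector positions
#'
#' @param grid A \code{pixel_grid}.
#' @param row,col 0-based pixel row (from the top) and column (from the left).
#' @return 1-based positions into a length-\code{N} density vector.
#' @keywords internal
#' @export
pixel_index <- function(grid, row, col) {
  stopifnot(inherits(grid, "pixel_grid"))
  if (any(row < 0L | row >= grid$n | col < 0L | col >= grid$n)) {
    stop("pixel coordinates out of range", call. = FALSE)
  }
  as.integer(row) * grid$n + as.integer(col) + 1L
}

#' Locate the pixel containing a point of E
#'
#' Boundary convention: a pixel owns its lower x-boundary and its upper
#' y-boundary (half-open intervals), so every interior point of E belongs to
#' exactly one pixel.
#'
#' @param grid A \code{pixel_grid}.
#' @param x,y Coordinates in \eqn{[-1, 1]}.
#' @return 1-based density-vector positions.
#' @keywords internal
#' @export
pixel_at <- function(grid, x, y) {
  stopifnot(inherits(grid, "pixel_grid"))
  h <- grid$pixel_size
  col <- pmin(grid$n - 1L, pmax(0L, as.integer(floor((x + 1) / h))))
  row <- pmin(grid$n - 1L, pmax(0L, as.integer(floor((1 - y) / h))))
  pixel_index(grid, row, col)
}
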