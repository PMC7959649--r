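#' Write / read a system matrix in MatrixMarket coordinate format
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces every nonzero exactly.
#'
#' @param A System matrix (any \code{Matrix} sparse matrix).
#' @param path File path (conventionally \code{.mtx}).
#' @return \code{write_matrix}: the path, invisibly. \code{read_matrix}: a
#'   \code{dgRMatrix}.
#' @export
write_matrix <- function(A, path) {
  T <- methods::as(methods::as(methods::as(A, "dMatrix"), "generalMatrix"),
                   "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate real general", con)
  writeLines(sprintf("%d %d %d", nrow(T), ncol(T), length(T@x)), con)
  ord <- order(T@j, T@i)  # column-major, the conventional MM ordering
  writeLines(sprintf("%d %d %.17g", T@i[ord] + 1L, T@j[ord] + 1L, T@x[ord]),
             con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  A <- tryCatch(
    Matrix::readMM(path),
    error = function(e) {
      stop(sprintf("cannot parse MatrixMarket file '%s': %s",
                   path, conditionMessage(e)), call. = FALSE)
    }
  )
  methods::as(methods::as(methods::as(A, "dMatrix"), "generalMatrix"),
              "RsparseMatrix")
}

#' Write / read a density or projection vector as CSV
#'
#' Two-column CSV \code{index,value} with contiguous 0-based indices; the
#' round trip is exact (values printed with 17 significant digits).
#'
#' @param v Numeric vector.
#' @param path File path.
#' @return \code{write_vector}: the path, invisibly. \code{read_vector}: the
#'   numeric vector.
#' @export
write_vector <- function(v, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("index,value", con)
  writeLines(sprintf("%d,%.17g", seq_along(v) - 1L, v), con)
  invisible(path)
}

#' @rdname write_vector
#' @export
read_vector <- function(path) {
  d <- utils::read.csv(path)
  if (!identical(names(d), c("index", "value")) || nrow(d) == 0L) {
    stop(sprintf("'%s' is not an index,value vector file", path),
         call. = FALSE)
  }
  if (!identical(as.integer(d$index), seq_len(nrow(d)) - 1L)) {
    stop(sprintf("'%s': indices must be 0-based, contiguous and ordered", path),
         call. = FALSE)
  }
  as.numeric(d$value)
}

#' Export a scanning geometry as CSV
#'
#' Columns: \code{ray_id}, \code{source_x}, \code{source_y},
#' \code{detector_x}, \code{detector_y}.
#'
#' @param geometry A \code{scan_geometry}.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "scan_geometry"))
  r <- geometry$rays
  out <- data.frame(ray_id = r$id, source_x = r$source_x,
                    source_y = r$source_y, detector_x = r$detector_x,
                    detector_y = r$detector_y)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a phantom definition from CSV
#'
#' Expects columns \code{x_lo}, \code{x_hi}, \code{y_lo}, \code{y_hi},
#' \code{density}; validation as in [phantom_regions()].
#'
#' @param path CSV file path.
#' @param background Background density.
#' @return A \code{phantom}.
#' @export
read_phantom <- function(path, background = 0) {
  phantom_regions(utils::read.csv(path), background = background)
}

#' Render a density vector as a plain (ASCII) PGM image
#'
#' Min–max scales the vector to 8-bit gray levels (a constant image maps to
#' mid-gray) and writes a P2 portable graymap in the grid's row-major pixel
#' order, row 0 at the top. Images are derived views only: the density
#' vector is the canonical artifact.
#'
#' @param x Density vector of length \code{grid$N}.
#' @param grid A \code{pixel_grid}.
#' @param path Output path (conventionally \code{.pgm}).
#' @return The path, invisibly.
#' @export
render_pgm <- function(x, grid, path) {
  stopifnot(inherits(grid, "pixel_grid"))
  if (length(x) != grid$N) {
    stop(sprintf("length(x) = %d but grid$N = %d", length(x), grid$N),
         call. = FALSE)
  }
  rng <- range(x)
  lev <- if (rng[2] > rng[1]) {
    as.integer(round(255 * (x - rng[1]) / (rng[2] - rng[1])))
  } else {
    rep(128L, length(x))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", grid$n, grid$n), "255"), con)
  rows <- matrix(lev, nrow = grid$n, byrow = TRUE)
  writeLines(apply(rows, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Run configuration: a flat, serializable record of every run parameter
#'
#' Captures the full parameterization of a pipeline run (geometry, phantom,
#' solver, outputs) as a flat named list that round-trips losslessly through
#' a JSON key-value file, so a run replayed from its serialized
#' configuration reproduces bit-identical outputs.
#'
#' @param ... Named scalar parameters (numbers, strings, logicals).
#' @return A \code{run_config} (named list).
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) && (is.null(names(cfg)) || any(names(cfg) == ""))) {
    stop("all run_config entries must be named", call. = FALSE)
  }
  ok <- vapply(cfg, function(v) {
    length(v) == 1L && (is.numeric(v) || is.character(v) || is.logical(v))
  }, logical(1))
  if (!all(ok)) {
    stop("run_config entries must be scalar numbers, strings or logicals",
         call. = FALSE)
  }
  # numbers normalized to double so that file round trips are identity
  cfg <- lapply(cfg, function(v) if (is.numeric(v)) as.double(v) else v)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A \code{run_config}.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}
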