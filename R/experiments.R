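#' Maximum absolute pixel error between reconstruction and truth
#'
#' The convergence criterion used throughout the package:
#' \eqn{\Delta = \max_i |f(pik_i) - \tilde f(pik_i)|}, the largest absolute
#' difference between true and reconstructed density over all pixels.
#'
#' @param recon,truth Density vectors of equal length.
#' @return Non-negative scalar \eqn{\Delta}.
#' @export
max_abs_error <- function(recon, truth) {
  if (length(recon) != length(truth)) {
    stop("recon and truth have different lengths", call. = FALSE)
  }
  max(abs(recon - truth))
}

solve_to_target <- function(A, B, truth, algorithm, M, lam, target_delta,
                            iter_cap, workers = 1L) {
  config <- suppressWarnings(solver_config(
    lam = lam, constraint = "nonneg", max_iterations = iter_cap,
    stop_delta = target_delta, record_residual = FALSE
  ))
  res <- if (algorithm == "pb") {
    pb_solve(A, B, M = M, config = config, truth = truth, workers = workers)
  } else {
    art_solve(A, B, config = config, truth = truth)
  }
  list(
    iterations = res$iterations_run,
    converged = res$converged,
    seconds = res$history$seconds_elapsed[res$iterations_run],
    min_delta = min(res$history$delta),
    result = res
  )
}

#' Iterations-to-target over a grid of source counts and relaxation values
#'
#' For every combination of \code{pkt_values} and \code{lam_values}: builds
#' the (1 x 1) limited-angle system on an \code{grid_n} grid, synthesizes
#' noiseless projections of the phantom, reconstructs, and records the
#' number of iterations needed to reach \eqn{\Delta <} \code{target_delta}.
#' Runs that do not reach the target within \code{iter_cap} iterations are
#' censored. Elapsed seconds are recorded for information only (iteration
#' counts, unlike seconds, are hardware-independent).
#'
#' @param grid_n Grid resolution \eqn{n}.
#' @param pkt_values Source/detector counts to scan.
#' @param lam_values Relaxation coefficients to scan.
#' @param algorithm \code{"art"} (single sweep order) or \code{"pb"}.
#' @param M Block count for \code{algorithm = "pb"}.
#' @param target_delta Target max-absolute error.
#' @param iter_cap Censoring bound on iterations.
#' @param phantom Phantom to reconstruct (default [phantom_f1()]).
#' @return A \code{sweep_result}: data frame with columns \code{pkt},
#'   \code{lam}, \code{iterations}, \code{converged}, \code{seconds}.
#' @export
sweep_lambda <- function(grid_n, pkt_values, lam_values,
                         algorithm = c("art", "pb"), M = 1L,
                         target_delta = 0.05, iter_cap = 5000L,
                         phantom = phantom_f1()) {
  algorithm <- match.arg(algorithm)
  stopifnot(length(pkt_values) >= 1L, length(lam_values) >= 1L,
            target_delta > 0)
  grid <- build_grid(grid_n)
  truth <- rasterize(phantom, grid)
  cells <- expand.grid(lam = lam_values, pkt = pkt_values,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (p in unique(cells$pkt)) {
    A <- build_system(make_one_by_one(p), grid)
    B <- forward_project(A, truth)
    for (idx in which(cells$pkt == p)) {
      r <- solve_to_target(A, B, truth, algorithm, M, cells$lam[idx],
                           target_delta, iter_cap)
      rows[[idx]] <- data.frame(
        pkt = p, lam = cells$lam[idx],
        iterations = r$iterations, converged = r$converged,
        seconds = r$seconds
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            class = c("sweep_result", "data.frame"),
            target_delta = target_delta, iter_cap = iter_cap,
            grid_n = grid_n, algorithm = algorithm, M = M)
}

#' Relaxation value minimizing iterations-to-target
#'
#' Aggregates a [sweep_lambda()] result over source counts (sum of iteration
#' counts per \eqn{\lambda}, censored cells counting as infinite) and returns
#' the \eqn{\lambda} with the smallest total; ties break toward the smallest
#' \eqn{\lambda}.
#'
#' @param sweep_result A \code{sweep_result}.
#' @return The optimal relaxation coefficient.
#' @export
optimal_lambda <- function(sweep_result) {
  stopifnot(inherits(sweep_result, "sweep_result"))
  d <- as.data.frame(sweep_result)
  lams <- sort(unique(d$lam))
  score <- vapply(lams, function(l) {
    cells <- d[d$lam == l, ]
    if (all(cells$converged)) sum(cells$iterations) else Inf
  }, numeric(1))
  if (all(!is.finite(score))) {
    stop("no relaxation value converged within the iteration cap",
         call. = FALSE)
  }
  lams[which.min(score)]  # which.min takes the first (smallest lam) on ties
}

#' Iteration growth of the parallel-block algorithm with block count
#'
#' Splitting the system into more blocks leaves each block with poorer
#' information about the object, so the number of iterations to a fixed
#' error target grows with \eqn{M}; this experiment measures that growth.
#' For each \eqn{M = 1, \dots, M_{max}} the PB solver is run to
#' \eqn{\Delta <} \code{target_delta} and the iteration counts are fitted by
#' ordinary least squares, \code{iterations ~ M}. The headline number is the
#' fitted slope divided by the single-block iteration count: the per-block
#' iteration increase as a fraction of the one-thread cost.
#'
#' @param grid_n Grid resolution \eqn{n}.
#' @param pkt Source/detector count of the (1 x 1) geometry.
#' @param lam Relaxation coefficient.
#' @param phantom Phantom to reconstruct.
#' @param M_max Largest block count (at least 3, so a slope is meaningful).
#' @param target_delta Target max-absolute error.
#' @param iter_cap Censoring bound on iterations; non-converged block counts
#'   are flagged and excluded from the fit.
#' @return A \code{block_scaling} list: \code{table} (per-M iterations),
#'   \code{slope}, \code{intercept}, and \code{ratio} = slope /
#'   iterations(M = 1).
#' @export
block_scaling <- function(grid_n, pkt, lam = 1, phantom = phantom_f1(),
                          M_max = 10L, target_delta = 0.1,
                          iter_cap = 20000L) {
  stopifnot(M_max >= 3L)
  grid <- build_grid(grid_n)
  truth <- rasterize(phantom, grid)
  A <- build_system(make_one_by_one(pkt), grid)
  B <- forward_project(A, truth)

  tab <- data.frame(M = seq_len(M_max), iterations = NA_integer_,
                    converged = FALSE, seconds = NA_real_)
  for (M in seq_len(M_max)) {
    r <- solve_to_target(A, B, truth, "pb", M, lam, target_delta, iter_cap)
    tab$iterations[M] <- r$iterations
    tab$converged[M] <- r$converged
    tab$seconds[M] <- r$seconds
  }

  fit_rows <- tab[tab$converged, ]
  if (nrow(fit_rows) < 2L) {
    stop("fewer than two block counts converged; no slope can be fitted",
         call. = FALSE)
  }
  fit <- stats::lm(iterations ~ M, data = fit_rows)
  slope <- unname(stats::coef(fit)[["M"]])
  intercept <- unname(stats::coef(fit)[["(Intercept)"]])
  iter1 <- if (tab$converged[1L]) tab$iterations[1L] else NA_integer_
  structure(
    list(table = tab, slope = slope, intercept = intercept,
         ratio = if (is.na(iter1)) NA_real_ else slope / iter1,
         grid_n = grid_n, pkt = pkt, lam = lam,
         target_delta = target_delta),
    class = "block_scaling"
  )
}

#' @export
print.block_scaling <- function(x, ...) {
  cat(sprintf(
    "<block_scaling> n = %d, pkt = %d, lam = %g, target delta = %g\n",
    x$grid_n, x$pkt, x$lam, x$target_delta))
  print(x$table, row.names = FALSE)
  cat(sprintf("slope = %.2f iterations/block, slope / iterations(M=1) = %.3f\n",
              x$slope, x$ratio))
  invisible(x)
}
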