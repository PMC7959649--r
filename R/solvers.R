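#' Solver configuration for row-action reconstruction
#'
#' @param lam Relaxation coefficient \eqn{\lambda} applied to every
#'   projection step. The methods are provably convergent for constant
#'   \eqn{0 < \lambda < 2}; values outside that interval are accepted with a
#'   warning (useful for probing the divergence boundary).
#' @param constraint \code{"nonneg"} (default) applies the constraining
#'   operator — negative entries clamped to zero — encoding that physical
#'   densities are non-negative; \code{"none"} disables it.
#' @param constraint_timing \code{"per_step"} (default) clamps after every
#'   projection step; \code{"per_iteration"} clamps once per full sweep.
#' @param max_iterations Iteration cap; one iteration is one pass over all
#'   rows of the system.
#' @param stop_delta Stop once the max-absolute-pixel error against the true
#'   density falls below this value (requires \code{truth} at solve time).
#' @param stop_residual Stop once the relative residual
#'   \eqn{\|Ax - B\| / \|B\|} falls below this value.
#' @param x0 Initial solution (default: the zero vector).
#' @param record_residual Record the relative residual each iteration
#'   (adds one matrix-vector product per iteration; disable in large sweeps).
#' @return A \code{solver_config} list.
#' @export
solver_config <- function(lam = 1,
                          constraint = c("nonneg", "none"),
                          constraint_timing = c("per_step", "per_iteration"),
                          max_iterations = 1000L,
                          stop_delta = NULL,
                          stop_residual = NULL,
                          x0 = NULL,
                          record_residual = TRUE) {
  constraint <- match.arg(constraint)
  constraint_timing <- match.arg(constraint_timing)
  stopifnot(is.numeric(lam), length(lam) == 1L, lam > 0,
            is.numeric(max_iterations), max_iterations >= 1)
  if (lam >= 2) {
    warning("lam = ", lam, " is outside (0, 2); ",
            "ART is guaranteed convergent only for 0 < lambda < 2",
            call. = FALSE)
  }
  if (!is.null(stop_delta)) stopifnot(stop_delta >= 0)
  if (!is.null(stop_residual)) stopifnot(stop_residual >= 0)
  structure(
    list(lam = lam, constraint = constraint,
         constraint_timing = constraint_timing,
         max_iterations = as.integer(max_iterations),
         stop_delta = stop_delta, stop_residual = stop_residual,
         x0 = x0, record_residual = record_residual),
    class = "solver_config"
  )
}

#' One relaxed projection step onto a row hyperplane
#'
#' Applies \eqn{x' = x + \lambda \, (p - a \circ x) / \|a\|^2 \, a}: the
#' orthogonal projection of \eqn{x} onto the hyperplane \eqn{a \circ x = p},
#' scaled by the relaxation coefficient. With \code{lam = 1} the result lies
#' exactly on the hyperplane.
#'
#' @param x Current solution vector.
#' @param a Row vector (dense numeric or \code{sparseVector}).
#' @param p Projection value for this row.
#' @param lam Relaxation coefficient.
#' @return Updated dense solution vector.
#' @export
art_step <- function(x, a, p, lam = 1) {
  a <- as.numeric(a)
  if (length(a) != length(x)) stop("length(a) != length(x)", call. = FALSE)
  na2 <- sum(a * a)
  if (na2 == 0) stop("degenerate row: zero norm", call. = FALSE)
  x + lam * ((p - sum(a * x)) / na2) * a
}

#' Non-negativity constraining operator
#'
#' Clamps negative entries to zero (idempotent), encoding that the density /
#' absorption being reconstructed is physically non-negative.
#'
#' @param x Numeric vector.
#' @return \code{pmax(x, 0)}.
#' @export
constrain <- function(x) pmax(x, 0)

# Pull validated CSR slots out of a system matrix.
csr_parts <- function(A) {
  if (!methods::is(A, "dgRMatrix")) {
    A <- methods::as(methods::as(methods::as(A, "dMatrix"), "generalMatrix"),
                     "RsparseMatrix")
  }
  rn2 <- row_norms2_cpp(A@p, A@x)
  list(p = A@p, j = A@j, x = A@x, m = nrow(A), N = ncol(A), rn2 = rn2, A = A)
}

new_recon_result <- function(x, history, config, algorithm,
                             converged, partition = NULL) {
  structure(
    list(x = x, iterations_run = nrow(history), history = history,
         config = config, algorithm = algorithm, converged = converged,
         partition = partition),
    class = "recon_result"
  )
}

#' @export
print.recon_result <- function(x, ...) {
  h <- x$history
  last <- h[nrow(h), ]
  cat(sprintf("<recon_result> %s: %d iteration(s)%s\n", x$algorithm,
              x$iterations_run,
              if (isTRUE(x$converged)) ", stop rule met" else ""))
  if (nrow(h)) {
    cat(sprintf("  final delta = %s, relative residual = %s\n",
                format(last$delta), format(last$relative_residual)))
  }
  invisible(x)
}

solve_history <- function(k, delta, resid, secs) {
  data.frame(iteration = seq_len(k), delta = delta[seq_len(k)],
             relative_residual = resid[seq_len(k)],
             seconds_elapsed = secs[seq_len(k)])
}

run_row_action <- function(parts, B, config, truth,
                           algorithm, sweep_fun, partition = NULL) {
  m <- parts$m
  N <- parts$N
  if (length(B) != m) {
    stop(sprintf("length(B) = %d but nrow(A) = %d", length(B), m),
         call. = FALSE)
  }
  if (any(parts$rn2 == 0)) {
    stop("system matrix contains an all-zero row", call. = FALSE)
  }
  if (!is.null(config$stop_delta) && is.null(truth)) {
    stop("stop_delta requires a truth vector", call. = FALSE)
  }
  if (!is.null(truth) && length(truth) != N) {
    stop("truth vector has wrong length", call. = FALSE)
  }

  x <- if (is.null(config$x0)) numeric(N) else as.numeric(config$x0)
  if (length(x) != N) stop("x0 has wrong length", call. = FALSE)
  nonneg <- config$constraint == "nonneg"
  if (nonneg) x <- constrain(x)
  per_iter <- nonneg && config$constraint_timing == "per_iteration"

  need_resid <- isTRUE(config$record_residual) || !is.null(config$stop_residual)
  bnorm <- sqrt(sum(B^2))
  kmax <- config$max_iterations
  delta <- rep(NA_real_, kmax)
  resid <- rep(NA_real_, kmax)
  secs <- rep(NA_real_, kmax)
  t0 <- proc.time()[["elapsed"]]
  converged <- FALSE
  k <- 0L
  while (k < kmax) {
    k <- k + 1L
    x <- sweep_fun(x)
    if (per_iter) x <- constrain(x)
    if (!is.null(truth)) delta[k] <- max(abs(x - truth))
    if (need_resid) {
      r <- sqrt(sum((as.numeric(parts$A %*% x) - B)^2))
      resid[k] <- if (bnorm > 0) r / bnorm else r
    }
    secs[k] <- proc.time()[["elapsed"]] - t0
    if (!is.null(config$stop_delta) && delta[k] < config$stop_delta) {
      converged <- TRUE
      break
    }
    if (!is.null(config$stop_residual) && !is.na(resid[k]) &&
        resid[k] < config$stop_residual) {
      converged <- TRUE
      break
    }
  }
  new_recon_result(x, solve_history(k, delta, resid, secs), config,
                   algorithm, converged, partition)
}

#' ART reconstruction (relaxed Kaczmarz with optional non-negativity)
#'
#' Sweeps the rows of the system in matrix order, applying the relaxed
#' orthogonal-projection update of [art_step()] to each row; with the
#' non-negativity constraint enabled the constraining operator is applied
#' per the configured timing. One iteration is a full pass over all rows.
#' With \code{lam = 1} and \code{constraint = "none"} this is exactly the
#' Kaczmarz algorithm.
#'
#' @param A System matrix (\code{dgRMatrix} from [build_system()], or any
#'   \code{Matrix} sparse matrix).
#' @param B Projection vector of length \code{nrow(A)}.
#' @param config A [solver_config()].
#' @param truth Optional true density vector; enables the per-iteration
#'   max-absolute-error history and the \code{stop_delta} rule.
#' @return A \code{recon_result}: final solution \code{x}, iteration count,
#'   and per-iteration history (delta, relative residual, elapsed seconds).
#' @export
art_solve <- function(A, B, config = solver_config(), truth = NULL) {
  parts <- csr_parts(A)
  clamp_step <- config$constraint == "nonneg" &&
    config$constraint_timing == "per_step"
  sweep_fun <- function(x) {
    sweep_rows_cpp(parts$p, parts$j, parts$x, parts$rn2, B, x,
                   0L, parts$m, config$lam, TRUE, clamp_step)
  }
  run_row_action(parts, B, config, truth, "art", sweep_fun)
}

#' Kaczmarz reconstruction (pure orthogonal projections)
#'
#' A distinct code path in which each row update is the bare orthogonal
#' projection onto the row hyperplane — no relaxation coefficient enters the
#' arithmetic. Produces iterates identical to [art_solve()] with
#' \code{lam = 1} and no constraint.
#'
#' @inheritParams art_solve
#' @param max_iterations,stop_residual,x0 See [solver_config()].
#' @return A \code{recon_result}.
#' @export
kaczmarz_solve <- function(A, B, max_iterations = 1000L,
                           stop_residual = NULL, x0 = NULL, truth = NULL) {
  config <- solver_config(lam = 1, constraint = "none",
                          max_iterations = max_iterations,
                          stop_residual = stop_residual, x0 = x0)
  parts <- csr_parts(A)
  sweep_fun <- function(x) {
    sweep_rows_cpp(parts$p, parts$j, parts$x, parts$rn2, B, x,
                   0L, parts$m, 1.0, FALSE, FALSE)
  }
  run_row_action(parts, B, config, truth, "kaczmarz", sweep_fun)
}

#' Partition system rows into contiguous balanced blocks
#'
#' Splits row indices \eqn{\{1, \dots, m\}} into \eqn{M} contiguous disjoint
#' blocks whose sizes differ by at most one: the first \code{m \%\% M} blocks
#' get the extra row.
#'
#' @param m_rows Total number of rows.
#' @param M Number of blocks, \eqn{1 \le M \le m}.
#' @return A \code{block_partition} with 0-based block boundaries
#'   \code{starts} (length \code{M + 1}) and \code{sizes}.
#' @examples
#' partition_rows(10, 3)$sizes  # 4 3 3
#' @export
partition_rows <- function(m_rows, M) {
  stopifnot(length(m_rows) == 1L, length(M) == 1L)
  m_rows <- as.integer(m_rows)
  M <- as.integer(M)
  if (M < 1L || M > m_rows) {
    stop("need 1 <= M <= m_rows", call. = FALSE)
  }
  base <- m_rows %/% M
  extra <- m_rows %% M
  sizes <- rep(base, M) + c(rep(1L, extra), rep(0L, M - extra))
  starts <- c(0L, cumsum(sizes))
  structure(list(M = M, sizes = sizes, starts = starts), class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("<block_partition> %d block(s), sizes %s\n", x$M,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Diagonal weighting matrices for the parallel-block algorithm
#'
#' For each block \eqn{B_i} and pixel \eqn{j}, the weight is the fraction of
#' the column-\eqn{j} mass carried by the block:
#' \eqn{w_j^i = \sum_{q \in B_i} a_{q,j} / \sum_q a_{q,j}}, the denominator
#' running over all rows. Columns no ray touches get \eqn{w_j^i = 1/M}, so
#' the weights sum to one for every pixel and the recombination is a true
#' averaging.
#'
#' @param A System matrix.
#' @param partition A [partition_rows()] result for \code{nrow(A)}.
#' @param scheme \code{"colsum"} (default): the column-sum-fraction weights
#'   above. \code{"uniform"}: plain averaging, \eqn{w_j^i = 1/M} everywhere —
#'   the simple "average the block solutions" recombination, provided for
#'   comparison; it converges considerably more slowly (see the methods
#'   vignette).
#' @return An \code{M} by \code{ncol(A)} matrix; row \eqn{i} holds the
#'   diagonal of \eqn{W_i}.
#' @export
block_weights <- function(A, partition, scheme = c("colsum", "uniform")) {
  stopifnot(inherits(partition, "block_partition"))
  scheme <- match.arg(scheme)
  parts <- csr_parts(A)
  if (partition$starts[partition$M + 1L] != parts$m) {
    stop("partition does not cover the rows of A", call. = FALSE)
  }
  M <- partition$M
  if (scheme == "uniform") {
    return(matrix(1 / M, nrow = M, ncol = parts$N))
  }
  W <- matrix(0, nrow = M, ncol = parts$N)
  for (i in seq_len(M)) {
    W[i, ] <- col_sums_range_cpp(parts$p, parts$j, parts$x, parts$N,
                                 partition$starts[i], partition$starts[i + 1L])
  }
  total <- colSums(W)
  hit <- total > 0
  W[, hit] <- sweep(W[, hit, drop = FALSE], 2L, total[hit], "/")
  W[, !hit] <- 1 / M
  W
}

pb_combine <- function(ys, W) {
  xnew <- W[1L, ] * ys[[1L]]
  for (i in seq_along(ys)[-1L]) xnew <- xnew + W[i, ] * ys[[i]]
  xnew
}

pb_iterate_internal <- function(x, parts, B, partition, W, lam,
                                clamp_step, workers) {
  M <- partition$M
  starts <- partition$starts
  block_sweep <- function(i) {
    sweep_rows_cpp(parts$p, parts$j, parts$x, parts$rn2, B, x,
                   starts[i], starts[i + 1L], lam, TRUE, clamp_step)
  }
  ys <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(M), block_sweep, mc.cores = workers)
  } else {
    lapply(seq_len(M), block_sweep)
  }
  pb_combine(ys, W)
}

#' One iteration of the parallel-block (PB) algorithm
#'
#' Every block starts from the shared iterate \eqn{x^{(k)}} and performs a
#' full ART sweep over its own rows (in ascending row order), yielding
#' \eqn{y^{(k+1,i)} = Q_i x^{(k)}}; the blocks are then recombined as
#' \eqn{x^{(k+1)} = \sum_i W_i y^{(k+1,i)}} with the column-sum weighting
#' matrices of [block_weights()], summed in ascending block order. The
#' result depends only on the partition, never on how many workers execute
#' the block sweeps.
#'
#' @param x Current solution vector.
#' @param A,B System matrix and projection vector.
#' @param partition A [partition_rows()] result.
#' @param weights A [block_weights()] matrix for the same partition.
#' @param config A [solver_config()].
#' @param workers Number of processes for the block sweeps.
#' @return The next solution vector.
#' @export
pb_iterate <- function(x, A, B, partition, weights, config = solver_config(),
                       workers = 1L) {
  parts <- csr_parts(A)
  clamp_step <- config$constraint == "nonneg" &&
    config$constraint_timing == "per_step"
  xnew <- pb_iterate_internal(x, parts, B, partition, weights, config$lam,
                              clamp_step, workers)
  if (config$constraint == "nonneg" &&
      config$constraint_timing == "per_iteration") {
    xnew <- constrain(xnew)
  }
  xnew
}

#' Parallel-block (PB) reconstruction
#'
#' Iterates [pb_iterate()] from the initial solution with a barrier at every
#' iteration: all blocks consume the same iterate and the weighted average
#' becomes the next shared iterate. With \code{M = 1} the single weighting
#' matrix is the identity on every touched pixel and the method reduces
#' exactly (bitwise) to [art_solve()]. The numbers produced are invariant to
#' \code{workers}; only elapsed time changes.
#'
#' @inheritParams art_solve
#' @param M Number of row blocks (= logical threads).
#' @param workers Number of processes executing block sweeps per iteration.
#' @param scheme Weighting scheme passed to [block_weights()].
#' @return A \code{recon_result}; \code{$partition} echoes the row blocks.
#' @export
pb_solve <- function(A, B, M, config = solver_config(), truth = NULL,
                     workers = 1L, scheme = c("colsum", "uniform")) {
  parts <- csr_parts(A)
  partition <- partition_rows(parts$m, M)
  W <- block_weights(A, partition, scheme = scheme)
  clamp_step <- config$constraint == "nonneg" &&
    config$constraint_timing == "per_step"
  sweep_fun <- function(x) {
    pb_iterate_internal(x, parts, B, partition, W, config$lam,
                        clamp_step, workers)
  }
  run_row_action(parts, B, config, truth, "pb", sweep_fun, partition)
}
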