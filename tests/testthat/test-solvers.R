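test_that("a single projection step lands where the update formula says", {
  # already on the hyperplane: unchanged for any lam
  x <- c(0.3, 0.7)
  a <- c(2, 1)
  p <- sum(a * x)
  expect_equal(art_step(x, a, p, lam = 1.7), x)

  expect_equal(art_step(c(0, 0), c(1, 0), 1, lam = 1), c(1, 0))

  xp <- art_step(c(0, 0), c(1, 1), 2, lam = 0.5)
  expect_equal(xp, c(0.5, 0.5))
  expect_equal(sum(c(1, 1) * xp), 1)   # halfway to the hyperplane

  # lam = 1 projects exactly onto the hyperplane
  set.seed(3)
  for (i in 1:20) {
    a <- stats::rnorm(6)
    p <- stats::rnorm(1)
    x1 <- art_step(stats::rnorm(6), a, p, lam = 1)
    expect_lt(abs(sum(a * x1) - p), 1e-10)
  }

  expect_error(art_step(c(0, 0), c(0, 0), 1), "degenerate")
})

test_that("the constraining operator clamps negatives and is idempotent", {
  expect_equal(constrain(c(-1, 2, 0)), c(0, 2, 0))
  set.seed(5)
  x <- stats::rnorm(50)
  expect_equal(constrain(x), pmax(x, 0))
  expect_equal(constrain(constrain(x)), constrain(x))
  expect_equal(constrain(abs(x)), abs(x))
})

test_that("solver configuration warns outside the convergence interval", {
  expect_warning(solver_config(lam = 2.5), "0 < lambda < 2")
  expect_warning(solver_config(lam = 2), "0 < lambda < 2")
  expect_silent(solver_config(lam = 1.99))
  expect_error(solver_config(lam = -1))
})

test_that("ART solves orthogonal and random consistent systems", {
  # axes-aligned 2x2 system {x = 1, y = 1}
  A <- methods::as(methods::as(Matrix::Matrix(diag(2), sparse = TRUE),
                               "generalMatrix"), "RsparseMatrix")
  r <- art_solve(A, c(1, 1),
                 solver_config(lam = 1, constraint = "none",
                               max_iterations = 2))
  expect_equal(r$x, c(1, 1), tolerance = 1e-8)

  # dense consistent 5x4 system: Kaczmarz converges to the LS oracle
  sys <- random_consistent_system(5, 4, seed = 21)
  oracle <- qr.solve(sys$A, sys$b)
  As <- methods::as(methods::as(Matrix::Matrix(sys$A, sparse = TRUE),
                                "generalMatrix"), "RsparseMatrix")
  r <- art_solve(As, sys$b,
                 solver_config(lam = 1, constraint = "none",
                               max_iterations = 500, record_residual = FALSE),
                 truth = sys$x)
  expect_lt(max(abs(r$x - oracle)), 1e-6)
  expect_lt(r$history$delta[r$iterations_run], 1e-6)
})

test_that("solver results satisfy their structural contract", {
  sys <- tiny_system()
  cfg <- solver_config(lam = 1.2, max_iterations = 25)
  r <- art_solve(sys$A, sys$B, cfg, truth = sys$truth)
  expect_s3_class(r, "recon_result")
  expect_equal(nrow(r$history), r$iterations_run)
  expect_equal(names(r$history),
               c("iteration", "delta", "relative_residual", "seconds_elapsed"))
  expect_true(all(r$x >= 0))
  expect_true(all(diff(r$history$seconds_elapsed) >= 0))
  # residual history is recorded and broadly decreasing on this easy system
  expect_lt(r$history$relative_residual[25],
            r$history$relative_residual[1])

  expect_error(art_solve(sys$A, sys$B[-1], cfg), "nrow")
  expect_error(
    art_solve(sys$A, sys$B, solver_config(stop_delta = 0.1)),
    "requires a truth")
})

test_that("per-step distance to the solution never increases for 0 < lam < 2", {
  sys <- random_consistent_system(6, 4, seed = 8)
  sol <- qr.solve(sys$A, sys$b)
  for (lam in c(0.5, 1, 1.5)) {
    x <- rep(0, 4)
    d_prev <- sqrt(sum((x - sol)^2))
    for (sweep in 1:3) {
      for (i in 1:6) {
        x <- art_step(x, sys$A[i, ], sys$b[i], lam = lam)
        d <- sqrt(sum((x - sol)^2))
        expect_lte(d, d_prev + 1e-12)
        d_prev <- d
      }
    }
  }
})

test_that("ART with lam = 1 and the Kaczmarz path produce identical iterates", {
  sys <- tiny_system(n = 6, pkt = 5)
  for (k in c(1, 3, 7)) {
    a <- art_solve(sys$A, sys$B,
                   solver_config(lam = 1, constraint = "none",
                                 max_iterations = k))
    kz <- kaczmarz_solve(sys$A, sys$B, max_iterations = k)
    expect_identical(a$x, kz$x)
  }
})

test_that("row partitions are contiguous, disjoint and balanced", {
  p <- partition_rows(10, 2)
  expect_equal(p$starts, c(0L, 5L, 10L))
  expect_equal(partition_rows(10, 3)$sizes, c(4L, 3L, 3L))
  expect_equal(partition_rows(5, 5)$sizes, rep(1L, 5))
  expect_equal(sum(partition_rows(2497, 7)$sizes), 2497L)
  expect_error(partition_rows(5, 6), "1 <= M <= m_rows")
  expect_error(partition_rows(5, 0), "1 <= M <= m_rows")
})

test_that("block weights are column-sum fractions summing to one", {
  # hand example: two rows, one column never touched
  A <- methods::as(methods::as(Matrix::Matrix(matrix(c(1, 0, 3, 0), 2, 2,
                                                     byrow = TRUE),
                                              sparse = TRUE),
                               "generalMatrix"), "RsparseMatrix")
  part <- partition_rows(2, 2)
  W <- block_weights(A, part)
  expect_equal(W[, 1], c(0.25, 0.75))
  expect_equal(W[, 2], c(0.5, 0.5))    # untouched column gets 1/M

  # M = 1: identity on every touched column
  sys <- tiny_system(n = 6, pkt = 5)
  W1 <- block_weights(sys$A, partition_rows(nrow(sys$A), 1))
  expect_equal(unname(W1[1, ]), rep(1, ncol(sys$A)))

  # partition of unity on random block counts
  for (M in c(2, 3, 5)) {
    W <- block_weights(sys$A, partition_rows(nrow(sys$A), M))
    expect_true(all(W >= 0 & W <= 1))
    expect_equal(unname(colSums(W)), rep(1, ncol(sys$A)), tolerance = 1e-12)
  }

  # uniform scheme is plain averaging
  Wu <- block_weights(sys$A, partition_rows(nrow(sys$A), 4),
                      scheme = "uniform")
  expect_true(all(Wu == 0.25))
})

test_that("one parallel-block iteration matches a dense evaluation", {
  # 4x2 toy system split into two blocks
  Ad <- matrix(c(1, 0.5,
                 0.2, 1,
                 1, 1,
                 0.7, 0.1), 4, 2, byrow = TRUE)
  b <- c(1, 0.8, 1.5, 0.4)
  As <- methods::as(methods::as(Matrix::Matrix(Ad, sparse = TRUE),
                                "generalMatrix"), "RsparseMatrix")
  part <- partition_rows(4, 2)
  W <- block_weights(As, part)
  x0 <- c(0.2, 0.1)
  for (nonneg in c(TRUE, FALSE)) {
    cfg <- solver_config(lam = 1.3,
                         constraint = if (nonneg) "nonneg" else "none")
    got <- pb_iterate(x0, As, b, part, W, cfg)
    want <- dense_pb_iteration(Ad, b, x0, part$starts, W, 1.3, nonneg)
    expect_equal(got, want, tolerance = 1e-14)
  }
})

test_that("PB with one block reproduces ART bitwise", {
  sys <- tiny_system(n = 8, pkt = 6)
  cfg <- solver_config(lam = 1.4, max_iterations = 12)
  a <- art_solve(sys$A, sys$B, cfg, truth = sys$truth)
  p <- pb_solve(sys$A, sys$B, M = 1, cfg, truth = sys$truth)
  expect_identical(a$x, p$x)
  expect_identical(a$history$delta, p$history$delta)
})

test_that("PB results are invariant to the worker count", {
  sys <- tiny_system(n = 8, pkt = 6)
  cfg <- solver_config(lam = 1.5, max_iterations = 8)
  runs <- lapply(c(1L, 2L, 3L), function(w) {
    pb_solve(sys$A, sys$B, M = 3, cfg, truth = sys$truth, workers = w)
  })
  expect_identical(runs[[1]]$x, runs[[2]]$x)
  expect_identical(runs[[1]]$x, runs[[3]]$x)
  expect_identical(runs[[1]]$history$delta, runs[[2]]$history$delta)
  expect_identical(runs[[1]]$history$delta, runs[[3]]$history$delta)
})

test_that("stop rules halt at iteration boundaries", {
  sys <- tiny_system(n = 8, pkt = 6)
  r <- art_solve(sys$A, sys$B,
                 solver_config(lam = 1, max_iterations = 2000,
                               stop_delta = 0.1, record_residual = FALSE),
                 truth = sys$truth)
  expect_true(r$converged)
  expect_lt(r$history$delta[r$iterations_run], 0.1)
  if (r$iterations_run > 1) {
    expect_gte(r$history$delta[r$iterations_run - 1], 0.1)
  }

  r2 <- art_solve(sys$A, sys$B,
                  solver_config(lam = 1, max_iterations = 2000,
                                stop_residual = 1e-3))
  expect_true(r2$converged)
  expect_lt(r2$history$relative_residual[r2$iterations_run], 1e-3)
})

test_that("column-sum weighting outpaces plain averaging as blocks are added", {
  sys <- tiny_system(n = 16, pkt = 14)
  cfg <- solver_config(lam = 1, max_iterations = 5000, stop_delta = 0.1,
                       record_residual = FALSE)
  runs <- lapply(c("colsum", "uniform"), function(s) {
    pb_solve(sys$A, sys$B, M = 3, cfg, truth = sys$truth, scheme = s)
  })
  expect_true(all(vapply(runs, `[[`, logical(1), "converged")))
  expect_lt(runs[[1]]$iterations_run, runs[[2]]$iterations_run)
})
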