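test_that("effective rank matches its analytic and oracle values", {
  expect_equal(effective_rank(diag(4)), 4)
  u <- c(1.3, 0.7, 2.1, 0.4); v <- c(0.9, 1.8, 0.6)
  expect_equal(effective_rank(outer(u, v)), 1, tolerance = 1e-9)

  # independent oracle: singular values from eigendecomposition of X^T X
  x <- withr::with_seed(42, matrix(rnorm(30), 6, 5))
  ev <- eigen(t(x) %*% x, symmetric = TRUE)$values
  d <- sqrt(pmax(ev, 0))
  p <- d / sum(d); p <- p[p > 0]
  expect_equal(effective_rank(x), exp(-sum(p * log(p))), tolerance = 1e-9)

  # scale invariance and range
  expect_equal(effective_rank(3.7 * x), effective_rank(x), tolerance = 1e-9)
  expect_gte(effective_rank(x), 1)
  expect_lte(effective_rank(x), 5)
  expect_error(effective_rank(matrix(0, 3, 3)), "undefined singular-value")
})

test_that("rank selection uses rank 2 below the small-study threshold", {
  for (n in c(2, 6, 12, 19))
    expect_identical(select_rank(rand_intensity(40, n, miss = 0.1, seed = n)), 2L)

  # above the threshold the rounded effective rank of the provisional
  # completion is used, clipped to [2, min(m, n) - 1]
  x <- rand_intensity(60, 25, miss = 0.1, seed = 9)
  filled <- x$values
  rm <- rowMeans(filled, na.rm = TRUE)
  filled[is.na(filled)] <- matrix(rm, nrow(filled), ncol(filled))[is.na(filled)]
  er <- effective_rank(filled)
  expect_identical(select_rank(x), max(2L, min(as.integer(round(er)), 24L)))
})

test_that("one ALS half-step equals the closed-form ridge solution", {
  x <- withr::with_seed(3, matrix(rnorm(12), 4, 3))
  u <- qr.Q(qr(withr::with_seed(4, matrix(rnorm(8), 4, 2))))
  d <- c(1, 1); lam <- 0.5
  b <- als_half_step(x, u, d, lam, side = "B")
  # normal-equations oracle: minimize ||X - A0 B^T||^2 + lam ||B||^2, A0 = U D
  a0 <- u %*% diag(d)
  b_oracle <- t(solve(t(a0) %*% a0 + lam * diag(2), t(a0) %*% x))
  expect_equal(b, b_oracle, tolerance = 1e-10)

  # A-side: minimize ||X - A B0^T||^2 + lam ||A||^2 with B0 = V D orthonormal V
  v <- qr.Q(qr(withr::with_seed(5, matrix(rnorm(6), 3, 2))))
  a <- als_half_step(x, v, d, lam, side = "A")
  b0 <- v %*% diag(d)
  a_oracle <- t(solve(t(b0) %*% b0 + lam * diag(2), t(b0) %*% t(x)))
  expect_equal(a, a_oracle, tolerance = 1e-10)
})

test_that("softImpute-ALS fits exact low-rank structure", {
  # complete 5x4 matrix of exact rank 2, lam = 0
  a <- withr::with_seed(1, matrix(rnorm(10), 5, 2))
  b <- withr::with_seed(2, matrix(rnorm(8), 4, 2))
  x <- a %*% t(b)
  fit <- softimpute_als(x, rank = 2, lam = 0, tol = 1e-12, max_iter = 300, seed = 1)
  expect_lt(sqrt(sum((x - reconstruct(fit))^2)), 1e-6)

  # rank-1 completion recovers the masked entry in closed form
  u <- c(1.5, 2.5, 0.8, 1.1, 3.0); v <- c(1.2, 0.7, 2.2, 0.9)
  x1 <- outer(u, v); x1[2, 3] <- NA
  fit1 <- softimpute_als(x1, rank = 1, lam = 0, tol = 1e-12, max_iter = 500, seed = 1)
  expect_equal(reconstruct(fit1)[2, 3], u[2] * v[3], tolerance = 1e-6)

  # complete matrix at full rank, lam = 0: exact reconstruction
  xf <- withr::with_seed(8, matrix(rnorm(30), 6, 5))
  ff <- softimpute_als(xf, rank = 5, lam = 0, tol = 1e-12, max_iter = 200, seed = 2)
  expect_lt(max(abs(xf - reconstruct(ff))), 1e-6)
})

test_that("the completion objective is non-increasing and seeded fits reproduce", {
  for (s in 1:20) {
    x <- rand_intensity(30, 8, miss = 0.2, seed = 100 + s)
    fit <- suppressWarnings(
      softimpute_als(x, rank = 2, lam = 0.1, tol = 1e-7, max_iter = 60, seed = s))
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
  }
  x <- rand_intensity(25, 6, miss = 0.2, seed = 77)
  f1 <- softimpute_als(x, rank = 2, seed = 5)
  f2 <- softimpute_als(x, rank = 2, seed = 5)
  expect_identical(f1$A, f2$A)
  expect_identical(f1$B, f2$B)
})

test_that("increasing lambda never increases the solution rank", {
  x <- rand_intensity(20, 8, miss = 0.15, seed = 13)
  nrank <- vapply(c(0, 1, 10, 100), function(l) {
    fit <- suppressWarnings(
      softimpute_als(x, rank = 4, lam = l, tol = 1e-9, max_iter = 200, seed = 3))
    sum(svd(reconstruct(fit))$d > 1e-8)
  }, numeric(1))
  expect_true(all(diff(nrank) <= 0))
})

test_that("non-convergence yields a warning and converged = FALSE, not an error", {
  x <- rand_intensity(40, 8, miss = 0.3, seed = 21)
  expect_warning(
    fit <- softimpute_als(x, rank = 3, lam = 0.1, tol = 1e-14, max_iter = 3, seed = 1),
    "did not converge")
  expect_false(fit$converged)
  expect_length(fit$objective_trace, 3)
})

test_that("reconstruction and objective follow their definitions", {
  model0 <- structure(list(A = matrix(0, 4, 2), B = matrix(1, 3, 2), lam = 0),
                      class = "lowrank_model")
  expect_equal(reconstruct(model0), matrix(0, 4, 3))

  # rank-2 factors built from two outer products
  a <- cbind(c(1, 2, 3), c(0.5, -1, 2)); b <- cbind(c(1, 1), c(2, -0.5))
  model2 <- structure(list(A = a, B = b, lam = 0), class = "lowrank_model")
  expect_equal(reconstruct(model2),
               outer(a[, 1], b[, 1]) + outer(a[, 2], b[, 2]), tolerance = 1e-12)

  # block-wise product agrees with the one-shot product
  x <- rand_intensity(20, 6, miss = 0.1, seed = 31)
  fit <- softimpute_als(x, rank = 2, seed = 1)
  full <- reconstruct(fit)
  blocks <- rbind(fit$A[1:10, ] %*% t(fit$B), fit$A[11:20, ] %*% t(fit$B))
  expect_equal(full, blocks, ignore_attr = TRUE, tolerance = 1e-12)

  # objective: perfect fit at lam = 0 is zero; A = B = 0 gives half the
  # observed sum of squares; general case matches an elementwise loop
  xc <- intensity_matrix(matrix(c(1, 2, 3, 4), 2, 2))
  mfit <- structure(list(A = matrix(c(1, 2), 2, 1), B = matrix(c(1, 2), 2, 1),
                         lam = 0), class = "lowrank_model")
  expect_equal(lowrank_objective(mfit, intensity_matrix(matrix(c(1, 2, 2, 4), 2, 2))), 0)
  zfit <- structure(list(A = matrix(0, 2, 1), B = matrix(0, 2, 1), lam = 0),
                    class = "lowrank_model")
  expect_equal(lowrank_objective(zfit, xc), 0.5 * sum(xc$values^2))

  x <- rand_intensity(10, 5, miss = 0.2, seed = 41)
  rmod <- structure(list(A = withr::with_seed(1, matrix(rnorm(20), 10, 2)),
                         B = withr::with_seed(2, matrix(rnorm(10), 5, 2)),
                         lam = 1), class = "lowrank_model")
  fitmat <- rmod$A %*% t(rmod$B)
  loop <- 0
  for (i in 1:10) for (k in 1:5)
    if (x$mask[i, k]) loop <- loop + 0.5 * (x$values[i, k] - fitmat[i, k])^2
  loop <- loop + 0.5 * 1 * (sum(rmod$A^2) + sum(rmod$B^2))
  expect_equal(lowrank_objective(rmod, x), loop, tolerance = 1e-10)
})
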