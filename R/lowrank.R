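#' Effective rank of a complete matrix
#'
#' `erank(X) = exp(H(p))` where `p_k = xi_k / sum(xi)` is the normalized
#' singular-value distribution of `X` and `H` the Shannon entropy (natural
#' log; zero singular values contribute nothing). A continuous surrogate for
#' matrix rank: `1 <= erank(X) <= min(m, n)`, equal to the number of equal
#' nonzero singular values when the spectrum is flat.
#'
#' @param x a complete numeric matrix (no `NA`s), not all zero.
#' @return the effective rank, a real in `[1, min(m, n)]`.
#' @examples
#' effective_rank(diag(4))            # 4: flat spectrum
#' effective_rank(outer(1:5, 1:3))    # 1: rank one
#' @export
effective_rank <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (anyNA(x)) stop("effective_rank needs a complete matrix")
  d <- svd(x, nu = 0, nv = 0)$d
  if (sum(d) <= 0) stop("undefined singular-value distribution (all-zero matrix)")
  p <- d / sum(d)
  p <- p[p > 0]
  exp(-sum(p * log(p)))
}

# fill missing entries with the peptide's observed mean; rows with no
# observation fall back to the column mean, then the grand mean
provisional_complete <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  v <- x$values
  rmean <- rowMeans(v, na.rm = TRUE)
  cmean <- colMeans(v, na.rm = TRUE)
  cmean[is.nan(cmean)] <- mean(v, na.rm = TRUE)
  fill <- matrix(rmean, nrow(v), ncol(v))
  bad <- is.nan(rmean)
  if (any(bad)) fill[bad, ] <- matrix(cmean, sum(bad), ncol(v), byrow = TRUE)
  v[!x$mask] <- fill[!x$mask]
  v
}

#' Select the rank of the low-rank model
#'
#' Small studies (fewer than `small_study_threshold` LC-MS runs) get a
#' rank-2 model: effective-rank estimates are unreliable at such sample
#' sizes and rank-2 reconstructions track low-abundance variability better.
#' Larger studies use the rounded effective rank of a provisionally
#' completed matrix (missing entries filled with peptide observed means),
#' clipped to `[2, min(m, n) - 1]`. Rounding is round-half-to-even.
#'
#' @param x an [intensity_matrix()].
#' @param small_study_threshold run-count cutoff below which rank 2 is
#'   always used (default 20).
#' @return an integer rank >= 2.
#' @export
select_rank <- function(x, small_study_threshold = 20L) {
  stopifnot(inherits(x, "intensity_matrix"))
  n <- ncol(x$values)
  if (n < small_study_threshold) return(2L)
  er <- effective_rank(provisional_complete(x))
  r <- as.integer(round(er))
  max(2L, min(r, min(dim(x$values)) - 1L))
}

# exact ridge half-steps: with A = U D (U orthonormal), the minimizer of
# ||Xstar - U D B^T||_F^2 + lam ||B||_F^2 is B^T = (D^2 + lam I)^-1 D U^T Xstar
ridge_update_b <- function(xstar, u, d, lam) {
  coef <- d / (d^2 + lam)
  coef[!is.finite(coef)] <- 0      # null component (d = 0, lam = 0)
  t(coef * (t(u) %*% xstar))
}
ridge_update_a <- function(xstar, v, d, lam) {
  coef <- d / (d^2 + lam)
  coef[!is.finite(coef)] <- 0
  xstar %*% v %*% diag(coef, length(d))
}

#' One ALS half-step of the matrix-completion solver
#'
#' Exposes the closed-form multiresponse ridge solution used inside
#' [softimpute_als()]: given the current orthonormal factor and singular
#' values, solve exactly for the opposite factor on a fully-filled matrix.
#' Mainly useful for verification and teaching.
#'
#' @param xstar complete numeric matrix (missing entries already filled at
#'   their current fitted values).
#' @param u,d orthonormal factor (`m x r` for side "B", `n x r` for side
#'   "A") and the length-`r` vector of current singular values.
#' @param lam ridge penalty.
#' @param side which factor to solve for.
#' @return the updated factor (`n x r` for side "B", `m x r` for side "A").
#' @export
als_half_step <- function(xstar, u, d, lam, side = c("B", "A")) {
  side <- match.arg(side)
  if (side == "B") ridge_update_b(xstar, u, d, lam)
  else ridge_update_a(xstar, u, d, lam)
}

#' Low-rank matrix completion by softImpute-ALS
#'
#' Fits factors `A` (`m x r`) and `B` (`n x r`) minimizing
#' `1/2 ||P_Omega(X - A B^T)||_F^2 + lam/2 (||A||_F^2 + ||B||_F^2)`,
#' where `P_Omega` projects onto the observed entries. The solver
#' alternates two exact multiresponse ridge regressions on a working matrix
#' whose missing entries are filled with the current fitted values, each
#' followed by an SVD re-orthogonalization that preserves the product
#' `A B^T` (the standard softImpute-ALS scheme). `A = U D` is initialized
#' with a random orthonormal `U` and `D = I`; `B` starts at zero. Each
#' half-step solves its subproblem exactly, so the objective is
#' non-increasing; iteration stops when its relative change drops below
#' `tol`.
#'
#' @param x an [intensity_matrix()] (or numeric matrix with `NA`s) on the
#'   log2 scale.
#' @param rank number of factors `r <= min(m, n)`.
#' @param lam nonnegative ridge/shrinkage penalty. Default 0.1: rank is
#'   controlled by `rank`, a small penalty just stabilizes the solves.
#' @param tol relative-objective-change convergence tolerance.
#' @param max_iter iteration cap; on hitting it a warning (not an error) is
#'   raised and the model is returned with `converged = FALSE`.
#' @param seed integer seed for the random orthonormal initialization;
#'   identical seeds give bit-identical fits.
#' @return a `lowrank_model`: list with `A`, `B`, `U`, `D`, `V`, `lam`,
#'   `rank`, `objective_trace`, `n_iter`, `converged`, plus the row/column
#'   ids.
#' @export
softimpute_als <- function(x, rank, lam = 0.1, tol = 1e-5, max_iter = 100L,
                           seed = 1L) {
  if (inherits(x, "intensity_matrix")) {
    X <- x$values; mask <- x$mask
    pid <- x$peptide_ids; rid <- x$run_ids
  } else {
    stopifnot(is.matrix(x), is.numeric(x))
    X <- x; mask <- !is.na(x)
    pid <- rownames(x); rid <- colnames(x)
  }
  m <- nrow(X); n <- ncol(X)
  rank <- as.integer(rank)
  if (rank < 1L || rank > min(m, n))
    stop("'rank' must be in [1, min(m, n)]")
  if (lam < 0) stop("'lam' must be nonnegative")
  X0 <- X; X0[!mask] <- 0

  U <- withr::with_seed(seed, qr.Q(qr(matrix(stats::rnorm(m * rank), m, rank))))
  d <- rep(1, rank)
  V <- matrix(0, n, rank)

  obj <- function(U, d, V) {
    fit <- U %*% (d * (d * t(V)))          # A B^T = U D^2 V^T
    res <- (X0 - fit)[mask]
    0.5 * sum(res^2) + 0.5 * lam * 2 * sum(d^2)   # ||A||^2 + ||B||^2 = 2 sum d^2
  }

  trace <- numeric(0)
  f_prev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # --- B-step ---
    fit <- U %*% (d * (d * t(V)))
    Xstar <- X0; Xstar[!mask] <- fit[!mask]
    Btilde <- ridge_update_b(Xstar, U, d, lam)            # n x r
    s <- svd(Btilde %*% diag(d, rank))                    # Btilde D = V~ D~^2 R^T
    V <- s$u
    U <- U %*% s$v                                        # rotation keeps A B^T fixed
    d <- sqrt(s$d)
    # --- A-step ---
    fit <- U %*% (d * (d * t(V)))
    Xstar <- X0; Xstar[!mask] <- fit[!mask]
    Atilde <- ridge_update_a(Xstar, V, d, lam)            # m x r
    s <- svd(Atilde %*% diag(d, rank))                    # Atilde D = U~ D~^2 R^T
    U <- s$u
    V <- V %*% s$v
    d <- sqrt(s$d)

    f <- obj(U, d, V)
    trace <- c(trace, f)
    if (is.finite(f_prev) && abs(f_prev - f) <= tol * max(f_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    f_prev <- f
  }
  if (!converged)
    warning(sprintf("softimpute_als did not converge in %d iterations", max_iter))

  A <- U %*% diag(d, rank)
  B <- V %*% diag(d, rank)
  structure(list(A = A, B = B, U = U, D = d, V = V, lam = lam, rank = rank,
                 objective_trace = trace, n_iter = it, converged = converged,
                 peptide_ids = pid, run_ids = rid),
            class = "lowrank_model")
}

#' @export
print.lowrank_model <- function(x, ...) {
  cat(sprintf("lowrank_model: rank %d, lambda %g, %d iterations (%s), objective %.6g\n",
              x$rank, x$lam, x$n_iter,
              if (x$converged) "converged" else "NOT converged",
              utils::tail(x$objective_trace, 1)))
  invisible(x)
}

#' Reconstruct the complete matrix from a fitted low-rank model
#'
#' @param model a fitted `lowrank_model`.
#' @return the complete `m x n` matrix `A %*% t(B)`, with ids as dimnames
#'   when available.
#' @export
reconstruct <- function(model) {
  stopifnot(inherits(model, "lowrank_model"))
  out <- model$A %*% t(model$B)
  if (!is.null(model$peptide_ids) && !is.null(model$run_ids))
    dimnames(out) <- list(model$peptide_ids, model$run_ids)
  out
}

#' Evaluate the regularized completion objective
#'
#' `1/2 ||P_Omega(X - A B^T)||_F^2 + lam/2 (||A||_F^2 + ||B||_F^2)`,
#' summing squared residuals over observed entries only.
#'
#' @param model a `lowrank_model`.
#' @param x the [intensity_matrix()] (or `NA`-holed matrix) it was fitted to.
#' @return the objective value (nonnegative real).
#' @export
lowrank_objective <- function(model, x) {
  stopifnot(inherits(model, "lowrank_model"))
  if (inherits(x, "intensity_matrix")) {
    X <- x$values; mask <- x$mask
  } else {
    X <- x; mask <- !is.na(x)
  }
  fit <- model$A %*% t(model$B)
  res <- (X - fit)[mask]
  0.5 * sum(res^2) + 0.5 * model$lam * (sum(model$A^2) + sum(model$B^2))
}
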