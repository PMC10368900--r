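#' Down-shift imputation parameters
#'
#' The down-shift approach replaces the missing values of run `k` with
#' independent draws from `Normal(xbar_k - shift * sdhat_k,
#' (width * sdhat_k)^2)`, where `xbar_k` and `sdhat_k` are the mean and
#' sample standard deviation of the run's observed log2 intensities. The
#' defaults `shift = 1.8` and `width = 0.3` are the conventional
#' left-censoring calibration: draws land 1.8 observed-sd below the run
#' mean, in a distribution 0.3 times as wide.
#'
#' @param shift nonnegative downward shift `s`, in units of the within-run
#'   observed standard deviation.
#' @param width positive width multiplier `w` (dimensionless).
#' @param seed integer seed making draws reproducible.
#' @return a `downshift_params` list.
#' @export
downshift_params <- function(shift = 1.8, width = 0.3, seed = 1L) {
  if (!is.numeric(shift) || length(shift) != 1L || shift < 0)
    input_error("'shift' must be a nonnegative number")
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    input_error("'width' must be a positive number")
  structure(list(shift = shift, width = width, seed = as.integer(seed)),
            class = "downshift_params")
}

#' Per-run mean and standard deviation of observed intensities
#'
#' @param x an [intensity_matrix()] on the log2 scale; every run must have
#'   at least 2 observed entries.
#' @return a data.frame with columns `run`, `n_observed`, `mean`, `sd`
#'   (sample sd, `n - 1` denominator).
#' @export
column_stats <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  nobs <- colSums(x$mask)
  if (any(nobs < 2L))
    stop(paste0("run(s) with fewer than 2 observed values: ",
                paste(x$run_ids[nobs < 2L], collapse = ", ")))
  mu <- colMeans(x$values, na.rm = TRUE)
  sdv <- apply(x$values, 2, stats::sd, na.rm = TRUE)
  data.frame(run = x$run_ids, n_observed = as.integer(nobs),
             mean = unname(mu), sd = unname(sdv),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Impute missing values by the down-shift approach
#'
#' Each missing entry in run `k` is an independent draw from
#' `Normal(mean_k - shift * sd_k, (width * sd_k)^2)` computed from the
#' run's observed values (a degenerate run with `sd = 0` yields the shifted
#' mean exactly). Observed entries are copied unchanged. Runs are imputed
#' independently: the target "multivariate normal" has diagonal covariance,
#' as only a mean vector and an sd vector are parameterized.
#'
#' @param x an [intensity_matrix()] on the log2 scale.
#' @param params a [downshift_params()]; or override via `...` shortcut
#'   arguments `shift`, `width`, `seed`.
#' @param shift,width,seed used when `params` is missing.
#' @return the complete `m x n` numeric matrix.
#' @export
downshift_impute <- function(x, params = downshift_params(shift, width, seed),
                             shift = 1.8, width = 0.3, seed = 1L) {
  stopifnot(inherits(x, "intensity_matrix"), inherits(params, "downshift_params"))
  cs <- column_stats(x)
  out <- x$values
  withr::with_seed(params$seed, {
    for (k in seq_len(ncol(out))) {
      miss <- !x$mask[, k]
      if (!any(miss)) next
      out[miss, k] <- stats::rnorm(sum(miss),
                                   mean = cs$mean[k] - params$shift * cs$sd[k],
                                   sd = params$width * cs$sd[k])
    }
  })
  dimnames(out) <- list(x$peptide_ids, x$run_ids)
  out
}
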