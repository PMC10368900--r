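#' Per-peptide mean and squared coefficient of variation, pre and post imputation
#'
#' For each peptide: the mean and squared coefficient of variation
#' (`CV^2 = (sd/mean)^2`, sample sd) of its log2 intensities, computed on
#' the observed values only and, when an imputation result is supplied, on
#' the completed row. Plotting post-imputation `CV^2` against mean
#' abundance (with a loess trend) reveals imputation-induced variance
#' distortion: over-smoothing pulls `CV^2` below the observed trend, while
#' banding at low abundance flags biased reconstruction.
#'
#' @param x the pre-imputation [intensity_matrix()] (log2 scale).
#' @param result optionally, the [barycenter_impute()] result for the same
#'   matrix; adds `mean_imputed`, `cv2_imputed`, `ebm`, `mv_type` columns.
#' @param trend if `TRUE`, adds a loess trend (span 0.75) of `CV^2` on mean
#'   abundance as column `cv2_trend` (observed columns; plus
#'   `cv2_imputed_trend` when `result` is given). Visualization aid only.
#' @param linear_scale compute CV on `2^value` instead of the log2 values.
#'   Off by default: the diagnostic pairs average log intensity with the CV
#'   of those same log values.
#' @return a data.frame with one row per peptide. Peptides whose mean is 0
#'   get `NA` for `CV^2` and are excluded from the trend.
#' @export
mean_cv_table <- function(x, result = NULL, trend = FALSE, linear_scale = FALSE) {
  stopifnot(inherits(x, "intensity_matrix"))
  tf <- if (linear_scale) function(v) 2^v else identity
  row_stats <- function(vals, mask) {
    mu <- cv2 <- rep(NA_real_, nrow(vals))
    for (i in seq_len(nrow(vals))) {
      v <- tf(vals[i, mask[i, ]])
      if (length(v) == 0L) next
      mu[i] <- mean(v)
      s <- if (length(v) >= 2L) stats::sd(v) else 0
      cv2[i] <- if (mu[i] == 0) NA_real_ else (s / mu[i])^2
    }
    list(mean = mu, cv2 = cv2)
  }
  obs <- row_stats(x$values, x$mask)
  out <- data.frame(peptide_id = x$peptide_ids,
                    n_observed = rowSums(x$mask),
                    mean_observed = obs$mean, cv2_observed = obs$cv2,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(result)) {
    stopifnot(inherits(result, "imputation_result"))
    if (!identical(dim(result$completed), dim(x$values)))
      stop("imputation result does not match the matrix shape")
    full <- matrix(TRUE, nrow(x$values), ncol(x$values))
    post <- row_stats(result$completed, full)
    out$mean_imputed <- post$mean
    out$cv2_imputed <- post$cv2
    out$ebm <- result$annotations$ebm
    out$mv_type <- result$annotations$mv_type
  }
  if (trend) {
    out$cv2_trend <- loess_trend(out$mean_observed, out$cv2_observed)
    if (!is.null(result))
      out$cv2_imputed_trend <- loess_trend(out$mean_imputed, out$cv2_imputed)
  }
  out
}

loess_trend <- function(x, y, span = 0.75) {
  ok <- is.finite(x) & is.finite(y)
  pred <- rep(NA_real_, length(x))
  if (sum(ok) >= 10) {
    fit <- stats::loess(y[ok] ~ x[ok], span = span, degree = 2)
    pred[ok] <- stats::predict(fit)
  }
  pred
}

#' Missingness composition summary
#'
#' Three tables describing where and how values are missing: the per-run
#' missing fraction, counts of peptides by missingness type (`complete`,
#' `random`, `group_specific`, classified by the entropy of mixing), and a
#' long table of per-peptide mean observed abundance by type, ready for
#' violin plots comparing the abundance of randomly-missing versus
#' group-specifically-missing peptides.
#'
#' @param x an [intensity_matrix()] (log2 scale).
#' @param design a [group_design()] covering all runs.
#' @return a list with data.frames `runs` (`run`, `group`, `n_missing`,
#'   `missing_fraction`), `types` (`mv_type`, `count`), and
#'   `abundance_by_type` (`peptide_id`, `mv_type`, `mean_observed`).
#' @export
missingness_summary <- function(x, design) {
  stopifnot(inherits(x, "intensity_matrix"))
  check_design(x, design)
  nmiss <- colSums(!x$mask)
  runs <- data.frame(run = x$run_ids, group = run_groups(x, design),
                     n_missing = as.integer(nmiss),
                     missing_fraction = unname(nmiss) / nrow(x$values),
                     stringsAsFactors = FALSE, row.names = NULL)
  cls <- classify_missingness(x, design)
  lv <- c("complete", "random", "group_specific")
  types <- data.frame(mv_type = lv,
                      count = as.integer(table(factor(cls$mv_type, levels = lv))),
                      stringsAsFactors = FALSE, row.names = NULL)
  abundance <- data.frame(peptide_id = x$peptide_ids, mv_type = cls$mv_type,
                          mean_observed = rowMeans(x$values, na.rm = TRUE),
                          stringsAsFactors = FALSE, row.names = NULL)
  list(runs = runs, types = types, abundance_by_type = abundance)
}
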