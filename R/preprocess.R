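#' Log2-transform observed intensities
#'
#' Applies log base 2 to every observed entry; the mask is unchanged. A
#' warning is raised when the largest observed value is below 64 (2^6),
#' which usually means the matrix is already on the log scale.
#'
#' @param x an [intensity_matrix()] of raw-scale intensities (all observed
#'   entries strictly positive; treat zeros as missing in the reader).
#' @return an [intensity_matrix()] on the log2 scale.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  obs <- x$values[x$mask]
  if (length(obs) && any(obs <= 0))
    stop("observed entries must be > 0 for log2 (zeros should be treated as missing)")
  if (length(obs) && max(obs) < 64)
    warning("max observed intensity < 64; values may already be log2-scale")
  v <- x$values
  v[x$mask] <- log2(v[x$mask])
  intensity_matrix(v, mask = x$mask, peptide_ids = x$peptide_ids,
                   run_ids = x$run_ids)
}

#' Drop peptides with too few observed values
#'
#' Low-rank completion needs enough observed entries per peptide to
#' constrain its factor row; peptides below the threshold are removed
#' (relative order of survivors preserved). The ids of removed peptides are
#' attached as attribute `"removed_peptides"`.
#'
#' @param x an [intensity_matrix()].
#' @param min_observed minimum number of observed entries a peptide must
#'   have to be kept. Default 4, the smallest count that meaningfully
#'   constrains a rank-2 model.
#' @return the filtered [intensity_matrix()] with attribute
#'   `removed_peptides`.
#' @export
filter_min_observed <- function(x, min_observed = 4L) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (min_observed < 1L) input_error("'min_observed' must be >= 1")
  keep <- rowSums(x$mask) >= min_observed
  if (!any(keep)) stop("no peptides survive filtering")
  out <- intensity_matrix(x$values[keep, , drop = FALSE],
                          mask = x$mask[keep, , drop = FALSE],
                          peptide_ids = x$peptide_ids[keep],
                          run_ids = x$run_ids)
  attr(out, "removed_peptides") <- x$peptide_ids[!keep]
  out
}

#' Quantile-normalize a completed intensity matrix
#'
#' Forces every run (column) onto a common distribution: after
#' normalization each column's sorted values equal the across-column mean of
#' sorted values; tied values within a column receive the mean of the
#' reference values over the tied span. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' The imputation pipeline runs log2 -> impute -> quantile-normalize, so by
#' default the matrix must be complete; set `allow_missing = TRUE` to
#' normalize an incomplete matrix from its observed entries only
#' (quantile-interpolated), for workflows that normalize before imputing.
#'
#' @param x an [intensity_matrix()].
#' @param allow_missing permit masked entries (normalization statistics then
#'   use observed values only).
#' @return a quantile-normalized [intensity_matrix()].
#' @export
quantile_normalize <- function(x, allow_missing = FALSE) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (!allow_missing && !all(x$mask))
    stop("quantile normalization requires a complete matrix")
  v <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(v) <- dimnames(x$values)
  intensity_matrix(v, mask = x$mask, peptide_ids = x$peptide_ids,
                   run_ids = x$run_ids)
}
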