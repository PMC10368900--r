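#' Entropy of mixing of a peptide's missingness pattern
#'
#' For peptide `i` with observed fraction `m_ig` in group `g`,
#' `EBM_i = sum_g m_ig * log(m_ig)` (natural log). A finite EBM means every
#' group retains at least one observation -- the missing values are spread
#' across groups, evidence of a random (MAR-like) mechanism. If any group
#' is entirely missing, `m_ig = 0` and EBM is `-Inf`, evidence of a
#' group-specific (MNAR-like) mechanism. Fully observed peptides have
#' `EBM = 0`.
#'
#' @param mask_row logical vector of observed indicators across runs,
#'   preferably named by run id; unnamed vectors are taken in the design's
#'   run order.
#' @param design a [group_design()] covering the runs.
#' @return a value in `[-Inf, 0]`.
#' @examples
#' d <- group_design(c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B"))
#' entropy_of_mixing(c(a1 = TRUE, a2 = TRUE, a3 = FALSE,
#'                     b1 = TRUE, b2 = TRUE, b3 = FALSE), d)
#' @export
entropy_of_mixing <- function(mask_row, design) {
  stopifnot(is.logical(mask_row), inherits(design, "group_design"))
  runs <- names(design$assignment)
  if (is.null(names(mask_row))) {
    if (length(mask_row) != length(runs))
      input_error("unnamed mask_row must have one entry per design run")
    names(mask_row) <- runs
  } else if (!all(names(mask_row) %in% runs)) {
    input_error("mask_row has runs not covered by the design")
  }
  groups <- design$assignment[names(mask_row)]
  frac <- vapply(design$groups,
                 function(g) mean(mask_row[groups == g]),
                 numeric(1))
  if (any(frac == 0)) return(-Inf)
  sum(ifelse(frac > 0, frac * log(frac), 0))
}

#' Barycenter weights from the entropy of mixing
#'
#' Peptides with finite EBM (missing values spread across groups) weight
#' the low-rank (MAR) estimate by `alpha_when_finite`; peptides with
#' non-finite EBM (a fully-missing group) weight the down-shift (MNAR)
#' estimate by the same amount. The weights are fixed, not adaptively
#' estimated.
#'
#' @param ebm the entropy-of-mixing value (`-Inf` allowed).
#' @param alpha_when_finite the MAR weight used when EBM is finite, in
#'   `[0, 1]`; default 0.8.
#' @return named numeric vector `c(alpha_mar, alpha_mnar)`; the two always
#'   sum to 1 exactly.
#' @export
assign_weights <- function(ebm, alpha_when_finite = 0.8) {
  if (!is.numeric(alpha_when_finite) || alpha_when_finite < 0 || alpha_when_finite > 1)
    input_error("'alpha_when_finite' must be in [0, 1]")
  a_mar <- if (is.finite(ebm)) alpha_when_finite else 1 - alpha_when_finite
  c(alpha_mar = a_mar, alpha_mnar = 1 - a_mar)
}

# per-peptide observed fraction by group: m x G matrix
observed_fraction_by_group <- function(x, design) {
  groups <- run_groups(x, design)
  sapply(design$groups, function(g)
    rowMeans(x$mask[, groups == g, drop = FALSE]))
}

# per-peptide EBM + missingness label from the mask alone
classify_missingness <- function(x, design) {
  frac <- observed_fraction_by_group(x, design)
  if (is.null(dim(frac))) frac <- matrix(frac, ncol = length(design$groups))
  ebm <- apply(frac, 1, function(f) {
    if (any(f == 0)) -Inf else sum(ifelse(f > 0, f * log(f), 0))
  })
  n_missing <- ncol(x$values) - rowSums(x$mask)
  mv_type <- ifelse(n_missing == 0L, "complete",
                    ifelse(is.finite(ebm), "random", "group_specific"))
  list(ebm = ebm, mv_type = mv_type, obs_frac = frac, n_missing = n_missing)
}

#' Impute missing intensities as the barycenter of MAR and MNAR estimates
#'
#' The end-to-end pipeline. A low-rank model (rank chosen by
#' [select_rank()] unless given) is fitted by [softimpute_als()] and its
#' reconstruction taken as the MAR estimate `X_MAR`; the down-shift draw
#' ([downshift_impute()]) is the MNAR estimate `X_MNAR`. Each peptide's
#' entropy of mixing sets its weights, and every missing entry `(i, k)` is
#' imputed as the convex combination
#' `alpha_mar_i * X_MAR[i, k] + alpha_mnar_i * X_MNAR[i, k]` -- the
#' barycenter of the two estimates under squared-Euclidean distance.
#' Observed entries are copied unchanged.
#'
#' The input must already be filtered ([filter_min_observed()]): peptides
#' with too few observations do not admit a stable low-rank solution and
#' must be discarded beforehand.
#'
#' @param x a filtered, log2-scale [intensity_matrix()].
#' @param design a [group_design()] covering all runs.
#' @param rank low-rank model rank; `0` (default) selects automatically.
#' @param lam ridge penalty for [softimpute_als()].
#' @param shift,width down-shift parameters (see [downshift_params()]).
#' @param alpha_when_finite MAR weight for finite-EBM peptides (default 0.8).
#' @param min_observed the filtering threshold the input is checked against.
#' @param tol,max_iter softImpute-ALS convergence controls.
#' @param seed master seed; the ALS initialization uses `seed` and the
#'   down-shift draws `seed + 1`.
#' @return an `imputation_result`: list with `completed` (m x n matrix),
#'   `annotations` (per-peptide data.frame: `peptide_id`, `ebm`, `mv_type`,
#'   `alpha_mar`, `alpha_mnar`, `n_missing`, one `obs_frac_<group>` column
#'   per group), `mar_estimate`, `mnar_estimate`, and `provenance` (full
#'   configuration, seeds, rank, lambda, objective trace, package version).
#' @examples
#' sim <- simulate_dataset(m = 60, runs_per_group = c(3, 3), mar_fraction = 0.1,
#'                         seed = 1)
#' res <- barycenter_impute(sim$matrix, sim$truth$design, seed = 1)
#' res$annotations[1:3, ]
#' @export
barycenter_impute <- function(x, design, rank = 0L, lam = 0.1,
                              shift = 1.8, width = 0.3,
                              alpha_when_finite = 0.8, min_observed = 4L,
                              tol = 1e-5, max_iter = 100L, seed = 1L) {
  stopifnot(inherits(x, "intensity_matrix"))
  check_design(x, design)
  if (!is.numeric(alpha_when_finite) || alpha_when_finite < 0 || alpha_when_finite > 1)
    input_error("'alpha_when_finite' must be in [0, 1]")
  if (any(rowSums(x$mask) < min_observed))
    stop(sprintf(
      "some peptides have fewer than %d observed values; run filter_min_observed() first",
      min_observed))
  seed <- as.integer(seed)

  rank_used <- if (is.null(rank) || rank == 0L) select_rank(x) else as.integer(rank)
  model <- softimpute_als(x, rank = rank_used, lam = lam, tol = tol,
                          max_iter = max_iter, seed = seed)
  x_mar <- reconstruct(model)
  x_mnar <- downshift_impute(x, downshift_params(shift, width, seed + 1L))

  cls <- classify_missingness(x, design)
  a_mar <- ifelse(is.finite(cls$ebm), alpha_when_finite, 1 - alpha_when_finite)

  completed <- x$values
  miss <- !x$mask
  w <- matrix(a_mar, nrow(completed), ncol(completed))
  completed[miss] <- w[miss] * x_mar[miss] + (1 - w[miss]) * x_mnar[miss]
  dimnames(completed) <- list(x$peptide_ids, x$run_ids)

  ann <- data.frame(peptide_id = x$peptide_ids, ebm = cls$ebm,
                    mv_type = cls$mv_type, alpha_mar = a_mar,
                    alpha_mnar = 1 - a_mar, n_missing = cls$n_missing,
                    stringsAsFactors = FALSE, row.names = NULL)
  obs_frac <- cls$obs_frac
  colnames(obs_frac) <- paste0("obs_frac_", design$groups)
  ann <- cbind(ann, as.data.frame(obs_frac, row.names = NULL))

  provenance <- list(
    package = "baryimpute",
    version = as.character(utils::packageVersion("baryimpute")),
    m = nrow(completed), n = ncol(completed),
    groups = design$groups,
    rank_requested = as.integer(rank), rank_used = rank_used,
    lam = lam, shift = shift, width = width,
    alpha_when_finite = alpha_when_finite, min_observed = as.integer(min_observed),
    tol = tol, max_iter = as.integer(max_iter), seed = seed,
    als_seed = seed, downshift_seed = seed + 1L,
    n_iter = model$n_iter, converged = model$converged,
    objective_trace = model$objective_trace)

  structure(list(completed = completed, annotations = ann,
                 mar_estimate = x_mar, mnar_estimate = x_mnar,
                 provenance = provenance),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  tab <- table(x$annotations$mv_type)
  cat(sprintf("imputation_result: %d peptides x %d runs (rank %d, lambda %g)\n",
              x$provenance$m, x$provenance$n, x$provenance$rank_used,
              x$provenance$lam))
  cat("  missingness types:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write an imputation result to disk
#'
#' Writes `completed_matrix.tsv` (wide TSV), `annotations.tsv`, and
#' `provenance.json` under `dir`. Output is byte-identical across repeated
#' runs with the same inputs and seed.
#'
#' @param result an `imputation_result`.
#' @param dir output directory (created if needed).
#' @return the three file paths, invisibly.
#' @export
write_imputation_result <- function(result, dir) {
  stopifnot(inherits(result, "imputation_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "completed_matrix.tsv")
  p2 <- file.path(dir, "annotations.tsv")
  p3 <- file.path(dir, "provenance.json")
  write_wide_matrix(result$completed, p1)
  utils::write.table(result$annotations, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(result$provenance, p3, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(p1, p2, p3))
}
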