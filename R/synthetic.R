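#' Simulate an LFQ-like peptide intensity matrix with known truth
#'
#' Emulates a log2-scale label-free peptide matrix with group structure and
#' the three missingness mechanisms the imputation model distinguishes.
#' Peptide baselines are `Normal(base_mean, peptide_sd^2)`; a `de_fraction`
#' subset of peptides is differentially abundant, shifted by
#' `+/- effect_size` in one randomly chosen group; iid
#' `Normal(0, noise_sd^2)` measurement noise is added. Missingness is then
#' imposed as:
#' \itemize{
#'   \item MAR: uniform Bernoulli(`mar_fraction`) masking;
#'   \item intensity-dependent MNAR: entries are censored with probability
#'     `1 / (1 + exp((value - q) / mnar_tau))`, `q` the
#'     `mnar_censor_quantile` of the complete matrix (0 disables);
#'   \item group-specific MNAR: for a `group_deletion_fraction` subset of
#'     the DE peptides, the down-regulated group's entries are deleted
#'     entirely (their effect sign is forced negative, emulating loss of
#'     signal from down-regulation).
#' }
#' The three masks are disjoint; group deletion takes precedence, then
#' intensity censoring, then MAR.
#'
#' @param m number of peptides.
#' @param runs_per_group integer vector, runs in each group (length = number
#'   of groups).
#' @param base_mean,peptide_sd mean and sd of peptide baseline log2
#'   abundance (defaults 20 and 2, typical MS1 intensity scale).
#' @param noise_sd measurement noise sd on the log2 scale (default 0.5).
#' @param de_fraction fraction of peptides with a group effect.
#' @param effect_size absolute group shift in log2 units (default 3,
#'   spike-in scale).
#' @param mar_fraction uniform missingness probability.
#' @param mnar_censor_quantile quantile of the complete matrix below which
#'   intensity-dependent censoring concentrates (0 = off).
#' @param mnar_tau logistic scale of the censoring curve (log2 units).
#' @param group_deletion_fraction fraction of DE peptides whose affected
#'   group is deleted wholesale.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a list with `matrix` (the masked [intensity_matrix()]) and
#'   `truth` (class `simulation_truth`): `complete_matrix`, `group_effects`
#'   (m x G), `de` (logical), `mar_mask`, `mnar_intensity_mask`,
#'   `mnar_group_mask` (disjoint logical matrices), `design`
#'   (a [group_design()]) and `params`.
#' @export
simulate_dataset <- function(m, runs_per_group,
                             base_mean = 20, peptide_sd = 2, noise_sd = 0.5,
                             de_fraction = 0.1, effect_size = 3,
                             mar_fraction = 0.05,
                             mnar_censor_quantile = 0, mnar_tau = 0.3,
                             group_deletion_fraction = 0, seed = 1L) {
  m <- as.integer(m)
  runs_per_group <- as.integer(runs_per_group)
  G <- length(runs_per_group)
  if (m < 2L || G < 1L || any(runs_per_group < 1L))
    input_error("need m >= 2 peptides and at least one run per group")
  for (f in c(de_fraction, mar_fraction, mnar_censor_quantile,
              group_deletion_fraction))
    if (f < 0 || f > 1) input_error("fractions must lie in [0, 1]")
  if (de_fraction > 0 && G < 2L)
    input_error("differential abundance simulation needs >= 2 groups")
  n <- sum(runs_per_group)
  groups <- paste0("G", seq_len(G))
  col_group <- rep(groups, runs_per_group)
  run_ids <- unlist(lapply(seq_len(G), function(g)
    paste0(groups[g], "_R", seq_len(runs_per_group[g]))))
  design <- group_design(stats::setNames(col_group, run_ids), groups)

  out <- withr::with_seed(as.integer(seed), {
    baseline <- stats::rnorm(m, base_mean, peptide_sd)
    group_effects <- matrix(0, m, G, dimnames = list(NULL, groups))
    de <- rep(FALSE, m)
    n_de <- round(de_fraction * m)
    if (n_de > 0) {
      de_idx <- sample.int(m, n_de)
      de[de_idx] <- TRUE
      tgt <- sample.int(G, n_de, replace = TRUE)
      sgn <- sample(c(-1, 1), n_de, replace = TRUE)
      group_effects[cbind(de_idx, tgt)] <- sgn * effect_size
    }
    complete <- matrix(baseline, m, n) +
      group_effects[, match(col_group, groups), drop = FALSE] +
      matrix(stats::rnorm(m * n, 0, noise_sd), m, n)
    dimnames(complete) <- list(paste0("peptide_", seq_len(m)), run_ids)

    # group-specific MNAR: delete the down-regulated group of some DE peptides
    grp_mask <- matrix(FALSE, m, n)
    if (group_deletion_fraction > 0 && n_de > 0) {
      n_del <- round(group_deletion_fraction * n_de)
      if (n_del > 0) {
        del_idx <- sample(which(de), n_del)
        for (i in del_idx) {
          g <- which(group_effects[i, ] != 0)[1]
          group_effects[i, g] <- -abs(group_effects[i, g])
          grp_mask[i, col_group == groups[g]] <- TRUE
        }
        # re-apply effects so forced-negative signs reach the data
        complete <- matrix(baseline, m, n) +
          group_effects[, match(col_group, groups), drop = FALSE] +
          matrix(stats::rnorm(m * n, 0, noise_sd), m, n)
        dimnames(complete) <- list(paste0("peptide_", seq_len(m)), run_ids)
      }
    }

    # intensity-dependent MNAR: logistic censoring below a quantile
    int_mask <- matrix(FALSE, m, n)
    if (mnar_censor_quantile > 0) {
      q <- stats::quantile(complete, mnar_censor_quantile, names = FALSE)
      p_miss <- 1 / (1 + exp((complete - q) / mnar_tau))
      int_mask <- matrix(stats::runif(m * n) < p_miss, m, n) & !grp_mask
    }

    # MAR: uniform masking of whatever is left
    mar_mask <- matrix(stats::runif(m * n) < mar_fraction, m, n) &
      !grp_mask & !int_mask
    dimnames(grp_mask) <- dimnames(int_mask) <- dimnames(mar_mask) <-
      dimnames(complete)

    list(complete = complete, group_effects = group_effects, de = de,
         grp_mask = grp_mask, int_mask = int_mask, mar_mask = mar_mask)
  })

  missing <- out$mar_mask | out$int_mask | out$grp_mask
  if (all(rowSums(!missing) < 4L))
    stop("infeasible missingness configuration: no peptide retains 4 observed values")
  if (any(colSums(!missing) < 2L))
    stop("infeasible missingness configuration: a run retains fewer than 2 observed values")
  vals <- out$complete
  vals[missing] <- NA_real_
  x <- intensity_matrix(vals, mask = !missing)

  params <- list(m = m, runs_per_group = runs_per_group, base_mean = base_mean,
                 peptide_sd = peptide_sd, noise_sd = noise_sd,
                 de_fraction = de_fraction, effect_size = effect_size,
                 mar_fraction = mar_fraction,
                 mnar_censor_quantile = mnar_censor_quantile,
                 mnar_tau = mnar_tau,
                 group_deletion_fraction = group_deletion_fraction,
                 seed = as.integer(seed))
  truth <- structure(list(complete_matrix = out$complete,
                          group_effects = out$group_effects, de = out$de,
                          mar_mask = out$mar_mask,
                          mnar_intensity_mask = out$int_mask,
                          mnar_group_mask = out$grp_mask,
                          design = design, params = params),
                     class = "simulation_truth")
  list(matrix = x, truth = truth)
}

#' Simulate technical replicates with no group structure
#'
#' A null-model generator: `n` technical replicate runs with zero group
#' effects, split into two nominal groups of `n/2` for downstream
#' null-calibration experiments (random two-group tests on such data should
#' produce uniform p-values). Missingness arguments are passed through to
#' [simulate_dataset()].
#'
#' @param m number of peptides.
#' @param n number of replicate runs (even; default 10).
#' @param seed integer seed.
#' @param mar_fraction,mnar_censor_quantile,mnar_tau missingness controls,
#'   see [simulate_dataset()]; default no missingness.
#' @inheritParams simulate_dataset
#' @return as [simulate_dataset()]; `truth$group_effects` is identically 0.
#' @export
simulate_null_replicates <- function(m, n = 10L, seed = 1L,
                                     mar_fraction = 0,
                                     mnar_censor_quantile = 0, mnar_tau = 0.3,
                                     base_mean = 20, peptide_sd = 2,
                                     noise_sd = 0.5) {
  n <- as.integer(n)
  if (n %% 2L != 0L) input_error("'n' must be even for a balanced null split")
  simulate_dataset(m, runs_per_group = c(n %/% 2L, n %/% 2L),
                   base_mean = base_mean, peptide_sd = peptide_sd,
                   noise_sd = noise_sd,
                   de_fraction = 0, effect_size = 0,
                   mar_fraction = mar_fraction,
                   mnar_censor_quantile = mnar_censor_quantile,
                   mnar_tau = mnar_tau,
                   group_deletion_fraction = 0, seed = seed)
}

# vectorized classical pooled two-sample t-tests on rows
row_t_tests <- function(mat, cols1, cols2) {
  x1 <- mat[, cols1, drop = FALSE]; x2 <- mat[, cols2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var); v2 <- apply(x2, 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(tt), df)
  p[se == 0 & m1 == m2] <- 1
  p[se == 0 & m1 != m2] <- 0
  data.frame(mean_diff = m1 - m2, t = tt, p = p, row.names = NULL)
}

#' Imputation recovery metrics against simulation truth
#'
#' Measures how well a completed matrix recovers the simulated complete
#' matrix at the masked entries: RMSE and Pearson correlation, overall and
#' stratified by missingness mechanism (MAR, intensity-dependent MNAR,
#' group-specific MNAR). When the design has two or more groups, a
#' differential-abundance evaluation is added: classical two-sample t-tests
#' (first vs second group) on the completed matrix with Benjamini-Hochberg
#' correction, scored against the true DE labels.
#'
#' @param truth a `simulation_truth` from [simulate_dataset()].
#' @param result an `imputation_result` (or a plain completed matrix of the
#'   same shape).
#' @param fdr FDR threshold for the DA call (default 0.05).
#' @return a list with data.frames `recovery` (`mechanism`, `n`, `rmse`,
#'   `cor`) and, for multi-group designs, `da` (`tp`, `fp`, `fn`,
#'   `n_called`).
#' @export
recovery_metrics <- function(truth, result, fdr = 0.05) {
  stopifnot(inherits(truth, "simulation_truth"))
  completed <- if (inherits(result, "imputation_result")) result$completed else result
  stopifnot(is.matrix(completed))
  # align on peptide ids: the pipeline may have filtered out sparse peptides
  keep <- match(rownames(completed), rownames(truth$complete_matrix))
  if (anyNA(keep)) stop("completed matrix has peptides absent from the truth")
  tr_complete <- truth$complete_matrix[keep, , drop = FALSE]
  tr_de <- truth$de[keep]
  stopifnot(identical(dim(completed), dim(tr_complete)))
  sub <- function(mk) mk[keep, , drop = FALSE]
  masks <- list(overall = sub(truth$mar_mask | truth$mnar_intensity_mask |
                                truth$mnar_group_mask),
                mar = sub(truth$mar_mask),
                mnar_intensity = sub(truth$mnar_intensity_mask),
                mnar_group = sub(truth$mnar_group_mask))
  rec <- do.call(rbind, lapply(names(masks), function(nm) {
    idx <- masks[[nm]]
    if (!any(idx))
      return(data.frame(mechanism = nm, n = 0L, rmse = NA_real_,
                        cor = NA_real_))
    err <- completed[idx] - tr_complete[idx]
    cc <- if (sum(idx) >= 3 && stats::sd(tr_complete[idx]) > 0 &&
              stats::sd(completed[idx]) > 0)
      stats::cor(completed[idx], tr_complete[idx]) else NA_real_
    data.frame(mechanism = nm, n = as.integer(sum(idx)),
               rmse = sqrt(mean(err^2)), cor = cc)
  }))
  rec$mechanism <- as.character(rec$mechanism)
  out <- list(recovery = rec)
  design <- truth$design
  if (length(design$groups) >= 2L) {
    grp <- design$assignment[colnames(completed)]
    c1 <- which(grp == design$groups[1]); c2 <- which(grp == design$groups[2])
    tests <- row_t_tests(completed, c1, c2)
    padj <- stats::p.adjust(tests$p, method = "BH")
    called <- !is.na(padj) & padj < fdr
    out$da <- data.frame(tp = sum(called & tr_de),
                         fp = sum(called & !tr_de),
                         fn = sum(!called & tr_de),
                         n_called = sum(called))
  }
  out
}
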