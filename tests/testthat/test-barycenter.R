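test_that("entropy of mixing distinguishes even from group-specific missingness", {
  d <- group_design(c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B"))
  # fully observed row: all group fractions 1, EBM = 0
  expect_identical(entropy_of_mixing(setNames(rep(TRUE, 6), names(d$assignment)), d), 0)
  # one group fully missing: -Inf
  expect_identical(
    entropy_of_mixing(c(a1 = FALSE, a2 = FALSE, a3 = FALSE,
                        b1 = TRUE, b2 = TRUE, b3 = TRUE), d), -Inf)
  # 2 of 3 observed in each group: direct formula evaluation
  ebm <- entropy_of_mixing(c(a1 = TRUE, a2 = TRUE, a3 = FALSE,
                             b1 = TRUE, b2 = TRUE, b3 = FALSE), d)
  expect_equal(ebm, 2 * (2 / 3) * log(2 / 3), tolerance = 1e-12)
  expect_lte(ebm, 0)
  # unnamed rows follow the design's run order
  expect_identical(entropy_of_mixing(c(F, F, F, T, T, T), d), -Inf)
})

test_that("barycenter weights follow the finite/non-finite EBM rule", {
  expect_equal(assign_weights(-0.54), c(alpha_mar = 0.8, alpha_mnar = 0.2))
  expect_equal(assign_weights(-Inf), c(alpha_mar = 0.2, alpha_mnar = 0.8))
  expect_equal(assign_weights(0), c(alpha_mar = 0.8, alpha_mnar = 0.2))
  expect_equal(assign_weights(-1, 0.5), c(alpha_mar = 0.5, alpha_mnar = 0.5))
  expect_equal(assign_weights(-Inf, 0.5), c(alpha_mar = 0.5, alpha_mnar = 0.5))
  w <- assign_weights(-2, 0.73)
  expect_identical(unname(sum(w)), 1)

  # the convex combination the weights imply
  w8 <- assign_weights(-0.54)
  expect_equal(unname(w8[1] * 20 + w8[2] * 16), 19.2)
  wn <- assign_weights(-Inf)
  expect_equal(unname(wn[1] * 20 + wn[2] * 16), 16.8)
})

test_that("every imputed entry is the stated convex combination of MAR and MNAR", {
  sim <- simulate_dataset(300, c(6, 6), mar_fraction = 0.1, de_fraction = 0.2,
                          group_deletion_fraction = 0.4, seed = 5)
  x <- filter_min_observed(sim$matrix, 4)
  res <- barycenter_impute(x, sim$truth$design, seed = 5)
  miss <- !x$mask
  # independent elementwise recombination loop
  for (i in seq_len(nrow(x$values))) {
    a <- res$annotations$alpha_mar[i]
    for (k in seq_len(ncol(x$values))) {
      if (miss[i, k]) {
        expect_equal(res$completed[i, k],
                     a * res$mar_estimate[i, k] + (1 - a) * res$mnar_estimate[i, k],
                     tolerance = 1e-12)
      } else {
        expect_identical(res$completed[i, k], x$values[i, k])
      }
    }
  }
  # convexity: bounded by the two estimates at missing entries
  lo <- pmin(res$mar_estimate, res$mnar_estimate)
  hi <- pmax(res$mar_estimate, res$mnar_estimate)
  expect_true(all(res$completed[miss] >= lo[miss] - 1e-12))
  expect_true(all(res$completed[miss] <= hi[miss] + 1e-12))
})

test_that("complete peptides pass through untouched with type 'complete'", {
  x <- filter_min_observed(rand_intensity(80, 6, miss = 0.15, seed = 3), 4)
  d <- two_group_design(x)
  res <- barycenter_impute(x, d, seed = 3)
  full <- rowSums(x$mask) == 6
  expect_true(all(res$annotations$mv_type[full] == "complete"))
  expect_identical(res$completed[full, ], x$values[full, ])
})

test_that("boundary weights reduce to the pure single-mechanism imputers", {
  # MAR-only masking: all EBM finite
  x <- filter_min_observed(rand_intensity(60, 6, miss = 0.12, seed = 8), 4)
  d <- two_group_design(x)
  res <- barycenter_impute(x, d, seed = 8)
  expect_true(all(is.finite(res$annotations$ebm)))

  r1 <- barycenter_impute(x, d, alpha_when_finite = 1, seed = 8)
  expect_equal(r1$completed[!x$mask], r1$mar_estimate[!x$mask], tolerance = 1e-12)
  r0 <- barycenter_impute(x, d, alpha_when_finite = 0, seed = 8)
  expect_equal(r0$completed[!x$mask], r0$mnar_estimate[!x$mask], tolerance = 1e-12)
})

test_that("group-deleted peptides are classified group-specific", {
  sim <- simulate_dataset(400, c(6, 6), mar_fraction = 0.05, de_fraction = 0.25,
                          group_deletion_fraction = 0.5, seed = 17)
  x <- filter_min_observed(sim$matrix, 4)
  res <- barycenter_impute(x, sim$truth$design, seed = 17)
  deleted <- rownames(sim$truth$complete_matrix)[rowSums(sim$truth$mnar_group_mask) > 0]
  deleted <- intersect(deleted, x$peptide_ids)
  types <- res$annotations$mv_type[match(deleted, res$annotations$peptide_id)]
  expect_gte(mean(types == "group_specific"), 0.95)
})

test_that("pipeline validates its inputs", {
  x <- rand_intensity(40, 6, miss = 0.1, seed = 2)
  d_bad <- group_design(c(z1 = "A", z2 = "B"))
  expect_error(barycenter_impute(x, d_bad, seed = 1), "design does not cover")
  v <- x$values; v[1, 1:4] <- NA
  xs <- intensity_matrix(v)
  expect_error(barycenter_impute(xs, two_group_design(xs), seed = 1),
               "filter_min_observed")
})

test_that("results are deterministic given the seed and fully annotated", {
  x <- filter_min_observed(rand_intensity(50, 6, miss = 0.1, seed = 4), 4)
  d <- two_group_design(x)
  r1 <- barycenter_impute(x, d, seed = 11)
  r2 <- barycenter_impute(x, d, seed = 11)
  expect_identical(r1$completed, r2$completed)
  expect_identical(r1$annotations, r2$annotations)
  prov <- r1$provenance
  expect_true(all(c("rank_used", "lam", "shift", "width", "alpha_when_finite",
                    "seed", "objective_trace", "converged") %in% names(prov)))
  expect_true(all(c("obs_frac_A", "obs_frac_B") %in% colnames(r1$annotations)))
  expect_equal(r1$annotations$alpha_mar + r1$annotations$alpha_mnar,
               rep(1, nrow(r1$completed)))
})
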