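# baryimpute

Imputation of missing peptide intensities in label-free quantitative mass
spectrometry (LFQ), for proteomics analysts working with peptide-by-run
intensity matrices from MaxQuant or similar quantification tools.

Missing values in LFQ data arise from a mixture of mechanisms. Some are
missing at random (MAR) — e.g. stochastic precursor selection in
data-dependent acquisition — and are well reconstructed from the correlation
structure of the observed data. Others are missing not at random (MNAR):
left-censored low-abundance signal, often absent wholesale from one
experimental group because a protein is down-regulated there. A single
imputation strategy suits one mechanism and distorts the other; baryimpute
estimates every missing entry under both assumptions and combines them.

## The model

For a log2 peptide intensity matrix **X** (m peptides x n runs) with
observed-entry set &Omega;:

1. **MAR estimate** — softImpute-ALS matrix completion: factors
   **A** (m x r), **B** (n x r) minimize

   ½‖P<sub>&Omega;</sub>(X − AB<sup>T</sup>)‖²<sub>F</sub> +
   (&lambda;/2)(‖A‖²<sub>F</sub> + ‖B‖²<sub>F</sub>),

   alternating two exact multiresponse ridge regressions with SVD
   re-orthogonalization. X<sub>MAR</sub> = AB<sup>T</sup>. The rank r is 2
   for studies with fewer than 20 runs, otherwise the rounded *effective
   rank* erank(X) = exp{H(p)}, the exponential Shannon entropy of the
   normalized singular-value distribution.

2. **MNAR estimate** — the down-shift approach: missing values in run k are
   drawn from Normal(x̄<sub>k</sub> − s·&sigma;̂<sub>k</sub>,
   (w·&sigma;̂<sub>k</sub>)²) with s = 1.8, w = 0.3, where x̄<sub>k</sub> and
   &sigma;̂<sub>k</sub> are the run's observed mean and sd.

3. **Barycenter** — each peptide's *entropy of mixing*
   EBM<sub>i</sub> = &Sigma;<sub>g</sub> m<sub>ig</sub> log m<sub>ig</sub>
   (m<sub>ig</sub> = observed fraction in group g) classifies its
   missingness: finite EBM means the missing values are spread over groups
   (MAR-like), −&infin; means a group is entirely missing (group-specific
   MNAR). The imputed value is the weighted average — the barycenter under
   squared-Euclidean distance —

   X&prime;<sub>ik</sub> = &alpha;<sub>i</sub><sup>MAR</sup>·X<sub>MAR,ik</sub> +
   &alpha;<sub>i</sub><sup>MNAR</sup>·X<sub>MNAR,ik</sub>,

   with fixed weights &alpha;<sup>MAR</sup> = 0.8 for finite-EBM peptides and
   0.2 otherwise.

The package also provides MaxQuant `evidence.txt` and wide-matrix readers,
preprocessing (max-intensity feature collapsing, contaminant/reverse
filtering, log2, minimum-observation filtering, quantile normalization),
mean–CV² and missingness diagnostics, a synthetic-data generator with known
ground truth, recovery metrics, and a command-line interface.

## Worked example

```r
library(baryimpute)

# synthetic two-group study: 1000 peptides, 6 + 6 runs, 10% MAR masking,
# 20% DE peptides of which 40% have their down-regulated group censored
sim <- simulate_dataset(m = 1000, runs_per_group = c(6, 6), mar_fraction = 0.10,
                        de_fraction = 0.2, group_deletion_fraction = 0.4, seed = 1)
x <- filter_min_observed(sim$matrix, 4)
x
#> intensity_matrix: 998 peptides x 12 runs, 86.5% observed

res <- barycenter_impute(x, sim$truth$design, seed = 1)
res
#> imputation_result: 998 peptides x 12 runs (rank 2, lambda 0.1)
#>   missingness types: complete=232, group_specific=78, random=688

m <- recovery_metrics(sim$truth, res)
m$recovery
#>        mechanism    n rmse   cor
#> 1        overall 1617 1.92 0.817
#> 2            mar 1149 1.28 0.919
#> 3 mnar_intensity    0   NA    NA
#> 4     mnar_group  468 2.96 0.389
m$da
#>    tp fp fn n_called
#> 1 196  8  2      204
```

Reading: of the 1617 masked entries, the 1149 MAR-masked ones are recovered
with RMSE 1.28 log2 units (r = 0.92) — these lean on the low-rank estimate.
The 468 group-censored entries are harder (the signal was deleted from an
entire group) but the down-shifted draws keep them low, so a two-sample
t-test with Benjamini–Hochberg correction at 5% FDR still recovers 196 of
the 198 surviving differentially abundant peptides with 8 false positives.
Missingness-type counts come from the entropy-of-mixing classification:
the 78 "group_specific" peptides are exactly those with an empty group.

Two thin wrappers expose the same pipeline from the shell:

```sh
Rscript inst/scripts/baryimpute.R simulate --m 1000 --runs-per-group 6,6 --out-dir sim/
Rscript inst/scripts/baryimpute.R impute --input sim/matrix.tsv --groups sim/design.tsv \
    --no-log2 --out-dir imputed/
Rscript inst/scripts/baryimpute.R diagnose --input sim/matrix.tsv --groups sim/design.tsv \
    --imputed imputed/completed_matrix.tsv --out-dir diag/
```

(`--no-log2` because simulated matrices are already log2-scale; for raw
MaxQuant input use `--evidence evidence.txt` and omit the flag.)

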