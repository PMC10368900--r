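# fixtures are built in code at test time; nothing is stored on disk

# random log2-scale intensity matrix with a given masking fraction
rand_intensity <- function(m, n, miss = 0, seed = 1, mean = 20, sd = 2) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(m * n, mean, sd), m, n,
                dimnames = list(paste0("p", seq_len(m)), paste0("r", seq_len(n))))
    mask <- matrix(runif(m * n) >= miss, m, n)
    v[!mask] <- NA_real_
    intensity_matrix(v, mask = mask)
  })
}

two_group_design <- function(x) {
  n <- length(x$run_ids)
  stopifnot(n %% 2 == 0)
  group_design(stats::setNames(rep(c("A", "B"), each = n / 2), x$run_ids))
}

# write a small MaxQuant-style evidence file; returns its path
write_evidence_fixture <- function(path = tempfile(fileext = ".txt")) {
  header <- c("Sequence", "Modified sequence", "Raw file", "Intensity",
              "Potential contaminant", "Reverse")
  row <- function(seq, mod, run, int, con = "", rev = "")
    paste(c(seq, mod, run, int, con, rev), collapse = "\t")
  lines <- c(
    paste(header, collapse = "\t"),
    # PEPA has two ions in run1: the max (3e6) must win
    row("PEPA", "_PEPA_", "run1", "1e6"),
    row("PEPA", "_PEPA_", "run1", "3e6"),
    row("PEPA", "_PEPA_", "run2", "2e6"),
    row("PEPB", "_PEPB_", "run1", "4e6"),
    row("PEPB", "_PEPB_", "run2", "5e6"),
    row("PEPB", "_PEPB_", "run3", "6e6"),
    row("PEPC", "_PEPC_", "run2", "7e6"),
    # contaminant-only peptide: must vanish entirely
    row("PEPD", "_PEPD_", "run1", "9e6", con = "+"),
    row("PEPD", "_PEPD_", "run2", "9e6", con = "+"),
    # reverse hit: excluded even though it is PEPE's only row
    row("PEPE", "_PEPE_", "run3", "8e6", rev = "+"),
    # PEPF ordinary single observation
    row("PEPF", "_PEPF_", "run3", "1.5e6"))
  writeLines(lines, path)
  path
}

# write a wide TSV from a character matrix of cells (first col = id)
write_wide_fixture <- function(cells, runs, path = tempfile(fileext = ".tsv")) {
  lines <- c(paste(c("peptide_id", runs), collapse = "\t"),
             apply(cells, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  path
}
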