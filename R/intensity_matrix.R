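#' Peptide-by-run intensity matrix with an explicit observed mask
#'
#' The central container: an `m x n` numeric matrix of peptide intensities
#' (log2 or raw scale, depending on pipeline stage) together with a logical
#' mask marking observed entries. Missing entries hold `NA` in `values`.
#'
#' @param values numeric matrix, peptides in rows, LC-MS runs in columns.
#'   Entries at `mask = FALSE` positions are set to `NA`.
#' @param mask logical matrix of the same shape; `TRUE` marks an observed
#'   value. Defaults to `!is.na(values)`.
#' @param peptide_ids,run_ids character vectors of unique identifiers;
#'   default to the dimnames of `values`.
#' @return An object of class `intensity_matrix`: a list with elements
#'   `values`, `mask`, `peptide_ids`, `run_ids`.
#' @examples
#' v <- matrix(c(20, 21, NA, 19), 2, 2,
#'             dimnames = list(c("PEPTIDEA", "PEPTIDEB"), c("run1", "run2")))
#' x <- intensity_matrix(v)
#' n_observed(x)
#' @export
intensity_matrix <- function(values, mask = !is.na(values),
                             peptide_ids = rownames(values),
                             run_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    input_error("'values' must be a numeric matrix")
  if (!is.matrix(mask) || !is.logical(mask) || !identical(dim(mask), dim(values)))
    input_error("'mask' must be a logical matrix with the same shape as 'values'")
  m <- nrow(values); n <- ncol(values)
  if (n < 2L) input_error("an intensity matrix needs at least 2 runs")
  if (is.null(peptide_ids)) peptide_ids <- paste0("peptide_", seq_len(m))
  if (is.null(run_ids)) run_ids <- paste0("run_", seq_len(n))
  peptide_ids <- as.character(peptide_ids); run_ids <- as.character(run_ids)
  if (length(peptide_ids) != m || length(run_ids) != n)
    input_error("id lengths do not match matrix dimensions")
  if (anyDuplicated(peptide_ids)) {
    dup <- unique(peptide_ids[duplicated(peptide_ids)])
    input_error(paste0("duplicate peptide ids: ", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(run_ids))
    input_error(paste0("duplicate run ids: ",
                       paste(unique(run_ids[duplicated(run_ids)]), collapse = ", ")))
  mask[is.na(mask)] <- FALSE
  if (any(!is.finite(values[mask])))
    input_error("observed entries must be finite")
  values[!mask] <- NA_real_
  dimnames(values) <- dimnames(mask) <- list(peptide_ids, run_ids)
  structure(list(values = values, mask = mask,
                 peptide_ids = peptide_ids, run_ids = run_ids),
            class = "intensity_matrix")
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' @export
print.intensity_matrix <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("intensity_matrix: %d peptides x %d runs, %.1f%% observed\n",
              d[1], d[2], 100 * mean(x$mask)))
  invisible(x)
}

#' Number of observed entries
#' @param x an `intensity_matrix`
#' @param by `"total"`, `"peptide"` (row counts) or `"run"` (column counts)
#' @return integer count(s) of observed entries
#' @export
n_observed <- function(x, by = c("total", "peptide", "run")) {
  stopifnot(inherits(x, "intensity_matrix"))
  switch(match.arg(by),
         total = sum(x$mask),
         peptide = rowSums(x$mask),
         run = colSums(x$mask))
}

#' Run-to-group experimental design
#'
#' @param assignment named character vector mapping run id (names) to group
#'   label (values).
#' @param groups optional ordered character vector of group labels; defaults
#'   to order of first appearance in `assignment`.
#' @return An object of class `group_design`: list with `assignment`, `groups`.
#' @examples
#' d <- group_design(c(r1 = "ctrl", r2 = "ctrl", r3 = "trt", r4 = "trt"))
#' d$groups
#' @export
group_design <- function(assignment, groups = NULL) {
  if (is.null(names(assignment)) || any(names(assignment) == ""))
    input_error("'assignment' must be a named vector (names are run ids)")
  assignment <- vapply(assignment, as.character, character(1))
  if (anyDuplicated(names(assignment)))
    input_error("design assigns some run more than once")
  if (is.null(groups)) groups <- unique(unname(assignment))
  groups <- as.character(groups)
  if (length(groups) < 1L) input_error("design needs at least one group")
  if (!setequal(groups, unique(unname(assignment))))
    input_error("'groups' must list exactly the labels used in 'assignment'")
  structure(list(assignment = assignment, groups = groups),
            class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  cat(sprintf("group_design: %d runs in %d groups (%s)\n",
              length(x$assignment), length(x$groups),
              paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' Read a run-to-group design table
#'
#' Expects a delimited table whose first column is the run id and second
#' column the group label (a header line is detected and skipped if its first
#' field is "run").
#'
#' @param path path to a TSV/CSV file
#' @return a [group_design()]
#' @export
read_group_design <- function(path) {
  if (!file.exists(path)) input_error(paste0("design file not found: ", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, header = FALSE,
                          colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 2L) input_error("design file needs two columns: run, group")
  if (tolower(df[1, 1]) %in% c("run", "run_id", "sample")) df <- df[-1, , drop = FALSE]
  if (nrow(df) == 0L) input_error("design file is empty")
  group_design(stats::setNames(df[[2]], df[[1]]))
}

# every run of x must be assigned exactly once
check_design <- function(x, design) {
  stopifnot(inherits(x, "intensity_matrix"), inherits(design, "group_design"))
  missing_runs <- setdiff(x$run_ids, names(design$assignment))
  if (length(missing_runs))
    input_error(paste0("design does not cover run(s): ",
                       paste(missing_runs, collapse = ", ")))
  invisible(TRUE)
}

# group label per column of x, in column order
run_groups <- function(x, design) {
  check_design(x, design)
  unname(design$assignment[x$run_ids])
}
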