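#' Read a wide peptide-by-run intensity matrix
#'
#' First column is the peptide id; every remaining column is one LC-MS run.
#' Cells matching `missing_tokens` (after whitespace trimming) are recorded
#' as missing. By default the literal cell `"0"` -- and, after parsing, any
#' numeric zero -- is treated as missing, the common LFQ export convention.
#'
#' @param path path to a delimited text file; `.csv` implies comma, anything
#'   else tab.
#' @param missing_tokens character vector of cell contents meaning "missing".
#' @param sep field separator; `NULL` (default) infers from the extension.
#' @return an [intensity_matrix()] on whatever scale the file is on (readers
#'   never transform; apply [log2_transform()] for raw intensities).
#' @export
read_wide_matrix <- function(path, missing_tokens = c("", "NA", "NaN", "0"),
                             sep = NULL) {
  if (!file.exists(path)) input_error(paste0("input file not found: ", path))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", strip.white = TRUE,
                          na.strings = NULL)
  if (ncol(df) < 3L) input_error("wide matrix needs an id column plus >= 2 run columns")
  ids <- trimws(df[[1]])
  if (anyDuplicated(ids))
    input_error(paste0("duplicate peptide ids: ",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  cells <- as.matrix(df[, -1, drop = FALSE])
  cells <- trimws(cells)
  miss <- matrix(cells %in% missing_tokens, nrow(cells), ncol(cells))
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  bad <- which(!miss & is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1, ]
    input_error(sprintf(
      "non-numeric cell '%s' at row %d (peptide '%s'), column '%s'",
      cells[b[1], b[2]], b[1], ids[b[1]], colnames(df)[-1][b[2]]))
  }
  if ("0" %in% missing_tokens) miss <- miss | (!is.na(vals) & vals == 0)
  vals[miss] <- NA_real_
  intensity_matrix(vals, mask = !miss, peptide_ids = ids,
                   run_ids = colnames(df)[-1])
}

#' Write an intensity matrix (or completed matrix) as a wide TSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces the doubles exactly; missing entries are written
#' as `NA`.
#'
#' @param x an [intensity_matrix()] or a plain numeric matrix with dimnames.
#' @param path output file path.
#' @param id_column header for the peptide id column.
#' @return `path`, invisibly.
#' @export
write_wide_matrix <- function(x, path, id_column = "peptide_id") {
  if (inherits(x, "intensity_matrix")) {
    vals <- x$values; ids <- x$peptide_ids; runs <- x$run_ids
  } else {
    stopifnot(is.matrix(x), is.numeric(x))
    vals <- x
    ids <- rownames(x); if (is.null(ids)) ids <- paste0("peptide_", seq_len(nrow(x)))
    runs <- colnames(x); if (is.null(runs)) runs <- paste0("run_", seq_len(ncol(x)))
  }
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  lines <- c(paste(c(id_column, runs), collapse = "\t"),
             vapply(seq_len(nrow(vals)), function(i)
               paste(c(ids[i], fmt(vals[i, ])), collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a MaxQuant evidence table into a peptide-by-run matrix
#'
#' Rows flagged as contaminant or reverse-database hits are discarded. When
#' several features (e.g. charge states) of the same peptide are reported for
#' one run, only the feature with the highest intensity is retained. Peptide
#' identity is the modified sequence when present, otherwise the plain
#' sequence. Column headers of the common MaxQuant dialects are accepted
#' ("Modified sequence"/"Sequence", "Raw file", "Intensity",
#' "Potential contaminant"/"Contaminant", "Reverse"; flags are `+`).
#'
#' @param path path to a tab-separated evidence file.
#' @return an [intensity_matrix()] of raw-scale intensities; (peptide, run)
#'   cells with no surviving feature row are missing.
#' @export
read_maxquant_evidence <- function(path) {
  if (!file.exists(path)) input_error(paste0("input file not found: ", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  pick <- function(candidates) {
    hit <- candidates[candidates %in% colnames(df)]
    if (length(hit)) hit[1] else NA_character_
  }
  seq_col <- pick(c("Modified sequence", "Sequence"))
  run_col <- pick("Raw file")
  int_col <- pick("Intensity")
  con_col <- pick(c("Potential contaminant", "Contaminant"))
  rev_col <- pick("Reverse")
  need <- c(`peptide sequence` = seq_col, `raw file` = run_col,
            intensity = int_col, contaminant = con_col, reverse = rev_col)
  if (anyNA(need))
    input_error(paste0("evidence table is missing required column(s): ",
                       paste(names(need)[is.na(need)], collapse = ", ")))
  flagged <- trimws(df[[con_col]]) == "+" | trimws(df[[rev_col]]) == "+"
  df <- df[!flagged, , drop = FALSE]
  if (nrow(df) == 0L) input_error("no evidence rows survive contaminant/reverse filtering")
  intensity <- suppressWarnings(as.numeric(df[[int_col]]))
  keep <- !is.na(intensity) & intensity > 0
  df <- df[keep, , drop = FALSE]; intensity <- intensity[keep]
  if (nrow(df) == 0L) input_error("no evidence rows carry a positive intensity")
  peptides <- unique(df[[seq_col]])
  runs <- unique(df[[run_col]])
  if (length(runs) < 2L) input_error("evidence table covers fewer than 2 raw files")
  vals <- matrix(NA_real_, length(peptides), length(runs),
                 dimnames = list(peptides, runs))
  # max-intensity collapsing across feature rows of the same (peptide, run)
  agg <- tapply(intensity, list(df[[seq_col]], df[[run_col]]), max)
  vals[rownames(agg), colnames(agg)] <- agg
  intensity_matrix(vals, peptide_ids = peptides, run_ids = runs)
}
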