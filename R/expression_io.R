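sep_for_path <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a sample-by-marker expression matrix
#'
#' Expects a header row of marker names with `sample_id` as first column;
#' comma/tab dialect is chosen from the file extension (`.csv` vs anything
#' else). Validates uniqueness of sample and marker ids, numeric
#' non-negative values and absence of missing cells, reporting the offending
#' row/column on failure.
#'
#' @param path TSV or CSV file path.
#' @return numeric matrix (samples x markers) with sample ids as rownames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop_ps("expression file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep_for_path(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA, comment.char = "#")
  if (ncol(df) < 2 || names(df)[1] != "sample_id")
    stop_ps("first column of %s must be 'sample_id'", path)
  markers <- names(df)[-1]
  if (anyDuplicated(markers))
    stop_ps("duplicated marker column(s) in %s: %s", path,
            paste(unique(markers[duplicated(markers)]), collapse = ", "))
  ids <- as.character(df$sample_id)
  if (anyDuplicated(ids))
    stop_ps("duplicated sample id(s) in %s: %s", path,
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[-1]
  # a column of only NA cells parses as logical; keep it for the missing-value
  # report rather than calling it non-numeric
  not_num <- !vapply(vals, function(v) is.numeric(v) || all(is.na(v)),
                     logical(1))
  if (any(not_num)) {
    j <- which(not_num)[1]
    bad_row <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
    stop_ps("non-numeric cell in %s at row %s, column '%s'", path,
            ids[bad_row %||% 1], markers[j])
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (anyNA(m)) {
    w <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop_ps("missing value in %s at sample '%s', marker '%s'", path,
            ids[w[1]], markers[w[2]])
  }
  if (any(m < 0)) {
    w <- which(m < 0, arr.ind = TRUE)[1, ]
    stop_ps("negative value in %s at sample '%s', marker '%s'", path,
            ids[w[1]], markers[w[2]])
  }
  m
}

#' Write an expression matrix as TSV/CSV
#'
#' @param mat samples x markers numeric matrix with sample id rownames.
#' @param path output path; `.csv` writes comma-separated, else tab.
#' @param header_lines optional `#`-prefixed comment lines written first.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, header_lines = NULL) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines) > 0) writeLines(paste0("# ", header_lines), con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = sep_for_path(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a sample annotation table
#'
#' Annotation columns: `sample_id`, `class` (bacterial/viral/noninfected),
#' `cohort_id`, `split` (train/validation). Sample ids must be unique and
#' each cohort must map to exactly one split.
#'
#' @param path TSV/CSV path.
#' @return data.frame with the four annotation columns.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) stop_ps("annotation file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep_for_path(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("sample_id", "class", "cohort_id", "split")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_ps("annotation %s lacks column(s): %s", path,
            paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_ps("duplicated sample id(s) in %s", path)
  as_class_factor(df$class)  # validates labels
  bad_split <- setdiff(unique(df$split), c("train", "validation"))
  if (length(bad_split) > 0)
    stop_ps("unknown split value(s) in %s: %s", path,
            paste(bad_split, collapse = ", "))
  mixed <- tapply(df$split, df$cohort_id, function(s) length(unique(s)))
  if (any(mixed > 1))
    stop_ps("cohort(s) mapped to more than one split in %s: %s", path,
            paste(names(mixed)[mixed > 1], collapse = ", "))
  df[need]
}

#' @rdname read_sample_annotation
#' @param annotation data.frame to write.
#' @param header_lines optional `#`-prefixed comment lines.
#' @export
write_sample_annotation <- function(annotation, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines) > 0) writeLines(paste0("# ", header_lines), con)
  utils::write.table(annotation, con, sep = sep_for_path(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a marker manifest
#'
#' Manifest columns: `marker`, `role` (original/alternative/housekeeping),
#' `gdna_pass` (0/1: passed the genomic-DNA screen), and direction codes
#' `dir_bi_uc`, `dir_vi_uc`, optionally `dir_bi_vi`.
#'
#' @param path TSV/CSV path.
#' @return data.frame with one row per marker, `gdna_pass` as logical.
#' @export
read_marker_manifest <- function(path) {
  if (!file.exists(path)) stop_ps("manifest file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep_for_path(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#", encoding = "UTF-8")
  need <- c("marker", "role", "gdna_pass", "dir_bi_uc", "dir_vi_uc")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_ps("manifest %s lacks column(s): %s", path,
            paste(miss, collapse = ", "))
  if (anyDuplicated(df$marker))
    stop_ps("duplicated marker(s) in manifest %s", path)
  bad_role <- setdiff(unique(df$role),
                      c("original", "alternative", "housekeeping"))
  if (length(bad_role) > 0)
    stop_ps("unknown role(s) in %s: %s", path, paste(bad_role, collapse = ", "))
  df$gdna_pass <- as.logical(as.integer(df$gdna_pass))
  df
}

#' Normalize expression to housekeeping (reference) markers
#'
#' Converts copy-number-scale values to log2 relative abundance against the
#' geometric mean of the housekeeping markers:
#' `log2(x + pseudocount) - mean_h log2(x_h + pseudocount)` per sample. This
#' is the standard reference-gene convention for relative mRNA
#' quantification; it makes non-reference values invariant to per-sample
#' global scaling (library size / input amount) in the limit of a small
#' pseudocount. Housekeeping columns are retained in the output.
#'
#' @param mat samples x markers copy-number matrix.
#' @param housekeeping_ids character vector of reference marker names
#'   (must all be columns of `mat`).
#' @param pseudocount positive offset (copies) keeping log2 defined at the
#'   detection floor; default 1.
#' @return samples x markers matrix of log2 relative abundances.
#' @export
#' @examples
#' m <- matrix(c(800, 100, 400), 1, dimnames = list("s1", c("T", "H1", "H2")))
#' normalize_to_housekeepers(m, c("H1", "H2"), pseudocount = 1e-9)
normalize_to_housekeepers <- function(mat, housekeeping_ids, pseudocount = 1) {
  if (length(housekeeping_ids) < 1)
    stop_ps("at least one housekeeping marker is required")
  miss <- setdiff(housekeeping_ids, colnames(mat))
  if (length(miss) > 0)
    stop_ps("housekeeping marker(s) absent from matrix: %s",
            paste(miss, collapse = ", "))
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop_ps("pseudocount must be > 0")
  lg <- log2(mat + pseudocount)
  ref <- rowMeans(lg[, housekeeping_ids, drop = FALSE])
  lg - ref
}
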