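#' Peak table: subjects (or replicates) by aligned peaks
#'
#' The pipeline's central exchange object: a numeric matrix of normalized
#' peak areas with one row per subject (or per replicate spectrum before
#' aggregation) and one column per aligned peak, plus group labels. Peak
#' columns are labelled by reference m/z to 1 decimal place.
#'
#' @param areas numeric matrix of normalized peak areas, all `>= 0`;
#'   rownames are subject (or replicate) identifiers.
#' @param mz numeric vector of reference m/z values, one per column.
#' @param group character vector of group labels, one per row
#'   (e.g. `"BTC"`, `"benign"`, `"healthy"`, `"QC"`).
#' @param subject_id optional character vector mapping rows to subjects;
#'   defaults to rownames. Differs from rownames for replicate-level tables.
#'
#' @return An object of class `peak_table`: the matrix with attributes
#'   `mz`, `group` and `subject_id`.
#' @export
peak_table <- function(areas, mz, group, subject_id = rownames(areas)) {
  areas <- as.matrix(areas)
  if (!is.numeric(areas)) stop_invalid("peak areas must be numeric")
  if (any(areas < 0, na.rm = TRUE)) stop_invalid("peak areas must be >= 0")
  if (length(mz) != ncol(areas)) {
    stop_invalid("length(mz) [%d] != number of peak columns [%d]",
                 length(mz), ncol(areas))
  }
  if (length(group) != nrow(areas)) {
    stop_invalid("length(group) [%d] != number of rows [%d]",
                 length(group), nrow(areas))
  }
  colnames(areas) <- mz_label(mz)
  if (anyDuplicated(colnames(areas))) {
    stop_invalid("peak m/z labels must be unique to 1 decimal place")
  }
  if (is.null(rownames(areas))) {
    rownames(areas) <- sprintf("S%03d", seq_len(nrow(areas)))
  }
  structure(areas,
            mz = as.numeric(mz),
            group = as.character(group),
            subject_id = as.character(subject_id %||% rownames(areas)),
            class = c("peak_table", "matrix", "array"))
}

#' @export
print.peak_table <- function(x, ...) {
  grp <- table(attr(x, "group"))
  cat(sprintf("peak_table: %d rows x %d peaks (m/z %s-%s)\n",
              nrow(x), ncol(x),
              mz_label(min(attr(x, "mz"))), mz_label(max(attr(x, "mz")))))
  cat("groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname peak_table
#' @param x a `peak_table`.
#' @export
peak_mz <- function(x) attr(x, "mz")

#' @rdname peak_table
#' @export
peak_groups <- function(x) attr(x, "group")

#' Subset a peak table by row
#'
#' @param x a `peak_table`.
#' @param rows logical or integer row index.
#' @return a `peak_table` with the selected rows and all attributes carried.
#' @export
subset_rows <- function(x, rows) {
  peak_table(unclass(x)[rows, , drop = FALSE], attr(x, "mz"),
             attr(x, "group")[rows], attr(x, "subject_id")[rows])
}

#' Read / write peak tables as TSV
#'
#' The on-disk format is a plain TSV with columns `subject_id`, `group`,
#' then one column per peak labelled by its m/z to 1 decimal.
#'
#' @param x a `peak_table`.
#' @param path file path.
#' @return `write_peak_table` returns `path` invisibly; `read_peak_table`
#'   returns a `peak_table`.
#' @export
write_peak_table <- function(x, path) {
  df <- data.frame(subject_id = attr(x, "subject_id"),
                   group = attr(x, "group"),
                   unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- c("subject_id", "group")
  if (!all(meta %in% names(df))) {
    stop_invalid("peak table file must have subject_id and group columns")
  }
  areas <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(areas) <- make.unique(df$subject_id)
  peak_table(areas, as.numeric(colnames(areas)), df$group,
             subject_id = df$subject_id)
}

#' Read a sample sheet
#'
#' @param path CSV with columns `subject_id`, `group`, and optionally
#'   `replicate_id` and `file`.
#' @return a data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(df))) {
    stop_invalid("sample sheet must have subject_id and group columns")
  }
  df
}
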