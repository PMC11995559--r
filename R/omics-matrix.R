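# Omics quantification tables: features x samples, tibble-first.
# Sample columns follow the `group_replicate` convention (e.g. WT_1, FAD_3);
# the value kind tags what the numbers mean. Missing values (empty cells on
# disk) are allowed only for the proteomics kinds ("intensity", "fot"),
# where they encode "not detected" -- never zero.

VALUE_KINDS <- c("count", "tpm", "fot", "intensity")

#' Construct an omics quantification table
#'
#' A thin validated wrapper around a tibble whose first column is `feature`
#' and whose remaining columns are numeric per-sample values named
#' `group_replicate` (e.g. `WT_1`).
#'
#' @param tbl A data frame with a `feature` character column and numeric
#'   sample columns.
#' @param kind One of `"count"`, `"tpm"`, `"fot"`, `"intensity"`.
#' @return A tibble of class `omics_tbl` with a `kind` attribute.
#' @examples
#' omics_matrix(tibble::tibble(feature = c("g1", "g2"),
#'                             WT_1 = c(3, 0), FAD_1 = c(1, 5)), "count")
#' @export
omics_matrix <- function(tbl, kind = c("count", "tpm", "fot", "intensity")) {
  kind <- match.arg(kind)
  tbl <- as_tibble(tbl)
  if (!"feature" %in% names(tbl)) {
    abort("omics matrix must have a 'feature' column")
  }
  tbl <- dplyr::relocate(tbl, "feature")
  if (anyDuplicated(tbl$feature)) {
    dup <- tbl$feature[duplicated(tbl$feature)][1]
    abort(sprintf("duplicate feature id '%s'", dup))
  }
  smp <- setdiff(names(tbl), "feature")
  if (length(smp) == 0L) abort("omics matrix has no sample columns")
  bad <- smp[!grepl("^.+_[0-9]+$", smp)]
  if (length(bad) > 0L) {
    abort(sprintf("sample column '%s' does not follow the group_replicate convention",
                  bad[1]))
  }
  vals <- as.matrix(tbl[smp])
  if (!is.numeric(vals)) abort("sample columns must be numeric")
  if (any(vals < 0, na.rm = TRUE)) abort("negative values are not allowed")
  if (!kind %in% c("intensity", "fot") && anyNA(vals)) {
    abort(sprintf("missing values are not allowed for kind='%s'", kind))
  }
  structure(tbl, kind = kind, class = c("omics_tbl", class(tbl)))
}

#' Value kind of an omics table
#' @param x An `omics_tbl`.
#' @return A string: the value kind tag.
#' @export
omics_kind <- function(x) attr(x, "kind", exact = TRUE)

#' Sample metadata parsed from column names
#'
#' @param x An `omics_tbl` (or any table with `group_replicate` columns
#'   besides `feature`).
#' @return Tibble with columns `sample`, `group`, `replicate`.
#' @export
sample_info <- function(x) {
  smp <- setdiff(names(x), "feature")
  tibble(
    sample = smp,
    group = sub("_[0-9]+$", "", smp),
    replicate = as.integer(sub("^.*_", "", smp))
  )
}

#' Extract the numeric value matrix
#' @param x An `omics_tbl`.
#' @return Numeric matrix, features as rownames, samples as colnames.
#' @export
omics_values <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "feature")])
  rownames(m) <- x$feature
  m
}

#' Read / write an omics matrix as TSV
#'
#' Round-trips are stable to 6 decimals. Missing values are written as empty
#' cells and read back as missing (allowed only for `kind = "intensity"`).
#' Rows and sample columns are written in sorted order for reproducible diffs.
#'
#' @param path File path.
#' @param kind Value kind tag (see [omics_matrix()]).
#' @return `read_matrix()` returns an `omics_tbl`; `write_matrix()` returns
#'   `path` invisibly.
#' @export
read_matrix <- function(path, kind = c("count", "tpm", "fot", "intensity")) {
  kind <- match.arg(kind)
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    feature = readr::col_character(), .default = readr::col_double()
  ), na = "", progress = FALSE)
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0L) {
    abort(sprintf("non-numeric cell at line %d, column %d of %s",
                  prob$row[1], prob$col[1], path))
  }
  omics_matrix(tbl, kind)
}

#' @rdname read_matrix
#' @param x An `omics_tbl`.
#' @export
write_matrix <- function(x, path) {
  smp <- sort(setdiff(names(x), "feature"))
  out <- x[order(x$feature), c("feature", smp)]
  out <- dplyr::mutate(out, across(all_of(smp), ~ round(.x, 6)))
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}
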