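#' Read a feature matrix (samples x features) from CSV/TSV
#'
#' Reads a delimited file with a header row of feature names and samples in
#' rows. If \code{group_column} names a column with exactly two levels, the
#' file is split into the two group matrices (returned as a named list in
#' level order). Non-numeric feature cells fail with a report of the
#' offending rows and columns.
#'
#' @param path file path; the delimiter defaults to tab for \code{.tsv} /
#'   \code{.txt} files and comma otherwise.
#' @param group_column optional name of the two-level grouping column.
#' @param sep field delimiter override.
#' @param transpose set \code{TRUE} for files with features in rows.
#' @return A numeric matrix, or a named list of two matrices when
#'   \code{group_column} is given.
#' @export
read_feature_matrix <- function(path, group_column = NULL, sep = NULL,
                                transpose = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sep <- sep %||% if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE))
    "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("input needs a header row and at least 2 columns")

  groups <- NULL
  if (!is.null(group_column)) {
    if (!group_column %in% names(df)) {
      stop(sprintf("group column '%s' not found", group_column))
    }
    groups <- as.character(df[[group_column]])
    lev <- unique(groups)
    if (length(lev) != 2) {
      stop(sprintf("group column '%s' must have exactly 2 levels, found %d",
                   group_column, length(lev)))
    }
    df <- df[setdiff(names(df), group_column)]
  }

  bad <- list()
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      rows <- which(is.na(conv) & !is.na(v))
      if (length(rows)) {
        bad[[names(df)[j]]] <- rows
      }
      df[[j]] <- conv
    }
  }
  if (length(bad)) {
    msg <- paste(vapply(names(bad), function(nm)
      sprintf("column '%s' rows %s", nm,
              paste(utils::head(bad[[nm]], 5), collapse = ",")),
      ""), collapse = "; ")
    stop(sprintf("non-numeric cells: %s", msg))
  }
  x <- as.matrix(df)
  if (transpose) {
    x <- t(x)
    colnames(x) <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  }
  if (is.null(groups)) return(x)
  lev <- unique(groups)
  stats::setNames(lapply(lev, function(g) x[groups == g, , drop = FALSE]),
                  lev)
}

#' Write a feature matrix as headered CSV
#'
#' @param x numeric matrix (samples x features).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  x <- .as_feature_matrix(x)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a differential connectivity result table
#'
#' \code{write_dc_result} stores one row per feature with columns
#' \code{feature, chi_g1, chi_g2, delta_chi, p_value, significant} (plus
#' \code{p_adjusted} when present), at full precision.
#' \code{read_dc_result} reads such a file back as a data frame.
#'
#' @param result a \code{"dc_test"} object.
#' @param path file path.
#' @return The path (write) or the result data frame (read).
#' @export
write_dc_result <- function(result, path) {
  if (!inherits(result, "dc_test")) stop("'result' must be a dc_test object")
  utils::write.csv(result$table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dc_result
#' @export
read_dc_result <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}
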