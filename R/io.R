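#' Construct a single-array scan object
#'
#' Container for one sample's raw two-channel scan: per-spot foreground and
#' background intensities in both channels, scanner flag, print-tip block and
#' gene ID.
#'
#' @param gene_id Character vector of gene identifiers (one per spot).
#' @param block Integer print-tip block index (1-based).
#' @param row,column Position within the block (informational).
#' @param fg_red,bg_red,fg_green,bg_green Non-negative intensities; by GenePix
#'   convention red is the 635 nm (sample) channel and green the 532 nm
#'   (reference) channel.
#' @param flagged Logical; spots flagged by the scanner or experimentalist.
#' @param sample_id Sample identifier.
#' @return An object of class \code{array_scan} with a \code{spots} data frame.
#' @export
array_scan <- function(gene_id, block, row = NULL, column = NULL,
                       fg_red, bg_red, fg_green, bg_green,
                       flagged, sample_id = "sample") {
  n <- length(gene_id)
  if (is.null(row)) row <- seq_len(n)
  if (is.null(column)) column <- rep(1L, n)
  spots <- data.frame(gene_id = as.character(gene_id),
                      block = as.integer(block),
                      row = as.integer(row),
                      column = as.integer(column),
                      fg_red = as.numeric(fg_red),
                      bg_red = as.numeric(bg_red),
                      fg_green = as.numeric(fg_green),
                      bg_green = as.numeric(bg_green),
                      flagged = as.logical(flagged),
                      stringsAsFactors = FALSE)
  stopifnot(nrow(spots) >= 1,
            all(spots$block >= 1),
            all(spots[, c("fg_red", "bg_red", "fg_green", "bg_green")] >= 0))
  structure(list(spots = spots, sample_id = as.character(sample_id)),
            class = "array_scan")
}

#' @export
print.array_scan <- function(x, ...) {
  cat(sprintf("array_scan '%s': %d spots, %d print-tip blocks, %d flagged\n",
              x$sample_id, nrow(x$spots), length(unique(x$spots$block)),
              sum(x$spots$flagged)))
  invisible(x)
}

#' Read a GPR-like scan file
#'
#' Parses a tab-separated scan file with the required columns \code{Block},
#' \code{Row}, \code{Column}, \code{ID}, \code{F635}, \code{B635},
#' \code{F532}, \code{B532}, \code{Flags}. Extra columns are ignored; a
#' nonzero \code{Flags} value marks the spot as flagged.
#'
#' @param path Path to the file.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param column_map Optional named character vector remapping required column
#'   names to the names used in the file, e.g.
#'   \code{c(F635 = "F635 Median")}.
#' @return An \code{\link{array_scan}}.
#' @export
read_gpr <- function(path, sample_id = NULL, column_map = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("Block", "Row", "Column", "ID", "F635", "B635", "F532", "B532", "Flags")
  lookup <- stats::setNames(required, required)
  if (!is.null(column_map)) lookup[names(column_map)] <- column_map
  missing_cols <- required[!lookup[required] %in% names(df)]
  if (length(missing_cols))
    stop(sprintf("'%s' is missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  num <- function(col) {
    v <- df[[lookup[col]]]
    x <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(x) & !is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' of '%s' at data line %d",
                   col, path, bad[1]))
    x
  }
  array_scan(gene_id = as.character(df[[lookup["ID"]]]),
             block = num("Block"), row = num("Row"), column = num("Column"),
             fg_red = num("F635"), bg_red = num("B635"),
             fg_green = num("F532"), bg_green = num("B532"),
             flagged = num("Flags") != 0,
             sample_id = sample_id)
}

#' Read a sample-to-class label file
#'
#' @param path Two-column tab-separated file with a header row; first column
#'   sample IDs, second column class labels. Samples without a class label
#'   (empty or NA) are omitted from the mapping.
#' @return A named character vector mapping sample_id to class.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0) return(stats::setNames(character(0), character(0)))
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sample_id in '%s': %s", path,
                 ids[duplicated(ids)][1]))
  cls <- df[[2]]
  keep <- !is.na(cls) & cls != "" & cls != "NA"
  stats::setNames(cls[keep], ids[keep])
}

#' Write and read a grid result table
#'
#' The result table (one row per dataset/analysis combination with its merged
#' adjusted Rand) is stored as a tab-separated file at full precision and
#' round-trips losslessly.
#'
#' @param results A result-table data frame as returned by
#'   \code{\link{run_grid}}.
#' @param path Output/input path.
#' @return \code{read_results} returns the data frame; \code{write_results}
#'   returns \code{path} invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- results
  if ("arand" %in% names(out))
    out$arand <- sprintf("%.17g", out$arand)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("arand" %in% names(df)) {
    df$arand <- suppressWarnings(as.numeric(df$arand))
    bad <- which(is.na(df$arand) & !grepl("^NA$|^$",
                 utils::read.delim(path, colClasses = "character")$arand))
    if (length(bad))
      stop(sprintf("malformed arand value in '%s' at data line %d", path, bad[1]))
  }
  if ("standardization" %in% names(df))
    df$standardization <- as.logical(df$standardization)
  df
}
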