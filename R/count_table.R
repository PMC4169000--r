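#' Tag-count table
#'
#' A transcript-by-library matrix of mapped-read counts together with the
#' declared library totals. Totals default to the column sums; they can
#' exceed the column sums when genes have been filtered out of the table
#' after counting, but never fall below them.
#'
#' @param counts Non-negative integer matrix with gene rownames and
#'   library colnames.
#' @param totals Optional named numeric vector of declared library totals.
#' @return An object of class \code{tag_count_table}.
#' @export
tag_count_table <- function(counts, totals = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and library colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  if (is.null(totals)) {
    totals <- colSums(counts)
  } else {
    totals <- totals[colnames(counts)]
    if (any(is.na(totals))) stop("totals must name every library column")
    if (any(totals < colSums(counts))) {
      stop("declared library totals fall below the column sums")
    }
  }
  structure(list(counts = counts, totals = totals), class = "tag_count_table")
}

#' @export
print.tag_count_table <- function(x, ...) {
  cat(sprintf("tag_count_table: %d genes x %d libraries\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  totals:", paste(sprintf("%s=%d", names(x$totals),
                                 as.integer(x$totals)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.tag_count_table <- function(x) dim(x$counts)

#' Write a tag-count table as TSV
#'
#' Plain UTF-8 TSV with Unix newlines: a `#totals` metadata line carrying
#' the declared library totals, a header row, then one row per gene.
#'
#' @param table A \code{tag_count_table}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "tag_count_table"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("#totals\t",
                    paste(sprintf("%s=%d", names(table$totals),
                                  as.integer(table$totals)),
                          collapse = "\t")),
             con, sep = "\n")
  writeLines(paste(c("gene", colnames(table$counts)), collapse = "\t"),
             con, sep = "\n")
  body <- cbind(rownames(table$counts),
                apply(table$counts, 2, format, scientific = FALSE,
                      trim = TRUE))
  writeLines(apply(body, 1, paste, collapse = "\t"), con, sep = "\n")
  invisible(path)
}

#' Read a tag-count table from TSV
#'
#' Accepts the dialect written by [write_count_table()]: an optional
#' `#totals` metadata line, a header row (gene column plus one column per
#' library), then integer counts. Without a `#totals` line the totals are
#' the column sums. Malformed rows, negative or non-integer counts and
#' duplicate gene ids are rejected with descriptive errors.
#'
#' @param path TSV file path.
#' @return A \code{tag_count_table}.
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  totals <- NULL
  if (length(lines) && startsWith(lines[1], "#totals")) {
    fields <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
    kv <- strsplit(fields, "=", fixed = TRUE)
    totals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                              vapply(kv, `[`, "", 1))
    lines <- lines[-1]
  }
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2) stop("count table has no data rows: ", path)
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(tab)[1] != "gene") {
    stop("first column must be 'gene', found '", colnames(tab)[1], "'")
  }
  genes <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!apply(tab[, -1, drop = FALSE], 2, is.numeric))[1]
    stop("non-numeric counts in column '", colnames(tab)[-1][bad], "'")
  }
  for (j in seq_len(ncol(mat))) {
    bad <- which(mat[, j] < 0 | mat[, j] != round(mat[, j]))
    if (length(bad)) {
      stop("invalid count at row '", genes[bad[1]], "', column '",
           colnames(mat)[j], "': ", mat[bad[1], j])
    }
  }
  rownames(mat) <- genes
  tag_count_table(mat, totals)
}
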