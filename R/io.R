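#' Read and write the plain-text formats used by the pipeline
#'
#' All genomic intervals are 0-based, half-open, as in BED. Read sets are
#' BED6 with an optional seventh `seq` column holding the read sequence in
#' read orientation (reverse-complemented for minus-strand reads).
#'
#' @param path File path.
#' @param reads A BED6(+seq) data.frame.
#' @return `read_bed()` returns a data.frame with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand` and, when present in the file, `seq`.
#' @name bed_io
NULL

#' @rdname bed_io
#' @export
read_bed <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    return(empty_reads())
  }
  ncol <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  cols <- c("chrom", "start", "end", "name", "score", "strand", "seq")
  what <- list(character(), integer(), integer(), character(), numeric(),
               character(), character())
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = sapply(what[seq_len(ncol)], class),
                          col.names = cols[seq_len(ncol)],
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  df
}

#' @rdname bed_io
#' @export
write_bed <- function(reads, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand",
                      "seq"), names(reads))
  utils::write.table(reads[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read or write a two-column chromosome sizes table
#'
#' @param path File path.
#' @param chrom_sizes Named vector, chromosome name to length in bp.
#' @return `read_chrom_sizes()` returns a named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"),
                          stringsAsFactors = FALSE)
  check_chrom_sizes(stats::setNames(df$size, df$chrom))
}

#' @rdname read_chrom_sizes
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  check_chrom_sizes(chrom_sizes)
  utils::write.table(
    data.frame(chrom = names(chrom_sizes), size = as.numeric(chrom_sizes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read or write a bead-bead interaction pair list
#'
#' Tab-separated, two columns of bead ids per row; pairs are unordered.
#'
#' @param path File path.
#' @param pairs Two-column data.frame or matrix of bead ids.
#' @return `read_pairs()` returns a data.frame with columns `bead_a`, `bead_b`.
#' @export
read_pairs <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(bead_a = integer(), bead_b = integer()))
  }
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("bead_a", "bead_b"),
                    colClasses = c("integer", "integer"),
                    stringsAsFactors = FALSE)
}

#' @rdname read_pairs
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(as.data.frame(pairs)[, 1:2], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read or write windowed early/late replication read counts
#'
#' Tab-separated with a header: `chrom, start, end, early, late`, one row per
#' genomic window (0-based, half-open).
#'
#' @param path File path.
#' @param counts The windowed-count data.frame.
#' @return `read_window_counts()` returns the data.frame.
#' @export
read_window_counts <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_window_counts
#' @export
write_window_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
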