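#' Extract 10-nt damage windows from aligned Damage-seq reads
#'
#' In Damage-seq the lesion dinucleotide sits two nucleotides upstream of
#' the sequenced read's 5' start. Each aligned read is therefore converted
#' to a 10-nt window positioned so the lesion occupies read-orientation
#' positions 5-6 (1-based): a plus-strand read `[s, e)` yields window
#' `[s-6, s+4)`, a minus-strand read yields `[e-4, e+6)`. Windows that
#' would extend past a chromosome end cannot hold positions 5-6 and are
#' dropped (and counted) rather than clipped.
#'
#' @param reads BED6 data.frame of aligned reads, strands required.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return A list: `windows` (BED6 data.frame of 10-nt windows) and
#'   `n_dropped` (reads whose window fell out of bounds, plus reads on
#'   unknown chromosomes).
#' @export
#' @examples
#' reads <- data.frame(chrom = "chr1", start = 100L, end = 140L,
#'                     name = "r1", score = 0L, strand = "+")
#' extract_damage_windows(reads, c(chr1 = 1000))$windows
extract_damage_windows <- function(reads, chrom_sizes) {
  check_reads(reads)
  check_chrom_sizes(chrom_sizes)
  if (nrow(reads) == 0) {
    return(list(windows = empty_reads(), n_dropped = 0L))
  }
  known <- reads$chrom %in% names(chrom_sizes)
  r <- reads[known, , drop = FALSE]
  plus <- r$strand == "+"
  ws <- ifelse(plus, r$start - 6L, r$end - 4L)
  we <- ws + 10L
  L <- unname(chrom_sizes[r$chrom])
  ok <- ws >= 0 & we <= L
  windows <- data.frame(
    chrom = r$chrom[ok],
    start = as.integer(ws[ok]),
    end = as.integer(we[ok]),
    name = if (!is.null(r$name)) r$name[ok] else paste0("win_", seq_len(sum(ok))),
    score = if (!is.null(r$score)) r$score[ok] else 0L,
    strand = r$strand[ok],
    stringsAsFactors = FALSE
  )
  rownames(windows) <- NULL
  list(windows = windows, n_dropped = sum(!ok) + sum(!known))
}

#' Sort reads and remove duplicated regions
#'
#' Sorts by (chrom, start, end, strand) and collapses records identical on
#' all four keys to a single record, the standard PCR-duplicate removal on
#' BED intervals. Records identical in coordinates but on opposite strands
#' are both kept.
#'
#' @param reads BED6 data.frame.
#' @return The sorted, deduplicated data.frame.
#' @export
sort_dedup <- function(reads) {
  check_reads(reads)
  if (nrow(reads) == 0) return(reads)
  o <- order(reads$chrom, reads$start, reads$end, reads$strand)
  r <- reads[o, , drop = FALSE]
  key <- paste(r$chrom, r$start, r$end, r$strand, sep = "\r")
  r <- r[!duplicated(key), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Post-alignment processing of Damage-seq or XR-seq reads
#'
#' Damage mode extracts the 10-nt lesion windows then sorts and
#' deduplicates; XR mode keeps reads full-length (excision products map the
#' repair event directly) and only sorts and deduplicates.
#'
#' @param reads BED6 data.frame of aligned reads.
#' @param mode `"damage"` or `"xr"`.
#' @param chrom_sizes Named vector of chromosome lengths (damage mode).
#' @return A list: `reads` (processed BED6 data.frame) and `n_dropped`.
#' @export
process_reads <- function(reads, mode = c("damage", "xr"),
                          chrom_sizes = NULL) {
  mode <- match.arg(mode)
  if (mode == "damage") {
    if (is.null(chrom_sizes)) {
      stop("damage mode requires chrom_sizes", call. = FALSE)
    }
    ex <- extract_damage_windows(reads, chrom_sizes)
    list(reads = sort_dedup(ex$windows), n_dropped = ex$n_dropped)
  } else {
    list(reads = sort_dedup(reads), n_dropped = 0L)
  }
}
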