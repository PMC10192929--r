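#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
# All generators route their randomness through this so a given seed yields
# byte-identical output regardless of surrounding RNG use.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Radial shell labels for a nucleus
#'
#' Concentric 1-um (by default) shells are labeled by their radial bounds,
#' `"0-1"` for the central sphere out to `"4-5"` at the periphery for a
#' 5-um nucleus radius. Bins are half-open `[k, k+1)`.
#'
#' @param nucleus_radius Nucleus radius in micrometres.
#' @param shell_width Shell width in micrometres.
#' @return Character vector of shell labels, centre first.
#' @export
#' @examples
#' shell_labels()
shell_labels <- function(nucleus_radius = 5, shell_width = 1) {
  k <- seq(0, nucleus_radius - shell_width, by = shell_width)
  paste0(format_num(k), "-", format_num(k + shell_width))
}

format_num <- function(x) {
  ifelse(x == round(x), format(as.integer(round(x))), format(x))
}

stopifnot_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(what, " must be a single positive number", call. = FALSE)
  }
  invisible(x)
}

# Validate a chrom-sizes object: named numeric vector of positive lengths.
check_chrom_sizes <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("chrom_sizes must be a named vector (chromosome -> length bp)",
         call. = FALSE)
  }
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0)) {
    stop("all chromosome lengths must be positive", call. = FALSE)
  }
  invisible(chrom_sizes)
}

# Validate a read set data.frame (BED6-like, 0-based half-open intervals).
check_reads <- function(reads, require_seq = FALSE) {
  need <- c("chrom", "start", "end", "strand")
  miss <- setdiff(need, names(reads))
  if (length(miss)) {
    stop("read set missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(reads) > 0) {
    if (any(is.na(reads$strand)) || !all(reads$strand %in% c("+", "-"))) {
      stop("read strand must be '+' or '-'", call. = FALSE)
    }
    if (any(reads$end <= reads$start)) {
      stop("read intervals must satisfy end > start", call. = FALSE)
    }
  }
  if (require_seq && is.null(reads$seq)) {
    stop("read set must carry a 'seq' column", call. = FALSE)
  }
  invisible(reads)
}

# Empty BED6(+seq) data.frame with the package's canonical columns.
empty_reads <- function(with_seq = FALSE) {
  df <- data.frame(
    chrom = character(), start = integer(), end = integer(),
    name = character(), score = integer(), strand = character(),
    stringsAsFactors = FALSE
  )
  if (with_seq) df$seq <- character()
  df
}

reads_as_granges <- function(reads) {
  GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = reads$start + 1L, end = reads$end),
    strand = reads$strand
  )
}
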