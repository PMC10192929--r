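#' Infer per-length, per-position nucleotide frequency profiles
#'
#' For each read length present in the input, computes the empirical 4 x L
#' matrix of A/C/G/T frequencies at every read position (in read
#' orientation), plus the empirical read-length distribution. Non-ACGT
#' bases are excluded from their column's denominator.
#'
#' @param seqs Character vector of read sequences, or a read data.frame
#'   carrying a `seq` column.
#' @return An object of class `freq_profile`: list with `matrices` (named
#'   by length; each a 4 x L matrix with rows A, C, G, T, columns summing
#'   to 1), `length_dist` (named probabilities over lengths) and
#'   `n_per_length` (reads behind each matrix, used downstream to scale
#'   profile smoothing).
#' @export
#' @examples
#' infer_freq_profile(c("AAAA", "TTTT"))
infer_freq_profile <- function(seqs) {
  if (is.data.frame(seqs)) {
    check_reads(seqs, require_seq = TRUE)
    seqs <- seqs$seq
  }
  if (length(seqs) == 0) stop("no reads to profile", call. = FALSE)
  lens <- nchar(seqs)
  length_dist <- table(lens) / length(lens)
  matrices <- lapply(sort(unique(lens)), function(L) {
    x <- Biostrings::DNAStringSet(seqs[lens == L])
    cm <- Biostrings::consensusMatrix(x)[c("A", "C", "G", "T"), ,
                                         drop = FALSE]
    denom <- colSums(cm)
    denom[denom == 0] <- 1
    sweep(cm, 2, denom, "/")
  })
  names(matrices) <- as.character(sort(unique(lens)))
  n_per_length <- vapply(as.integer(names(matrices)),
                         function(L) sum(lens == L), numeric(1))
  structure(
    list(matrices = matrices,
         length_dist = stats::setNames(as.numeric(length_dist),
                                       names(length_dist)),
         n_per_length = stats::setNames(n_per_length, names(matrices))),
    class = "freq_profile"
  )
}

#' @export
print.freq_profile <- function(x, ...) {
  cat("freq_profile over read lengths:",
      paste(names(x$matrices), collapse = ", "), "\n")
  invisible(x)
}

#' Mean absolute deviation between two frequency profiles
#'
#' Averaged over all (base, position) cells of the lengths shared by both
#' profiles; the convergence measure for the read simulator.
#'
#' @param target,emitted [freq_profile] objects.
#' @return Named numeric vector, one MAD per shared read length.
#' @export
freq_profile_mad <- function(target, emitted) {
  shared <- intersect(names(target$matrices), names(emitted$matrices))
  if (!length(shared)) stop("profiles share no read length", call. = FALSE)
  vapply(shared, function(L) {
    mean(abs(target$matrices[[L]] - emitted$matrices[[L]]))
  }, numeric(1))
}
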