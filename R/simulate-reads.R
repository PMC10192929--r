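#' Simulate reads matching a nucleotide frequency profile
#'
#' Draws pseudo-reads from a reference genome (or from the footprint of a
#' background read set, which preserves regional copy number) so that the
#' emitted reads match a target per-length, per-position nucleotide
#' frequency profile. Candidates are proposed uniformly from the reference
#' (or from background read intervals) and accepted with probability
#' proportional to the product over read positions of the ratio of the
#' target frequency to the profile's typical (median-across-positions)
#' composition — so only positions that deviate from the profile background
#' (the lesion dinucleotide of a damage profile) filter candidates —
#' continually adjusted by a closed-loop feedback factor, the ratio of
#' target to already-emitted frequency clamped to
#' `[1/feedback_clamp, feedback_clamp]`, which steers the running output
#' onto the target.
#'
#' @param genome Named [Biostrings::DNAStringSet] reference.
#' @param profile Target [freq_profile], e.g. from [infer_freq_profile()]
#'   on the observed reads.
#' @param n Number of reads to emit; lengths are drawn multinomially from
#'   the profile's length distribution.
#' @param seed Integer seed.
#' @param background Optional BED6 data.frame of background (input DNA)
#'   reads; candidate coordinates are then drawn from these intervals so
#'   simulated read density tracks background density.
#' @param epsilon Convergence goal: mean absolute deviation between target
#'   and emitted per-position frequencies (reported, not enforced
#'   per-read).
#' @param max_attempts Maximum proposed candidates per requested read
#'   before aborting with a diagnostic of the worst-matched positions.
#' @param feedback_clamp Bound on the per-position feedback ratio.
#' @param batch_size Candidates proposed per vectorised batch.
#' @return BED6 data.frame with a `seq` column; attribute `mad` holds the
#'   per-length MAD between target and emitted profiles.
#' @export
simulate_reads <- function(genome, profile, n, seed, background = NULL,
                           epsilon = 0.02, max_attempts = 200,
                           feedback_clamp = 1.5, batch_size = 20000L) {
  stopifnot(inherits(profile, "freq_profile"), n > 0)
  if (!is.null(background)) check_reads(background)
  with_seed(seed, {
    lens <- as.integer(names(profile$length_dist))
    n_per_len <- as.vector(stats::rmultinom(1, n, profile$length_dist))
    pieces <- vector("list", length(lens))
    for (k in seq_along(lens)) {
      if (n_per_len[k] == 0) next
      n_obs <- profile$n_per_length[[as.character(lens[k])]]
      if (is.null(n_obs)) n_obs <- 500
      pieces[[k]] <- simulate_one_length(
        genome, background, profile$matrices[[as.character(lens[k])]],
        lens[k], n_per_len[k], n_obs, max_attempts, feedback_clamp,
        batch_size
      )
    }
    out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
    out <- out[sample.int(nrow(out)), ]
    out$name <- paste0("sim_", seq_len(nrow(out)))
    out <- out[, c("chrom", "start", "end", "name", "score", "strand", "seq")]
    rownames(out) <- NULL
    attr(out, "mad") <- freq_profile_mad(profile, infer_freq_profile(out$seq))
    out
  })
}

simulate_one_length <- function(genome, background, target, L, n_l, n_obs,
                                max_attempts, feedback_clamp,
                                batch_size) {
  # Static acceptance weight. The baseline is the profile's own typical
  # composition (median across positions): positions whose target matches
  # the profile background pass unfiltered, so only genuinely deviant
  # positions (the lesion dinucleotide of a damage profile) steer
  # acceptance, and a read's acceptance tracks the local availability of
  # those deviant bases. Aggregate per-position convergence onto the target
  # is then the feedback loop's job. Columns are normalised by their
  # maximum so log-weights are <= 0.
  # Shrink the steering target toward the profile baseline in proportion to
  # the read count behind the profile (Dirichlet prior of 25 pseudo-reads).
  # A sparse length class has sampling noise in every column, and because
  # per-column log-weights add over L positions, unshrunk noise would
  # compound into vanishing acceptance; shrinkage leaves well-supported
  # deviations (the lesion dinucleotide) sharp while the feedback loop
  # still drives the emitted aggregate onto the raw empirical target.
  # Genuinely unattainable targets reject orders of magnitude harder than
  # noisy ones and abort through the attempt budget.
  t0 <- (target * n_obs + 4) / (n_obs + 16)
  ref_comp <- apply(t0, 1, stats::median)
  ref_comp <- ref_comp / sum(ref_comp)
  t_acc <- sweep(target * n_obs, 1, 25 * ref_comp, "+") / (n_obs + 25)
  lw_static <- log(t_acc) - log(ref_comp)
  lw_static <- sweep(lw_static, 2, apply(lw_static, 2, max), "-")
  emitted <- target * 50 + 1e-9                   # pseudocounts seed feedback
  acc <- vector("list", 64L)
  n_acc <- 0L
  n_chunks <- 0L
  proposed <- 0L
  # floor the budget: a sparse length class needing a handful of reads may
  # still face a noisy (hence selective) target, and batched candidates are
  # cheap; a genuinely unattainable target rejects orders of magnitude
  # harder and still exhausts this budget
  budget <- max_attempts * max(n_l, 250L)
  while (n_acc < n_l) {
    if (proposed >= budget) {
      efreq <- sweep(emitted, 2, colSums(emitted), "/")
      dev <- colSums(abs(target - efreq))
      worst <- order(dev, decreasing = TRUE)[seq_len(min(3L, L))]
      stop("simulate_reads: target profile unattainable from the reference ",
           "within max_attempts; worst positions: ",
           paste0(worst, " (dev=", signif(dev[worst], 3), ")",
                  collapse = ", "), call. = FALSE)
    }
    m <- min(batch_size, budget - proposed)
    cand <- propose_candidates(genome, background, L, m)
    proposed <- proposed + m
    codes <- candidate_codes(cand$seq, L)
    keep <- !is.na(codes$bad) & !codes$bad
    if (!any(keep)) next
    efreq <- sweep(emitted, 2, colSums(emitted), "/")
    lf <- log(pmin(pmax(target / efreq, 1 / feedback_clamp), feedback_clamp))
    W <- lw_static + lf
    idx <- cbind(as.vector(codes$codes[keep, , drop = FALSE]),
                 rep(seq_len(L), each = sum(keep)))
    lp <- rowSums(matrix(W[idx], nrow = sum(keep)))
    p <- pmin(1, exp(lp))
    u <- stats::runif(length(p))
    sel <- which(u < p)
    if (!length(sel)) next
    sel <- sel[seq_len(min(length(sel), n_l - n_acc))]
    rows <- which(keep)[sel]
    taken <- cand[rows, , drop = FALSE]
    # update running emitted counts (the feedback loop's memory)
    cm <- Biostrings::consensusMatrix(
      Biostrings::DNAStringSet(taken$seq)
    )[c("A", "C", "G", "T"), , drop = FALSE]
    emitted <- emitted + cm
    n_chunks <- n_chunks + 1L
    if (n_chunks > length(acc)) acc <- c(acc, vector("list", length(acc)))
    acc[[n_chunks]] <- taken
    n_acc <- n_acc + nrow(taken)
  }
  do.call(rbind, acc[seq_len(n_chunks)])
}

propose_candidates <- function(genome, background, L, m) {
  widths <- Biostrings::width(genome)
  if (is.null(background)) {
    ok_chr <- which(widths >= L)
    w <- widths[ok_chr] - L + 1
    ci <- ok_chr[sample.int(length(ok_chr), m, replace = TRUE,
                            prob = w / sum(w))]
    start <- floor(stats::runif(m) * (widths[ci] - L + 1))
    chrom <- names(genome)[ci]
  } else {
    bi <- sample.int(nrow(background), m, replace = TRUE)
    bs <- background$start[bi]
    be <- background$end[bi]
    bw <- be - bs
    # fit the candidate inside the background read when it is long enough,
    # otherwise centre it on the background read
    off <- floor(stats::runif(m) * pmax(bw - L + 1, 1))
    start <- ifelse(bw >= L, bs + off, bs + bw %/% 2L - L %/% 2L)
    chrom <- background$chrom[bi]
    lim <- genome_sizes(genome)[chrom] - L
    start <- pmax(0, pmin(start, lim))
  }
  cand <- data.frame(chrom = chrom, start = as.integer(start),
                     end = as.integer(start + L), score = 0L,
                     strand = sample(c("+", "-"), m, replace = TRUE),
                     stringsAsFactors = FALSE)
  cand$seq <- extract_read_seqs(genome, cand)
  cand
}

candidate_codes <- function(seqs, L) {
  chars <- as.matrix(Biostrings::DNAStringSet(seqs))
  codes <- matrix(match(chars, c("A", "C", "G", "T")), nrow = nrow(chars))
  list(codes = codes, bad = rowSums(is.na(codes)) > 0)
}
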