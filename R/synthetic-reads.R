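#' Specify a planted radial effect on read sampling
#'
#' Describes how strongly reads are drawn from beads in each radial shell:
#' a per-shell multiplier on the sampling rate, relative to a uniform rate
#' proportional to bead length. Shells omitted from the map keep
#' multiplier 1.
#'
#' @param per_shell_multiplier Named numeric vector, shell label (for
#'   example `"4-5"`) to positive multiplier.
#' @param baseline_rate Optional baseline sampling rate in reads per kb,
#'   used to derive a read count when one is not given explicitly.
#' @param nucleus_radius,shell_width Geometry defining the valid shell
#'   label set.
#' @return An object of class `radial_effect`.
#' @export
#' @examples
#' eff <- radial_effect(c("4-5" = 2))
radial_effect <- function(per_shell_multiplier, baseline_rate = NULL,
                          nucleus_radius = 5, shell_width = 1) {
  labels <- shell_labels(nucleus_radius, shell_width)
  m <- unlist(per_shell_multiplier)
  if (length(m) && (is.null(names(m)) || !all(names(m) %in% labels))) {
    stop("multiplier names must be shell labels: ",
         paste(labels, collapse = ", "), call. = FALSE)
  }
  if (any(m <= 0)) stop("shell multipliers must be > 0", call. = FALSE)
  full <- stats::setNames(rep(1, length(labels)), labels)
  full[names(m)] <- m
  structure(list(per_shell_multiplier = full, baseline_rate = baseline_rate),
            class = "radial_effect")
}

#' Plant a bead-to-shell assignment
#'
#' Assigns beads to radial shells directly, without running the geometric
#' optimizer, so that planted radial read-sampling effects can be recovered
#' by the downstream analysis. By default beads are spread uniformly across
#' shells, which, unlike geometric placement, populates the small central
#' shell well enough for shell-level statistics.
#'
#' @param bead_ids Integer vector of bead ids.
#' @param seed Integer seed.
#' @param shell_prob Optional probabilities over shells (recycled names of
#'   [shell_labels()]); default uniform.
#' @param nucleus_radius,shell_width Shell geometry.
#' @return Data.frame with columns `bead_id`, `shell`.
#' @export
plant_shell_assignment <- function(bead_ids, seed, shell_prob = NULL,
                                   nucleus_radius = 5, shell_width = 1) {
  labels <- shell_labels(nucleus_radius, shell_width)
  if (is.null(shell_prob)) shell_prob <- rep(1 / length(labels), length(labels))
  with_seed(seed, {
    # balanced base assignment, then shuffled: every shell is populated
    # whenever there are at least as many beads as shells
    base <- rep(labels, length.out = length(bead_ids))
    if (!is.null(shell_prob) && length(unique(shell_prob)) > 1) {
      base <- sample(labels, length(bead_ids), replace = TRUE,
                     prob = shell_prob)
    }
    data.frame(bead_id = as.integer(bead_ids), shell = sample(base),
               stringsAsFactors = FALSE)
  })
}

#' Excision-product read-length distribution
#'
#' Truncated distribution over 20-30 nt with mode 26, the typical length
#' range of human nucleotide excision repair products captured by XR-seq.
#'
#' @return Named numeric probabilities over lengths 20 to 30.
#' @export
xr_length_dist <- function() {
  p <- stats::dbinom(0:10, size = 10, prob = 0.6)
  stats::setNames(p / sum(p), 20:30)
}

#' Generate synthetic sequencing reads over a bead partition
#'
#' Emulates three read kinds. `"input"` reads are composition-unbiased:
#' sampled per bead at rate proportional to bead length times the planted
#' shell multiplier, uniformly within the bead. `"damage"` reads emulate
#' Damage-seq: with probability `purity` a read starts exactly two
#' nucleotides downstream of a real dipyrimidine in the genome (so the
#' lesion occupies positions 5-6 of the 10-nt window recovered by
#' [extract_damage_windows()]); sites are sampled with weight equal to the
#' containing bead's shell multiplier, so read density tracks both the
#' genome's dipyrimidine density and the planted radial effect. `"repair"`
#' reads emulate XR-seq excision products: variable lengths (default
#' [xr_length_dist()]) containing a dipyrimidine near the 3' end.
#'
#' @param partition Bead partition data.frame (`chrom`, `start`, `end`,
#'   `bead_id`), tiling each chromosome (see [build_bead_partition()]).
#' @param kind One of `"input"`, `"damage"`, `"repair"`.
#' @param n_reads Number of reads to draw.
#' @param seed Integer seed.
#' @param genome Optional [Biostrings::DNAStringSet]; required for
#'   `"damage"`/`"repair"` kinds and for emitting sequences.
#' @param effect Optional [radial_effect()]; requires `shells`.
#' @param shells Bead-to-shell assignment data.frame (`bead_id`, `shell`),
#'   required when `effect` is given.
#' @param read_length Single length, or named probability vector over
#'   lengths. Defaults: 40 (damage), 50 (input), [xr_length_dist()] (repair).
#' @param purity Fraction of damage/repair reads anchored at a true
#'   dipyrimidine site.
#' @param with_seq Attach read sequences (read orientation); requires
#'   `genome`.
#' @return BED6 data.frame of reads, optionally with a `seq` column.
#' @export
generate_reads <- function(partition, kind = c("input", "damage", "repair"),
                           n_reads, seed, genome = NULL, effect = NULL,
                           shells = NULL, read_length = NULL, purity = 0.95,
                           with_seq = !is.null(genome)) {
  kind <- match.arg(kind)
  if (!is.null(effect) && is.null(shells)) {
    stop("a bead-to-shell assignment must be supplied with a radial effect",
         call. = FALSE)
  }
  if (kind %in% c("damage", "repair") && is.null(genome)) {
    stop(kind, " reads require a genome to locate dipyrimidine sites",
         call. = FALSE)
  }
  if (with_seq && is.null(genome)) {
    stop("sequences require a genome", call. = FALSE)
  }
  if (is.null(read_length)) {
    read_length <- switch(kind, damage = 40L, input = 50L,
                          repair = xr_length_dist())
  }
  chrom_sizes <- tapply(partition$end, partition$chrom, max)
  chrom_sizes <- stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  mult <- bead_multipliers(partition, effect, shells)

  with_seed(seed, {
    lens <- draw_lengths(read_length, n_reads)
    if (kind == "input") {
      reads <- sample_uniform_reads(partition, mult, lens, chrom_sizes)
    } else {
      pure <- stats::rbinom(1, n_reads, purity)
      site_reads <- sample_site_reads(partition, mult, genome,
                                      lens[seq_len(pure)], kind, chrom_sizes)
      bg_reads <- sample_uniform_reads(partition, mult,
                                       lens[seq_len(n_reads - pure) + pure],
                                       chrom_sizes)
      reads <- rbind(site_reads, bg_reads)
      if (nrow(reads)) reads <- reads[sample.int(nrow(reads)), ]
    }
    reads$name <- paste0(kind, "_", seq_len(nrow(reads)))
    reads$score <- 0L
    reads <- reads[, c("chrom", "start", "end", "name", "score", "strand")]
    rownames(reads) <- NULL
    if (with_seq && nrow(reads)) {
      reads$seq <- extract_read_seqs(genome, reads)
    } else if (with_seq) {
      reads$seq <- character(0)
    }
    reads
  })
}

bead_multipliers <- function(partition, effect, shells) {
  if (is.null(effect)) {
    return(rep(1, nrow(partition)))
  }
  sh <- shells$shell[match(partition$bead_id, shells$bead_id)]
  if (any(is.na(sh))) {
    stop("shell assignment missing for some beads", call. = FALSE)
  }
  unname(effect$per_shell_multiplier[sh])
}

draw_lengths <- function(read_length, n) {
  if (length(read_length) == 1L && is.null(names(read_length))) {
    return(rep(as.integer(read_length), n))
  }
  as.integer(sample(names(read_length), n, replace = TRUE,
                    prob = read_length))
}

# Uniform within-bead sampling: bead chosen with probability proportional
# to bp x multiplier, read midpoint uniform in the bead.
sample_uniform_reads <- function(partition, mult, lens, chrom_sizes) {
  n <- length(lens)
  if (n == 0) return(empty_reads()[, c("chrom", "start", "end", "strand")])
  w <- (partition$end - partition$start) * mult
  bead <- sample.int(nrow(partition), n, replace = TRUE, prob = w)
  span <- partition$end[bead] - partition$start[bead]
  mid <- partition$start[bead] + floor(stats::runif(n) * span)
  start <- mid - lens %/% 2L
  L <- chrom_sizes[partition$chrom[bead]]
  start <- pmax(0L, pmin(start, as.integer(L - lens)))
  data.frame(chrom = partition$chrom[bead], start = as.integer(start),
             end = as.integer(start + lens),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Enumerate dipyrimidine dimer start positions (0-based) per chromosome.
# plus: pyrimidine-pyrimidine on the forward strand; minus: purine-purine on
# the forward strand (a dipyrimidine on the reverse strand).
dipyrimidine_sites <- function(genome) {
  pats <- list(plus = c("TT", "TC", "CT", "CC"),
               minus = c("AA", "AG", "GA", "GG"))
  lapply(stats::setNames(names(genome), names(genome)), function(chrom) {
    subj <- genome[[chrom]]
    lapply(pats, function(ps) {
      starts <- unlist(lapply(ps, function(p) {
        BiocGenerics::start(Biostrings::matchPattern(p, subj))
      }))
      sort(as.integer(starts)) - 1L
    })
  })
}

# Reads anchored at dipyrimidine sites. For damage reads the dimer sits two
# nucleotides upstream of the read 5' start; for repair reads it sits at
# read positions (L-6, L-5), near the 3' end of the excision product.
sample_site_reads <- function(partition, mult, genome, lens, kind,
                              chrom_sizes) {
  n <- length(lens)
  if (n == 0) return(empty_reads()[, c("chrom", "start", "end", "strand")])
  sites <- dipyrimidine_sites(genome)
  # flatten to one table: chrom, dimer start d, strand, bead multiplier
  tabs <- lapply(names(sites), function(chrom) {
    part <- partition[partition$chrom == chrom, ]
    m <- mult[partition$chrom == chrom]
    rbind(
      data.frame(chrom = chrom, d = sites[[chrom]]$plus, strand = "+",
                 stringsAsFactors = FALSE),
      data.frame(chrom = chrom, d = sites[[chrom]]$minus, strand = "-",
                 stringsAsFactors = FALSE)
    ) -> tab
    if (nrow(part)) {
      idx <- findInterval(tab$d, part$start)
      idx[idx < 1L] <- 1L
      tab$w <- m[idx]
    } else {
      tab$w <- 0
    }
    tab
  })
  tab <- do.call(rbind, tabs)
  if (!nrow(tab) || all(tab$w == 0)) {
    stop("no dipyrimidine sites available", call. = FALSE)
  }
  pick <- sample.int(nrow(tab), n, replace = TRUE, prob = tab$w)
  d <- tab$d[pick]
  strand <- tab$strand[pick]
  chrom <- tab$chrom[pick]
  if (kind == "damage") {
    # + read: dimer at [s-2, s); - read [s,e): dimer at [e, e+2)
    start <- ifelse(strand == "+", d + 2L, d - lens)
  } else {
    # dimer at read positions (L-6, L-5), 1-based, in read orientation
    start <- ifelse(strand == "+", d - lens + 7L, d - 5L)
  }
  end <- start + lens
  L <- chrom_sizes[chrom]
  ok <- start >= 0 & end <= L &
    (strand == "+" | kind != "damage" | d + 2L <= L)
  # replace out-of-bounds anchors by resampling from the interior; with
  # bead-scale chromosomes the edge loss is negligible, so recycle valid rows
  if (any(!ok)) {
    repl <- sample(which(ok), sum(!ok), replace = TRUE)
    start[!ok] <- start[repl]
    end[!ok] <- end[repl]
    chrom[!ok] <- chrom[repl]
    strand[!ok] <- strand[repl]
  }
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

#' Extract read sequences from a genome
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param reads BED6 data.frame; minus-strand reads are
#'   reverse-complemented.
#' @return Character vector of sequences in read orientation.
#' @export
extract_read_seqs <- function(genome, reads) {
  check_reads(reads)
  out <- character(nrow(reads))
  for (chrom in unique(reads$chrom)) {
    i <- which(reads$chrom == chrom)
    ss <- Biostrings::extractAt(
      genome[[chrom]],
      IRanges::IRanges(start = reads$start[i] + 1L, end = reads$end[i])
    )
    neg <- reads$strand[i] == "-"
    if (any(neg)) ss[neg] <- Biostrings::reverseComplement(ss[neg])
    out[i] <- as.character(ss)
  }
  out
}

#' Generate windowed early/late replication read counts
#'
#' Tiles each chromosome with fixed-size windows and draws Poisson counts
#' for an early and a late sequencing fraction. Inside planted early
#' domains the early fraction is elevated by `2^(log2_effect / 2)` and the
#' late fraction depressed symmetrically; everywhere else (the late
#' background) the pattern is reversed. A trailing window shorter than
#' `window` is kept and flagged `partial`.
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param early_domains BED-like data.frame of true early-replicating
#'   intervals; the complement is late-replicating.
#' @param seed Integer seed.
#' @param window Window size in bp (50 kb by default).
#' @param depth Expected reads per fraction per full window.
#' @param log2_effect Planted log2 early/late ratio inside early domains.
#' @return Data.frame `chrom, start, end, early, late, partial`.
#' @export
generate_edu_counts <- function(chrom_sizes, early_domains, seed,
                                window = 50000L, depth = 100,
                                log2_effect = 1) {
  check_chrom_sizes(chrom_sizes)
  with_seed(seed, {
    out <- lapply(names(chrom_sizes), function(chrom) {
      L <- as.integer(chrom_sizes[[chrom]])
      starts <- seq.int(0L, L - 1L, by = as.integer(window))
      ends <- pmin(starts + as.integer(window), L)
      mid <- (starts + ends) / 2
      ed <- early_domains[early_domains$chrom == chrom, , drop = FALSE]
      is_early <- rep(FALSE, length(starts))
      if (nrow(ed)) {
        for (j in seq_len(nrow(ed))) {
          is_early <- is_early | (mid >= ed$start[j] & mid < ed$end[j])
        }
      }
      frac <- (ends - starts) / window
      hi <- depth * 2^(log2_effect / 2) * frac
      lo <- depth * 2^(-log2_effect / 2) * frac
      data.frame(
        chrom = chrom, start = starts, end = ends,
        early = stats::rpois(length(starts), ifelse(is_early, hi, lo)),
        late = stats::rpois(length(starts), ifelse(is_early, lo, hi)),
        partial = ends - starts < window,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
}
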