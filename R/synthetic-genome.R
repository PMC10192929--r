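#' Specify a synthetic genome
#'
#' A genome specification holds chromosome sizes, a base composition, and an
#' optional positional dipyrimidine gradient. The gradient multiplies the
#' TT/TC dinucleotide density linearly from the 5' to the 3' end of a
#' chromosome: a multiplier of `g` makes TT+TC density at the 3' end `g`
#' times that at the 5' end (pyrimidine probabilities are scaled by
#' `sqrt(m(x))` since dipyrimidine density is quadratic in them).
#'
#' @param chrom_sizes Named vector, chromosome name to length in bp.
#' @param base_composition Probabilities over A, C, G, T (must sum to 1).
#' @param dipyrimidine_gradient Optional named vector/list, chromosome to
#'   gradient multiplier (> 0); chromosomes absent from it get multiplier 1.
#' @return An object of class `genome_spec`.
#' @export
#' @examples
#' spec <- genome_spec(c(chr1 = 1e5))
genome_spec <- function(chrom_sizes,
                        base_composition = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25),
                        dipyrimidine_gradient = NULL) {
  check_chrom_sizes(chrom_sizes)
  bc <- base_composition[c("A", "C", "G", "T")]
  if (any(is.na(bc)) || abs(sum(bc) - 1) > 1e-9 || any(bc < 0)) {
    stop("base_composition must be probabilities over A, C, G, T summing to 1",
         call. = FALSE)
  }
  if (!is.null(dipyrimidine_gradient)) {
    g <- unlist(dipyrimidine_gradient)
    if (any(g <= 0)) stop("gradient multipliers must be > 0", call. = FALSE)
    unknown <- setdiff(names(g), names(chrom_sizes))
    if (length(unknown)) {
      stop("gradient names unknown chromosome(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    dipyrimidine_gradient <- g
  }
  structure(
    list(chrom_sizes = chrom_sizes, base_composition = bc,
         dipyrimidine_gradient = dipyrimidine_gradient),
    class = "genome_spec"
  )
}

#' Generate a synthetic genome
#'
#' Draws each chromosome independently from the specification's base
#' composition, applying the positional dipyrimidine gradient if one is set.
#' The sequence is generated in 1-kb blocks with per-block base
#' probabilities, so the gradient is piecewise constant at 1-kb resolution.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed; identical seeds give byte-identical genomes.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
#' @examples
#' genome <- generate_genome(genome_spec(c(chr1 = 5000)), seed = 7)
generate_genome <- function(spec, seed) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(seed, {
    seqs <- lapply(names(spec$chrom_sizes), function(chrom) {
      len <- as.integer(spec$chrom_sizes[[chrom]])
      g <- 1
      if (!is.null(spec$dipyrimidine_gradient) &&
          chrom %in% names(spec$dipyrimidine_gradient)) {
        g <- spec$dipyrimidine_gradient[[chrom]]
      }
      generate_chrom_seq(len, spec$base_composition, g)
    })
    out <- Biostrings::DNAStringSet(unlist(seqs))
    names(out) <- names(spec$chrom_sizes)
    out
  })
}

# One chromosome as a character string; gradient g multiplies TT/TC density
# linearly from 1 (5' end) to g (3' end).
generate_chrom_seq <- function(len, bc, g, block = 1000L) {
  n_blocks <- ceiling(len / block)
  pieces <- character(n_blocks)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n_blocks)) {
    from <- (i - 1L) * block
    size <- min(block, len - from)
    x <- (from + size / 2) / len          # position fraction along chromosome
    m <- 1 + (g - 1) * x                  # dinucleotide-density multiplier
    s <- sqrt(m)
    p_py <- (bc[["C"]] + bc[["T"]]) * s
    if (p_py > 0.995) {
      stop("dipyrimidine gradient infeasible: pyrimidine probability would ",
           "reach ", round(p_py, 3), call. = FALSE)
    }
    pu <- bc[["A"]] + bc[["G"]]
    scale_pu <- if (pu > 0) (1 - p_py) / pu else 0
    prob <- c(bc[["A"]] * scale_pu, bc[["C"]] * s,
              bc[["G"]] * scale_pu, bc[["T"]] * s)
    pieces[i] <- paste(sample(bases, size, replace = TRUE, prob = prob),
                       collapse = "")
  }
  paste(pieces, collapse = "")
}

#' Chromosome sizes of a genome
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return Named numeric vector of sequence lengths.
#' @export
genome_sizes <- function(genome) {
  stats::setNames(as.numeric(Biostrings::width(genome)), names(genome))
}

#' Generate random genomic intervals (contact domains or genes)
#'
#' Domains are placed uniformly at random: each interval is assigned to a
#' chromosome with probability proportional to its length, given a length
#' drawn uniformly from `size_range`. With `allow_overlap = FALSE` the
#' intervals on each chromosome are laid out without overlap by distributing
#' the free space between them uniformly; with `allow_overlap = TRUE` starts
#' are independent and at least one overlapping pair is guaranteed (when two
#' or more intervals exist) so downstream merging is exercised.
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param n_domains Number of intervals to generate.
#' @param size_range Length-2 vector, minimum and maximum interval size (bp).
#' @param seed Integer seed.
#' @param allow_overlap Allow (and guarantee) overlapping intervals.
#' @param prefix Name prefix for the interval names.
#' @return BED-like data.frame (`chrom`, `start`, `end`, `name`), sorted.
#' @export
generate_domains <- function(chrom_sizes, n_domains, size_range, seed,
                             allow_overlap = FALSE, prefix = "domain") {
  check_chrom_sizes(chrom_sizes)
  if (n_domains == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      stringsAsFactors = FALSE))
  }
  size_range <- as.integer(size_range)
  if (length(size_range) != 2L || size_range[1] > size_range[2] ||
      size_range[1] < 1L) {
    stop("size_range must be an increasing pair of positive sizes",
         call. = FALSE)
  }
  if (size_range[2] > max(chrom_sizes)) {
    stop("size_range exceeds every chromosome", call. = FALSE)
  }
  with_seed(seed, {
    chroms <- sample(names(chrom_sizes), n_domains, replace = TRUE,
                     prob = chrom_sizes / sum(chrom_sizes))
    lens <- sample(size_range[1]:size_range[2], n_domains, replace = TRUE)
    out <- vector("list", length(chrom_sizes))
    for (k in seq_along(chrom_sizes)) {
      chrom <- names(chrom_sizes)[k]
      idx <- which(chroms == chrom)
      if (!length(idx)) next
      L <- as.integer(chrom_sizes[[k]])
      li <- lens[idx]
      if (allow_overlap) {
        starts <- vapply(li, function(l) {
          sample.int(L - l + 1L, 1L) - 1L
        }, integer(1))
      } else {
        free <- L - sum(li)
        if (free < 0) {
          stop("n_domains infeasible: ", chrom, " cannot hold ",
               length(idx), " non-overlapping domains", call. = FALSE)
        }
        gaps <- diff(c(0, sort(stats::runif(length(li))), 1)) * free
        starts <- as.integer(floor(cumsum(gaps)[-length(gaps)] +
                                     cumsum(c(0, li[-length(li)]))))
      }
      out[[k]] <- data.frame(chrom = chrom, start = starts,
                             end = starts + li, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (allow_overlap && nrow(df) >= 2) {
      # guarantee an overlapping pair: shift record 2 onto record 1 if the
      # random layout happens to be overlap-free
      gr <- GenomicRanges::GRanges(df$chrom,
                                   IRanges::IRanges(df$start + 1L, df$end))
      if (!any(IRanges::countOverlaps(gr) > 1L)) {
        l2 <- df$end[2] - df$start[2]
        df$chrom[2] <- df$chrom[1]
        df$start[2] <- df$start[1] + max(1L, (df$end[1] - df$start[1]) %/% 2L)
        df$end[2] <- min(df$start[2] + l2,
                         as.integer(chrom_sizes[[df$chrom[1]]]))
      }
    }
    df <- df[order(match(df$chrom, names(chrom_sizes)), df$start, df$end), ]
    df$name <- paste0(prefix, "_", seq_len(nrow(df)))
    rownames(df) <- NULL
    df
  })
}

#' Generate gene intervals
#'
#' Convenience wrapper around [generate_domains()] with overlap allowed by
#' default, emulating an unmerged gene annotation.
#'
#' @inheritParams generate_domains
#' @param n_genes Number of genes.
#' @export
generate_genes <- function(chrom_sizes, n_genes, size_range, seed,
                           allow_overlap = TRUE) {
  generate_domains(chrom_sizes, n_genes, size_range, seed,
                   allow_overlap = allow_overlap, prefix = "gene")
}

#' Generate significant bead-bead interaction pairs
#'
#' Emits distinct unordered bead-id pairs. When `central_set` is given, a
#' fraction `excess` of the pairs is drawn from within that set, planting
#' the radial structure that the interaction-constrained optimizer is
#' expected to recover (interacting beads are pulled together, so a densely
#' self-interacting set ends up spatially clustered).
#'
#' @param bead_ids Integer vector of bead ids.
#' @param n_pairs Number of distinct pairs to generate.
#' @param seed Integer seed.
#' @param central_set Optional subset of `bead_ids` to enrich for
#'   within-set pairs.
#' @param excess Fraction of pairs falling within `central_set`.
#' @return Data.frame with columns `bead_a`, `bead_b` (`bead_a < bead_b`).
#' @export
generate_interactions <- function(bead_ids, n_pairs, seed,
                                  central_set = NULL, excess = 0.8) {
  bead_ids <- as.integer(bead_ids)
  n <- length(bead_ids)
  possible <- n * (n - 1) / 2
  if (n_pairs > possible) {
    stop("n_pairs exceeds the ", possible, " possible distinct pairs",
         call. = FALSE)
  }
  if (n_pairs == 0) {
    return(data.frame(bead_a = integer(), bead_b = integer()))
  }
  if (!is.null(central_set) && !all(central_set %in% bead_ids)) {
    stop("central_set contains unknown bead ids", call. = FALSE)
  }
  with_seed(seed, {
    if (is.null(central_set)) {
      pairs <- sample_distinct_pairs(bead_ids, n_pairs)
    } else {
      n_in <- min(round(excess * n_pairs),
                  length(central_set) * (length(central_set) - 1) / 2)
      inner <- sample_distinct_pairs(as.integer(central_set), n_in)
      outer <- sample_distinct_pairs(bead_ids, n_pairs - n_in,
                                     exclude = inner,
                                     not_within = as.integer(central_set))
      pairs <- rbind(inner, outer)
    }
    rownames(pairs) <- NULL
    pairs
  })
}

# Distinct unordered pairs by rejection sampling with enumeration fallback.
# `exclude`: pairs already taken; `not_within`: disallow pairs fully inside
# this set (keeps the planted excess fraction exact).
sample_distinct_pairs <- function(ids, k, exclude = NULL, not_within = NULL) {
  if (k == 0) return(data.frame(bead_a = integer(), bead_b = integer()))
  n <- length(ids)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  taken <- if (is.null(exclude)) character() else key(exclude[[1]], exclude[[2]])
  acc_a <- integer(0)
  acc_b <- integer(0)
  attempts <- 0L
  while (length(acc_a) < k && attempts < 60L) {
    m <- max(2L * (k - length(acc_a)), 16L)
    a <- ids[sample.int(n, m, replace = TRUE)]
    b <- ids[sample.int(n, m, replace = TRUE)]
    ok <- a != b
    if (!is.null(not_within)) {
      ok <- ok & !(a %in% not_within & b %in% not_within)
    }
    a <- a[ok]; b <- b[ok]
    kk <- key(a, b)
    keep <- !duplicated(kk) & !(kk %in% taken)
    a <- a[keep]; b <- b[keep]; kk <- kk[keep]
    take <- seq_len(min(length(a), k - length(acc_a)))
    acc_a <- c(acc_a, pmin(a, b)[take])
    acc_b <- c(acc_b, pmax(a, b)[take])
    taken <- c(taken, kk[take])
    attempts <- attempts + 1L
  }
  if (length(acc_a) < k) {
    # dense request: enumerate remaining admissible pairs and sample
    all_p <- utils::combn(sort(ids), 2)
    kk <- key(all_p[1, ], all_p[2, ])
    ok <- !(kk %in% taken)
    if (!is.null(not_within)) {
      ok <- ok & !(all_p[1, ] %in% not_within & all_p[2, ] %in% not_within)
    }
    cand <- which(ok)
    need <- k - length(acc_a)
    if (length(cand) < need) stop("not enough admissible pairs", call. = FALSE)
    pick <- cand[sample.int(length(cand), need)]
    acc_a <- c(acc_a, all_p[1, pick])
    acc_b <- c(acc_b, all_p[2, pick])
  }
  data.frame(bead_a = acc_a, bead_b = acc_b)
}
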