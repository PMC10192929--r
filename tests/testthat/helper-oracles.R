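# Independent brute-force oracles used to cross-check the implementation.

# Textbook Welch unequal-variance t-test.
welch_oracle <- function(x, y) {
  vx <- sum((x - mean(x))^2) / (length(x) - 1)
  vy <- sum((y - mean(y))^2) / (length(y) - 1)
  se2 <- vx / length(x) + vy / length(y)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                   (vy / length(y))^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Interval union by coverage vector on a small coordinate space.
union_oracle <- function(starts, ends, max_coord) {
  cov <- logical(max_coord)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) cov[(starts[i] + 1):ends[i]] <- TRUE
  }
  r <- rle(cov)
  stops <- cumsum(r$lengths)
  begins <- stops - r$lengths + 1L
  keep <- r$values
  data.frame(start = begins[keep] - 1L, end = stops[keep])
}

# Assign each read midpoint to the containing bead by linear scan.
midpoint_oracle <- function(reads, partition) {
  vapply(seq_len(nrow(reads)), function(i) {
    mid <- (reads$start[i] + reads$end[i]) %/% 2
    hit <- which(partition$chrom == reads$chrom[i] &
                   partition$start <= mid & mid < partition$end)
    if (length(hit) == 1L) partition$bead_id[hit] else NA_integer_
  }, integer(1))
}

# RPKM recomputed from first principles.
rpkm_oracle <- function(count, length_bp, total) {
  count * 1e9 / (length_bp * total)
}

# A small uniform-composition genome plus tiling bead partition, shared by
# several pipeline tests.
make_toy_system <- function(chrom_sizes = c(chrA = 4e5, chrB = 3e5),
                            n_domains = 8, seed = 101) {
  spec <- genome_spec(chrom_sizes)
  genome <- generate_genome(spec, seed = seed)
  domains <- generate_domains(chrom_sizes, n_domains, c(1e4, 3e4),
                              seed = seed + 1)
  partition <- build_bead_partition(domains, chrom_sizes)
  list(genome = genome, sizes = chrom_sizes, domains = domains,
       partition = partition)
}

# Two-bead model on separate chromosomes at an explicit placement.
make_two_bead_model <- function(r1 = 0.4, r2 = 0.5, d = NULL,
                                interactions = NULL) {
  part <- data.frame(
    chrom = c("c1", "c2"), start = c(0L, 0L), end = c(1000L, 1000L),
    bead_id = 1:2, type = "domain", length_bp = 1000L
  )
  m <- bead_model(part, interactions = interactions)
  m$beads$radius <- c(r1, r2)   # explicit radii for closed-form checks
  if (!is.null(d)) {
    m$beads$x <- c(0, d); m$beads$y <- 0; m$beads$z <- 0
  }
  m
}
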