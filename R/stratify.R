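#' Merge overlapping genes into a genic mask
#'
#' Standard interval union per chromosome; the complement of the mask is
#' the intergenic space.
#'
#' @param genes BED-like data.frame (`chrom`, `start`, `end`).
#' @return Sorted, non-overlapping data.frame (`chrom`, `start`, `end`).
#' @export
merge_genes <- function(genes) {
  if (nrow(genes) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end)
  ))
  gr <- BiocGenerics::sort(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}

#' Split reads into genic and intergenic strata
#'
#' A read is genic iff its midpoint lies inside the merged gene mask — the
#' same midpoint rule used for bead assignment, so the two partitions are
#' consistent. The split is exhaustive and exclusive.
#'
#' @param reads BED6 data.frame.
#' @param mask Merged mask from [merge_genes()].
#' @return List with elements `genic` and `intergenic` (BED6 data.frames).
#' @export
split_reads_by_mask <- function(reads, mask) {
  check_reads(reads)
  if (nrow(reads) == 0) return(list(genic = reads, intergenic = reads))
  mid <- (reads$start + reads$end) %/% 2L
  pts <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(mid + 1L, mid + 1L))
  mgr <- GenomicRanges::GRanges(mask$chrom,
                                IRanges::IRanges(mask$start + 1L, mask$end))
  hit <- IRanges::overlapsAny(pts, mgr)
  list(genic = reads[hit, , drop = FALSE],
       intergenic = reads[!hit, , drop = FALSE])
}

#' Call replication domains from windowed early/late counts
#'
#' Computes the per-window log2 early/late ratio with a 0.5 pseudocount,
#' `r = log2((early + 0.5) / (late + 0.5))`, and segments maximal runs of
#' at least `min_windows` consecutive same-sign windows into domains
#' labeled `early` (r > 0) or `late` (r < 0). Windows with `r == 0` break
#' runs and belong to no domain.
#'
#' @param counts Windowed counts data.frame (`chrom, start, end, early,
#'   late`), windows tiling each chromosome in order.
#' @param min_windows Minimum run length for a domain (3 windows = 150 kb
#'   at the default 50-kb window).
#' @return A list: `domains` (data.frame `chrom, start, end, label`) and
#'   `windows` (the input with an `r` column appended).
#' @export
call_replication_domains <- function(counts, min_windows = 3L) {
  need <- c("chrom", "start", "end", "early", "late")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  counts$r <- log2((counts$early + 0.5) / (counts$late + 0.5))
  doms <- list()
  for (chrom in unique(counts$chrom)) {
    w <- counts[counts$chrom == chrom, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    if (nrow(w) > 1 && any(w$start[-1] != w$end[-nrow(w)])) {
      stop("windows must tile the chromosome without gaps", call. = FALSE)
    }
    sgn <- sign(w$r)
    runs <- rle(sgn)
    pos <- cumsum(c(1L, runs$lengths))
    for (j in seq_along(runs$lengths)) {
      if (runs$values[j] == 0 || runs$lengths[j] < min_windows) next
      i0 <- pos[j]
      i1 <- pos[j] + runs$lengths[j] - 1L
      doms[[length(doms) + 1L]] <- data.frame(
        chrom = chrom, start = w$start[i0], end = w$end[i1],
        label = if (runs$values[j] > 0) "early" else "late",
        stringsAsFactors = FALSE
      )
    }
  }
  domains <- if (length(doms)) {
    do.call(rbind, doms)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               label = character(), stringsAsFactors = FALSE)
  }
  list(domains = domains, windows = counts)
}

#' Radial analysis stratified by interval sets
#'
#' Splits every read set by midpoint membership in each stratum's intervals
#' and reruns [radial_shell_analysis()] per stratum. For a genic/intergenic
#' split pass `list(genic = mask, intergenic = NULL)` where `NULL` means
#' the complement of all other strata; for replication timing pass the
#' early and late domain tables.
#'
#' @param partition Bead partition.
#' @param assignment Shell assignment.
#' @param strata Named list of BED-like data.frames; at most one element
#'   may be NULL (the complement stratum).
#' @param damage,damage_sim,repair,repair_sim Read sets, as in
#'   [radial_shell_analysis()].
#' @param pseudocount Passed through.
#' @return Named list, one [radial_shell_analysis()] result per stratum
#'   (NULL for a stratum that received no reads, with a warning).
#' @export
stratified_radial_analysis <- function(partition, assignment, strata,
                                       damage, damage_sim,
                                       repair = NULL, repair_sim = NULL,
                                       pseudocount = 0) {
  if (is.null(names(strata)) || any(!nzchar(names(strata)))) {
    stop("strata must be named", call. = FALSE)
  }
  comp <- vapply(strata, is.null, logical(1))
  if (sum(comp) > 1) stop("at most one complement stratum", call. = FALSE)
  masks <- lapply(strata[!comp], merge_genes)
  assign_stratum <- function(reads) {
    if (is.null(reads)) return(NULL)
    mid <- (reads$start + reads$end) %/% 2L
    pts <- GenomicRanges::GRanges(reads$chrom,
                                  IRanges::IRanges(mid + 1L, mid + 1L))
    assigned <- rep(NA_character_, nrow(reads))
    for (nm in names(masks)) {
      m <- masks[[nm]]
      mgr <- GenomicRanges::GRanges(m$chrom,
                                    IRanges::IRanges(m$start + 1L, m$end))
      hit <- IRanges::overlapsAny(pts, mgr)
      assigned[is.na(assigned) & hit] <- nm
    }
    if (any(comp)) assigned[is.na(assigned)] <- names(strata)[comp]
    assigned
  }
  labels <- list(damage = assign_stratum(damage),
                 damage_sim = assign_stratum(damage_sim),
                 repair = assign_stratum(repair),
                 repair_sim = assign_stratum(repair_sim))
  sets <- list(damage = damage, damage_sim = damage_sim,
               repair = repair, repair_sim = repair_sim)
  lapply(stats::setNames(names(strata), names(strata)), function(nm) {
    pick <- function(which) {
      reads <- sets[[which]]
      if (is.null(reads)) return(NULL)
      lab <- labels[[which]]
      reads[!is.na(lab) & lab == nm, , drop = FALSE]
    }
    d <- pick("damage")
    ds <- pick("damage_sim")
    if (nrow(d) == 0 || nrow(ds) == 0) {
      warning("stratum '", nm, "' received no reads", call. = FALSE)
      return(NULL)
    }
    r <- pick("repair")
    rs <- pick("repair_sim")
    if (!is.null(r) && (nrow(r) == 0 || is.null(rs) || nrow(rs) == 0)) {
      warning("stratum '", nm, "' received no repair reads", call. = FALSE)
      r <- NULL
      rs <- NULL
    }
    radial_shell_analysis(partition, assignment, d, ds,
                          repair = r, repair_sim = rs,
                          pseudocount = pseudocount)
  })
}
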