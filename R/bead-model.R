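#' Tile chromosomes with domain and gap beads
#'
#' Overlapping contact domains are merged into single domains; regions not
#' covered by any domain become gap beads. Abutting (non-overlapping)
#' domains stay separate beads: only genuine overlap triggers merging. The
#' result is, per chromosome, a gap-free and overlap-free tiling, with one
#' bead per merged domain or inter-domain gap.
#'
#' @param domains BED-like data.frame (`chrom`, `start`, `end`) of contact
#'   domains; may be empty.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return Data.frame `chrom, start, end, bead_id, type, length_bp`, with
#'   `type` either `"domain"` or `"gap"`, ordered by chromosome (in
#'   `chrom_sizes` order) then position; `bead_id` is a global 1-based
#'   index.
#' @export
build_bead_partition <- function(domains, chrom_sizes) {
  check_chrom_sizes(chrom_sizes)
  if (nrow(domains)) {
    if (!all(domains$chrom %in% names(chrom_sizes))) {
      stop("domain on unknown chromosome", call. = FALSE)
    }
    bad <- domains$start < 0 | domains$end > chrom_sizes[domains$chrom]
    if (any(bad)) stop("domain outside chromosome bounds", call. = FALSE)
  }
  out <- lapply(names(chrom_sizes), function(chrom) {
    L <- as.integer(chrom_sizes[[chrom]])
    d <- domains[domains$chrom == chrom, , drop = FALSE]
    if (nrow(d) == 0) {
      return(data.frame(chrom = chrom, start = 0L, end = L,
                        type = "gap", stringsAsFactors = FALSE))
    }
    # min.gapwidth = 0: merge overlapping domains only, never abutting ones
    merged <- IRanges::reduce(
      IRanges::IRanges(start = d$start + 1L, end = d$end),
      min.gapwidth = 0L
    )
    ds <- BiocGenerics::start(merged) - 1L
    de <- BiocGenerics::end(merged)
    starts <- integer(0); ends <- integer(0); types <- character(0)
    pos <- 0L
    for (j in seq_along(ds)) {
      if (ds[j] > pos) {
        starts <- c(starts, pos); ends <- c(ends, ds[j])
        types <- c(types, "gap")
      }
      starts <- c(starts, ds[j]); ends <- c(ends, de[j])
      types <- c(types, "domain")
      pos <- de[j]
    }
    if (pos < L) {
      starts <- c(starts, pos); ends <- c(ends, L); types <- c(types, "gap")
    }
    data.frame(chrom = chrom, start = starts, end = ends, type = types,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  df$bead_id <- seq_len(nrow(df))
  df$length_bp <- df$end - df$start
  rownames(df) <- NULL
  df[, c("chrom", "start", "end", "bead_id", "type", "length_bp")]
}

#' Scale bead radii to a fixed nuclear occupancy
#'
#' Bead volumes are proportional to the genomic length each bead represents
#' and sum exactly to `occupancy` times the nucleus volume (15% of a
#' 10-um-diameter nucleus by default).
#'
#' @param partition Bead partition from [build_bead_partition()].
#' @param nucleus_diameter_um Nucleus diameter in micrometres.
#' @param occupancy Fraction of nuclear volume occupied by beads.
#' @return Numeric vector of bead radii (um), aligned with `partition` rows.
#' @export
scale_bead_radii <- function(partition, nucleus_diameter_um = 10,
                             occupancy = 0.15) {
  stopifnot_scalar_pos(nucleus_diameter_um, "nucleus_diameter_um")
  stopifnot_scalar_pos(occupancy, "occupancy")
  bp <- partition$end - partition$start
  total_bp <- sum(bp)
  if (total_bp <= 0) stop("total bp must be positive", call. = FALSE)
  R <- nucleus_diameter_um / 2
  v_nucleus <- 4 / 3 * pi * R^3
  v <- occupancy * v_nucleus * bp / total_bp
  (3 * v / (4 * pi))^(1 / 3)
}

#' Construct a 3D bead model of the nucleus
#'
#' Packages a bead partition, scaled radii, and an interaction pair list
#' into a model object ready for [optimize_model()]. Bead centres are unset
#' until placement.
#'
#' @inheritParams scale_bead_radii
#' @param interactions Data.frame of bead-id pairs (`bead_a`, `bead_b`), or
#'   NULL for none.
#' @return An object of class `bead_model`: a list with elements `beads`
#'   (partition plus `radius`, `x`, `y`, `z`), `nucleus_radius`,
#'   `occupancy`, `interactions`.
#' @export
bead_model <- function(partition, interactions = NULL,
                       nucleus_diameter_um = 10, occupancy = 0.15) {
  beads <- partition
  beads$radius <- scale_bead_radii(partition, nucleus_diameter_um, occupancy)
  beads$x <- NA_real_; beads$y <- NA_real_; beads$z <- NA_real_
  if (is.null(interactions)) {
    interactions <- data.frame(bead_a = integer(), bead_b = integer())
  }
  if (nrow(interactions) &&
      !all(unlist(interactions[, 1:2]) %in% beads$bead_id)) {
    stop("interaction references unknown bead id", call. = FALSE)
  }
  structure(
    list(beads = beads, nucleus_radius = nucleus_diameter_um / 2,
         occupancy = occupancy,
         interactions = stats::setNames(as.data.frame(interactions)[, 1:2],
                                        c("bead_a", "bead_b"))),
    class = "bead_model"
  )
}

#' @export
print.bead_model <- function(x, ...) {
  placed <- sum(!is.na(x$beads$x))
  cat("bead_model:", nrow(x$beads), "beads (", placed, "placed ),",
      nrow(x$interactions), "interactions, nucleus radius",
      x$nucleus_radius, "um, occupancy", x$occupancy, "\n")
  invisible(x)
}

#' Map genomic interval pairs to bead pairs
#'
#' Interactions given as genomic coordinates are attached to the beads
#' containing each interval's midpoint.
#'
#' @param pairs Data.frame with columns `chrom_a, start_a, end_a, chrom_b,
#'   start_b, end_b`.
#' @param partition Bead partition.
#' @return Data.frame of bead-id pairs (`bead_a`, `bead_b`), self-pairs
#'   dropped.
#' @export
map_interactions_to_beads <- function(pairs, partition) {
  mid_bead <- function(chrom, start, end) {
    mid <- floor((start + end) / 2)
    out <- rep(NA_integer_, length(chrom))
    for (ch in unique(chrom)) {
      part <- partition[partition$chrom == ch, ]
      i <- which(chrom == ch)
      if (!nrow(part)) next
      idx <- findInterval(mid[i], part$start)
      ok <- idx >= 1L & mid[i] < max(part$end)
      out[i[ok]] <- part$bead_id[idx[ok]]
    }
    out
  }
  a <- mid_bead(pairs$chrom_a, pairs$start_a, pairs$end_a)
  b <- mid_bead(pairs$chrom_b, pairs$start_b, pairs$end_b)
  keep <- !is.na(a) & !is.na(b) & a != b
  data.frame(bead_a = pmin(a[keep], b[keep]),
             bead_b = pmax(a[keep], b[keep]))
}
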