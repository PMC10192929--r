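#' Count reads per bead
#'
#' Each read is assigned to the unique bead containing its midpoint,
#' `floor((start + end) / 2)`; beads tile each chromosome so the assignment
#' is unique and read counts are conserved. Reads on chromosomes absent
#' from the partition are skipped and counted.
#'
#' @param reads BED6 data.frame.
#' @param partition Bead partition (or the `beads` element of a
#'   [bead_model()]).
#' @return A list of class `bead_signal`: `counts` (data.frame `bead_id,
#'   count, rpkm`), `total_mapped` (total input reads), `n_skipped`.
#' @export
count_reads_per_bead <- function(reads, partition) {
  check_reads(reads)
  counts <- stats::setNames(rep(0L, nrow(partition)), partition$bead_id)
  skipped <- 0L
  for (chrom in unique(reads$chrom)) {
    i <- which(reads$chrom == chrom)
    part <- partition[partition$chrom == chrom, , drop = FALSE]
    if (!nrow(part)) {
      skipped <- skipped + length(i)
      next
    }
    mid <- (reads$start[i] + reads$end[i]) %/% 2L
    idx <- findInterval(mid, part$start)
    ok <- idx >= 1L & mid < max(part$end)
    skipped <- skipped + sum(!ok)
    tab <- table(part$bead_id[idx[ok]])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  total <- nrow(reads)
  df <- data.frame(bead_id = partition$bead_id,
                   count = as.integer(unname(counts)),
                   stringsAsFactors = FALSE)
  df$rpkm <- rpkm(df$count, partition$end - partition$start, total)
  structure(list(counts = df, total_mapped = total, n_skipped = skipped),
            class = "bead_signal")
}

#' Reads per kilobase per million mapped reads
#'
#' `count / (length_bp / 1000) / (total_mapped / 1e6)`.
#'
#' @param count Read count(s) in the region.
#' @param length_bp Region length(s) in bp (> 0).
#' @param total_mapped Total mapped reads in the library (> 0).
#' @return Numeric RPKM value(s).
#' @export
#' @examples
#' rpkm(1, 1000, 1e6)  # 1
rpkm <- function(count, length_bp, total_mapped) {
  if (any(length_bp <= 0)) stop("length_bp must be positive", call. = FALSE)
  if (length(total_mapped) != 1L || total_mapped <= 0) {
    stop("total_mapped must be a single positive count", call. = FALSE)
  }
  count / (length_bp / 1000) / (total_mapped / 1e6)
}

#' Observed/expected per-bead ratio
#'
#' Per-bead RPKM of the observed reads divided by the RPKM of the matched
#' simulated ("expected") reads. Beads with zero expected signal are
#' excluded and counted, unless a pseudocount is supplied, in which case it
#' is added to both RPKMs.
#'
#' @param obs,sim `bead_signal` objects over the same bead set.
#' @param pseudocount Optional value added to both RPKMs before the ratio.
#' @return A list: `ratio` (data.frame `bead_id, value`), `n_excluded`.
#' @export
observed_expected <- function(obs, sim, pseudocount = 0) {
  o <- obs$counts
  s <- sim$counts
  if (!identical(o$bead_id, s$bead_id)) {
    s <- s[match(o$bead_id, s$bead_id), ]
    if (any(is.na(s$bead_id))) {
      stop("observed and simulated signals cover different beads",
           call. = FALSE)
    }
  }
  num <- o$rpkm + pseudocount
  den <- s$rpkm + pseudocount
  keep <- den > 0
  list(
    ratio = data.frame(bead_id = o$bead_id[keep],
                       value = num[keep] / den[keep],
                       stringsAsFactors = FALSE),
    n_excluded = sum(!keep)
  )
}

#' Double-normalized repair
#'
#' The fold change between simulation-normalized repair and
#' simulation-normalized damage:
#' `(rpkm_repair / rpkm_repairSim) / (rpkm_damage / rpkm_damageSim)` per
#' bead. Beads with a zero denominator are excluded and counted.
#'
#' @param repair_ratio,damage_ratio Outputs of [observed_expected()] (or
#'   their `ratio` data.frames) for repair and damage respectively.
#' @return A list: `ratio` (data.frame `bead_id, value`), `n_excluded`.
#' @export
double_normalize <- function(repair_ratio, damage_ratio) {
  r <- if (is.list(repair_ratio) && !is.data.frame(repair_ratio)) {
    repair_ratio$ratio
  } else {
    repair_ratio
  }
  d <- if (is.list(damage_ratio) && !is.data.frame(damage_ratio)) {
    damage_ratio$ratio
  } else {
    damage_ratio
  }
  common <- intersect(r$bead_id, d$bead_id)
  rv <- r$value[match(common, r$bead_id)]
  dv <- d$value[match(common, d$bead_id)]
  keep <- dv > 0
  list(
    ratio = data.frame(bead_id = common[keep], value = rv[keep] / dv[keep],
                       stringsAsFactors = FALSE),
    n_excluded = sum(!keep) +
      (nrow(r) - length(common)) + (nrow(d) - length(common))
  )
}

#' Per-shell distributions of per-bead values
#'
#' Joins per-bead values with the radial shell assignment and summarises
#' each shell (unweighted per-bead values, one row per bead in the table).
#'
#' @param values Data.frame `bead_id, value` (e.g. the `ratio` element of
#'   [observed_expected()], or RPKM from a `bead_signal`).
#' @param assignment Shell assignment data.frame (`bead_id`, `shell`).
#' @param nucleus_radius,shell_width Geometry defining the full shell set,
#'   so empty shells still get a summary row.
#' @return A list: `table` (data.frame `bead_id, shell, value`) and
#'   `summary` (data.frame `shell, n, median, mean, sd`; `n = 0` rows carry
#'   NA statistics).
#' @export
shell_distributions <- function(values, assignment, nucleus_radius = 5,
                                shell_width = 1) {
  shell <- assignment$shell[match(values$bead_id, assignment$bead_id)]
  if (any(is.na(shell))) {
    stop("every valued bead needs a shell assignment", call. = FALSE)
  }
  tab <- data.frame(bead_id = values$bead_id, shell = shell,
                    value = values$value, stringsAsFactors = FALSE)
  labels <- shell_labels(nucleus_radius, shell_width)
  summ <- do.call(rbind, lapply(labels, function(lab) {
    v <- tab$value[tab$shell == lab]
    data.frame(shell = lab, n = length(v),
               median = if (length(v)) stats::median(v) else NA_real_,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(table = tab, summary = summ)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided two-sample t-test without the equal-variance assumption, with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param x,y Numeric vectors, each of length >= 2, with nonzero variance
#'   in at least one sample.
#' @return A list of class `welch_result`: `t`, `df`, `p`, `n_x`, `n_y`.
#' @export
#' @examples
#' welch_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
welch_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("welch_test needs at least 2 observations per sample",
         call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (x[1] == y[1]) {
      # identical constants: no evidence of difference
      return(structure(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                            n_x = length(x), n_y = length(y)),
                       class = "welch_result"))
    }
    stop("both samples have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  structure(
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = unname(ht$p.value), n_x = length(x), n_y = length(y)),
    class = "welch_result"
  )
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch's t-test: t = %.4g, df = %.4g, p = %.4g (n = %d, %d)\n",
              x$t, x$df, x$p, x$n_x, x$n_y))
  invisible(x)
}

#' Compare the central shell against every other shell
#'
#' Welch's t-test of the per-bead values in shell `"0-1"` against each of
#' the other shells, as in the per-figure shell comparisons.
#'
#' @param shell_table The `table` element of [shell_distributions()] (or an
#'   equivalent `bead_id, shell, value` data.frame).
#' @param reference Reference shell label.
#' @return Data.frame, one row per comparison: `shell, t, df, p,
#'   median_ref, median_shell, n_ref, n_shell`; undersized comparisons get
#'   NA statistics.
#' @export
shell_comparison_report <- function(shell_table, reference = "0-1") {
  shells <- setdiff(unique(shell_table$shell), reference)
  shells <- shells[order(shells)]
  ref <- shell_table$value[shell_table$shell == reference]
  do.call(rbind, lapply(shells, function(lab) {
    v <- shell_table$value[shell_table$shell == lab]
    row <- data.frame(shell = lab, t = NA_real_, df = NA_real_, p = NA_real_,
                      median_ref = stats::median(ref),
                      median_shell = stats::median(v),
                      n_ref = length(ref), n_shell = length(v),
                      stringsAsFactors = FALSE)
    if (length(ref) >= 2 && length(v) >= 2 &&
        (stats::var(ref) > 0 || stats::var(v) > 0)) {
      wt <- welch_test(ref, v)
      row$t <- wt$t; row$df <- wt$df; row$p <- wt$p
    }
    row
  }))
}

#' Radial shell analysis of damage and repair signals
#'
#' The end-to-end statistic pipeline on processed reads: per-bead RPKM for
#' each read set, observed/expected normalization of damage (and repair)
#' against their matched simulations, double-normalized repair when both
#' damage and repair are supplied, per-shell distributions, and the
#' central-shell comparison report for every computed quantity.
#'
#' @param partition Bead partition.
#' @param assignment Shell assignment (`bead_id`, `shell`).
#' @param damage,damage_sim BED6 data.frames: observed and simulated damage
#'   reads.
#' @param repair,repair_sim Optional BED6 data.frames: observed and
#'   simulated repair reads.
#' @param pseudocount Passed to [observed_expected()].
#' @return A list of per-quantity results; each has elements `shells` (the
#'   [shell_distributions()] list) and `report` (the
#'   [shell_comparison_report()]); quantities are `damage_rpkm`,
#'   `damage_obs_exp`, and when repair data are given `repair_rpkm`,
#'   `repair_obs_exp`, `double_norm`. `exclusions` counts zero-expected
#'   beads per ratio.
#' @export
radial_shell_analysis <- function(partition, assignment, damage, damage_sim,
                                  repair = NULL, repair_sim = NULL,
                                  pseudocount = 0) {
  res <- list(exclusions = list())
  quantify <- function(values) {
    sh <- shell_distributions(values, assignment)
    list(shells = sh, report = shell_comparison_report(sh$table))
  }
  dmg <- count_reads_per_bead(damage, partition)
  dmg_sim <- count_reads_per_bead(damage_sim, partition)
  res$damage_rpkm <- quantify(
    data.frame(bead_id = dmg$counts$bead_id, value = dmg$counts$rpkm)
  )
  dmg_oe <- observed_expected(dmg, dmg_sim, pseudocount)
  res$exclusions$damage_obs_exp <- dmg_oe$n_excluded
  res$damage_obs_exp <- quantify(dmg_oe$ratio)
  if (!is.null(repair)) {
    if (is.null(repair_sim)) {
      stop("repair_sim required with repair", call. = FALSE)
    }
    rep_ <- count_reads_per_bead(repair, partition)
    rep_sim <- count_reads_per_bead(repair_sim, partition)
    res$repair_rpkm <- quantify(
      data.frame(bead_id = rep_$counts$bead_id, value = rep_$counts$rpkm)
    )
    rep_oe <- observed_expected(rep_, rep_sim, pseudocount)
    res$exclusions$repair_obs_exp <- rep_oe$n_excluded
    res$repair_obs_exp <- quantify(rep_oe$ratio)
    dn <- double_normalize(rep_oe, dmg_oe)
    res$exclusions$double_norm <- dn$n_excluded
    res$double_norm <- quantify(dn$ratio)
  }
  res
}
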