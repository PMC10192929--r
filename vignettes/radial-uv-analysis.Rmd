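---
title: "Radial shell analysis of UV damage and excision repair in a 3D nucleus model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial shell analysis of UV damage and excision repair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucshield)
```

## The question and the model

UV light damages DNA at dipyrimidines (TT, TC, CT, CC), producing
cyclobutane pyrimidine dimers (CPDs) and pyrimidine-pyrimidone (6-4)
photoproducts, which are mapped genome-wide by Damage-seq; nucleotide
excision repair releases short oligomers that XR-seq captures. Whether the
radial organization of chromatin inside the nucleus — dense heterochromatin
at the periphery, open chromatin toward the centre — shields interior DNA
from UV damage, and whether repair is radially biased, are quantitative
questions that need (i) a 3D position for every genomic region and (ii) a
normalization that removes the sequence-composition bias inherent to
lesion maps.

`nucshield` addresses both. The genome is modelled as a chain of spherical
beads, one per contact domain (TAD) or inter-domain gap, with bead volume
proportional to the genomic length it represents and total bead volume
fixed at 15% of a 10-µm-diameter spherical nucleus. Significant Hi-C
interactions pull bead pairs together during a Monte Carlo placement;
concentric 1-µm shells ("0-1" at the centre to "4-5" at the periphery for
the default 5-µm radius) then partition beads by the radial distance of
their centres. Per-bead signal is RPKM (reads per kb per million mapped);
radial profiles are summarized per shell and the central shell is compared
with each other shell by Welch's unequal-variance t-test.

## The expected-signal baseline

Lesion reads are biased toward dipyrimidine-rich sequence, so a raw radial
RPKM profile confounds 3D organization with base composition. The package
therefore simulates an *expected* read set: pseudo-reads drawn from the
reference genome (or from input-DNA reads, which additionally preserves
regional copy number) whose per-length, per-position nucleotide
frequencies match the observed reads. The per-bead statistics are then

* observed/expected: `rpkm_obs / rpkm_sim`, per bead, and
* double-normalized repair:
  `(rpkm_repair / rpkm_repairSim) / (rpkm_damage / rpkm_damageSim)`,

the latter isolating repair efficiency from the non-uniform initial damage
landscape. Beads with zero expected signal are excluded and counted rather
than pseudocounted (a `pseudocount` argument exists but defaults to 0),
since ratios of well-covered beads are the object of interest.

## Simulator mechanism and numerical choices

`simulate_reads()` proposes candidate reads uniformly from the reference
(or from background read intervals) and accepts each with a probability
built from two factors:

1. **Static steering.** Per position, the ratio of the target frequency to
   a *baseline*; the product over positions, column-normalized, caps the
   probability at 1. The baseline is the profile's own median-across-
   positions composition, not the genome composition. This choice matters:
   most window positions simply reflect where reads come from, and
   measuring them against the profile's typical column makes them neutral,
   so only genuinely deviant positions — the lesion dinucleotide at
   positions 5–6 of a damage window — filter candidates. Acceptance then
   tracks the local availability of those deviant bases, which is exactly
   the "expected damage given composition" a baseline should encode.
   Measuring instead against the genome composition makes all L positions
   weakly selective, and on a composition-gradient genome the compounded
   mismatch distorts regional densities.
2. **Closed-loop feedback.** The ratio of target to already-emitted
   frequency per (base, position), clamped to `[1/1.5, 1.5]`, continually
   steers the aggregate output onto the empirical target.

Two smoothing rules keep the mechanism robust. The steering target is the
Dirichlet posterior mean given the reads behind the profile with a prior
of 25 pseudo-reads: a length class observed in only a few dozen reads has
sampling noise in every column, and because log-weights add across L
positions, unshrunk noise compounds into vanishing acceptance, while
well-supported deviations stay sharp. Second, the attempt budget is
`max_attempts × max(n, 250)` candidates per length class, so small classes
are not starved; a genuinely unattainable target (a base the reference
cannot supply) rejects orders of magnitude harder than a noisy one and
still aborts with a diagnostic of the worst-matched positions. Default
convergence goal `epsilon = 0.02` mean absolute deviation; in practice the
emitted profiles sit near 1e-3 at n = 50,000.

Matching is per-position mononucleotide, which is sufficient for the
radial statistics here because both observed and simulated densities then
scale with local dipyrimidine availability; full dinucleotide matching is
a possible extension, not implemented.

## The 3D model

`build_bead_partition()` merges *overlapping* domains only — abutting
domains remain separate beads, since merging is meant to resolve redundant
domain calls, not to coarsen the partition — and fills uncovered regions
with gap beads, giving a gap-free, overlap-free tiling of each chromosome.
`scale_bead_radii()` makes bead volume proportional to bp with total
volume exactly `occupancy × nucleus volume` (defaults 0.15 and a 10-µm
diameter).

`optimize_model()` minimizes a quadratic hinge loss with four terms, all
weighted 1 by default: interacting pairs beyond touching distance, any
overlapping pair, chain-adjacent beads beyond touching (keeping each
chromosome a connected polymer), and protrusion beyond the nuclear
envelope. Proposals are single-bead Gaussian moves (0.1 µm), accepted by
Metropolis under a geometric temperature schedule (`t0 = 1`,
ratio 0.999; `t0 = 0` gives pure greedy descent, under which the
accepted-state loss trace is non-increasing). The envelope is additionally
enforced as a hard constraint — moves that would place a bead partly
outside the nucleus are rejected outright — mirroring how constraint-based
chromosome-modelling protocols treat the nuclear boundary, and
guaranteeing containment of the final model; the loss term still scores
violations in user-supplied placements. Runs are exactly reproducible
under a seed.

Shell membership is by bead centre in half-open 1-µm bins; a bead
straddling a boundary is not split fractionally. The rule is unambiguous
and matches the per-bead unit of every downstream statistic; a
volume-weighted alternative would blur the bead-level Welch tests.

## Damage-seq and XR-seq read processing

In Damage-seq the lesion lies two nucleotides upstream of the sequenced
read's 5' start. `extract_damage_windows()` converts a plus-strand read
`[s, e)` to the 10-nt window `[s-6, s+4)` (minus strand: `[e-4, e+6)`), so
the lesion dinucleotide occupies window positions 5–6 in read orientation.
Windows that would cross a chromosome end are dropped and counted, never
clipped — a clipped window cannot hold positions 5–6. Deduplication
collapses records identical on (chrom, start, end, strand); same-interval
reads on opposite strands are distinct events. XR-seq reads are excision
products and map repair directly, so they are only sorted and
deduplicated, never window-transformed.

## Stratified analyses

`merge_genes()` / `split_reads_by_mask()` partition reads into genic and
intergenic strata by read midpoint — the same midpoint rule used to assign
reads to beads, keeping the two partitions consistent and conservative
(every read lands in exactly one stratum). `call_replication_domains()`
computes `log2((early + 0.5) / (late + 0.5))` in 50-kb windows (the 0.5
pseudocount handles empty windows) and labels maximal runs of at least
`min_windows = 3` same-sign windows (≥150 kb) as early or late domains;
exact-zero windows break runs. The run-length rule is a declared stand-in
for unpublished segmentation heuristics and both knobs are exposed.
`stratified_radial_analysis()` reruns the full radial analysis per
stratum.

## What the synthetic data emulate

The generators produce every pipeline input with known planted structure:

* `generate_genome()` — i.i.d. sequence from a base composition, with an
  optional linear 5'→3' multiplier on TT/TC density (implemented by
  scaling pyrimidine probabilities with the square root of the density
  multiplier, piecewise constant per kb).
* `generate_domains()` / `generate_genes()` — uniformly placed intervals,
  optionally overlapping (overlap guaranteed when requested, to exercise
  merging).
* `generate_interactions()` — distinct unordered bead pairs, optionally
  enriched within a central set.
* `generate_reads()` — `input` reads are composition-unbiased, sampled
  per bead at rate ∝ bp × planted shell multiplier; `damage` and `repair`
  reads are anchored at actual dipyrimidine positions of the genome
  (default purity 0.95), with sites weighted by the containing bead's
  shell multiplier. Site-level anchoring (rather than a uniform per-bead
  rate) is what lets a planted composition gradient produce a raw RPKM
  trend that observed/expected must flatten — the pipeline's central
  normalization claim is thereby testable. Damage reads default to 40 nt;
  repair reads draw lengths from a truncated 20–30 nt distribution with
  mode 26 nt, typical of human excision products (the true distribution is
  assay-dependent; this default is configurable, not asserted).
* `generate_edu_counts()` — Poisson counts per 50-kb window, with a
  planted log2 early/late effect (default 1.0) inside true early domains
  and a depth of 100 reads per fraction per window, a realistic desk-scale
  coverage.
* `plant_shell_assignment()` — a direct bead→shell map, uniform across
  shells by default. Recovery and calibration studies use planted
  assignments rather than geometric placement because, in a real 5-µm
  nucleus, the central 1-µm sphere holds under 1% of the volume and
  therefore very few beads — too few for stable shell statistics at toy
  scale. The geometric optimizer is validated separately on its own
  contracts (monotone greedy descent, convergence to touching,
  interaction-driven clustering, containment).

Every generator routes randomness through one seeded RNG per call and is
byte-identical under a fixed seed.

What the synthetic data do **not** emulate: sequencing error, mappability
and alignment artefacts, chromatin-state covariates of real damage and
repair, realistic Hi-C contact structure, and cell-to-cell variability of
nuclear architecture. Passing the planted-truth tests therefore shows the
statistics recover what they are defined to recover, not that real nuclei
behave like the toy model.

## Verification strategy and problem sizes

The test suite checks closed-form examples (volume arithmetic, window
coordinates, RPKM, loss terms) against hand-computed values, and the core
statistics against independent brute-force oracles (a textbook Welch
formula, coverage-vector interval union, linear-scan midpoint assignment).
End-to-end properties run at deliberately modest scale — genomes of 5–10
Mb, 50–120 beads, 200,000 reads, 200 replicates for null calibration —
chosen so each property is statistically decisive (planted multipliers are
recovered within a few percent; the null false-positive rate estimate has
a standard error near 0.015) while the whole suite runs in minutes.
`scripts/acceptance.R` recomputes the same quantities from scratch under a
user-supplied seed.

## Known limitations

* Shell statistics treat beads as exchangeable units; bead sizes differ,
  so RPKM variances are heteroskedastic within shells. Welch's test is
  robust to unequal variance between groups but the per-bead unit follows
  the figure-legend convention rather than a variance-weighted model.
* The Monte Carlo optimizer finds a local optimum of a simplified loss;
  it is a single-model placement, not an ensemble average.
* Interactions are mapped to beads by interval midpoint; interactions
  spanning bead boundaries are not split.
* No multiple-testing correction is applied to the four shell comparisons
  by default (raw p-values are reported, with an optional Bonferroni
  flag left to the caller via `p.adjust`).
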