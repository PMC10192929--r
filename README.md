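# nucshield

Radial 3D genome organization of UV damage and nucleotide excision repair.

## What it does

UV light forms lesions — cyclobutane pyrimidine dimers (CPDs) and (6-4)
photoproducts — at dipyrimidine sites (TT/TC/CT/CC). Damage-seq maps these
lesions genome-wide; XR-seq maps the short oligomers excised during
nucleotide excision repair. `nucshield` asks how both signals distribute
along the **radial axis of the nucleus**: does peripheral chromatin shield
the interior from damage, and is repair radially biased?

The package, aimed at epigenomics analysts working with Damage-seq/XR-seq
and Hi-C-derived domain structure, provides the full analysis chain:

1. **3D bead model** — each contact domain (TAD) or inter-domain gap
   becomes a spherical bead with volume ∝ genomic length; bead volumes sum
   to 15% of a 10-µm-diameter nucleus. Significant Hi-C interactions pull
   bead pairs together in a Monte Carlo placement minimizing a hinge loss
   over interaction, overlap, chain-connectivity and containment
   constraints. Beads are binned into concentric 1-µm shells, labeled
   `"0-1"` (centre) … `"4-5"` (periphery).
2. **Read processing** — Damage-seq reads become 10-nt lesion windows: the
   lesion lies 2 nt upstream of the read 5′ start, so a plus-strand read
   `[s, e)` maps to window `[s−6, s+4)` with the lesion at window
   positions 5–6; reads are sorted and deduplicated on
   (chrom, start, end, strand). XR-seq reads stay full-length.
3. **Expected baseline** — a read simulator draws pseudo-reads from the
   reference (or from input-DNA reads, preserving copy number) matching
   the observed per-length, per-position nucleotide frequencies via
   closed-loop feedback acceptance sampling.
4. **Radial statistics** — per-bead RPKM; observed/expected
   `rpkm_obs / rpkm_sim`; double-normalized repair
   `(rpkm_repair / rpkm_repairSim) / (rpkm_damage / rpkm_damageSim)`;
   per-shell distributions; Welch's unequal-variance t-test of shell
   `"0-1"` against every other shell.
5. **Stratification** — the same analysis on genic/intergenic reads and on
   early/late replication domains segmented from 50-kb-window
   `log2(early/late)` EdU-seq ratios.
6. **Synthetic data** — generators for genomes (with plantable positional
   dipyrimidine gradients), domains, interaction pairs, damage-, repair-
   and input-like reads (with plantable per-shell rate multipliers), gene
   sets and replication counts, so every stage is testable end to end with
   known ground truth.

## Worked example

Plant a 2× outer-shell damage enrichment on a 10-Mb synthetic genome,
recover it through the full pipeline:

```r
library(nucshield)

spec      <- genome_spec(c(chr1 = 5e6, chr2 = 5e6))
genome    <- generate_genome(spec, seed = 2)
sizes     <- genome_sizes(genome)
domains   <- generate_domains(sizes, 60, c(3e4, 1.2e5), seed = 3)
partition <- build_bead_partition(domains, sizes)
shells    <- plant_shell_assignment(partition$bead_id, seed = 4)

eff    <- radial_effect(c("4-5" = 2))          # 2x damage rate at periphery
damage <- generate_reads(partition, "damage", 2e5, seed = 5, genome = genome,
                         effect = eff, shells = shells, with_seq = FALSE)
wins   <- process_reads(damage, "damage", sizes)$reads
wins$seq <- extract_read_seqs(genome, wins)

profile  <- infer_freq_profile(wins)
expected <- simulate_reads(genome, profile, 2e5, seed = 6)

res <- radial_shell_analysis(partition, shells, wins, expected)
res$damage_obs_exp$shells$summary
#>   shell  n median  mean     sd
#> 1   0-1 25  0.852 0.837 0.1072
#> 2   1-2 25  0.836 0.840 0.0395
#> 3   2-3 24  0.832 0.843 0.0499
#> 4   3-4 24  0.836 0.838 0.0552
#> 5   4-5 24  1.637 1.645 0.0623
res$damage_obs_exp$report
#>   shell        t   df        p median_ref median_shell n_ref n_shell
#> 1   1-2  -0.1413 30.4 8.89e-01      0.852        0.836    25      25
#> 2   2-3  -0.2608 34.3 7.96e-01      0.852        0.832    25      24
#> 3   3-4  -0.0237 36.2 9.81e-01      0.852        0.836    25      24
#> 4   4-5 -32.4305 38.8 9.68e-30      0.852        1.637    25      24
```

The observed/expected medians are flat (≈0.84) across the four inner
shells and 1.637/0.852 ≈ 1.92 in the outer shell — the planted 2× gradient
recovered within 4% — and only the `"0-1"` vs `"4-5"` Welch comparison is
significant. With no planted gradient the same pipeline yields flat
medians and a calibrated test (false-positive rate ≈ 0.05).

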