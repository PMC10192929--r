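test_that("bead partition merges overlapping domains and fills gaps", {
  sizes <- c(chr1 = 200000)
  doms <- data.frame(chrom = "chr1", start = c(0L, 50000L),
                     end = c(100000L, 150000L))
  p <- build_bead_partition(doms, sizes)
  expect_equal(p$start, c(0L, 150000L))
  expect_equal(p$end, c(150000L, 200000L))
  expect_equal(p$type, c("domain", "gap"))

  # no domains: single gap bead spanning the chromosome
  p0 <- build_bead_partition(doms[0, ], c(chr1 = 1e7))
  expect_equal(nrow(p0), 1)
  expect_equal(p0$end - p0$start, 1e7)
  expect_equal(p0$type, "gap")

  # abutting domains stay separate beads
  ab <- data.frame(chrom = "chr1", start = c(0L, 50000L),
                   end = c(50000L, 100000L))
  pa <- build_bead_partition(ab, sizes)
  expect_equal(sum(pa$type == "domain"), 2)

  expect_error(build_bead_partition(
    data.frame(chrom = "chr1", start = 0L, end = 300000L), sizes
  ), "bounds")
})

test_that("bead partitions tile chromosomes for random domain sets", {
  sizes <- c(a = 5e6, b = 3e6)
  for (seed in 1:5) {
    doms <- generate_domains(sizes, 25, c(1e4, 4e5), seed = seed,
                             allow_overlap = TRUE)
    p <- build_bead_partition(doms, sizes)
    for (ch in names(sizes)) {
      pp <- p[p$chrom == ch, ]
      expect_equal(pp$start[1], 0L)
      expect_equal(pp$end[nrow(pp)], unname(sizes[ch]))
      if (nrow(pp) > 1) expect_equal(pp$start[-1], pp$end[-nrow(pp)])
    }
  }
})

test_that("bead radii reproduce closed-form volumes and occupancy", {
  part <- data.frame(chrom = "c", start = c(0, 1e6), end = c(1e6, 8e6),
                     bead_id = 1:2, type = "domain",
                     length_bp = c(1e6, 7e6))
  r <- scale_bead_radii(part, nucleus_diameter_um = 10, occupancy = 0.15)
  v_nuc <- 4 / 3 * pi * 5^3
  v_expect <- 0.15 * v_nuc * c(1, 7) / 8        # closed-form volumes
  expect_equal(4 / 3 * pi * r^3, v_expect, tolerance = 1e-12)
  expect_equal(r, (3 * v_expect / (4 * pi))^(1 / 3), tolerance = 1e-12)

  single <- part[1, ]
  r1 <- scale_bead_radii(single)
  expect_equal(r1, 0.15^(1 / 3) * 5, tolerance = 1e-12)

  expect_error(scale_bead_radii(part, occupancy = 0), "positive")
})

test_that("volume conservation holds for arbitrary partitions", {
  for (seed in 1:5) {
    sizes <- c(x = 4e6, y = 6e6)
    doms <- generate_domains(sizes, 18, c(2e4, 5e5), seed = seed)
    part <- build_bead_partition(doms, sizes)
    r <- scale_bead_radii(part)
    occ <- sum(4 / 3 * pi * r^3) / (4 / 3 * pi * 5^3)
    expect_equal(occ, 0.15, tolerance = 1e-9)
  }
})

test_that("loss score matches hand-computed hinge penalties", {
  # contained, non-overlapping, non-interacting: zero loss
  m <- make_two_bead_model(0.4, 0.5, d = 2)
  expect_equal(model_loss(m), 0)

  # touching interacting pair: interaction term zero
  mi <- make_two_bead_model(0.4, 0.5, d = 0.9,
                            interactions = data.frame(bead_a = 1,
                                                      bead_b = 2))
  expect_equal(model_loss(mi), 0)

  # gap of exactly 1 um beyond touching: interaction term 1.0
  mg <- make_two_bead_model(0.4, 0.5, d = 1.9,
                            interactions = data.frame(bead_a = 1,
                                                      bead_b = 2))
  expect_equal(model_loss(mg), 1.0)

  # overlap and containment penalties engage
  mo <- make_two_bead_model(0.4, 0.5, d = 0.5)
  expect_equal(model_loss(mo), (0.9 - 0.5)^2)
  mn <- make_two_bead_model(0.4, 0.5, d = 2)
  mn$beads$x <- c(4.8, 0)                      # |c| + r = 5.2 > R = 5
  expect_equal(model_loss(mn), 0.2^2, tolerance = 1e-12)

  expect_error(model_loss(make_two_bead_model(0.4, 0.5)), "placed")
})

test_that("greedy optimization is monotone and finds the touching optimum", {
  # zero interactions from a zero-loss start: loss stays zero
  m <- make_two_bead_model(0.4, 0.5, d = 2)
  m0 <- optimize_model(m, n_steps = 200, t0 = 0, seed = 1)
  expect_equal(m0$final_loss, 0)

  mi <- make_two_bead_model(0.4, 0.5, d = 3.5,
                            interactions = data.frame(bead_a = 1,
                                                      bead_b = 2))
  fit <- optimize_model(mi, n_steps = 10000, t0 = 0, seed = 2)
  expect_true(all(diff(fit$loss_trace) <= 1e-12))
  d <- sqrt(sum((as.numeric(fit$beads[1, c("x", "y", "z")]) -
                   as.numeric(fit$beads[2, c("x", "y", "z")]))^2))
  expect_lte(abs(d - 0.9), 0.05)
  expect_lte(fit$final_loss, model_loss(mi))

  # step budget 0 returns the initial placement
  same <- optimize_model(mi, n_steps = 0, seed = 3)
  expect_equal(same$beads$x, mi$beads$x)
})

test_that("interacting pairs end up closer than random pairs", {
  sizes <- c(chr1 = 5e6)
  doms <- generate_domains(sizes, 24, c(5e4, 1.5e5), seed = 11)
  part <- build_bead_partition(doms, sizes)
  ints <- generate_interactions(part$bead_id, 40, seed = 12)
  m <- bead_model(part, ints)
  fit <- optimize_model(m, n_steps = 30000, t0 = 0.3, cooling = 0.995,
                        seed = 13)
  xyz <- as.matrix(fit$beads[, c("x", "y", "z")])
  dmat <- as.matrix(dist(xyz))
  ia <- match(ints$bead_a, fit$beads$bead_id)
  ib <- match(ints$bead_b, fit$beads$bead_id)
  d_int <- mean(dmat[cbind(ia, ib)])
  key <- paste(pmin(ints$bead_a, ints$bead_b),
               pmax(ints$bead_a, ints$bead_b))
  all_pairs <- t(utils::combn(seq_len(nrow(fit$beads)), 2))
  pk <- paste(pmin(fit$beads$bead_id[all_pairs[, 1]],
                   fit$beads$bead_id[all_pairs[, 2]]),
              pmax(fit$beads$bead_id[all_pairs[, 1]],
                   fit$beads$bead_id[all_pairs[, 2]]))
  non <- all_pairs[!(pk %in% key), , drop = FALSE]
  d_non <- mean(dmat[non])
  expect_lt(d_int, d_non)

  # containment after optimization
  excess <- sqrt(rowSums(xyz^2)) + fit$beads$radius - fit$nucleus_radius
  expect_lte(sum(pmax(0, excess)), 0.01)

  # identical seed and parameters reproduce coordinates exactly
  fit2 <- optimize_model(m, n_steps = 30000, t0 = 0.3, cooling = 0.995,
                         seed = 13)
  expect_identical(fit$beads$x, fit2$beads$x)
})

test_that("shell assignment bins bead centres into half-open 1-um shells", {
  m <- make_two_bead_model(0.1, 0.1, d = 0)
  m$beads$x <- c(2.4, 1.0)
  sh <- assign_shells(m)
  expect_equal(sh$shell, c("2-3", "1-2"))
  expect_equal(shell_labels(5, 1), c("0-1", "1-2", "2-3", "3-4", "4-5"))
  m$beads$x <- c(5.5, 0)
  expect_error(assign_shells(m), "outside")
})

test_that("model export round-trips through the plain-text table", {
  sizes <- c(chr1 = 2e6)
  part <- build_bead_partition(
    generate_domains(sizes, 6, c(5e4, 2e5), seed = 21), sizes
  )
  m <- optimize_model(bead_model(part), n_steps = 300, seed = 22)
  sh <- assign_shells(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- export_model(m, sh, path)
  expect_equal(nrow(df), nrow(m$beads))
  back <- import_model(path)
  expect_equal(back$model$beads$x, m$beads$x, tolerance = 1e-12)
  expect_equal(back$model$nucleus_radius, m$nucleus_radius)
  expect_equal(back$assignment$shell, sh$shell)
  # empty model: header only
  empty <- m
  empty$beads <- m$beads[0, ]
  p2 <- withr::local_tempfile(fileext = ".tsv")
  export_model(empty, NULL, p2)
  expect_equal(nrow(import_model(p2)$model$beads), 0)
})

test_that("genomic interval pairs map to midpoint-containing beads", {
  sizes <- c(chr1 = 100000)
  part <- build_bead_partition(
    data.frame(chrom = "chr1", start = 0L, end = 50000L), sizes
  )
  pairs <- data.frame(chrom_a = "chr1", start_a = 0L, end_a = 10000L,
                      chrom_b = "chr1", start_b = 60000L, end_b = 70000L)
  mapped <- map_interactions_to_beads(pairs, part)
  expect_equal(mapped$bead_a, 1L)
  expect_equal(mapped$bead_b, 2L)
})
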