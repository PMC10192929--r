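test_that("reads are assigned to the bead containing their midpoint", {
  part <- data.frame(chrom = "c1", start = c(0L, 150L), end = c(150L, 300L),
                     bead_id = 1:2, type = "gap", length_bp = 150L)
  # read [100,140): midpoint 120 -> bead 1
  r <- data.frame(chrom = "c1", start = 100L, end = 140L, name = "a",
                  score = 0L, strand = "+")
  sig <- count_reads_per_bead(r, part)
  expect_equal(sig$counts$count, c(1L, 0L))
  # midpoint exactly on a bead start belongs to that bead (half-open)
  r2 <- data.frame(chrom = "c1", start = 140L, end = 160L, name = "b",
                   score = 0L, strand = "+")
  expect_equal(count_reads_per_bead(r2, part)$counts$count, c(0L, 1L))
  # unknown chromosome reads are skipped and counted
  r3 <- data.frame(chrom = "cX", start = 0L, end = 10L, name = "c",
                   score = 0L, strand = "+")
  s3 <- count_reads_per_bead(r3, part)
  expect_equal(s3$n_skipped, 1L)
  expect_equal(sum(s3$counts$count), 0L)
})

test_that("midpoint counting conserves reads and matches a linear scan", {
  sys <- make_toy_system(seed = 91)
  reads <- generate_reads(sys$partition, "input", 1000, seed = 92)
  sig <- count_reads_per_bead(reads, sys$partition)
  expect_equal(sum(sig$counts$count) + sig$n_skipped, 1000L)
  want <- table(factor(midpoint_oracle(reads, sys$partition),
                       levels = sys$partition$bead_id))
  expect_equal(sig$counts$count, as.integer(want), ignore_attr = TRUE)
})

test_that("rpkm matches its definition", {
  expect_equal(rpkm(1, 1000, 1e6), 1.0)
  expect_equal(rpkm(10, 2000, 2e6), 2.5)
  expect_equal(rpkm(0, 500, 1e6), 0.0)
  set.seed(1)
  cnt <- rpois(20, 50)
  len <- sample(1e3:1e5, 20)
  expect_equal(rpkm(cnt, len, 123456), rpkm_oracle(cnt, len, 123456),
               tolerance = 1e-12)
  expect_error(rpkm(1, 1000, 0), "positive")
  expect_error(rpkm(1, 0, 100), "positive")
})

test_that("observed/expected ratios follow RPKM arithmetic and exclusions", {
  part <- data.frame(chrom = "c", start = c(0L, 100L, 200L),
                     end = c(100L, 200L, 300L), bead_id = 1:3,
                     type = "gap", length_bp = 100L)
  mk <- function(counts, total) {
    df <- data.frame(bead_id = 1:3, count = counts,
                     rpkm = rpkm(counts, 100, total))
    structure(list(counts = df, total_mapped = total, n_skipped = 0L),
              class = "bead_signal")
  }
  same <- observed_expected(mk(c(5, 7, 9), 21), mk(c(5, 7, 9), 21))
  expect_equal(same$ratio$value, rep(1, 3))
  oe <- observed_expected(mk(c(4, 0, 2), 6), mk(c(1, 4, 0), 5))
  expect_equal(oe$ratio$value[1], (4 / 6) / (1 / 5))
  expect_equal(oe$n_excluded, 1L)           # bead 3 has zero expected
  expect_equal(oe$ratio$bead_id, c(1L, 2L))
  # pseudocount keeps all beads
  oe2 <- observed_expected(mk(c(4, 0, 2), 6), mk(c(1, 4, 0), 5),
                           pseudocount = 0.5)
  expect_equal(nrow(oe2$ratio), 3)
})

test_that("double normalization is exact identity on identical inputs", {
  rr <- data.frame(bead_id = 1:4, value = c(3, 1.5, 2, 0.5))
  dd <- data.frame(bead_id = 1:4, value = c(1.5, 1.5, 2, 0.5))
  dn <- double_normalize(rr, dd)
  expect_equal(dn$ratio$value, c(2, 1, 1, 1))
  ident <- double_normalize(rr, rr)
  expect_true(all(ident$ratio$value == 1.0))  # exact, not approximate
})

test_that("shell summaries equal a brute-force group-by", {
  vals <- data.frame(bead_id = 1:5, value = c(1, 2, 3, 10, 20))
  asn <- data.frame(bead_id = 1:5,
                    shell = c("0-1", "0-1", "0-1", "1-2", "2-3"))
  sh <- shell_distributions(vals, asn)
  expect_equal(sh$summary$median[sh$summary$shell == "0-1"], 2)
  expect_equal(sh$summary$n, c(3L, 1L, 1L, 0L, 0L))
  expect_true(all(is.na(sh$summary$median[sh$summary$n == 0])))

  set.seed(5)
  n <- 10000
  vals2 <- data.frame(bead_id = seq_len(n), value = rnorm(n))
  asn2 <- data.frame(bead_id = seq_len(n),
                     shell = sample(shell_labels(), n, replace = TRUE))
  sh2 <- shell_distributions(vals2, asn2)
  for (lab in shell_labels()) {
    v <- vals2$value[asn2$shell == lab]
    row <- sh2$summary[sh2$summary$shell == lab, ]
    expect_equal(row$n, length(v))
    expect_equal(row$median, median(v))
    expect_equal(row$mean, mean(v))
    expect_equal(row$sd, sd(v))
  }
  expect_error(shell_distributions(vals, asn[1:3, ]), "shell")
})

test_that("welch_test matches the textbook formula to 1e-10", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 3, 4, 5)
  got <- welch_test(x, y)
  want <- welch_oracle(x, y)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$df, want$df, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)

  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    g <- welch_test(a, b)
    w <- welch_oracle(a, b)
    expect_equal(g$t, w$t, tolerance = 1e-10)
    expect_equal(g$df, w$df, tolerance = 1e-10)
    expect_equal(g$p, w$p, tolerance = 1e-10)
  }
})

test_that("welch_test symmetry, identity and error cases", {
  x <- c(1, 2, 3)
  expect_equal(welch_test(x, x)$t, 0)
  expect_equal(welch_test(x, x)$p, 1)
  a <- c(1, 2, 3, 4)
  b <- c(10, 11, 13)
  expect_equal(welch_test(a, b)$t, -welch_test(b, a)$t)
  expect_equal(welch_test(a, b)$p, welch_test(b, a)$p)
  expect_error(welch_test(1, x), "at least 2")
  expect_error(welch_test(c(1, 1), c(2, 2)), "zero variance")
  expect_equal(welch_test(c(1, 1), c(1, 1))$p, 1)
})

test_that("the central-shell report compares 0-1 against each other shell", {
  tab <- data.frame(
    bead_id = 1:20,
    shell = rep(shell_labels(), each = 4),
    value = c(rnorm(4, 1), rnorm(4, 1.2), rnorm(4, 1.4), rnorm(4, 1.6),
              rnorm(4, 1.8))
  )
  rep_ <- shell_comparison_report(tab)
  expect_equal(nrow(rep_), 4)
  expect_equal(rep_$shell, c("1-2", "2-3", "3-4", "4-5"))
  expect_true(all(rep_$n_ref == 4))
  expect_identical(rep_, shell_comparison_report(tab))
  # undersized shell yields NA statistics
  tab2 <- tab[-(5:7), ]
  r2 <- shell_comparison_report(tab2)
  expect_true(is.na(r2$p[r2$shell == "1-2"]))
})

test_that("the full radial analysis wires RPKM, ratios and reports", {
  sys <- make_toy_system(seed = 95)
  sh <- plant_shell_assignment(sys$partition$bead_id, seed = 96)
  dmg <- generate_reads(sys$partition, "input", 20000, seed = 97)
  sim <- generate_reads(sys$partition, "input", 20000, seed = 98)
  res <- radial_shell_analysis(sys$partition, sh, dmg, sim,
                               repair = dmg, repair_sim = sim)
  expect_named(res,
               c("exclusions", "damage_rpkm", "damage_obs_exp",
                 "repair_rpkm", "repair_obs_exp", "double_norm"))
  # repair inputs identical to damage inputs: double normalization is 1
  expect_true(all(res$double_norm$shells$table$value == 1.0))
  expect_equal(nrow(res$damage_obs_exp$report), 4)
})
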