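test_that("window grid follows the sparse-tiling geometry", {
  asm <- genome_assembly("chrT", 10000)
  g <- make_window_grid(asm, 100L, 300L)
  expect_equal(start(g)[1:3] - 1L, c(0L, 300L, 600L))
  expect_true(all(width(g) == 100L))
  expect_true(all(countOverlaps(g, g) == 1L))   # disjoint by construction
  dense <- make_window_grid(asm, 1000L, 1000L)
  expect_equal(sum(width(dense)), 10000)
})

test_that("TMM scaling factors obey the closed form under global scaling", {
  set.seed(7)
  mu <- exp(runif(500, log(20), log(400)))
  a <- rpois(500, mu)
  counts <- cbind(a = a, b = a)           # identical samples
  f <- chromdiff:::tmm_factors(counts)
  expect_equal(unname(f), c(1, 1))
  counts <- cbind(a = a, b = 2L * a)      # exact 2x scaling
  f <- chromdiff:::tmm_factors(counts)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-9)
})

test_that("TMM matches a naive reimplementation of the M/A trimming", {
  set.seed(8)
  mu <- exp(runif(800, log(10), log(500)))
  counts <- cbind(s1 = rpois(800, mu), s2 = rpois(800, 1.7 * mu),
                  s3 = rpois(800, 0.6 * mu))
  f <- chromdiff:::tmm_factors(counts)
  # oracle: explicit trims, written independently
  lib <- colSums(counts)
  ref <- which.min(abs(lib - mean(lib)))
  raw <- sapply(seq_len(3), function(s) {
    if (s == ref) return(1)
    ok <- counts[, s] > 0 & counts[, ref] > 0
    M <- log2(counts[ok, s] / counts[ok, ref])
    A <- 0.5 * log2(as.numeric(counts[ok, s]) * counts[ok, ref])
    qm <- quantile(M, c(0.3, 0.7)); qa <- quantile(A, c(0.05, 0.95))
    keep <- M >= qm[1] & M <= qm[2] & A >= qa[1] & A <= qa[2]
    2^mean(M[keep])
  })
  oracle <- raw / exp(mean(log(raw)))
  expect_equal(unname(f), unname(oracle), tolerance = 1e-12)
})

test_that("the NB exact test handles degenerate and symmetric inputs", {
  # all-zero bin: p = 1
  expect_equal(chromdiff:::nb_exact_p(0, 0, 2, 2, 0.05), 1)
  # perfectly balanced split is the most probable outcome: p = 1
  expect_equal(chromdiff:::nb_exact_p(50, 50, 2, 2, 0), 1, tolerance = 1e-9)
  # symmetry in the two margins
  expect_equal(chromdiff:::nb_exact_p(10, 40, 2, 2, 0.05),
               chromdiff:::nb_exact_p(40, 10, 2, 2, 0.05))
  # p-values in (0, 1]
  p <- chromdiff:::nb_exact_p(5, 80, 2, 2, 0.02)
  expect_gt(p, 0); expect_lt(p, 0.001)
  # Poisson limit agrees with the exact binomial conditional test
  p_nb <- chromdiff:::nb_exact_p(20, 45, 2, 2, 1e-14)
  y <- 0:65
  pr <- dbinom(y, 65, 0.5)
  p_binom <- sum(pr[pr <= pr[21] * (1 + 1e-7)])
  expect_equal(p_nb, p_binom, tolerance = 1e-9)
})

test_that("window test is calibrated under its negative-binomial null", {
  set.seed(1234)
  n <- 10000
  mu <- exp(runif(n, log(10), log(200)))
  counts <- sapply(1:4, function(j) rnbinom(n, mu = mu, size = 1 / 0.02))
  res <- differential_window_test(counts, rep(c("c", "t"), each = 2))
  frac <- mean(res$p_value < 0.001)
  expect_gte(frac, 0.0005)
  expect_lte(frac, 0.002)
})

test_that("merge_significant_bins chains by start-to-start distance", {
  asm <- genome_assembly("chrT", 1e5)
  g <- make_window_grid(asm)
  sig <- g[c(1, 2, 40, 41, 42, 90)]   # starts 0,300 | 11700,12000,12300 | 26700
  merged <- merge_significant_bins(sig, 2000L)
  expect_length(merged, 3)
  expect_equal(start(merged) - 1L, c(0L, 11700L, 26700L))
  expect_equal(end(merged), c(400L, 12400L, 26800L))
  expect_equal(mcols(merged)$n_bins, c(2L, 3L, 1L))

  # two bins 5 kb apart stay separate
  far <- g[c(1, 18)]
  expect_length(merge_significant_bins(far, 2000L), 2)

  # random significance mask vs brute-force chain construction
  set.seed(10)
  for (rep in 1:5) {
    sel <- sort(sample.int(length(g), 40))
    merged <- merge_significant_bins(g[sel], 2000L)
    starts <- start(g)[sel]
    brk <- c(TRUE, diff(starts) > 2000)
    expect_length(merged, sum(brk))
    expect_equal(start(merged), starts[brk])
  }
})

test_that("identical-count features give null fold change and p near 1", {
  asm <- genome_assembly("chrT", 1e5)
  pk <- interval_set("chrT", c(10000, 40000), c(10600, 40600), asm)
  rd <- reads_at_midpoints("chrT", c(rep(10300, 30), rep(40300, 30)))
  res <- call_differential_peaks(list(pk, pk), list(pk, pk),
                                 list(rd, rd), list(rd, rd), asm)
  expect_true(all(abs(res$results$log2fc) < 1e-9))
  expect_true(all(res$results$p_value > 0.99))
  expect_false(any(res$results$significant))
})

test_that("consensus keeps only window regions confirmed by peak features", {
  asm <- genome_assembly("chrT", 1e5)
  w <- interval_set("chrT", c(1000, 20000, 50000), c(2000, 21000, 51000), asm)
  mcols(w)$log2fc <- c(1.5, -0.8, 2.0)
  p <- interval_set("chrT", c(1500, 20500, 80000), c(2500, 21500, 81000), asm)
  mcols(p)$log2fc <- c(1.2, 0.9, 1.0)
  # disjoint inputs -> empty
  expect_length(consensus_regions(w[3], p[3]), 0)
  # identical inputs -> all retained
  expect_length(consensus_regions(w[1], p[1]), 1)
  # direction agreement: region 2 has opposite signs, dropped by default
  cons <- consensus_regions(w, p)
  expect_equal(start(cons) - 1L, c(1000L))
  cons_all <- consensus_regions(w, p, require_direction_agreement = FALSE)
  expect_equal(start(cons_all) - 1L, c(1000L, 20000L))
  # brute-force overlap filter oracle on random fixtures
  set.seed(12)
  for (rep in 1:5) {
    wr <- merge_overlapping(random_intervals(30, asm, 2000))
    mcols(wr)$log2fc <- 1
    pr <- merge_overlapping(random_intervals(30, asm, 2000))
    mcols(pr)$log2fc <- 1
    cons <- consensus_regions(wr, pr)
    keep <- vapply(seq_along(wr), function(i)
      any(start(pr) <= end(wr)[i] & end(pr) >= start(wr)[i]), TRUE)
    expect_equal(granges(cons), granges(wr[keep]))
  }
})

test_that("direction summary recovers planted gain/loss fractions", {
  asm <- genome_assembly("chrT", 1e5)
  g <- interval_set("chrT", seq(0, 99000, 1000), seq(500, 99500, 1000), asm)
  set.seed(13)
  lfc <- c(rep(1.2, 80), rep(-1.2, 20))[sample(100)]
  gr <- g[1:100]
  mcols(gr)$log2fc <- lfc
  ds <- direction_summary(gr)
  expect_equal(ds$n, 100L)
  expect_equal(ds$induced_fraction, 0.8)
  expect_equal(ds$repressed_fraction, 0.2)
  empty <- direction_summary(gr[0])
  expect_equal(empty$n, 0L)
})
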