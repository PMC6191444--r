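test_that("constant signal fills every meta-gene cell", {
  asm <- genome_assembly("chrT", 5e4)
  tr <- constant_track(asm, value = 2.5)
  genes <- interval_set("chrT", c(10000, 25000), c(14000, 30000), asm,
                        strand = c("+", "-"), label = c("g1", "g2"))
  mg <- build_metagene(tr, genes, flank_bp = 6000, flank_bin = 50,
                       body_bins = 120)
  expect_equal(dim(mg$values), c(2L, 360L))
  expect_equal(max(abs(mg$values - 2.5)), 0, tolerance = 1e-12)
})

test_that("a 600-bp gene yields exact 5-bp body slices", {
  asm <- genome_assembly("chrT", 5e4)
  set.seed(3)
  v <- runif(5e4)
  tr <- vector_track(asm, list(chrT = v))
  g0 <- 20000   # 0-based gene start
  genes <- interval_set("chrT", g0, g0 + 600, asm, strand = "+",
                        label = "g")
  mg <- build_metagene(tr, genes)
  bc <- (mg$flank_bins + 1):(mg$flank_bins + mg$body_bins)
  body <- mg$values[1, bc]
  for (k in 0:119) {
    expect_equal(unname(body[k + 1]),
                 mean(v[(g0 + 5 * k + 1):(g0 + 5 * k + 5)]))
  }
})

test_that("minus-strand rows equal the reversed plus-strand computation", {
  asm <- genome_assembly("chrT", 6e4)
  set.seed(17)
  v <- rpois(6e4, 3) + rep(c(0, 5), each = 3e4)   # step signal
  tr <- vector_track(asm, list(chrT = v))
  plus <- interval_set("chrT", 21000, 28500, asm, strand = "+")
  minus <- interval_set("chrT", 21000, 28500, asm, strand = "-")
  mp <- build_metagene(tr, plus)
  mm <- build_metagene(tr, minus)
  expect_equal(unname(mm$values[1, ]), rev(unname(mp$values[1, ])))
})

test_that("body-bin row means conserve the gene-body mean", {
  asm <- toy_assembly(2e5)
  set.seed(23)
  v <- rexp(2e5)
  tr <- vector_track(asm, list(chrT = v))
  n <- 40
  w <- sample(150:9000, n)
  s <- floor(runif(n, 7000, 2e5 - 7000 - w))
  genes <- interval_set("chrT", s, s + w, asm,
                        strand = sample(c("+", "-"), n, TRUE))
  mg <- build_metagene(tr, genes)
  bc <- (mg$flank_bins + 1):(mg$flank_bins + mg$body_bins)
  for (i in seq_len(n)) {
    expect_equal(mean(mg$values[i, bc]),
                 mean(v[(s[i] + 1):(s[i] + w[i])]),
                 tolerance = 1e-9)
  }
})

test_that("short genes and off-chromosome flanks are excluded", {
  asm <- genome_assembly("chrT", 3e4)
  tr <- constant_track(asm, 1)
  genes <- interval_set("chrT", c(100, 10000, 10500), c(200, 10100, 14000),
                        asm, strand = "+", label = c("flank_off", "short", "ok"))
  mg <- build_metagene(tr, genes, flank_bp = 6000)
  expect_equal(rownames(mg$values), "ok")
  expect_setequal(mg$excluded, c("flank_off", "short"))
  expect_error(build_metagene(tr, genes[1:2]), "no eligible genes")
})

test_that("k-means recovers planted profile groups and is deterministic", {
  asm <- toy_assembly(1e6)
  tr <- constant_track(asm, 1)
  genes <- interval_set("chrT", seq(10000, 890000, by = 20000) - 1,
                        seq(10000, 890000, by = 20000) + 5999, asm,
                        strand = "+")
  mg <- build_metagene(tr, genes)
  # plant two well-separated profile shapes
  set.seed(44)
  n <- nrow(mg$values)
  truth <- rep(1:2, length.out = n)
  base <- matrix(rnorm(n * ncol(mg$values), 0, 0.05), nrow = n)
  shape1 <- sin(seq(0, pi, length.out = ncol(mg$values)))
  shape2 <- cos(seq(0, 2 * pi, length.out = ncol(mg$values)))
  mg$values <- base + outer(truth == 1, shape1) * 3 +
    outer(truth == 2, shape2) * 3 + 5
  cl <- cluster_metagene(mg, k = 2, seed = 7)
  expect_equal(adjusted_rand(cl$cluster, truth), 1.0)
  cl2 <- cluster_metagene(mg, k = 2, seed = 7)
  expect_identical(cl$cluster, cl2$cluster)
  # cluster 1 has the highest mean body signal
  bc <- (mg$flank_bins + 1):(mg$flank_bins + mg$body_bins)
  bm <- tapply(rowMeans(mg$values[, bc]), cl$cluster, mean)
  expect_equal(which.max(bm), c("1" = 1L))
  # k = n_rows: every row its own cluster
  cln <- cluster_metagene(mg, k = n, seed = 1, nstart = 1)
  expect_equal(length(unique(cln$cluster)), n)
})

test_that("body vs downstream comparison flags a planted shift", {
  asm <- toy_assembly(5e5)
  set.seed(55)
  n <- 25
  s <- seq(10000, 480000, length.out = n)
  genes <- interval_set("chrT", s, s + 4000, asm, strand = "+")
  v <- rep(1, 5e5)
  for (i in seq_len(n)) v[(s[i] + 1):(s[i] + 4000)] <- 1 + runif(1, 0.5, 1)
  tr <- vector_track(asm, list(chrT = v))
  cmp <- compare_body_vs_downstream(tr, genes, alternative = "greater")
  expect_lt(cmp$p_signed_rank, 0.01)
  expect_lt(cmp$p_rank_sum, 0.01)
  expect_true(all(cmp$data$body_mean > cmp$data$down_mean))

  # identical windows: null center, p = 1 for the paired test
  flat <- constant_track(asm, 1)
  cmp0 <- compare_body_vs_downstream(flat, genes)
  expect_equal(cmp0$p_signed_rank, 1)
})

test_that("paired signed-rank p matches exact enumeration at small n", {
  asm <- toy_assembly(3e5)
  set.seed(66)
  n <- 8
  s <- seq(10000, 250000, length.out = n)
  genes <- interval_set("chrT", s, s + 2000, asm, strand = "+")
  v <- rep(1, 3e5)
  for (i in seq_len(n)) {
    v[(s[i] + 1):(s[i] + 2000)] <- 1 + rnorm(1, 0.3, 0.5)     # body
    v[(s[i] + 2001):(s[i] + 2500)] <- 1 + rnorm(1, 0, 0.5)    # downstream
  }
  tr <- vector_track(asm, list(chrT = v))
  cmp <- compare_body_vs_downstream(tr, genes, window_bp = 500)
  d <- cmp$data$body_mean - cmp$data$down_mean
  expect_equal(cmp$p_signed_rank, signed_rank_exact_p(d),
               tolerance = 1e-10)
})
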