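test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 9L, n_genes = 50L, n_peaks = 60L,
                           n_differential_sites = 5L,
                           reads_per_sample = 5000)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1$truth$state_segments, s2$truth$state_segments)
  expect_identical(s1$truth$genes, s2$truth$genes)
  expect_identical(s1$truth$peaks, s2$truth$peaks)
  expect_identical(s1$truth$differential_sites, s2$truth$differential_sites)

  r1 <- simulate_counts(s1, cfg, "control")
  r2 <- simulate_counts(s2, cfg, "control")
  expect_identical(r1, r2)

  t1 <- simulate_peptide_table(4, 1, seed = 3)
  t2 <- simulate_peptide_table(4, 1, seed = 3)
  expect_identical(t1, t2)
})

test_that("generated truth satisfies the structural invariants", {
  cfg <- simulation_config(seed = 2L, n_genes = 80L, n_peaks = 100L,
                           n_differential_sites = 10L)
  sim <- simulate_genome(cfg)
  seg <- sim$truth$state_segments
  # segments tile each chromosome exactly
  for (ch in sim$assembly$chrom_names) {
    s <- seg[as.character(seqnames(seg)) == ch]
    expect_equal(sum(width(s)), sim$assembly$chrom_lengths[[ch]])
    expect_equal(min(start(s)), 1L)
    expect_true(all(start(s)[-1] == head(end(s), -1) + 1L))
  }
  # differential sites lie within the acetylation peak regions of both marks
  for (mark in cfg$factors[3:4]) {
    expect_true(all(overlapsAny(sim$truth$differential_sites,
                                sim$truth$peaks[[mark]])))
  }
  # genes are non-overlapping and stranded
  g <- sim$truth$genes
  expect_true(all(countOverlaps(g, g, ignore.strand = TRUE) == 1L))
  expect_true(all(as.character(strand(g)) %in% c("+", "-")))
  expect_true(all(width(g) >= 2000))
})

test_that("zero peaks and zero differential sites are valid configurations", {
  cfg <- simulation_config(seed = 4L, n_peaks = 0L,
                           n_differential_sites = 0L, n_genes = 10L)
  sim <- simulate_genome(cfg)
  expect_true(all(lengths(sim$truth$peaks) == 0))
  expect_length(sim$truth$differential_sites, 0)
  expect_gt(length(sim$truth$state_segments), 0)
})

test_that("peak placement follows the state weights (binomial check)", {
  cfg <- simulation_config(seed = 6L, n_peaks = 1000L, n_genes = 10L,
                           n_differential_sites = 0L)
  sim <- simulate_genome(cfg)
  seg <- sim$truth$state_segments
  w3 <- sum(width(seg[mcols(seg)$state == 3]))
  tot <- total_size(sim$assembly)
  other <- tot - w3
  p3 <- 5 * w3 / (5 * w3 + other)      # segment-choice probability
  pk <- sim$truth$peaks[[cfg$factors[1]]]
  x <- sum(mcols(pk)$state == 3)
  n <- length(pk)
  expect_lt(abs(x - n * p3), 3 * sqrt(n * p3 * (1 - p3)))
})

test_that("effect_fold = 1 makes conditions exchangeable at planted sites", {
  cfg <- simulation_config(seed = 12L, effect_fold = 1,
                           n_peaks = 200L, n_differential_sites = 200L,
                           reads_per_sample = 5e4)
  sim <- simulate_genome(cfg)
  ctrl <- simulate_counts(sim, cfg, "control")
  kd <- simulate_counts(sim, cfg, "knockdown")
  sites <- merge_overlapping(sim$truth$differential_sites)
  cc <- count_reads_in_regions(ctrl["rep1"], sites, sim$assembly)$counts
  ck <- count_reads_in_regions(kd["rep1"], sites, sim$assembly)$counts
  ks <- suppressWarnings(ks.test(as.vector(cc), as.vector(ck)))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero dispersion gives Poisson-like background bin counts", {
  cfg <- simulation_config(seed = 21L, nb_dispersion = 0,
                           n_peaks = 10L, n_differential_sites = 0L,
                           n_genes = 10L, reads_per_sample = 5e4,
                           libsize_jitter = 0)
  sim <- simulate_genome(cfg)
  rd <- simulate_counts(sim, cfg, "control")
  # 1-kb background bins away from peaks, counts across replicates+bins
  grid <- make_window_grid(sim$assembly, 1000L, 1000L)
  bg <- grid[!overlapsAny(grid, sim$truth$peaks[[cfg$factors[3]]],
                          maxgap = 500)]
  bg <- bg[seq_len(min(1000L, length(bg)))]
  cm <- count_reads_in_regions(rd, bg, sim$assembly)
  counts <- as.vector(cm$counts)
  expect_gt(var(counts) / mean(counts), 0.8)
  expect_lt(var(counts) / mean(counts), 1.2)
})

test_that("peptide tables encode their planted truth", {
  # noiseless non-isobaric: naive ratios recover percentages exactly
  tab <- simulate_peptide_table(3, 0, seed = 5, noise_sd = 0,
                                true_percent = c(60, 30, 10))
  truth <- attr(tab, "truth")
  naive <- tab[, .(modification, pct = 100 * ms1_area / sum(ms1_area)),
               by = peptide]
  m <- merge(naive, truth, by = c("peptide", "modification"))
  expect_equal(m$pct, m$true_percent, tolerance = 1e-12)

  # one isobaric pair split 75/25 at zero noise: fragment means in ratio 3:1
  tab <- simulate_peptide_table(1, 1, seed = 8, noise_sd = 0,
                                true_percent = c(20, 60, 20))
  pair <- tab[!is.na(isobaric_group)]
  expect_equal(nrow(pair), 2L)
  expect_equal(length(unique(pair$ms1_area)), 1L)
  fm <- rowMeans(as.matrix(pair[, .(frag1, frag2, frag3)]))
  expect_equal(unname(fm[1] / fm[2]), 3, tolerance = 1e-12)
})
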