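# Independent brute-force oracles and small fixture factories.
# Everything here works on dense per-base boolean masks or double loops,
# deliberately avoiding the interval algebra under test.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(data.table)
})

toy_assembly <- function(len = 1e5, chroms = "chrT") {
  genome_assembly(chroms, rep(len, length(chroms)))
}

# random 0-based half-open intervals on a single-chromosome assembly
random_intervals <- function(n, asm, max_width = 2000) {
  ch <- sample(asm$chrom_names, n, replace = TRUE)
  len <- asm$chrom_lengths[ch]
  w <- sample.int(max_width, n, replace = TRUE)
  s <- floor(runif(n) * (len - w))
  interval_set(ch, s, s + w, asm)
}

# per-base boolean mask of an interval set (one chromosome)
interval_mask <- function(gr, asm, chrom) {
  m <- logical(asm$chrom_lengths[[chrom]])
  sel <- as.character(seqnames(gr)) == chrom
  for (i in which(sel)) m[start(gr)[i]:end(gr)[i]] <- TRUE
  m
}

# mask -> sorted disjoint intervals (0-based half-open data.table)
mask_to_intervals <- function(m) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- c(0L, head(ends, -1L))
  data.table(start = starts[r$values], end = ends[r$values])
}

mask_union_width <- function(a, b, asm, chrom) {
  sum(interval_mask(a, asm, chrom) & interval_mask(b, asm, chrom))
}

# adjusted Rand index (closed form from the pair-counting contingency table)
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  a <- ch2(as.vector(tab))
  b <- ch2(rowSums(tab))
  cc <- ch2(colSums(tab))
  n <- ch2(sum(tab))
  (a - b * cc / n) / ((b + cc) / 2 - b * cc / n)
}

# constant-value coverage track on an assembly, built directly
constant_track <- function(asm, value = 1, fragment_length = 150L) {
  cov <- as(setNames(lapply(asm$chrom_names,
                            function(ch) Rle(value, asm$chrom_lengths[[ch]])),
                     asm$chrom_names), "RleList")
  structure(list(cov = cov, assembly = asm, scale = 1,
                 fragment_length = fragment_length,
                 n_reads = NA_integer_, clipped = 0),
            class = "coverage_track")
}

# arbitrary per-base track from a list of numeric vectors
vector_track <- function(asm, values) {
  cov <- as(setNames(lapply(asm$chrom_names,
                            function(ch) Rle(values[[ch]])),
                     asm$chrom_names), "RleList")
  structure(list(cov = cov, assembly = asm, scale = 1,
                 fragment_length = 150L, n_reads = NA_integer_, clipped = 0),
            class = "coverage_track")
}

# reads whose 150-bp fragment midpoint lands exactly at `mid0` (0-based)
reads_at_midpoints <- function(chrom, mid0) {
  data.table(chrom = chrom, pos = as.integer(mid0 - 75L), strand = "+")
}

# exact paired signed-rank p-value by enumeration of all sign assignments
signed_rank_exact_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  null_w <- signs %*% r
  w_obs <- sum(r[d > 0])
  switch(alternative,
         greater = mean(null_w >= w_obs),
         less = mean(null_w <= w_obs),
         two.sided = min(1, 2 * min(mean(null_w >= w_obs),
                                    mean(null_w <= w_obs))))
}
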