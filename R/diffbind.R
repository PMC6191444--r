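#' Consensus differential-binding caller
#'
#' Two independent re-implemented routes to differential regions between
#' control and knockdown conditions, and their intersection:
#'
#' * the *window* route bins the genome into 100-bp bins every 300 bp,
#'   normalizes with trimmed-mean-of-M scaling factors from 10-kb bins,
#'   tests each bin with a two-sided negative-binomial exact test
#'   (conditional on the bin total), retains bins with raw p < 0.001 and
#'   chains neighboring significant bins within 2 kb into regions;
#' * the *peak* route intersects replicate peak calls within each condition,
#'   merges the condition-consistent peaks across conditions into features,
#'   normalizes counts by median-of-ratios and applies a per-feature
#'   negative-binomial Wald test with Benjamini-Hochberg adjustment.
#'
#' Only regions detected by both routes form the consensus set.
#'
#' @name diffbind
NULL

#' Window grid over an assembly
#'
#' @param assembly A [genome_assembly].
#' @param bin_width Bin width, bp (default 100).
#' @param step Distance between bin starts, bp (default 300; with the
#'   default bin width this leaves 200-bp gaps, i.e. a sparse tiling).
#' @return `GRanges` of bins, sorted by (chrom, start).
#' @export
make_window_grid <- function(assembly, bin_width = 100L, step = 300L) {
  rows <- lapply(assembly$chrom_names, function(ch) {
    len <- assembly$chrom_lengths[[ch]]
    starts0 <- seq.int(0L, len - bin_width, by = step)
    GRanges(ch, IRanges(start = starts0 + 1L, width = bin_width),
            seqinfo = as_seqinfo(assembly))
  })
  sort(do.call(c, rows))
}

#' Trimmed-mean-of-M scaling factors from large genomic bins
#'
#' Counts reads in non-overlapping `scale_bin`-bp bins and derives
#' per-sample scaling factors by a trimmed mean of per-bin log2 count ratios
#' against a reference sample (the one with library size closest to the
#' mean): bins in the extreme 30% of M values (each tail) or the extreme 5%
#' of A values are discarded; the factor is `2^mean(M)` over the rest,
#' absorbing the total-count difference. Factors are centered so their
#' geometric mean is 1.
#'
#' @param reads_list Named list of read-start tables (all samples).
#' @param assembly A [genome_assembly].
#' @param scale_bin Bin width for factor estimation, bp (default 10000).
#' @param fragment_length Read-extension length, bp.
#' @return Named numeric vector of per-sample scaling factors (geometric
#'   mean 1). Normalized counts are raw counts divided by these.
#' @export
window_scaling_factors <- function(reads_list, assembly, scale_bin = 10000L,
                                   fragment_length = 150L) {
  stopifnot(length(reads_list) >= 2)
  if (any(vapply(reads_list, nrow, 0L) == 0L))
    stop("a sample has zero reads")
  bins <- make_window_grid(assembly, bin_width = scale_bin, step = scale_bin)
  cm <- count_reads_in_regions(reads_list, bins, assembly, fragment_length)
  tmm_factors(cm$counts)
}

# TMM on a raw count matrix; factors absorb library-size differences.
tmm_factors <- function(counts, m_trim = 0.30, a_trim = 0.05) {
  lib <- colSums(counts)
  ref <- which.min(abs(lib - mean(lib)))
  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    y <- counts[, s]; r <- counts[, ref]
    ok <- y > 0 & r > 0
    if (!any(ok)) stop("no co-detected bins between samples")
    M <- log2(y[ok] / r[ok])
    A <- 0.5 * log2(as.numeric(y[ok]) * r[ok])
    keepM <- M >= quantile(M, m_trim) & M <= quantile(M, 1 - m_trim)
    keepA <- A >= quantile(A, a_trim) & A <= quantile(A, 1 - a_trim)
    2^mean(M[keepM & keepA])
  }, 0)
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

# Method-of-moments NB dispersion, pooled within abundance strata.
# z: normalized count matrix; group: condition per column.
# Returns one alpha per row (var = mu + alpha * mu^2).
estimate_dispersion_strata <- function(z, group, n_strata = 10L) {
  group <- as.factor(group)
  reps <- table(group)
  if (all(reps < 2)) {
    warning("no condition has replicates; dispersion set to 0 (Poisson)")
    return(rep(0, nrow(z)))
  }
  num <- rep(0, nrow(z)); den <- rep(0, nrow(z))
  for (g in levels(group)) {
    idx <- which(group == g)
    if (length(idx) < 2) next
    zg <- z[, idx, drop = FALSE]
    mu <- rowMeans(zg)
    v <- apply(zg, 1, var)
    w <- length(idx) - 1
    num <- num + w * (v - mu)
    den <- den + w * mu^2
  }
  ab <- rowMeans(z)
  strat <- cut(rank(ab, ties.method = "first"),
               breaks = n_strata, labels = FALSE)
  alpha <- numeric(nrow(z))
  for (s in unique(strat)) {
    i <- strat == s
    alpha[i] <- max(0, sum(num[i]) / max(sum(den[i]), .Machine$double.eps))
  }
  alpha
}

# Two-sided NB exact test of a condition split conditional on the bin total.
# With a common per-replicate mean under the null, the conditional law of
# the control total given the bin total does not depend on the mean, only on
# the dispersion (negative-hypergeometric; binomial in the Poisson limit).
nb_exact_p <- function(s1, s2, n1, n2, alpha) {
  t <- s1 + s2
  if (t == 0) return(1)
  y <- 0:t
  if (alpha <= 1e-12) {
    lp <- dbinom(y, t, n1 / (n1 + n2), log = TRUE)
  } else {
    lp <- dnbinom(y, size = n1 / alpha, prob = 0.5, log = TRUE) +
      dnbinom(t - y, size = n2 / alpha, prob = 0.5, log = TRUE)
  }
  lp <- lp - max(lp)
  p <- exp(lp); p <- p / sum(p)
  sum(p[p <= p[s1 + 1] * (1 + 1e-7)])
}

#' Windowed differential test on a count matrix
#'
#' The statistical core of the window route, exposed separately so it can be
#' run on any bin-level count matrix. Counts are divided by per-sample
#' scaling factors, low-abundance bins (mean normalized count below
#' `count_floor`) are removed, a common NB dispersion is estimated by the
#' method of moments within 10 abundance strata, and each bin receives a
#' two-sided NB exact test on the condition totals conditional on the bin
#' total.
#'
#' @param counts Integer matrix, bins x samples.
#' @param group Condition per column (two levels; first level = control).
#' @param factors Per-sample scaling factors (default all 1).
#' @param alpha Raw p-value threshold for significance (default 0.001, no
#'   multiplicity adjustment — by design for this route).
#' @param count_floor Minimum mean normalized count for a bin to be tested.
#' @return `data.table` with one row per tested bin: `bin` (row index),
#'   `mean_control`, `mean_treat`, `log2fc` (0.5 pseudocount), `p_value`,
#'   `significant`.
#' @export
differential_window_test <- function(counts, group, factors = NULL,
                                     alpha = 0.001, count_floor = 5) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2, ncol(counts) == length(group))
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  z <- sweep(counts, 2, factors, "/")
  keep <- rowMeans(z) >= count_floor
  if (!any(keep))
    return(data.table(bin = integer(), mean_control = numeric(),
                      mean_treat = numeric(), log2fc = numeric(),
                      p_value = numeric(), significant = logical()))
  zk <- z[keep, , drop = FALSE]
  disp <- estimate_dispersion_strata(zk, group)
  i1 <- group == levels(group)[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  pseudo <- round(zk)
  s1 <- rowSums(pseudo[, i1, drop = FALSE])
  s2 <- rowSums(pseudo[, !i1, drop = FALSE])
  pv <- vapply(seq_along(s1),
               function(i) nb_exact_p(s1[i], s2[i], n1, n2, disp[i]), 0)
  m1 <- rowMeans(zk[, i1, drop = FALSE])
  m2 <- rowMeans(zk[, !i1, drop = FALSE])
  data.table(bin = which(keep),
             mean_control = m1, mean_treat = m2,
             log2fc = log2((m2 + 0.5) / (m1 + 0.5)),
             p_value = pv, significant = pv < alpha)
}

#' Call differential windows from read tables
#'
#' Runs the full window route: sparse 100-bp/300-bp binning, midpoint
#' counting, 10-kb trimmed-mean scaling factors, and the conditional NB
#' exact test of [differential_window_test()].
#'
#' @param reads_control,reads_treat Lists of replicate read-start tables.
#' @param assembly A [genome_assembly].
#' @param bin_width,step Window grid parameters (defaults 100/300).
#' @param scale_bin Scaling-factor bin width (default 10000).
#' @param alpha Raw p threshold (default 0.001).
#' @param count_floor Abundance filter on mean normalized counts.
#' @param fragment_length Read-extension length, bp.
#' @return A list: `bins` (tested-bin `data.table` with coordinates),
#'   `significant` (`GRanges` of significant bins carrying `log2fc` and
#'   `p_value`), `factors`, `grid`.
#' @export
call_differential_windows <- function(reads_control, reads_treat, assembly,
                                      bin_width = 100L, step = 300L,
                                      scale_bin = 10000L, alpha = 0.001,
                                      count_floor = 5,
                                      fragment_length = 150L) {
  if (length(reads_control) < 2 || length(reads_treat) < 2)
    warning("fewer than 2 replicates in a condition; ",
            "dispersion may be unestimable (Poisson fallback)")
  samples <- c(setNames(reads_control,
                        paste0("control_", seq_along(reads_control))),
               setNames(reads_treat,
                        paste0("treat_", seq_along(reads_treat))))
  factors <- window_scaling_factors(samples, assembly, scale_bin,
                                    fragment_length)
  grid <- make_window_grid(assembly, bin_width, step)
  cm <- count_reads_in_regions(samples, grid, assembly, fragment_length)
  group <- factor(rep(c("control", "treat"),
                      c(length(reads_control), length(reads_treat))),
                  levels = c("control", "treat"))
  res <- differential_window_test(cm$counts, group, factors,
                                  alpha = alpha, count_floor = count_floor)
  res[, `:=`(chrom = as.character(seqnames(grid))[bin],
             start = start(grid)[bin] - 1L,
             end = end(grid)[bin])]
  sig <- grid[res$bin[res$significant]]
  if (length(sig)) {
    mcols(sig)$log2fc <- res$log2fc[res$significant]
    mcols(sig)$p_value <- res$p_value[res$significant]
  }
  list(bins = res, significant = sig, factors = factors, grid = grid)
}

#' Merge neighboring significant bins into regions
#'
#' Chains significant bins whose starts lie within `merge_window` bp of the
#' previous significant bin's start (sliding-window merge) and emits each
#' chain as one region spanning the first bin's start to the last bin's
#' end. Singleton chains are allowed.
#'
#' @param sig `GRanges` of significant bins (may carry `log2fc`,
#'   `p_value`).
#' @param merge_window Chain distance in bp, start-to-start (default 2000).
#' @return `GRanges` of merged regions with `n_bins`, `log2fc` (mean over
#'   member bins) and `min_p` metadata.
#' @export
merge_significant_bins <- function(sig, merge_window = 2000L) {
  if (length(sig) == 0L) return(sig)
  sig <- sort(sig, ignore.strand = TRUE)
  ch <- as.character(seqnames(sig))
  s <- start(sig)
  new_chain <- c(TRUE, ch[-1] != ch[-length(ch)] |
                   (s[-1] - s[-length(s)]) > merge_window)
  chain <- cumsum(new_chain)
  lfc <- if (!is.null(mcols(sig)$log2fc)) mcols(sig)$log2fc else
    rep(NA_real_, length(sig))
  pv <- if (!is.null(mcols(sig)$p_value)) mcols(sig)$p_value else
    rep(NA_real_, length(sig))
  dt <- data.table(chrom = ch, start = s, end = end(sig),
                   chain = chain, lfc = lfc, pv = pv)
  agg <- dt[, .(chrom = chrom[1], start = min(start), end = max(end),
                n_bins = .N, log2fc = mean(lfc), min_p = min(pv)),
            by = chain]
  out <- GRanges(agg$chrom, IRanges(agg$start, agg$end),
                 seqinfo = seqinfo(sig))
  mcols(out)$n_bins <- agg$n_bins
  mcols(out)$log2fc <- agg$log2fc
  mcols(out)$min_p <- agg$min_p
  out
}

#' Call differential peaks (peak route)
#'
#' Peaks present in both replicates of a condition (>= 1 bp reciprocal
#' overlap) are kept, combined across conditions, and overlapping peaks
#' merged into single features spanning the originals. Feature counts are
#' normalized by median-of-ratios size factors; each feature receives an NB
#' Wald test (method-of-moments dispersion, log link) of the condition
#' effect, with Benjamini-Hochberg adjustment.
#'
#' @param peaks_control,peaks_treat Lists of replicate peak `GRanges`.
#' @param reads_control,reads_treat Lists of replicate read-start tables.
#' @param assembly A [genome_assembly].
#' @param alpha_adj BH-adjusted p threshold (default 0.05).
#' @param fragment_length Read-extension length, bp.
#' @return A list: `results` (`data.table` per feature: coordinates,
#'   `base_mean`, `log2fc`, `p_value`, `p_adj`, `significant`),
#'   `significant` (`GRanges` of significant features with `log2fc`),
#'   `features` (all tested features), `size_factors`.
#' @export
call_differential_peaks <- function(peaks_control, peaks_treat,
                                    reads_control, reads_treat, assembly,
                                    alpha_adj = 0.05,
                                    fragment_length = 150L) {
  consistent <- function(reps) {
    reps <- lapply(reps, granges)
    if (length(reps) == 1L) return(merge_overlapping(reps[[1]]))
    kept <- reps[[1]]
    for (r in reps[-1]) {
      kept <- c(subsetByOverlaps(kept, r, ignore.strand = TRUE),
                subsetByOverlaps(r, kept, ignore.strand = TRUE))
      kept <- merge_overlapping(kept)
    }
    kept
  }
  features <- merge_overlapping(c(consistent(peaks_control),
                                  consistent(peaks_treat)))
  if (length(features) == 0L) stop("no condition-consistent peaks")
  samples <- c(setNames(reads_control,
                        paste0("control_", seq_along(reads_control))),
               setNames(reads_treat,
                        paste0("treat_", seq_along(reads_treat))))
  if (length(samples) < 2) stop("need at least 2 samples in total")
  cm <- count_reads_in_regions(samples, features, assembly, fragment_length)
  sf <- tryCatch(median_of_ratios_size_factors(cm$counts),
                 error = function(e)
                   median_of_ratios_size_factors(cm$counts, pseudocount = 0.5))
  z <- sweep(cm$counts, 2, sf, "/")
  group <- factor(rep(c("control", "treat"),
                      c(length(reads_control), length(reads_treat))),
                  levels = c("control", "treat"))
  disp <- estimate_dispersion_strata(z, group)
  off <- log(sf)
  fit_one <- function(y, alpha) {
    if (all(y == 0)) return(c(0, 1))
    if (length(unique(y)) == 1L && length(unique(off)) == 1L)
      return(c(0, 1))
    fam <- if (alpha > 1e-12)
      MASS::negative.binomial(theta = 1 / alpha) else poisson(link = "log")
    fit <- tryCatch(glm(y ~ group, family = fam, offset = off),
                    error = function(e) NULL,
                    warning = function(w)
                      suppressWarnings(glm(y ~ group, family = fam,
                                           offset = off)))
    if (is.null(fit) || !fit$converged) return(c(NA_real_, 1))
    b <- coef(fit)[2]
    se <- sqrt(diag(vcov(fit)))[2]
    if (!is.finite(b) || !is.finite(se) || se <= 0) return(c(NA_real_, 1))
    c(b / log(2), 2 * pnorm(-abs(b / se)))
  }
  stats <- t(vapply(seq_len(nrow(cm$counts)),
                    function(i) fit_one(cm$counts[i, ], disp[i]),
                    numeric(2)))
  padj <- p.adjust(stats[, 2], method = "BH")
  res <- data.table(chrom = as.character(seqnames(features)),
                    start = start(features) - 1L, end = end(features),
                    base_mean = rowMeans(z),
                    log2fc = stats[, 1], p_value = stats[, 2],
                    p_adj = padj, significant = padj < alpha_adj)
  sig <- features[res$significant]
  if (length(sig)) mcols(sig)$log2fc <- res$log2fc[res$significant]
  list(results = res, significant = sig, features = features,
       size_factors = sf)
}

#' Consensus of the window and peak routes
#'
#' Retains window-route regions that overlap (>= 1 bp) a peak-route
#' differential feature; by default the two routes must also agree on the
#' direction of change.
#'
#' @param window_regions `GRanges` from [merge_significant_bins()] (with
#'   `log2fc`).
#' @param peak_regions `GRanges` of significant peak features (with
#'   `log2fc`).
#' @param require_direction_agreement Drop regions where the overlapping
#'   feature's fold change has the opposite sign (default `TRUE`).
#' @return `GRanges` of consensus regions with `log2fc` (window route) and
#'   `peak_log2fc` metadata.
#' @export
consensus_regions <- function(window_regions, peak_regions,
                              require_direction_agreement = TRUE) {
  if (length(window_regions) == 0L || length(peak_regions) == 0L)
    return(window_regions[0])
  hits <- findOverlaps(window_regions, peak_regions, ignore.strand = TRUE)
  if (length(hits) == 0L) return(window_regions[0])
  wl <- mcols(window_regions)$log2fc[queryHits(hits)]
  pl <- mcols(peak_regions)$log2fc[subjectHits(hits)]
  ok <- if (require_direction_agreement) sign(wl) == sign(pl) else
    rep(TRUE, length(hits))
  keep_q <- unique(queryHits(hits)[ok])
  out <- window_regions[keep_q]
  first <- match(keep_q, queryHits(hits)[ok])
  mcols(out)$peak_log2fc <- pl[ok][first]
  out
}

#' Direction summary of consensus regions
#'
#' @param consensus `GRanges` with a `log2fc` metadata column.
#' @return A list: `n`, `induced_fraction` (log2fc > 0),
#'   `repressed_fraction`, and the signal `table` (`data.table` of region
#'   coordinates, fold changes and direction labels) ready for boxplots.
#' @export
direction_summary <- function(consensus) {
  if (length(consensus) == 0L)
    return(list(n = 0L, induced_fraction = NA_real_,
                repressed_fraction = NA_real_, table = data.table()))
  lfc <- mcols(consensus)$log2fc
  tab <- data.table(chrom = as.character(seqnames(consensus)),
                    start = start(consensus) - 1L, end = end(consensus),
                    log2fc = lfc,
                    direction = ifelse(lfc > 0, "induced", "repressed"))
  list(n = length(consensus),
       induced_fraction = mean(lfc > 0),
       repressed_fraction = mean(lfc < 0),
       table = tab)
}
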