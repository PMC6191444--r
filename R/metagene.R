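#' Meta-gene matrices
#'
#' Signal around genes rescaled to a common coordinate: fixed-width flank
#' bins upstream of the TSS and downstream of the TES, and a fixed number of
#' variable-width bins across the gene body. Rows of the matrix are genes in
#' 5'-to-3' orientation (minus-strand rows are reversed relative to the
#' genome), columns are position bins.
#'
#' @name metagene
NULL

# mean of a piecewise-constant per-base signal over fractional slices.
# v: per-base values of the gene body; breaks: B+1 fractional positions in
# [0, length(v)]. Exact length-weighted averaging via the cumulative sum, so
# the slice means conserve the overall body mean to floating-point accuracy.
fractional_bin_means <- function(v, n_bins) {
  L <- length(v)
  cs <- c(0, cumsum(v))
  bnd <- seq(0, L, length.out = n_bins + 1L)
  ingral <- function(x) {            # integral of the step function on [0, x]
    f <- floor(x)
    frac <- x - f
    cs[f + 1L] + ifelse(f < L, frac * v[pmin(f + 1L, L)], 0)
  }
  I <- ingral(bnd)
  diff(I) / diff(bnd)
}

#' Build a meta-gene matrix
#'
#' Flank columns are mean signal over consecutive `flank_bin`-bp bins across
#' `flank_bp` upstream of the TSS and downstream of the TES; body columns
#' are mean signal over `body_bins` equal-fraction slices of the gene body,
#' with fractional base pairs handled by length-weighted averaging so that
#' the mean over body bins equals the gene-body mean exactly. Rows of
#' minus-strand genes are reversed into 5'-to-3' orientation.
#'
#' Genes shorter than `body_bins` bp, or whose flanks extend past a
#' chromosome end, are excluded (recorded in the `excluded` attribute).
#'
#' @param track A `coverage_track`.
#' @param genes Stranded `GRanges` of gene bodies (named).
#' @param flank_bp Flank width, bp (default 6000; divisible by `flank_bin`).
#' @param flank_bin Flank bin width, bp (default 50).
#' @param body_bins Number of gene-body bins (default 120).
#' @return A `metagene_matrix`: list with `values` (genes x bins matrix),
#'   `strand`, `flank_bins`, `body_bins`, `cluster` (NULL until clustered).
#' @export
build_metagene <- function(track, genes, flank_bp = 6000L, flank_bin = 50L,
                           body_bins = 120L) {
  stopifnot(inherits(track, "coverage_track"), flank_bp %% flank_bin == 0)
  asm <- track$assembly
  n_fb <- flank_bp %/% flank_bin
  lens <- asm$chrom_lengths[as.character(seqnames(genes))]
  eligible <- width(genes) >= body_bins &
    (start(genes) - 1L - flank_bp) >= 0 &
    (end(genes) + flank_bp) <= lens &
    as.character(strand(genes)) %in% c("+", "-")
  if (!any(eligible)) stop("no eligible genes")
  excluded <- if (!is.null(names(genes))) names(genes)[!eligible] else
    which(!eligible)
  g <- genes[eligible]
  rows <- matrix(0, nrow = length(g), ncol = 2L * n_fb + body_bins)
  for (i in seq_along(g)) {
    ch <- as.character(seqnames(g))[i]
    s1 <- start(g)[i]; e1 <- end(g)[i]
    win <- as.numeric(window(track$cov[[ch]], s1 - flank_bp, e1 + flank_bp))
    left <- win[seq_len(flank_bp)]
    body <- win[(flank_bp + 1L):(flank_bp + e1 - s1 + 1L)]
    right <- win[(length(win) - flank_bp + 1L):length(win)]
    row <- c(colMeans(matrix(left, nrow = flank_bin)),
             fractional_bin_means(body, body_bins),
             colMeans(matrix(right, nrow = flank_bin)))
    if (as.character(strand(g))[i] == "-") row <- rev(row)
    rows[i, ] <- row
  }
  rownames(rows) <- if (!is.null(names(g))) names(g) else
    paste0("gene", seq_along(g))
  colnames(rows) <- c(paste0("up", seq_len(n_fb)),
                      paste0("body", seq_len(body_bins)),
                      paste0("down", seq_len(n_fb)))
  structure(list(values = rows,
                 strand = as.character(strand(g)),
                 flank_bins = n_fb, body_bins = body_bins,
                 flank_bp = flank_bp, flank_bin = flank_bin,
                 cluster = NULL, excluded = excluded),
            class = "metagene_matrix")
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat(sprintf("metagene_matrix: %d genes x (%d + %d + %d) bins%s\n",
              nrow(x$values), x$flank_bins, x$body_bins, x$flank_bins,
              if (is.null(x$cluster)) "" else
                sprintf(", %d clusters", length(unique(x$cluster)))))
  invisible(x)
}

# column indices of the gene-body bins
body_columns <- function(m) (m$flank_bins + 1L):(m$flank_bins + m$body_bins)

#' Cluster meta-gene profiles
#'
#' k-means on row-standardized profiles (each gene's profile centered and
#' scaled to unit variance) with a fixed seed and multiple restarts. Cluster
#' labels are renumbered by decreasing mean gene-body signal so that cluster
#' 1 is always the body-signal-richest group (the analogue of the
#' H3K36me3-enriched gene cluster).
#'
#' @param m A `metagene_matrix`.
#' @param k Number of clusters (default 3).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Random restarts (default 10).
#' @return `m` with `cluster` filled in (integer labels 1..k).
#' @export
cluster_metagene <- function(m, k = 3L, seed = 1L, nstart = 10L) {
  stopifnot(inherits(m, "metagene_matrix"), k >= 2,
            nrow(m$values) >= k)
  z <- m$values
  mu <- rowMeans(z)
  s <- apply(z, 1, sd)
  degen <- s == 0
  if (any(degen)) {
    warning(sum(degen), " gene(s) with constant profile; standardized to 0")
    s[degen] <- 1
  }
  z <- (z - mu) / s
  if (k == nrow(z)) {
    # trivial limit: every gene its own cluster
    clusters <- seq_len(k)
  } else {
    set.seed(seed)
    km <- suppressWarnings(kmeans(z, centers = k, nstart = nstart,
                                  iter.max = 100L))
    clusters <- km$cluster
  }
  body_mean <- tapply(rowMeans(m$values[, body_columns(m), drop = FALSE]),
                      clusters, mean)
  ord <- order(body_mean, decreasing = TRUE)
  relabel <- integer(k)
  relabel[as.integer(names(body_mean))[ord]] <- seq_len(k)
  m$cluster <- relabel[clusters]
  names(m$cluster) <- rownames(m$values)
  m
}

#' Compare 3' gene-body signal with the downstream region
#'
#' For each gene, computes the mean coverage over a window at the 3' end of
#' the gene body and over an equal-width window immediately downstream of
#' the TES (strand-aware), then tests the paired difference. Both the paired
#' Wilcoxon signed-rank p-value and the unpaired Wilcoxon rank-sum p-value
#' are reported.
#'
#' @param track A `coverage_track`.
#' @param genes Stranded `GRanges`.
#' @param window_bp Window width in bp; `NULL` (default) uses 25% of each
#'   gene's body length.
#' @param alternative Test alternative (`"two.sided"`, `"greater"`,
#'   `"less"`) for body vs downstream; default two-sided.
#' @return A list: `data` (`data.table` of per-gene paired means),
#'   `p_signed_rank`, `p_rank_sum`, `statistic_signed_rank`,
#'   `statistic_rank_sum`.
#' @export
compare_body_vs_downstream <- function(track, genes, window_bp = NULL,
                                       alternative = "two.sided") {
  asm <- track$assembly
  lens <- asm$chrom_lengths[as.character(seqnames(genes))]
  str <- as.character(strand(genes))
  w <- if (is.null(window_bp)) pmax(1L, round(0.25 * width(genes))) else
    rep(as.integer(window_bp), length(genes))
  ok <- str %in% c("+", "-") & w <= width(genes) &
    ifelse(str == "+", end(genes) + w <= lens, start(genes) - 1L - w >= 0)
  if (!any(ok)) stop("no gene admits the requested window")
  g <- genes[ok]; w <- w[ok]; str <- str[ok]
  n <- length(g)
  body_mean <- numeric(n); down_mean <- numeric(n)
  for (i in seq_len(n)) {
    ch <- as.character(seqnames(g))[i]
    r <- track$cov[[ch]]
    if (str[i] == "+") {
      body_mean[i] <- mean(as.numeric(window(r, end(g)[i] - w[i] + 1L,
                                             end(g)[i])))
      down_mean[i] <- mean(as.numeric(window(r, end(g)[i] + 1L,
                                             end(g)[i] + w[i])))
    } else {
      body_mean[i] <- mean(as.numeric(window(r, start(g)[i],
                                             start(g)[i] + w[i] - 1L)))
      down_mean[i] <- mean(as.numeric(window(r, start(g)[i] - w[i],
                                             start(g)[i] - 1L)))
    }
  }
  dat <- data.table(gene = if (!is.null(names(g))) names(g) else seq_len(n),
                    body_mean = body_mean, down_mean = down_mean,
                    window_bp = w)
  if (all(body_mean == down_mean)) {
    ws <- list(p.value = 1, statistic = NA_real_)
    wr <- suppressWarnings(wilcox.test(body_mean, down_mean,
                                       alternative = alternative))
  } else {
    ws <- suppressWarnings(wilcox.test(body_mean, down_mean, paired = TRUE,
                                       alternative = alternative))
    wr <- suppressWarnings(wilcox.test(body_mean, down_mean,
                                       alternative = alternative))
  }
  list(data = dat,
       p_signed_rank = ws$p.value,
       p_rank_sum = wr$p.value,
       statistic_signed_rank = unname(ws$statistic),
       statistic_rank_sum = unname(wr$statistic))
}
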