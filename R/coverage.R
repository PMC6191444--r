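#' Coverage tracks and count matrices
#'
#' A coverage track is a run-length encoded per-base signal over the whole
#' assembly (an `RleList`), together with the normalization scale that has
#' been applied and the fragment length used for read extension. Count
#' matrices pair an interval set of regions with per-sample integer read
#' counts and, once computed, per-sample size factors.
#'
#' @name coverage
NULL

# read table -> extended-fragment GRanges (trimmed at chromosome ends).
# `pos` is the 0-based 5' end: plus-strand fragments cover [pos, pos+L),
# minus-strand fragments cover (pos-L, pos] in 0-based closed terms.
reads_to_fragments <- function(reads, assembly, fragment_length) {
  stopifnot(fragment_length >= 1)
  if (!all(c("chrom", "pos", "strand") %in% names(reads)))
    stop("read table needs columns chrom, pos, strand")
  bad <- !(reads$chrom %in% assembly$chrom_names)
  if (any(bad))
    stop("reads on chromosomes not in assembly: ",
         paste(unique(reads$chrom[bad]), collapse = ", "))
  plus <- reads$strand != "-"
  s0 <- ifelse(plus, reads$pos, reads$pos - fragment_length + 1)
  # fragments may poke past chromosome ends before trimming; silence the
  # out-of-bound warning, the clip is intended and accounted for
  gr <- suppressWarnings(
    GRanges(factor(reads$chrom, levels = assembly$chrom_names),
            IRanges(start = s0 + 1, width = fragment_length),
            strand = reads$strand,
            seqinfo = as_seqinfo(assembly)))
  suppressWarnings(trim(gr))
}

#' Extend reads and pile up coverage
#'
#' Each read is extended to the expected fragment size (default 150 bp) from
#' its 5' end in the read direction and contributes +1 over the extended
#' fragment; fragments are clipped at chromosome ends (clipped bases counted
#' in the `clipped` attribute, not fatal).
#'
#' @param reads A read-start table (`chrom`, `pos` 0-based, `strand`).
#' @param assembly A [genome_assembly].
#' @param fragment_length Extension length in bp, default 150.
#' @return A `coverage_track`: list with `cov` (`RleList`), `assembly`,
#'   `scale` (1 for raw pileup), `fragment_length`, `n_reads`, `clipped`.
#' @export
extend_and_pileup <- function(reads, assembly, fragment_length = 150L) {
  frags <- reads_to_fragments(reads, assembly, fragment_length)
  clipped <- nrow(reads) * fragment_length - sum(as.numeric(width(frags)))
  cov <- coverage(frags)
  structure(list(cov = cov, assembly = assembly, scale = 1,
                 fragment_length = fragment_length,
                 n_reads = nrow(reads), clipped = clipped),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d reads, fragment %d bp, scale %.4g, mean %.4g\n",
              x$n_reads, x$fragment_length, x$scale, track_mean(x)))
  invisible(x)
}

#' Genome-wide mean per-base value of a track
#' @param track A `coverage_track`.
#' @return Numeric scalar.
#' @export
track_mean <- function(track) {
  sum(vapply(track$cov, function(r) sum(as.numeric(runValue(r)) *
                                          as.numeric(runLength(r))), 0)) /
    total_size(track$assembly)
}

#' Normalize a track to 1x sequencing depth
#'
#' Rescales values so the genome-wide mean per-base coverage is exactly 1
#' (the "normalize to 1x depth" convention for comparing tracks of different
#' library sizes).
#'
#' @param track A `coverage_track` with positive total mass.
#' @return The rescaled `coverage_track` (`scale` records the multiplier).
#' @export
normalize_1x <- function(track) {
  m <- track_mean(track)
  if (m <= 0) stop("cannot normalize a zero-mass track")
  track$cov <- track$cov * (1 / m)
  track$scale <- track$scale / m
  track
}

#' Write a coverage track as bedGraph
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$cov), function(ch) {
    r <- track$cov[[ch]]
    ends <- cumsum(runLength(r))
    data.table(chrom = ch, start = c(0, head(ends, -1L)), end = ends,
               value = signif(as.numeric(runValue(r)), 6))
  })
  dt <- rbindlist(rows)
  dt <- dt[dt$value != 0, ]
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# extended-fragment midpoints as width-1 GRanges
fragment_midpoints <- function(reads, assembly, fragment_length) {
  frags <- reads_to_fragments(reads, assembly, fragment_length)
  mid <- floor((start(frags) - 1 + end(frags)) / 2)   # 0-based midpoint
  GRanges(seqnames(frags), IRanges(start = mid + 1, width = 1L),
          seqinfo = as_seqinfo(assembly))
}

#' Count reads in regions
#'
#' A read is counted in a region if the midpoint of its extended fragment
#' falls inside the region (half-open at the region end), so each read is
#' counted at most once even across adjacent regions.
#'
#' @param reads_list Named list of read-start tables, one per sample.
#' @param regions Non-overlapping `GRanges` (merge first if needed).
#' @param assembly A [genome_assembly].
#' @param fragment_length Extension length in bp, default 150.
#' @param allow_overlaps Permit overlapping query regions (each read may
#'   then be counted in several regions); default `FALSE`, which demands a
#'   disjoint region set as required for normalization-grade count matrices.
#' @return A `count_matrix`: list with `regions`, `counts` (integer matrix
#'   regions x samples), `samples`, `size_factors` (NULL until computed).
#' @export
count_reads_in_regions <- function(reads_list, regions, assembly,
                                   fragment_length = 150L,
                                   allow_overlaps = FALSE) {
  if (is.data.frame(reads_list)) reads_list <- list(sample1 = reads_list)
  if (!allow_overlaps &&
      any(countOverlaps(regions, regions, ignore.strand = TRUE) > 1L))
    stop("regions overlap; merge them first (see merge_overlapping)")
  if (is.null(names(reads_list)))
    names(reads_list) <- paste0("sample", seq_along(reads_list))
  counts <- vapply(reads_list, function(rd) {
    mids <- fragment_midpoints(rd, assembly, fragment_length)
    countOverlaps(regions, mids, ignore.strand = TRUE)
  }, integer(length(regions)))
  counts <- matrix(as.integer(counts), nrow = length(regions),
                   dimnames = list(NULL, names(reads_list)))
  structure(list(regions = regions, counts = counts,
                 samples = names(reads_list), size_factors = NULL),
            class = "count_matrix")
}

#' Median-of-ratios size factors
#'
#' The standard count-normalization estimator: for each sample, the size
#' factor is the median over regions (restricted to regions with positive
#' counts in every sample) of the ratio between that sample's count and the
#' across-sample geometric mean. Normalized counts are raw counts divided by
#' the size factor.
#'
#' @param m A `count_matrix` or a plain integer matrix (regions x samples).
#' @param pseudocount Added to all counts before estimation (default 0; use
#'   a small value when no region has all-positive counts).
#' @return For a matrix input, the numeric vector of size factors. For a
#'   `count_matrix`, the same object with `size_factors` filled in.
#' @export
median_of_ratios_size_factors <- function(m, pseudocount = 0) {
  if (inherits(m, "count_matrix")) {
    m$size_factors <- median_of_ratios_size_factors(m$counts, pseudocount)
    return(m)
  }
  counts <- m + pseudocount
  if (ncol(counts) < 2) stop("need at least 2 samples")
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok))
    stop("no region with all-positive counts; consider a pseudocount")
  lg <- log(counts[ok, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, median)
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("degenerate size factors")
  sf
}

#' Normalized counts of a count matrix
#' @param m A `count_matrix` with size factors computed.
#' @return Numeric matrix of counts divided by their sample's size factor.
#' @export
normalized_counts <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(m$size_factors))
    m <- median_of_ratios_size_factors(m)
  sweep(m$counts, 2, m$size_factors, "/")
}

#' Write a count matrix as TSV
#'
#' BED-like first three columns (0-based half-open), then one column per
#' sample.
#' @param m A `count_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(m, path) {
  dt <- data.table(chrom = as.character(seqnames(m$regions)),
                   start = start(m$regions) - 1L,
                   end = end(m$regions))
  dt <- cbind(dt, as.data.table(m$counts))
  fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
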