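#' Interval sets
#'
#' Peaks, chromatin-state segments, gene models and called regions are all
#' represented as `GRanges` tied to a [genome_assembly] through their
#' `Seqinfo`. Coordinates are 0-based half-open at the file boundary (BED
#' native) and 1-based closed inside `GRanges`, the conversion happening
#' exclusively in [read_bed()] and [write_bed()].
#'
#' @name intervals
NULL

#' Build an interval set from vectors
#'
#' Convenience constructor used throughout the package and its tests.
#' `start`/`end` are 0-based half-open, as in a BED file.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors; 0-based half-open (`start < end`).
#' @param assembly A [genome_assembly]; intervals must lie within it.
#' @param strand Strand per interval (`"+"`, `"-"` or `"*"`); default `"*"`.
#' @param score Optional numeric score per interval.
#' @param label Optional name/label per interval.
#' @return A `GRanges` with the assembly's `Seqinfo`.
#' @export
interval_set <- function(chrom, start, end, assembly, strand = "*",
                         score = NULL, label = NULL) {
  stopifnot(inherits(assembly, "genome_assembly"))
  chrom <- as.character(chrom)
  bad <- !(chrom %in% assembly$chrom_names)
  if (any(bad))
    stop("chromosome(s) not in assembly: ",
         paste(unique(chrom[bad]), collapse = ", "))
  if (any(start < 0) || any(end <= start))
    stop("intervals must satisfy 0 <= start < end")
  if (any(end > assembly$chrom_lengths[chrom]))
    stop("interval end beyond chromosome length")
  gr <- GRanges(seqnames = factor(chrom, levels = assembly$chrom_names),
                ranges = IRanges(start = start + 1L, end = end),
                strand = strand,
                seqinfo = as_seqinfo(assembly))
  if (!is.null(score)) mcols(gr)$score <- score
  if (!is.null(label)) names(gr) <- label
  gr
}

#' Read a BED or bedGraph file
#'
#' Accepts BED3/BED6/BED12 and 4-column bedGraph. Coordinates in the file are
#' 0-based half-open and are converted to `GRanges` convention. Records on
#' chromosomes absent from `assembly`, or with `start >= end`, raise an error
#' naming the offending line.
#'
#' @param path Path to the file. Lines starting with `#`, `track` or
#'   `browser` are skipped.
#' @param assembly A [genome_assembly].
#' @param format `"auto"` (default), `"bed"` or `"bedgraph"`. Under `"auto"`,
#'   a 4-column file with a numeric fourth column is read as bedGraph (score),
#'   otherwise as BED (name).
#' @return A `GRanges`; BED6+ name, score and strand are carried as `names`,
#'   `score` and strand. bedGraph values land in `score`.
#' @export
read_bed <- function(path, assembly, format = c("auto", "bed", "bedgraph")) {
  format <- match.arg(format)
  stopifnot(inherits(assembly, "genome_assembly"))
  raw <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- seq_along(raw)[keep]
  if (length(lines) == 0L) {
    return(GRanges(seqinfo = as_seqinfo(assembly)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("parse error at line %d: fewer than 3 fields",
                 lineno[which(nf < 3L)[1]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop(sprintf("parse error at line %d: non-numeric coordinates",
                 lineno[which(bad)[1]]))
  bad <- start < 0 | end <= start
  if (any(bad))
    stop(sprintf("parse error at line %d: requires 0 <= start < end",
                 lineno[which(bad)[1]]))
  bad <- !(chrom %in% assembly$chrom_names)
  if (any(bad))
    stop(sprintf("line %d: chromosome '%s' not in assembly",
                 lineno[which(bad)[1]], chrom[which(bad)[1]]))
  bad <- end > assembly$chrom_lengths[chrom]
  if (any(bad))
    stop(sprintf("line %d: interval end %s beyond chromosome length",
                 lineno[which(bad)[1]], end[which(bad)[1]]))

  col4 <- if (min(nf) >= 4L) vapply(fields, `[[`, "", 4L) else NULL
  is_bedgraph <- switch(format,
    bedgraph = TRUE,
    bed = FALSE,
    auto = !is.null(col4) && max(nf) == 4L &&
      !anyNA(suppressWarnings(as.numeric(col4)))
  )
  label <- NULL; score <- NULL; strand <- "*"
  if (is_bedgraph) {
    if (is.null(col4)) stop("bedGraph requires 4 columns")
    score <- as.numeric(col4)
  } else {
    if (!is.null(col4)) label <- col4
    if (min(nf) >= 5L) {
      s5 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
      if (!anyNA(s5)) score <- s5
    }
    if (min(nf) >= 6L) {
      strand <- vapply(fields, `[[`, "", 6L)
      strand[!strand %in% c("+", "-")] <- "*"
    }
  }
  interval_set(chrom, start, end, assembly, strand = strand,
               score = score, label = label)
}

#' Write a BED6 (or bedGraph) file
#'
#' Writes 0-based half-open coordinates. BED6 output round-trips through
#' [read_bed()] identically; scores are written with 6 significant digits.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param format `"bed"` (default) or `"bedgraph"` (chrom, start, end, score).
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path, format = c("bed", "bedgraph")) {
  format <- match.arg(format)
  if (length(gr) == 0L) {
    writeLines("# empty interval set", path)
    return(invisible(path))
  }
  s0 <- start(gr) - 1L
  e0 <- end(gr)
  score <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else rep(0, length(gr))
  if (format == "bedgraph") {
    dt <- data.table(as.character(seqnames(gr)), s0, e0,
                     signif(score, 6))
  } else {
    nm <- if (!is.null(names(gr))) names(gr) else paste0("iv", seq_along(gr))
    str <- as.character(strand(gr))
    str[str == "*"] <- "."
    dt <- data.table(as.character(seqnames(gr)), s0, e0, nm,
                     signif(score, 6), str)
  }
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Merge overlapping intervals
#'
#' Overlapping intervals are collapsed into single features spanning the
#' union of the merged inputs. Half-open semantics: at `gap = 0` book-ended
#' intervals (e.g. `[0,100)` and `[100,200)`) are *not* merged; with
#' `gap = g > 0`, intervals separated by fewer than `g` bp are merged.
#' Strand is ignored (output is unstranded), matching the strand-blind
#' overlap arithmetic used for peak sets.
#'
#' @param gr A `GRanges`.
#' @param gap Non-negative merge slack in bp; default 0.
#' @return An unstranded, sorted `GRanges` of disjoint intervals.
#' @export
merge_overlapping <- function(gr, gap = 0) {
  stopifnot(gap >= 0)
  reduce(gr, min.gapwidth = gap, ignore.strand = TRUE)
}

#' Total width of the union of an interval set
#' @param gr A `GRanges`.
#' @return Total bp covered (overlaps counted once).
#' @export
total_width <- function(gr) {
  sum(as.numeric(width(merge_overlapping(gr))))
}

#' Overlap width of two interval sets
#'
#' Total base pairs covered by both sets; each side is internally unioned
#' first, so the result is symmetric and never exceeds either set's
#' [total_width()]. Strand-blind.
#'
#' @param a,b `GRanges` on the same assembly (same `Seqinfo`).
#' @return Numeric scalar, bp of overlap.
#' @export
overlap_width <- function(a, b) {
  sia <- seqinfo(a); sib <- seqinfo(b)
  if (!identical(seqlevels(sia), seqlevels(sib)) ||
      !identical(seqlengths(sia), seqlengths(sib)))
    stop("interval sets are on different assemblies")
  ov <- GenomicRanges::intersect(merge_overlapping(a), merge_overlapping(b),
                                 ignore.strand = TRUE)
  sum(as.numeric(width(ov)))
}
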