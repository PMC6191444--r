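#' Chromatin-state overlap enrichment
#'
#' For a peak set and a chromatin-state segmentation, computes per state the
#' observed overlap fraction O (bp of peak territory falling in the state,
#' divided by total peak territory), the expected fraction E (the state's
#' share of the total genome size), and the log2 observed/expected ratio.
#' Peaks are unioned first so O is a proper fraction of peak territory.
#'
#' @param peaks `GRanges` of peaks (non-empty).
#' @param seg `GRanges` segmentation with an integer/character `state`
#'   metadata column; segments must be non-overlapping.
#' @param assembly A [genome_assembly] (supplies the total genome size).
#' @param union Union peaks before overlap (default `TRUE`; `FALSE` uses the
#'   raw peak list's summed widths for sensitivity analysis).
#' @return A `data.table` with columns `state`, `state_width`, `observed`,
#'   `expected`, `log2_ratio` (`-Inf` with `depleted_to_zero = TRUE` for
#'   states with no peak overlap) — one row per state present in the
#'   segmentation, sorted by state.
#' @export
state_enrichment <- function(peaks, seg, assembly, union = TRUE) {
  if (length(peaks) == 0L) stop("empty peak set")
  if (is.null(mcols(seg)$state)) stop("segmentation lacks a 'state' column")
  if (any(countOverlaps(seg, seg, ignore.strand = TRUE) > 1L))
    stop("state segments overlap")
  pk <- if (union) merge_overlapping(peaks) else peaks
  denom <- if (union) sum(as.numeric(width(pk))) else
    sum(as.numeric(width(peaks)))
  states <- sort(unique(mcols(seg)$state))
  res <- lapply(states, function(s) {
    seg_s <- seg[mcols(seg)$state == s]
    ws <- sum(as.numeric(width(seg_s)))
    ov <- overlap_width(pk, seg_s)
    O <- ov / denom
    E <- ws / total_size(assembly)
    data.table(state = s, state_width = ws, observed = O, expected = E,
               log2_ratio = log2(O / E),
               depleted_to_zero = O == 0)
  })
  rbindlist(res)
}
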