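#' Histone-PTM isoform quantification
#'
#' Operates on exported MS1 chromatogram-area tables (long format, one row
#' per peptide modification isoform per sample) with the column schema
#' `sample_id`, `histone`, `peptide`, `modification`, `isobaric_group`,
#' `ms1_area`, `frag1`..`frag3`. Coeluting isobaric isoforms share one MS1
#' area within an `isobaric_group` and are apportioned using their unique
#' MS2 fragment integrals before percentages are computed.
#'
#' @name ptm_quant
NULL

#' Resolve isobaric groups into effective areas
#'
#' Within each isobaric group (members sharing one MS1 area), each member's
#' weight is the arithmetic mean of its MS2 fragment integrals (missing
#' fragments are averaged over the present ones); the shared MS1 area is
#' split proportionally to the weights, so the effective areas sum exactly
#' to the shared area. If all members' weights are zero the area is split
#' equally, with a warning. Rows outside any group keep their own MS1 area.
#'
#' @param tab A peptide isoform `data.table`/data.frame (see
#'   [ptm_quant]).
#' @param weight_mean `"arithmetic"` (default) or `"geometric"` mean of the
#'   fragment integrals.
#' @return The table with an added `effective_area` column.
#' @export
resolve_isobaric <- function(tab, weight_mean = c("arithmetic", "geometric")) {
  weight_mean <- match.arg(weight_mean)
  tab <- as.data.table(tab)
  fr <- as.matrix(tab[, c("frag1", "frag2", "frag3")])
  w <- if (weight_mean == "arithmetic") rowMeans(fr, na.rm = TRUE) else
    exp(rowMeans(log(fr), na.rm = TRUE))
  w[is.nan(w)] <- NA_real_
  tab[, effective_area := ms1_area]
  grp_rows <- !is.na(tab$isobaric_group)
  if (any(grp_rows)) {
    key <- paste(tab$sample_id, tab$isobaric_group)[grp_rows]
    idx <- split(which(grp_rows), key)
    for (rows in idx) {
      if (length(rows) < 2)
        stop("isobaric group with fewer than 2 members")
      ms1 <- tab$ms1_area[rows]
      if (length(unique(ms1)) != 1L)
        stop("isobaric group members must share one ms1_area")
      wg <- w[rows]
      wg[is.na(wg)] <- 0
      if (sum(wg) == 0) {
        warning("all fragment weights zero in an isobaric group; ",
                "splitting the MS1 area equally")
        wg <- rep(1, length(rows))
      }
      eff <- ms1[1] * wg / sum(wg)
      # pin the largest member so the split sums to the shared area exactly
      i_max <- which.max(wg)
      eff[i_max] <- ms1[1] - sum(eff[-i_max])
      data.table::set(tab, rows, "effective_area", eff)
    }
  }
  tab[]
}

#' Isoform percentages per peptide and sample
#'
#' The percentage of each modification isoform is its effective area as a
#' share of the summed effective areas of all isoforms of that peptide in
#' that sample. Isobaric groups must be resolved first ([resolve_isobaric()]
#' is applied automatically if the `effective_area` column is absent).
#'
#' @param tab A peptide isoform table.
#' @return `data.table` with columns `sample_id`, `histone`, `peptide`,
#'   `modification`, `percentage` and `flagged` (TRUE when the peptide's
#'   total area was zero, leaving the percentage undefined).
#' @export
isoform_percentages <- function(tab) {
  tab <- as.data.table(tab)
  if (!"effective_area" %in% names(tab)) tab <- resolve_isobaric(tab)
  out <- tab[, {
    tot <- sum(effective_area)
    .(modification = modification,
      percentage = if (tot > 0) 100 * effective_area / tot else
        rep(NA_real_, .N),
      flagged = rep(tot <= 0, .N))
  }, by = .(sample_id, histone, peptide)]
  out[]
}

#' Normalize IP percentages to input percentages
#'
#' @param ip,input Percentage tables from [isoform_percentages()] (matched
#'   on `sample_id` optionally, and on `peptide` + `modification`).
#' @param by_sample Match samples one-to-one by `sample_id` (default
#'   `FALSE`: `input` is a single reference sample).
#' @param mode `"ratio"` (default, IP percentage / input percentage) or
#'   `"difference"`.
#' @return `data.table` with `peptide`, `modification`, IP and input
#'   percentages, `value` (ratio or difference) and `flagged` (input
#'   percentage zero or key absent).
#' @export
normalize_to_input <- function(ip, input, by_sample = FALSE,
                               mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  ip <- as.data.table(ip); input <- as.data.table(input)
  keys <- c(if (by_sample) "sample_id", "peptide", "modification")
  inp <- input[, c(keys, "percentage"), with = FALSE]
  data.table::setnames(inp, "percentage", "input_percentage")
  out <- merge(ip, inp, by = keys, all.x = TRUE, sort = FALSE)
  if (mode == "ratio") {
    out[, value := ifelse(is.na(input_percentage) | input_percentage == 0,
                          NA_real_, percentage / input_percentage)]
  } else {
    out[, value := percentage - input_percentage]
  }
  out[, flagged := is.na(value)]
  out[]
}

utils::globalVariables(c("input_percentage", "value", "flagged"))
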