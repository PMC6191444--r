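#' qPCR quantification
#'
#' Percent-input analysis for ChIP-qPCR and relative expression by the
#' 2^-ddCt method, with the SEM-based error-bar range. Input is a long Ct
#' table with columns `target`, `condition`, `replicate`, `role` (one of
#' `"IP"`, `"input"`, `"cDNA"`) and `ct`.
#'
#' @name qpcr
NULL

#' Percent input from ChIP-qPCR Ct values
#'
#' The input Ct is first adjusted for the input dilution:
#' `ct_adj = ct_input - log2(1 / input_fraction)`; percent input is then
#' `100 * 2^(ct_adj - ct_IP)`, computed per replicate (IP and input rows
#' paired by replicate index) and summarized as mean and SEM per target and
#' condition.
#'
#' @param tab Ct table (see [qpcr]); needs matched `IP` and `input` rows.
#' @param input_fraction Fraction of chromatin reserved as input, in (0, 1].
#' @return `data.table` per (target, condition): `n`, `percent_input`
#'   (mean), `sem`.
#' @export
percent_input <- function(tab, input_fraction) {
  stopifnot(input_fraction > 0, input_fraction <= 1)
  tab <- as.data.table(tab)
  ip <- tab[role == "IP", .(target, condition, replicate, ct_ip = ct)]
  inp <- tab[role == "input", .(target, condition, replicate, ct_in = ct)]
  m <- merge(ip, inp, by = c("target", "condition", "replicate"))
  if (nrow(m) == 0L) stop("no matched IP/input pairs")
  missing_ip <- nrow(ip) - nrow(m)
  if (missing_ip > 0 || nrow(inp) > nrow(m))
    stop("unmatched IP or input rows; check replicate pairing")
  m[, pct := 100 * 2^((ct_in - log2(1 / input_fraction)) - ct_ip)]
  out <- m[, .(n = .N, percent_input = mean(pct),
               sem = if (.N > 1) sd(pct) / sqrt(.N) else NA_real_),
           by = .(target, condition)]
  out[]
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, `dCt = ct_target - ct_reference` within the same
#' condition; `ddCt = dCt - mean(dCt of the calibrator condition)`. The fold
#' change is `2^-mean(ddCt)`, and the error-bar range is
#' `[2^(-ddCt - SEM), 2^(-ddCt + SEM)]`, where SEM is the standard error of
#' the replicate ddCt values — the upper bound comes from `+SEM` because the
#' fold is `2^-ddCt`.
#'
#' @param tab Ct table with `role == "cDNA"` rows.
#' @param reference_gene Housekeeping gene present in every condition.
#' @param calibrator_condition Condition used as the fold-change baseline.
#' @return `data.table` per (target, condition): `n`, `ddct` (mean), `sem`,
#'   `fold` (2^-ddct), `fold_lower`, `fold_upper` (NA with a warning when a
#'   condition has < 2 replicates).
#' @export
ddct_expression <- function(tab, reference_gene, calibrator_condition) {
  tab <- as.data.table(tab)
  cdna <- tab[role == "cDNA"]
  if (!reference_gene %in% cdna$target)
    stop("reference gene absent from the table")
  ref <- cdna[target == reference_gene,
              .(condition, replicate, ct_ref = ct)]
  tg <- cdna[target != reference_gene]
  m <- merge(tg, ref, by = c("condition", "replicate"))
  m[, dct := ct - ct_ref]
  cal <- m[condition == calibrator_condition,
           .(cal_dct = mean(dct)), by = target]
  if (nrow(cal) == 0L) stop("calibrator condition absent")
  m <- merge(m, cal, by = "target")
  m[, ddct := dct - cal_dct]
  out <- m[, .(n = .N, ddct = mean(ddct),
               sem = if (.N > 1) sd(ddct) / sqrt(.N) else NA_real_),
           by = .(target, condition)]
  if (anyNA(out$sem))
    warning("condition(s) with < 2 replicates: error range unavailable")
  out[, fold := 2^(-ddct)]
  out[, fold_lower := 2^(-ddct - sem)]
  out[, fold_upper := 2^(-ddct + sem)]
  out[]
}

utils::globalVariables(c("ct_ip", "ct_in", "pct", "ct_ref", "dct",
                         "cal_dct", "ddct", "fold", "fold_lower",
                         "fold_upper", "sem"))
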