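#' Mean meta-gene profile plot
#'
#' Mean signal per position bin, one line per cluster (or one overall line
#' when the matrix is unclustered).
#'
#' @param m A `metagene_matrix`.
#' @return A ggplot object.
#' @export
plot_metagene_profile <- function(m) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  cl <- if (is.null(m$cluster)) rep(1L, nrow(m$values)) else m$cluster
  prof <- lapply(sort(unique(cl)), function(k) {
    data.table(bin = seq_len(ncol(m$values)),
               mean_signal = colMeans(m$values[cl == k, , drop = FALSE]),
               cluster = factor(k))
  })
  dat <- rbindlist(prof)
  tss <- m$flank_bins + 0.5
  tes <- m$flank_bins + m$body_bins + 0.5
  ggplot2::ggplot(dat, ggplot2::aes(x = bin, y = mean_signal,
                                    colour = cluster)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(tss, tes), linetype = "dashed") +
    ggplot2::labs(x = "meta-gene bin (TSS/TES dashed)",
                  y = "mean normalized signal") +
    ggplot2::theme_minimal()
}

#' Chromatin-state enrichment bar plot
#'
#' log2 observed/expected ratio per state; `-Inf` values (states with no
#' peak overlap) are clipped to `floor`.
#'
#' @param se Result of [state_enrichment()].
#' @param floor Clip value for fully depleted states (default -6).
#' @return A ggplot object.
#' @export
plot_state_enrichment <- function(se, floor = -6) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  dat <- as.data.table(se)
  dat$log2_ratio <- pmax(dat$log2_ratio, floor)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(state), y = log2_ratio)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "chromatin state",
                  y = "log2(observed / expected overlap)") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("bin", "mean_signal", "cluster", "log2_ratio"))
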