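.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package", call. = FALSE)
}

#' Cost-effectiveness plane
#'
#' Scatter of the PSA draws on the incremental cost-effectiveness plane,
#' with the willingness-to-pay thresholds drawn as lines through the origin.
#'
#' @param samples a `psa_samples` data.frame from [sample_psa()].
#' @param thresholds willingness-to-pay lines to draw; defaults to the
#'   thresholds recorded on `samples`.
#' @return a ggplot object.
#' @export
plot_ce_plane <- function(samples, thresholds = attr(samples, "thresholds")) {
  .need_ggplot()
  thr <- data.frame(slope = thresholds,
                    label = format(thresholds, big.mark = ","))
  ggplot2::ggplot(as.data.frame(samples),
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_abline(data = thr,
                         ggplot2::aes(slope = .data$slope, intercept = 0,
                                      linetype = .data$label)) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost",
                  linetype = "Threshold / QALY") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' Probability that each strategy is cost-effective as a function of the
#' willingness-to-pay threshold.
#'
#' @param curve a `ceac_curve` data.frame from [ceac()].
#' @return a ggplot object.
#' @export
plot_ceac <- function(curve) {
  .need_ggplot()
  p_cols <- grep("^p_", names(curve), value = TRUE)
  long <- do.call(rbind, lapply(p_cols, function(cn) data.frame(
    threshold = curve$threshold, strategy = sub("^p_", "", cn),
    p = curve[[cn]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$p,
                                     colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay per QALY",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tornado diagram
#'
#' Horizontal bars of the ICER interval each parameter's one-way range
#' induces, widest spread on top, with the base-case ICER as a vertical
#' line.
#'
#' @param entries a `tornado_result` from [tornado()].
#' @param base_icer base-case ICER (vertical reference line); omitted when
#'   `NULL`.
#' @return a ggplot object.
#' @export
plot_tornado <- function(entries, base_icer = NULL) {
  .need_ggplot()
  df <- as.data.frame(entries)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  df$lo <- pmin(df$icer_at_low, df$icer_at_high)
  df$hi <- pmax(df$icer_at_low, df$icer_at_high)
  p <- ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::labs(x = "ICER per QALY", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(base_icer))
    p <- p + ggplot2::geom_vline(xintercept = base_icer, linetype = 2)
  p
}
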