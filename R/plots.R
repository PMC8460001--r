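#' Bland-Altman plot
#'
#' Difference-versus-mean plot for one method pair with the flagging
#' threshold drawn as dotted guide lines. Requires ggplot2.
#'
#' @param ba `data.frame` from [blandAltman()] (or the `bland_altman`
#'   element of [runPipeline()] filtered to one marker and pair).
#' @param threshold guide-line position (default 10 percentage points).
#' @return a ggplot object.
#' @export
plotBlandAltman <- function(ba, threshold = 10) {
    if (!requireNamespace("ggplot2", quietly = TRUE))
        stop("ggplot2 is required for plotting", call. = FALSE)
    ggplot2::ggplot(ba, ggplot2::aes(x = mean, y = difference,
                                     colour = flagged)) +
        ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
        ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                            linetype = "dotted", colour = "red") +
        ggplot2::geom_point(alpha = 0.8) +
        ggplot2::scale_colour_manual(
            values = c(`FALSE` = "black", `TRUE` = "red")) +
        ggplot2::labs(x = "Mean of methods (%)",
                      y = "Difference (%)") +
        ggplot2::theme_minimal()
}
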