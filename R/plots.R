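# Figures: metaplot (mean line with +/- SD band over flank/body/flank bins)
# and a chromatin-state percentage heatmap.

#' Plot a methylation metaplot
#'
#' Smoothed mean line with a +/- 1 SD ribbon over the
#' flank / body / flank bin axis; dashed lines distinguish insertion groups
#' from original elements.
#'
#' @param mp result of [metaplot()]
#' @param title plot title
#' @param linetype "solid" (original elements) or "dashed" (insertions)
#' @return a ggplot object
#' @export
plot_metaplot <- function(mp, title = "", linetype = "solid") {
  df <- data.frame(bin = seq_along(mp$mean), mean = mp$smoothed, sd = mp$sd)
  nf <- mp$n_flank
  marks <- c(1, nf + 0.5, nf + mp$body_bins + 0.5, length(mp$mean))
  ggplot2::ggplot(df, ggplot2::aes(x = bin, y = mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, mean - sd),
                                      ymax = pmin(1, mean + sd)),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(linetype = linetype, color = "steelblue4") +
    ggplot2::geom_vline(xintercept = marks[2:3], linetype = "dotted") +
    ggplot2::scale_x_continuous(
      breaks = marks, labels = c("-2 kb", "start", "end", "+2 kb")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = title, x = NULL, y = "methylated fraction") +
    ggplot2::theme_minimal()
}

#' Plot a chromatin-state percentage heatmap
#'
#' @param m matrix from [state_fraction_matrix()]
#' @return a ggplot object
#' @export
plot_state_heatmap <- function(m) {
  df <- data.frame(state = rep(rownames(m), ncol(m)),
                   set = rep(colnames(m), each = nrow(m)),
                   pct = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = set, y = state,
                                   fill = pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = "% of set") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
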