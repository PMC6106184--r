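#' Plot the randomization null of a K statistic
#'
#' Histogram of the randomized mean patch sizes with the observed mean
#' patch size `p_o` (solid) and the null mean `p_r` (dashed) marked; the
#' gap between the two lines is what K measures.
#'
#' @param object A [k_statistic()] computed with `keep_null = TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot k_statistic
#' @export
autoplot.k_statistic <- function(object, ...) {
  if (is.null(object$null_means))
    abort("no null_means kept; rerun k_statistic() with keep_null = TRUE")
  df <- tibble(mean_patch_size = object$null_means)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_patch_size)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$p_o, linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$p_r, linetype = "dashed") +
    ggplot2::labs(
      x = "mean patch size under randomization (segments)",
      y = "randomizations",
      title = sprintf("K = %.2f, p = %.3g", object$k, object$p_value),
      subtitle = sprintf(
        "observed p_o = %.2f (solid), null p_r = %.2f (dashed)",
        object$p_o, object$p_r)
    ) +
    ggplot2::theme_minimal()
}

#' Plot reef status along transects
#'
#' One horizontal band per tow, each 5-s segment coloured by its reef
#' status class; missing (unusable) segments are grey. Patches of presence
#' show up as contiguous coloured runs.
#'
#' @param data A scored segment table.
#' @return A ggplot object.
#' @export
plot_transect_status <- function(data) {
  if (!"status" %in% names(data))
    abort("segments must be scored first (see score_segments())")
  pal <- c(
    NoReef = "#f3f0e8", NotAReef = "#d9c9a3", Low = "#8fbf9f",
    Medium = "#3d9970", High = "#14594a", Missing = "grey75"
  )
  ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$segment_index, y = .data$tow_id,
                 fill = .data$status)
  ) +
    ggplot2::geom_tile(height = 0.8) +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::labs(x = "segment index (5-s bins)", y = NULL,
                  fill = "reef status") +
    ggplot2::theme_minimal()
}
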