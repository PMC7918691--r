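#' Line plot of one or more phenotypic signatures
#'
#' Draws Z-scores in signature order with the conventional significance
#' band at +/- 5 and block boundaries between the four
#' (channel x site) quadrants.
#'
#' @param signatures A single `phenotypic_signature` or a list of them.
#' @param threshold Significance band half-width.
#' @return A ggplot object.
#' @export
plot_signature <- function(signatures, threshold = 5) {
  if (inherits(signatures, "phenotypic_signature")) {
    signatures <- list(signatures)
  }
  df <- dplyr::bind_rows(lapply(signatures, function(s) {
    tibble::tibble(index = seq_along(s$values), z = unname(s$values),
                   line = paste0(s$line, " D", s$day))
  }))
  n_block <- nrow(df) / length(signatures) / 4
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$z,
                                   colour = .data$line)) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = n_block * (1:3) + 0.5,
                        colour = "grey85") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "parameter index (mito-distal | mito-proximal | lyso-distal | lyso-proximal)",
                  y = "Z-score", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Phenotypic-strength time courses
#'
#' @param strengths Tibble from [strength_curve()] or the `strengths` slot
#'   of a study report (columns `line`, `day`, `total`, `distal`,
#'   `proximal`).
#' @return A ggplot object: one panel per line, total/distal/proximal
#'   curves over days.
#' @export
plot_strength_curves <- function(strengths) {
  long <- tidyr::pivot_longer(strengths, c("total", "distal", "proximal"),
                              names_to = "subset", values_to = "strength")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$strength,
                                     colour = .data$subset)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~line) +
    ggplot2::labs(x = "day in culture", y = "sum of |Z|", colour = NULL) +
    ggplot2::theme_minimal()
}
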