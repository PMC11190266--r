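#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

#' Trace plot of a design run
#'
#' Total batch energy per sweep with the inverse-temperature ramp as a
#' secondary curve.
#'
#' @param object an `evh_design` from [design_batch()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.evh_design <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$sweep, y = .data$total_U)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "batch sweep", y = "total batch energy U",
                  title = "Annealed batch Gibbs design run",
                  subtitle = sprintf("beta %.2g to %.2g",
                                     min(object$trace$beta),
                                     max(object$trace$beta))) +
    ggplot2::theme_minimal()
}

#' Quadrant scatter of design-mutation effects
#'
#' Predicted effect of each design mutation in the wild-type background
#' (x) versus the design background (y), colored by quadrant.
#'
#' @param object an `evh_quadrants` from [quadrant_analysis()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.evh_quadrants <- function(object, ...) {
  ggplot2::ggplot(object$mutations,
                  ggplot2::aes(x = .data$delta_wt_background,
                               y = .data$delta_design_background,
                               color = .data$quadrant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "delta EVH in wild-type background",
                  y = "delta EVH in design background") +
    ggplot2::theme_minimal()
}

#' Contact map of top-ranked couplings
#'
#' Top-scoring position pairs (upper triangle) overlaid on a reference
#' contact set (lower triangle) when one is supplied.
#'
#' @param scores matrix from [coupling_scores()].
#' @param contacts optional two-column table of reference contacts.
#' @param top_n number of top pairs to draw (default `nrow(scores)`).
#' @param min_sep minimum primary-sequence separation (default 5).
#' @return a ggplot.
#' @export
plot_contact_map <- function(scores, contacts = NULL, top_n = nrow(scores),
                             min_sep = 5L) {
  top <- pair_score_table(scores, min_sep = min_sep)
  top <- top[seq_len(min(top_n, nrow(top))), ]
  p <- ggplot2::ggplot(top, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_point(color = "firebrick", size = 1)
  if (!is.null(contacts)) {
    cdf <- tibble::tibble(i = pmax(contacts[[1]], contacts[[2]]),
                          j = pmin(contacts[[1]], contacts[[2]]))
    p <- p + ggplot2::geom_point(data = cdf, color = "grey40", size = 1)
  }
  p + ggplot2::coord_fixed() +
    ggplot2::labs(x = "position i", y = "position j",
                  title = "Top couplings (red) vs reference contacts (grey)") +
    ggplot2::theme_minimal()
}

#' Distribution of substitution effects
#'
#' Histogram of a full mutation scan's predicted effects, optionally with a
#' rug of highlighted substitutions (for example a design's mutations or
#' reversions).
#'
#' @param scan a tibble from [mutation_matrix()] or [reversion_scan()].
#' @param highlight optional tibble with a `delta_evh` column.
#' @return a ggplot.
#' @export
plot_mutation_effects <- function(scan, highlight = NULL) {
  p <- ggplot2::ggplot(scan, ggplot2::aes(x = .data$delta_evh)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue", color = "white")
  if (!is.null(highlight))
    p <- p + ggplot2::geom_rug(data = highlight, color = "red")
  p + ggplot2::labs(x = "delta EVH", y = "substitutions") +
    ggplot2::theme_minimal()
}
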