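# ---- broom-style tidiers and plots ----------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted candidate set
#'
#' One row per candidate: index, Newick string, maximized log-likelihood,
#' log-likelihood difference to the ML tree, and whether it is the ML tree.
#'
#' @param x A `"topo_fit"`.
#' @param ... Unused.
#' @return A tibble sorted by the candidate index.
#' @export
tidy.topo_fit <- function(x, ...) {
  tibble::tibble(
    tree = seq_len(n_trees(x)),
    newick = vapply(x$candidates, format, character(1)),
    logL = x$loglik,
    delta = delta_loglik(x),
    is_ml = seq_len(n_trees(x)) == x$ml_index)
}

#' @rdname tidy.topo_fit
#' @export
glance.topo_fit <- function(x, ...) {
  tibble::tibble(n_trees = n_trees(x), n_sites = ncol(x$values),
                 ml_index = x$ml_index, max_logL = max(x$loglik))
}

#' Tidy a Monte Carlo study
#'
#' @param x A `"study_result"`.
#' @param ... Unused.
#' @return Per-method tibble with `coverage` (percent), `mean_set_size`,
#'   `sd_set_size` and `avg_power`.
#' @export
tidy.study_result <- function(x, ...) x$summary

#' @rdname tidy.study_result
#' @export
glance.study_result <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(m = cfg$m, setting = cfg$setting,
                 internal_length = cfg$internal_length,
                 n_sites = cfg$n_sites, n_reps = x$n_reps,
                 n_correct = x$n_correct, n_incorrect = x$n_incorrect,
                 alpha = cfg$alpha, seed = cfg$seed, failures = x$failures)
}

#' Plot coverage against mean confidence-set size
#'
#' The study's two performance axes: each method is a point; the dashed
#' line marks nominal coverage and the dotted line the number of true
#' trees (the ideal set size).
#'
#' @param object A `"study_result"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.study_result <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_set_size,
                                   y = .data$coverage,
                                   label = .data$method)) +
    ggplot2::geom_hline(yintercept = 100 * (1 - object$config$alpha),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = object$n_correct,
                        linetype = "dotted", colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "mean 95% set size (trees)", y = "coverage (%)",
                  title = sprintf("m=%d, %s, tI=%g", object$config$m,
                                  object$config$setting,
                                  object$config$internal_length)) +
    ggplot2::coord_cartesian(ylim = c(0, 102)) +
    ggplot2::theme_minimal()
}

#' Plot per-split support values across methods
#'
#' @param supports Output of [split_supports()] (percent scale).
#' @return A ggplot with one bar group per split.
#' @export
plot_split_supports <- function(supports) {
  long <- tidyr::pivot_longer(supports, -c("split", "split_label"),
                              names_to = "method", values_to = "support")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$split_label,
                                     y = .data$support,
                                     fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 95, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "support (%)") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
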