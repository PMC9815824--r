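#' Plot similarity measures by condition
#'
#' Bar chart of Fisher-z similarity per measure and condition, averaged
#' over subjects when a `subject` column is present.
#'
#' @param sim_table Tibble from [trial_measures()] or [similarity_table()].
#' @return A ggplot object.
#' @export
plot_similarity <- function(sim_table) {
  dat <- dplyr::summarise(
    dplyr::group_by(sim_table, .data$condition, .data$measure),
    z = mean(.data$z), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$measure, y = .data$z,
                                    fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "similarity (Fisher z)",
                  fill = "condition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @describeIn cv_predict_r Histogram of the permutation null with the
#'   observed r marked.
#' @param object A `prediction_result` (for `autoplot`).
#' @export
autoplot.prediction_result <- function(object, ...) {
  if (is.null(object$r_perm)) {
    abort("No permutation draws stored; use permutation_p().")
  }
  ggplot2::ggplot(tibble::tibble(r = object$r_perm),
                  ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$r, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(x = "surrogate r(predicted, observed)", y = "count",
                  title = sprintf("observed r = %.3f, p = %.3g",
                                  object$r, object$p_perm)) +
    ggplot2::theme_minimal()
}

#' @describeIn bootstrap_indirect Point estimates with BC bootstrap
#'   intervals.
#' @param object An `indirect_effects` tibble (for `autoplot`).
#' @param ... Unused.
#' @export
autoplot.indirect_effects <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$effect, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper)) +
    ggplot2::labs(x = NULL, y = "indirect effect (standardized)") +
    ggplot2::theme_minimal()
}

#' @describeIn searchlight_map Tile plot of one axial slice of the
#'   contrast map.
#' @param object A `searchlight_map` (for `autoplot`).
#' @param slice Z index of the slice (default: middle slice).
#' @param ... Unused.
#' @export
autoplot.searchlight_map <- function(object, slice = NULL, ...) {
  dims <- dim(object)
  slice <- slice %||% ceiling(dims[3] / 2)
  sl <- unclass(object)[, , slice]
  dat <- tidyr::expand_grid(x = seq_len(dims[1]), y = seq_len(dims[2]))
  dat$value <- as.numeric(sl)[dat$x + (dat$y - 1) * dims[1]]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("searchlight contrast, slice z = %d",
                                  slice),
                  fill = "aversive - neutral z") +
    ggplot2::theme_minimal()
}
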