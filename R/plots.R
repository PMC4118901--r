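#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot pairwise LD as a triangle heatmap
#'
#' @param object An `ld_pairs` tibble from [ld_matrix()].
#' @param ... Unused.
#' @return A ggplot object: r-squared between site pairs, ordered by
#'   alignment position.
#' @export
autoplot.ld_pairs <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$pos1),
                                   y = factor(.data$pos2),
                                   fill = .data$r2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = expression(r^2)) +
    ggplot2::labs(x = "site position (bp)", y = "site position (bp)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot LD decay with the fitted model families
#'
#' Scatter of pairwise r-squared against distance with every converged
#' fitted decay curve; the selected family is drawn solid, the rest
#' dashed.
#'
#' @param object An `ld_decay_fit` from [fit_ld_decay()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ld_decay_fit <- function(object, ...) {
  d <- object$data
  grid <- seq(max(1, min(d$distance)), max(d$distance), length.out = 200)
  curves <- purrr::map2_dfr(
    object$models$model[object$models$converged],
    object$models$params[object$models$converged],
    function(m, p) {
      y <- switch(m,
        linear = p[["a"]] + p[["b"]] * grid,
        loglinear = p[["a"]] + p[["b"]] * log(grid),
        exponential = p[["a"]] * exp(p[["b"]] * grid),
        power = p[["a"]] * grid^p[["b"]],
        remington = remington_expectation(p[["rho"]] * grid, object$n)
      )
      tibble::tibble(model = m, distance = grid, r2 = y)
    }
  )
  curves$selected <- curves$model == object$selected
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance, y = .data$r2)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(colour = .data$model, linetype = .data$selected)
    ) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dashed"),
                                   guide = "none") +
    ggplot2::geom_hline(yintercept = object$r2_target, linetype = "dotted") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "distance (bp)", y = expression(r^2),
                  colour = "model") +
    ggplot2::theme_minimal()
}

#' Per-region diversity bar plot
#'
#' Side-by-side pi and Watterson's theta per region (unions and the
#' entire-locus row included).
#'
#' @param ds A tibble from [summarize_regions()].
#' @return A ggplot object.
#' @export
plot_diversity <- function(ds) {
  long <- tidyr::pivot_longer(
    dplyr::select(ds, "region", "pi", "theta_w"),
    c("pi", "theta_w"), names_to = "estimator", values_to = "value"
  )
  long$region <- factor(long$region, levels = unique(ds$region))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$region, y = .data$value,
                                     fill = .data$estimator)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(
      values = c(pi = "#3B6E8F", theta_w = "#C08A3E"),
      labels = c(pi = expression(pi), theta_w = expression(theta[W]))
    ) +
    ggplot2::labs(x = NULL, y = "per-site diversity", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
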