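# ggplot2 views of the fitted objects: the estimated choice function with
# the sampled asynchronies, the threshold-by-slope posterior heatmap, and a
# maximum-intensity projection of the corrected p map.

#' Plot an estimated choice function with its sampled asynchronies
#'
#' The fitted psychometric function (posterior-mean parameters) with one dot
#' per sampled asynchrony; dot area is proportional to the number of
#' estimation trials at that value and dot height is the observed
#' choose-first frequency.
#'
#' @param object A `psy_session`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psy_session
#' @export
autoplot.psy_session <- function(object, ...) {
  est <- object$estimate
  dbl <- object$trials |>
    dplyr::filter(.data$phase == "main", .data$kind == "double") |>
    dplyr::summarise(n = dplyr::n(), p_first = mean(.data$chose_first),
                     .by = "delta_ms")
  curve <- tibble(delta_ms = seq(0, max(object$config$candidates), length.out = 301))
  curve$p <- psy_prob(curve$delta_ms, params = est)
  ggplot2::ggplot(dbl, ggplot2::aes(x = .data$delta_ms)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$p)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$p_first, size = .data$n),
                        alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::coord_cartesian(ylim = c(0.4, 1)) +
    ggplot2::labs(x = "asynchrony δ (ms)",
                  y = "P(choose first target)",
                  size = "trials",
                  title = sprintf("slope %.2f, threshold %.0f ms",
                                  est$beta, est$alpha)) +
    ggplot2::theme_minimal()
}

#' Heatmap of the threshold-by-slope posterior
#'
#' @param object A `psy_posterior`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psy_posterior
#' @export
autoplot.psy_posterior <- function(object, ...) {
  ggplot2::ggplot(marginal_alpha_beta(object),
                  ggplot2::aes(x = .data$alpha, y = .data$beta,
                               fill = .data$mass)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "threshold α (ms)", y = "slope β",
                  fill = "mass") +
    ggplot2::theme_minimal()
}

#' Maximum-intensity projection of a corrected p map
#'
#' Projects `-log10(p_corr)` along the third axis and marks voxels
#' significant at `alpha`.
#'
#' @param object A `voxel_ptest`.
#' @param alpha Significance level for highlighting (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot voxel_ptest
#' @export
autoplot.voxel_ptest <- function(object, alpha = 0.05, ...) {
  df <- tidy(object) |>
    dplyr::mutate(nlp = -log10(.data$p_corr)) |>
    dplyr::summarise(nlp = max(.data$nlp), .by = c("i", "j"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$nlp)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s direction, min p = %.3g",
                                  object$direction, min(object$p_corr)),
                  x = "i", y = "j", fill = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Recovery scatter: true versus estimated slope
#'
#' @param object A `psy_recovery` from [recovery_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psy_recovery
#' @export
autoplot.psy_recovery <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$beta_true, y = .data$beta_est)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "true slope β", y = "posterior-mean slope",
                  title = sprintf("r = %.3f", cor(object$beta_true, object$beta_est))) +
    ggplot2::theme_minimal()
}
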