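#' Plot empirical ROC curves
#'
#' Cumulative hit vs false-alarm points (most conservative criterion at
#' the lower left), pooled over subjects, optionally split by
#' memorability bin. The dashed diagonal is chance.
#'
#' @inheritParams exclude_at_chance
#' @param by_bin Draw one curve per memorability bin?
#' @return A ggplot object.
#' @export
plot_roc <- function(trials, B = 6, by_bin = TRUE) {
  check_trials(trials, B)
  pts <- if (by_bin) {
    trials |>
      dplyr::mutate(mem_bin = bin_memorability(.data$memorability)) |>
      dplyr::group_by(.data$mem_bin) |>
      dplyr::group_map(function(df, key) {
        dplyr::mutate(roc_points(rating_counts(df, B)), mem_bin = key$mem_bin)
      }) |>
      purrr::list_rbind()
  } else {
    dplyr::mutate(roc_points(rating_counts(trials, B)), mem_bin = "all")
  }
  ggplot2::ggplot(pts, ggplot2::aes(.data$fa, .data$hit,
                                    colour = .data$mem_bin)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False-alarm rate", y = "Hit rate",
                  colour = "Memorability") +
    ggplot2::theme_minimal()
}

#' Plot z-transformed ROC points
#'
#' A zROC slope below 1 (or an upward bend at conservative criteria)
#' signals the asymmetry that the DPSD model attributes to recollection.
#'
#' @inheritParams plot_roc
#' @return A ggplot object.
#' @export
plot_zroc <- function(trials, B = 6, by_bin = TRUE) {
  check_trials(trials, B)
  pts <- if (by_bin) {
    trials |>
      dplyr::mutate(mem_bin = bin_memorability(.data$memorability)) |>
      dplyr::group_by(.data$mem_bin) |>
      dplyr::group_map(function(df, key) {
        dplyr::mutate(z_transform(roc_points(rating_counts(df, B))),
                      mem_bin = key$mem_bin)
      }) |>
      purrr::list_rbind()
  } else {
    dplyr::mutate(z_transform(roc_points(rating_counts(trials, B))),
                  mem_bin = "all")
  }
  ggplot2::ggplot(pts, ggplot2::aes(.data$zfa, .data$zhit,
                                    colour = .data$mem_bin)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "z(False-alarm rate)", y = "z(Hit rate)",
                  colour = "Memorability") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_rating_counts Plot the observed ROC points with the
#'   fitted model curve.
#' @param object,x A `roc_fit` object.
#' @param ... Unused.
#' @export
autoplot.roc_fit <- function(object, ...) {
  obs <- roc_points(object$counts)
  cgrid <- seq(min(object$criteria) - 3, max(object$criteria) + 3,
               length.out = 200)
  fa <- 1 - pnorm(cgrid)
  hit <- if (object$model == "dpsd") {
    object$ro + (1 - object$ro) * (1 - pnorm(cgrid - object$dprime))
  } else {
    1 - pnorm((cgrid - object$dprime) / object$vo)
  }
  curve <- tibble::tibble(fa = fa, hit = hit)
  ggplot2::ggplot(obs, ggplot2::aes(.data$fa, .data$hit)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False-alarm rate", y = "Hit rate",
                  title = sprintf("%s fit", toupper(object$model))) +
    ggplot2::theme_minimal()
}

#' Plot per-quantile model parameters
#'
#' Fitted parameter trajectories across memorability quantile ranks, one
#' panel per parameter.
#'
#' @param quantile_fits A tibble from [fit_quantiles()].
#' @return A ggplot object.
#' @export
plot_quantile_params <- function(quantile_fits) {
  long <- quantile_fits |>
    dplyr::select("quantile", "model", "ro", "dprime", "vo") |>
    tidyr::pivot_longer(c("ro", "dprime", "vo"), names_to = "parameter") |>
    dplyr::filter(is.finite(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$quantile, .data$value,
                                     colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Memorability quantile rank", y = "Estimate",
                  colour = "Model") +
    ggplot2::theme_minimal()
}
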