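#' Plot a simulated transit trajectory
#'
#' @param object A `gis_trajectory`.
#' @param what `"concentration"` (dissolved concentration per chamber),
#'   `"amounts"` (solid/dissolved/precipitated amounts) or `"ds"` (degree of
#'   supersaturation).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gis_trajectory <- function(object,
                                    what = c("concentration", "amounts",
                                             "ds"),
                                    ...) {
  what <- match.arg(what)
  df <- as_tibble(object)
  df$compartment <- factor(df$compartment,
                           levels = c("stomach", "duodenum", "jejunum"))
  if (what == "concentration") {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_min,
                                          .data$conc_ug_per_ml)) +
      ggplot2::geom_line(colour = "#2c7fb8") +
      ggplot2::labs(y = "dissolved concentration (\u00b5g/mL)")
  } else if (what == "ds") {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$ds)) +
      ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
      ggplot2::geom_line(colour = "#d95f02") +
      ggplot2::labs(y = "degree of supersaturation (-)")
  } else {
    long <- tidyr::pivot_longer(
      df, c("solid_ug", "dissolved_ug", "precipitated_ug"),
      names_to = "pool", values_to = "amount_ug")
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_min,
                                            .data$amount_ug,
                                            colour = .data$pool)) +
      ggplot2::geom_line() +
      ggplot2::labs(y = "amount (\u00b5g)", colour = NULL)
  }
  p + ggplot2::facet_wrap(~compartment, nrow = 1, scales = "free_y") +
    ggplot2::labs(x = "time (min)",
                  title = attr(object, "condition")$label) +
    ggplot2::theme_minimal()
}

#' Plot a simulated plasma profile
#'
#' @param object A `plasma_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plasma_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$time_min, .data$conc_ug_per_ml)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "time (min)",
                  y = "plasma concentration (\u00b5g/mL)") +
    ggplot2::theme_minimal()
}

#' Plot observed versus fitted concentrations of a transit fit
#'
#' @param object A `gis_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gis_fit <- function(object, ...) {
  res <- object$residuals
  res$compartment <- factor(res$compartment,
                            levels = c("stomach", "duodenum", "jejunum"))
  ggplot2::ggplot(res, ggplot2::aes(.data$time_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_conc_ug_per_ml),
                        colour = "black") +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted),
                       colour = "#d95f02") +
    ggplot2::facet_wrap(~compartment, nrow = 1, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "concentration (\u00b5g/mL)",
                  title = "observed (points) vs fitted (line)") +
    ggplot2::theme_minimal()
}

#' Plot the plasma profiles of a pipeline run
#'
#' @param object A `gis_pipeline`.
#' @param ... Unused.
#' @return A ggplot object overlaying the per-condition plasma curves.
#' @export
autoplot.gis_pipeline <- function(object, ...) {
  long <- bind_rows(lapply(names(object$plasma), function(nm) {
    mutate(as_tibble(object$plasma[[nm]]), condition = nm)
  }))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$conc_ug_per_ml,
                                     colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)",
                  y = "plasma concentration (\u00b5g/mL)", colour = NULL) +
    ggplot2::theme_minimal()
}
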