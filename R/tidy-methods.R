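#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.patlak_fit <- function(x, ...) {
  tibble::tibble(term = c("Ki", "V0"), estimate = c(x$Ki, x$V0),
                 unit = c("mL/cm^3/min", "mL/cm^3"))
}

#' @export
glance.patlak_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_points = x$n_points,
                 t_star_min = x$t_star_min)
}

#' @export
tidy.tc2_fit <- function(x, ...) {
  tibble::tibble(
    term = c("K1", "k2", "k3", "vb", "Ki"),
    estimate = c(x$K1, x$k2, x$k3, x$vb, x$Ki),
    unit = c("mL/cm^3/min", "/min", "/min", "", "mL/cm^3/min")
  )
}

#' @export
glance.tc2_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged,
                 n_starts_converged = x$n_starts_converged)
}

#' @export
tidy.tofts_fit <- function(x, ...) {
  tibble::tibble(term = c("Ktrans", "kep", "ve", "vp"),
                 estimate = c(x$Ktrans, x$kep, x$ve, x$vp),
                 unit = c("/min", "/min", "", ""))
}

#' @export
glance.tofts_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged)
}

#' @export
tidy.spectrum <- function(x, ...) {
  tibble::tibble(beta_per_min = x$beta_per_min, alpha = x$alpha)
}

#' @export
glance.spectrum <- function(x, ...) {
  tibble::tibble(Ki_trap = attr(x, "Ki_trap"), VT_rev = attr(x, "VT_rev"),
                 blood_weight = attr(x, "blood_weight"), rss = attr(x, "rss"))
}

#' @export
tidy.lasso_fit <- function(x, ...) x$coefficients

#' @export
glance.lasso_fit <- function(x, ...) {
  tibble::tibble(lambda_min = x$lambda_min,
                 cv_error_min = min(x$cv_mean),
                 n_selected = length(x$selected), family = x$family)
}

#' Patlak plot
#' @param object A `patlak_fit`.
#' @param ... Unused.
#' @export
autoplot.patlak_fit <- function(object, ...) {
  df <- tibble::tibble(x = object$x, y = object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$Ki, intercept = object$V0,
                         colour = "steelblue") +
    ggplot2::labs(x = "Normalised time  ∫Cp/Cp (min)", y = "CT/Cp",
                  title = sprintf("Patlak plot: Ki = %.4g mL/cm³/min",
                                  object$Ki)) +
    ggplot2::theme_minimal()
}

#' Kinetic spectrum plot
#' @param object A `spectrum`.
#' @param ... Unused.
#' @export
autoplot.spectrum <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$alpha > 0, , drop = FALSE]
  df$beta_plot <- pmax(df$beta_per_min, 5e-4)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta_plot, y = .data$alpha)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$beta_plot, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "decay rate β (/min; trapping component at left edge)",
                  y = "weight α",
                  title = sprintf("Kinetic spectrum (Ki_trap = %.4g)",
                                  attr(object, "Ki_trap"))) +
    ggplot2::theme_minimal()
}

#' Time-activity curve plot
#' @param object A `tissue_tac`.
#' @param ... Unused.
#' @export
autoplot.tissue_tac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mid_time_min,
                                       y = .data$value_kBq_mL)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)", y = "activity (kBq/mL)",
                  title = paste0("TAC: ", object$region[1],
                                 " (", object$statistic[1], ")")) +
    ggplot2::theme_minimal()
}

#' Cross-validation curve and selected coefficients for a LASSO fit
#' @param object A `lasso_fit`.
#' @param ... Unused.
#' @export
autoplot.lasso_fit <- function(object, ...) {
  cf <- object$coefficients
  cf <- cf[cf$term != "(Intercept)" & cf$estimate != 0, , drop = FALSE]
  ggplot2::ggplot(cf, ggplot2::aes(x = stats::reorder(.data$term, .data$estimate),
                                   y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "coefficient (standardised scale)",
                  title = sprintf("Selected features at lambda_min = %.3g",
                                  object$lambda_min)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
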