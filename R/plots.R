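group_palette <- c(wild = "#2e7d52", zoo = "#c8a24b")

#' Plot epigenetic age against calendar age
#'
#' Scatter of leave-one-out predicted age versus calendar age, coloured by
#' group, with per-group linear fits and the identity line.
#'
#' @param object A `grid_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grid_fit <- function(object, ...) {
  df <- object$predictions
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$predicted_age,
                                   colour = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.7) +
    ggplot2::scale_colour_manual(values = group_palette) +
    ggplot2::labs(x = "calendar age (years)",
                  y = "epigenetic age (years)",
                  colour = NULL,
                  subtitle = sprintf("best grid point: s = %.2f, b = %.1f y",
                                     object$best$s, object$best$b)) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of epigenetic age acceleration by group
#'
#' @param fit A `grid_fit`.
#' @return A ggplot.
#' @export
plot_eaa_distribution <- function(fit) {
  df <- fit$predictions
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$eaa,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.shape = 1) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::scale_fill_manual(values = group_palette, guide = "none") +
    ggplot2::labs(x = NULL, y = "age acceleration (years)") +
    ggplot2::theme_minimal()
}

#' Plot the permutation null with the observed effect
#'
#' @param object A `null_distribution`.
#' @param observed Observed intercept (years); drawn as a vertical line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.null_distribution <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(object$draws, ggplot2::aes(x = .data$b)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    ggplot2::labs(x = "permuted group intercept (years)", y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed,
                                 colour = "#b03030", linewidth = 1)
  }
  p
}

#' Volcano plot of candidate DMRs
#'
#' @param object A `dmr_calls` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dmr_calls <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$class <- ifelse(!df$significant, "n.s.",
                     ifelse(df$mean_diff > 0, "hyper (zoo)", "hypo (zoo)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_diff,
                                   y = -log10(pmax(.data$q, 1e-300)),
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(
      "hyper (zoo)" = "#c8a24b", "hypo (zoo)" = "#2e7d52", "n.s." = "grey70"
    )) +
    ggplot2::labs(x = "methylation difference (zoo - wild)",
                  y = expression(-log[10] ~ q), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Survival curves per stratum
#'
#' @param object A `cox_contrast`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cox_contrast <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group,
                               linetype = .data$sex)) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(values = group_palette) +
    ggplot2::labs(x = "age (years)", y = "survival probability",
                  colour = NULL, linetype = NULL,
                  subtitle = sprintf("HR (zoo vs wild) = %.2f [%.2f-%.2f]",
                                     object$hr, object$ci[1],
                                     object$ci[2])) +
    ggplot2::theme_minimal()
}
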