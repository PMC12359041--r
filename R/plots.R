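# ggplot2 methods for result objects.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col labs
#'   scale_x_log10 scale_y_log10 facet_wrap theme_minimal geom_errorbar
NULL

#' Plot a force-strain curve
#'
#' @param object An `nm_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nm_curve <- function(object, ...) {
  ggplot(tibble::as_tibble(object), aes(x = .data$strain, y = .data$force)) +
    geom_line(color = "grey30") +
    labs(x = expression(strain ~ lambda == Delta * L / R[0]),
         y = expression(force ~ (k[B] * T / sigma))) +
    theme_minimal()
}

#' Plot a contact-frequency curve P(s)
#'
#' @param object An `nm_ps`.
#' @param ... Unused.
#' @return A ggplot (log-log).
#' @export
autoplot.nm_ps <- function(object, ...) {
  ggplot(tibble::as_tibble(object), aes(x = .data$s_mb, y = .data$p)) +
    geom_line() + geom_point(size = 0.6) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "genomic separation s (Mb)", y = "contact frequency P(s)") +
    theme_minimal()
}

#' Plot a lamina contact-index profile (simulated DamID)
#'
#' @param object An `nm_profile`.
#' @param ... Unused.
#' @return A ggplot faceted by chromosome.
#' @export
autoplot.nm_profile <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(x = .data$start_mb, y = .data$contact_index)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~chromosome, ncol = 1, labeller = ggplot2::label_both) +
    labs(x = "genomic position (Mb)", y = "lamina contact index") +
    theme_minimal()
}

#' Plot the relative contact change after deformation
#'
#' @param object An `nm_delta`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nm_delta <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(x = .data$s_mb, y = .data$delta_rel)) +
    geom_line() +
    scale_x_log10() +
    labs(x = "genomic separation s (Mb)",
         y = expression("|" * Delta[rel] * "|")) +
    theme_minimal()
}

#' Plot group means with SEM error bars for a condition comparison
#'
#' @param object An `nm_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nm_comparison <- function(object, ...) {
  gs <- object$group_stats
  ggplot(gs, aes(x = .data$group, y = .data$mean)) +
    geom_col(fill = "grey70") +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem), width = 0.2) +
    labs(x = NULL, y = "mean +/- SEM") +
    theme_minimal()
}
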