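#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a table disparity fit
#'
#' @param x A `disparity_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `term` (`m1...mR`,
#'   `pi1...piC`), `estimate` and the asymptotic `std.error` from the
#'   inverse Fisher information (free parameters; the reference levels get
#'   `NA`).
#' @export
tidy.disparity_fit <- function(x, ...) {
  m <- x$model$row_probs; p <- x$model$col_probs
  R <- length(m); C <- length(p)
  se <- rep(NA_real_, R + C)
  if (all(m > 0) && all(p > 0)) {
    info <- fisher_information(x$model, N = x$table$N)
    se_free <- sqrt(diag(solve(info)))
    se[c(seq_len(R - 1), R + seq_len(C - 1))] <- se_free
  }
  tibble::tibble(
    term = c(paste0("m", seq_len(R)), paste0("pi", seq_len(C))),
    estimate = c(m, p),
    std.error = se
  )
}

#' @rdname tidy.disparity_fit
#' @export
glance.disparity_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family$id,
    objective = x$objective,
    converged = x$converged,
    n_iter = x$n_iter,
    N = x$table$N,
    min_weight = min(x$residuals$weights)
  )
}

#' Tidy a mixed-scale disparity fit
#'
#' @param x A `mixed_disparity_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`pi<level>`, `mu<dim>`).
#' @export
tidy.mixed_disparity_fit <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("pi", seq_along(x$pi)), paste0("mu", seq_along(x$mu))),
    estimate = c(x$pi, x$mu)
  )
}

#' @rdname tidy.mixed_disparity_fit
#' @export
glance.mixed_disparity_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family$id,
    objective = x$objective,
    converged = x$converged,
    n_iter = x$n_iter,
    n = x$n,
    bandwidth_max = max(diag(as.matrix(x$H)))
  )
}

#' Tidy a Monte-Carlo summary
#'
#' @param x An `mc_summary`.
#' @param ... Unused.
#' @return `tidy()` returns the per-parameter results tibble; `glance()`
#'   the per-family overall absolute bias and failure counts.
#' @export
tidy.mc_summary <- function(x, ...) x$results

#' @rdname tidy.mc_summary
#' @export
glance.mc_summary <- function(x, ...) x$overall

#' Plot the downweighting pattern of a table fit
#'
#' Tile map of the fitted weights `w(delta)` over the table; light cells are
#' the surprising (downweighted) ones.
#'
#' @param object A `disparity_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.disparity_fit <- function(object, ...) {
  df <- weight_report(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$x), y = factor(.data$y),
                                   fill = .data$weight)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$delta)),
                       size = 3) +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "white", high = "steelblue") +
    ggplot2::labs(x = "X level", y = "Y level", fill = "w",
                  title = sprintf("Cell weights (%s fit); labels = Pearson residuals",
                                  object$family$id)) +
    ggplot2::theme_minimal()
}

#' Plot observation weights of a mixed-scale fit
#'
#' Jittered per-observation weights by category; points with `w` well below
#' 1 are the surprising observations the estimator downweights.
#'
#' @param object A `mixed_disparity_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixed_disparity_fit <- function(object, ...) {
  df <- weight_report(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$weight)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.4) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "category", y = "w(delta)",
                  title = sprintf("Observation weights (%s fit)", object$family$id)) +
    ggplot2::theme_minimal()
}

#' Plot a Monte-Carlo summary
#'
#' Estimate means with +/- 2 Monte-Carlo standard errors against the true
#' values, per parameter, faceted by family.
#'
#' @param object An `mc_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mc_summary <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - 2 * .data$mc_se,
                                        ymax = .data$mean + 2 * .data$mc_se),
                           width = 0.2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$true), shape = 4, colour = "red") +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(y = "Monte-Carlo mean (bars: +/- 2 MC SE; x: truth)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
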