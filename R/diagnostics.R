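#' Fisher information of the independence multinomial
#'
#' Information matrix of the free parameters `m[1..R-1], pi[1..C-1]` of the
#' independence model at sample size `N`. Because the log likelihood
#' separates into the two marginals, the matrix is block diagonal with
#' blocks `N * (diag(1/m_free) + 1/m_R)` (and the analogue for `pi`); its
#' inverse is the asymptotic covariance of the minimum disparity estimators
#' under the correct model, so `sqrt(diag(solve(I)))` gives asymptotic
#' standard errors.
#'
#' @param model An interior [independence_model()].
#' @param N Sample size.
#' @return A symmetric positive-definite matrix with named rows/columns.
#' @export
fisher_information <- function(model, N = 1) {
  m <- model$row_probs; p <- model$col_probs
  if (any(m <= 0) || any(p <= 0)) stop("Boundary model: information undefined.")
  R <- length(m); C <- length(p)
  block <- function(q, prefix) {
    k <- length(q) - 1
    B <- N * (diag(1 / q[seq_len(k)], nrow = k) + 1 / q[length(q)])
    dimnames(B) <- list(paste0(prefix, seq_len(k)), paste0(prefix, seq_len(k)))
    B
  }
  Im <- block(m, "m"); Ip <- block(p, "pi")
  out <- matrix(0, R + C - 2, R + C - 2)
  out[seq_len(R - 1), seq_len(R - 1)] <- Im
  out[R - 1 + seq_len(C - 1), R - 1 + seq_len(C - 1)] <- Ip
  dimnames(out) <- list(c(rownames(Im), rownames(Ip)),
                        c(rownames(Im), rownames(Ip)))
  out
}

# score of the free independence parameters at cell (y, x)
independence_score <- function(model, y, x) {
  m <- model$row_probs; p <- model$col_probs
  R <- length(m); C <- length(p)
  # d log(m_y pi_x) / d m_r with m_R = 1 - sum(m_free), likewise for pi
  um <- vapply(seq_len(R - 1), function(r) (y == r) / m[r] - (y == R) / m[R], 0)
  up <- vapply(seq_len(C - 1), function(s) (x == s) / p[s] - (x == C) / p[C], 0)
  stats::setNames(c(um, up),
                  c(paste0("m", seq_len(R - 1)), paste0("pi", seq_len(C - 1))))
}

#' Empirical influence function of a table estimator
#'
#' Differentiates the fitted functional under point-mass contamination: the
#' model is refitted at `(1 - eps) d + eps * Delta_(y, x)` over a ladder of
#' contamination fractions and the derivative at zero is obtained by
#' Richardson extrapolation. Under the correct model the result equals the
#' maximum likelihood influence `I(beta)^{-1} u(y, x)`, reflecting the full
#' first-order efficiency of the disparity estimators; their robustness
#' shows up away from the model, where the weights bound the effect of the
#' contaminated cell.
#'
#' @param table A [contingency_table()], count matrix, or probability
#'   matrix (`allow_real`), defining the base distribution `d`.
#' @param family A [disparity_family()] or id string.
#' @param point Integer pair `c(y, x)`: the contaminated cell.
#' @param eps_grid Decreasing contamination fractions in `(0, 0.1]`
#'   (default `c(0.02, 0.01, 0.005)`).
#' @return A list of class `influence_estimate`: `direction` (the derivative
#'   for the full `(m, pi)` vector), `eps_used` and `extrapolation_error`
#'   (difference between the last two Richardson stages).
#' @export
influence_curve <- function(table, family, point,
                            eps_grid = c(0.02, 0.01, 0.005)) {
  table <- as_contingency_table(table, allow_real = TRUE)
  family <- as_disparity_family(family)
  stopifnot(length(point) == 2, all(eps_grid > 0), all(eps_grid <= 0.1))
  eps_grid <- sort(eps_grid, decreasing = TRUE)
  d <- table$props
  R <- nrow(d); C <- ncol(d)
  opts <- list(restarts = 0L, grad_tol = 1e-8, polish = TRUE)

  base <- fit_dmatrix(d, family, options = utils::modifyList(opts, list(restarts = 2L)))
  if (!base$converged) stop("Base fit did not converge.")
  base_par <- c(base$row_probs, base$col_probs)
  warm <- independence_model(base$row_probs, base$col_probs)

  theta_at <- function(eps) {
    d_eps <- (1 - eps) * d
    d_eps[point[1], point[2]] <- d_eps[point[1], point[2]] + eps
    sol <- fit_dmatrix(d_eps, family, init = warm, options = opts)
    if (!sol$converged) stop(sprintf("Contaminated fit at eps = %g did not converge.", eps))
    c(sol$row_probs, sol$col_probs)
  }

  slopes <- vapply(eps_grid, function(e) (theta_at(e) - base_par) / e,
                   numeric(R + C))
  # Richardson: successively cancel the O(eps) error (eps halves down the grid)
  stages <- list(slopes)
  k <- length(eps_grid)
  cur <- slopes
  for (lev in seq_len(k - 1)) {
    nxt <- matrix(0, R + C, k - lev)
    for (j in seq_len(k - lev)) {
      r <- eps_grid[j] / eps_grid[j + lev]
      nxt[, j] <- (r * cur[, j + 1] - cur[, j]) / (r - 1)
    }
    stages[[lev + 1]] <- nxt
    cur <- nxt
  }
  final <- cur[, 1]
  prev <- stages[[max(1, k - 1)]][, 1]
  names(final) <- c(paste0("m", seq_len(R)), paste0("pi", seq_len(C)))
  structure(
    list(direction = final, eps_used = eps_grid,
         extrapolation_error = max(abs(final - prev))),
    class = "influence_estimate"
  )
}

#' @export
print.influence_estimate <- function(x, ...) {
  cat("<influence_estimate> extrapolation error ",
      format(x$extrapolation_error, digits = 3), "\n", sep = "")
  print(round(x$direction, 4))
  invisible(x)
}

#' Ranked downweighting report
#'
#' Lists cells (table fits) or observations (mixed fits) ordered by
#' ascending weight `w(delta)`: the first rows are the most surprising
#' under the fitted model, i.e. the candidate outliers. For the LD all
#' weights are 1 and the ranking is uninformative by construction.
#'
#' @param fit A `disparity_fit` or `mixed_disparity_fit`.
#' @return A tibble with the location, Pearson residual `delta` and weight
#'   `w`, sorted by ascending weight.
#' @export
weight_report <- function(fit) {
  UseMethod("weight_report")
}

#' @export
weight_report.disparity_fit <- function(fit) {
  delta <- fit$residuals$delta
  w <- fit$residuals$weights
  idx <- expand.grid(y = seq_len(nrow(delta)), x = seq_len(ncol(delta)))
  tibble::tibble(
    y = idx$y, x = idx$x,
    count = as.vector(fit$table$counts),
    delta = as.vector(delta),
    weight = as.vector(w)
  ) |>
    dplyr::arrange(.data$weight, dplyr::desc(abs(.data$delta)))
}

#' @export
weight_report.mixed_disparity_fit <- function(fit) {
  smp <- fit$sample
  H <- as.matrix(fit$H)
  # evaluate the smoothed data and model densities at the observations
  f_at <- kde_at_points(smp$values, H)
  S <- fit$model_cov + H
  m_at <- mvn_at_points(smp$values, fit$mu, S)
  k <- as.integer(smp$labels)
  delta <- f_at * (fit$shares[k] / (pmax(m_at, 1e-300) * fit$pi[k])) - 1
  w <- weight(fit$family, delta)
  tibble::tibble(
    obs = seq_len(smp$n),
    level = smp$labels,
    delta = delta,
    weight = w
  ) |>
    dplyr::arrange(.data$weight, dplyr::desc(abs(.data$delta)))
}

kde_at_points <- function(y, H) {
  n <- nrow(y); d <- ncol(y)
  sd_j <- sqrt(diag(H))
  dens <- matrix(1, n, n)
  for (j in seq_len(d)) {
    dens <- dens * outer(y[, j], y[, j], function(a, b) stats::dnorm(a - b, sd = sd_j[j]))
  }
  rowMeans(dens)
}

mvn_at_points <- function(y, mu, S) {
  if (is_diagonal(S)) {
    dens <- rep(1, nrow(y))
    for (j in seq_len(ncol(y))) {
      dens <- dens * stats::dnorm(y[, j], mu[j], sqrt(S[j, j]))
    }
    return(dens)
  }
  L <- chol(S)
  z <- backsolve(L, t(y) - mu, transpose = TRUE)
  (2 * pi)^(-ncol(y) / 2) / prod(diag(L)) * exp(-0.5 * colSums(z^2))
}
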