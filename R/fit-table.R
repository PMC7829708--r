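# Constrained minimisation of sum G(delta) * m(y) * pi(x) over the two
# probability simplexes. The simplex constraints are absorbed by a
# multinomial-logit reparameterisation (reference level = last), giving a
# smooth unconstrained problem solved by quasi-Newton with the analytic
# gradient d rho / d(model cell mass) = -A(delta), then polished by a few
# damped Newton steps on the gradient for near-machine-precision stationarity.

softmax_ref <- function(l) {
  e <- exp(c(l, 0) - max(c(l, 0)))
  e / sum(e)
}

probs_to_logits <- function(p, bound = 30) {
  p <- pmax(p, 1e-12)
  l <- log(p[-length(p)] / p[length(p)])
  pmin(pmax(l, -bound), bound)
}

default_table_options <- function(options = list()) {
  utils::modifyList(
    list(restarts = 5L, maxit = 500L, grad_tol = 1e-8, logit_bound = 30,
         polish = TRUE, rel_tol = 1e-15),
    options
  )
}

# objective and gradient in the free logits
table_obj_env <- function(d, family, R, C) {
  force(d); force(family)
  obj <- function(theta) {
    m <- softmax_ref(theta[seq_len(R - 1)])
    p <- softmax_ref(theta[R - 1 + seq_len(C - 1)])
    mm <- outer(m, p)
    delta <- d / mm - 1
    sum(g_value(family, as.vector(delta)) * as.vector(mm))
  }
  grad <- function(theta) {
    m <- softmax_ref(theta[seq_len(R - 1)])
    p <- softmax_ref(theta[R - 1 + seq_len(C - 1)])
    mm <- outer(m, p)
    a <- matrix(raf_raw(family, as.vector(d / mm - 1)), R, C)
    gm <- -as.vector(a %*% p)        # d rho / d m_y
    gp <- -as.vector(crossprod(a, m)) # d rho / d pi_x
    lm <- m * (gm - sum(gm * m))
    lp <- p * (gp - sum(gp * p))
    c(lm[-R], lp[-C])
  }
  list(obj = obj, grad = grad)
}

newton_polish <- function(theta, grad, max_steps = 12L, tol = 1e-11, h = 1e-6) {
  k <- length(theta)
  for (step in seq_len(max_steps)) {
    g <- grad(theta)
    if (max(abs(g)) < tol) break
    H <- matrix(0, k, k)
    for (j in seq_len(k)) {
      e <- numeric(k); e[j] <- h
      H[, j] <- (grad(theta + e) - grad(theta - e)) / (2 * h)
    }
    H <- (H + t(H)) / 2
    delta <- tryCatch(solve(H + diag(1e-10, k), g), error = function(e) NULL)
    if (is.null(delta)) break
    # backtrack on the gradient norm
    stp <- 1
    g0 <- sum(g^2)
    repeat {
      cand <- theta - stp * delta
      if (sum(grad(cand)^2) < g0 || stp < 1e-4) break
      stp <- stp / 2
    }
    theta <- theta - stp * delta
  }
  theta
}

fit_dmatrix <- function(d, family, init = NULL, options = list()) {
  opts <- default_table_options(options)
  R <- nrow(d); C <- ncol(d)
  fe <- table_obj_env(d, family, R, C)
  bound <- opts$logit_bound
  lower <- rep(-bound, (R - 1) + (C - 1))
  upper <- rep(bound, (R - 1) + (C - 1))

  make_init <- function() {
    m0 <- stats::runif(R); p0 <- stats::runif(C)
    c(probs_to_logits(m0 / sum(m0), bound), probs_to_logits(p0 / sum(p0), bound))
  }
  theta0 <- if (!is.null(init)) {
    c(probs_to_logits(init$row_probs, bound), probs_to_logits(init$col_probs, bound))
  } else {
    make_init()
  }

  best <- NULL
  n_tries <- opts$restarts + 1L
  for (try in seq_len(n_tries)) {
    res <- tryCatch(
      stats::nlminb(theta0, fe$obj, gradient = fe$grad,
                    lower = lower, upper = upper,
                    control = list(iter.max = opts$maxit, eval.max = 4 * opts$maxit,
                                   rel.tol = opts$rel_tol)),
      error = function(e) NULL
    )
    if (!is.null(res)) {
      theta <- res$par
      if (opts$polish) theta <- newton_polish(theta, fe$grad)
      gnorm <- max(abs(fe$grad(theta)))
      cand <- list(theta = theta, objective = fe$obj(theta), grad_norm = gnorm,
                   n_iter = res$iterations, converged = gnorm < opts$grad_tol)
      if (is.null(best) || cand$objective < best$objective ||
          (cand$converged && !best$converged)) {
        best <- cand
      }
      if (best$converged) break
    }
    theta0 <- make_init()
  }
  if (is.null(best)) stop("Table optimiser failed on every restart.")
  m <- softmax_ref(best$theta[seq_len(R - 1)])
  p <- softmax_ref(best$theta[R - 1 + seq_len(C - 1)])
  list(row_probs = m, col_probs = p, objective = best$objective,
       converged = best$converged, n_iter = best$n_iter,
       grad_norm = best$grad_norm)
}

#' Fit the independence model to a contingency table by minimum disparity
#'
#' Minimises `sum G(delta(y, x)) m(y) pi(x)` over the row and column
#' probability vectors, each constrained to the unit simplex. With the LD
#' family the solution is the observed marginal proportions (the MLE); the
#' robust families (HD, SCS, ...) downweight surprising cells instead.
#'
#' Initial values default to independent uniform draws normalised to the
#' simplex (seed the RNG for reproducibility); up to `options$restarts`
#' fresh starts are tried if the stationarity check fails, after which a
#' non-convergence error carrying the best iterate is raised.
#'
#' @param table A [contingency_table()], count matrix, or wide data frame.
#' @param family A [disparity_family()] or id string.
#' @param init Optional [independence_model()] starting point.
#' @param options Solver settings: `restarts` (default 5), `maxit` (500),
#'   `grad_tol` (1e-8), `polish` (TRUE).
#' @return An object of class `disparity_fit` with elements `model`,
#'   `objective`, `converged`, `n_iter`, `residuals` (Pearson residuals and
#'   weights at the fit), `family` and `table`.
#' @examples
#' set.seed(1)
#' tab <- contingency_table(matrix(c(20, 5, 5, 20), 2, 2))
#' fit <- fit_table(tab, "HD")
#' tidy(fit)
#' @export
fit_table <- function(table, family, init = NULL, options = list()) {
  table <- as_contingency_table(table, allow_real = TRUE)
  family <- as_disparity_family(family)
  if (nrow(table$counts) < 2 || ncol(table$counts) < 2) {
    stop("Need at least a 2 x 2 table.")
  }
  sol <- fit_dmatrix(table$props, family, init = init, options = options)
  model <- independence_model(sol$row_probs, sol$col_probs)
  res <- pearson_residuals_table(table, model, family)
  fit <- structure(
    list(model = model, objective = sol$objective, converged = sol$converged,
         n_iter = sol$n_iter, grad_norm = sol$grad_norm, residuals = res,
         family = family, table = table),
    class = "disparity_fit"
  )
  if (!sol$converged) {
    cond <- structure(
      class = c("mindisp_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "fit_table did not reach stationarity (max |grad| = %.2e) after restarts; best iterate attached as `fit`.",
        sol$grad_norm), call = sys.call(-1), fit = fit)
    )
    stop(cond)
  }
  fit
}

#' @export
print.disparity_fit <- function(x, ...) {
  cat("<disparity_fit> family = ", x$family$id,
      ", objective = ", format(x$objective, digits = 6),
      ", converged = ", x$converged, "\n", sep = "")
  print(x$model)
  invisible(x)
}

#' Weighted estimating-equation residual
#'
#' The weighted score of the reduced (free) parameterisation
#' `m[1..R-1], pi[1..C-1]`: components
#' `(1/N) * sum_x (w * n)[r, x] / m[r] - (w * n)[R, x] / m[R]` and the
#' analogous column block. Its norm is ~0 at a minimum-disparity fit
#' (exactly 0 at the LD/MLE) and positive at non-stationary models.
#'
#' @param table A [contingency_table()] or count matrix.
#' @param model An interior [independence_model()] (all probabilities in
#'   (0, 1)).
#' @param family A [disparity_family()] or id string.
#' @return Numeric vector of length `(R - 1) + (C - 1)`.
#' @export
estimating_equation_residual <- function(table, model, family) {
  table <- as_contingency_table(table, allow_real = TRUE)
  family <- as_disparity_family(family)
  m <- model$row_probs; p <- model$col_probs
  if (any(m <= 0) || any(m >= 1) || any(p <= 0) || any(p >= 1)) {
    stop("Boundary model: all probabilities must be strictly inside (0, 1).")
  }
  res <- pearson_residuals_table(table, model, family)
  wn <- res$weights * table$counts
  R <- length(m); C <- length(p)
  row_score <- rowSums(wn) / m
  col_score <- colSums(wn) / p
  c(row_score[-R] - row_score[R], col_score[-C] - col_score[C]) / table$N
}
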