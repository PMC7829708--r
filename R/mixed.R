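#' Mixed-scale samples
#'
#' A sample of one categorical variable `X` (the group label) and a
#' `d`-dimensional continuous vector `Y`, assumed independent of `X`. The
#' natural container is a data frame whose first column is the label and
#' whose remaining columns are numeric.
#'
#' @param data A data frame (first column = label, rest numeric), or a
#'   vector of labels when `values` is supplied.
#' @param values Optional `n x d` numeric matrix of the continuous part.
#' @return An object of class `mixed_sample` with elements `labels`
#'   (factor), `values` (matrix), `levels`, `group_counts`, `n`, `d`.
#' @export
mixed_sample <- function(data, values = NULL) {
  if (is.data.frame(data)) {
    labels <- data[[1]]
    values <- as.matrix(data[, -1, drop = FALSE])
  } else {
    labels <- data
    values <- as.matrix(values)
  }
  storage.mode(values) <- "double"
  if (anyNA(labels) || anyNA(values)) stop("Missing values are not allowed.")
  labels <- factor(labels)
  if (nrow(values) != length(labels)) stop("Label and value lengths differ.")
  if (ncol(values) < 1) stop("Need at least one continuous dimension.")
  if (is.null(colnames(values))) colnames(values) <- paste0("y", seq_len(ncol(values)))
  structure(
    list(labels = labels, values = values, levels = levels(labels),
         group_counts = as.vector(table(labels)), n = nrow(values),
         d = ncol(values)),
    class = "mixed_sample"
  )
}

as_mixed_sample <- function(x) {
  if (inherits(x, "mixed_sample")) x else mixed_sample(x)
}

#' @export
print.mixed_sample <- function(x, ...) {
  cat("<mixed_sample> n = ", x$n, ", d = ", x$d, ", levels: ",
      paste(x$levels, collapse = ", "), " (counts ",
      paste(x$group_counts, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Read / write a mixed-scale sample CSV
#'
#' The layout is one categorical label column followed by `d` numeric
#' columns, with a header row.
#'
#' @param path CSV path.
#' @return A [mixed_sample()].
#' @export
read_mixed_csv <- function(path) {
  mixed_sample(utils::read.csv(path))
}

#' @rdname read_mixed_csv
#' @param sample A [mixed_sample()] or suitable data frame.
#' @export
write_mixed_csv <- function(sample, path) {
  sample <- as_mixed_sample(sample)
  df <- data.frame(x = sample$labels, sample$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parametric model for a mixed-scale sample
#'
#' Category probabilities `pi` for `X` and a multivariate normal
#' `N(mu, model_cov)` for `Y`, with the covariance treated as known
#' (identity by default) so only `(pi, mu)` are estimated.
#'
#' @param pi Probability vector over the categories.
#' @param mu Mean vector of the continuous part.
#' @param model_cov Known covariance of the continuous part (default
#'   identity).
#' @return An object of class `mixed_model`.
#' @export
mixed_model <- function(pi, mu, model_cov = NULL) {
  pi <- as.numeric(pi); mu <- as.numeric(mu)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8) stop("`pi` must lie on the simplex.")
  if (is.null(model_cov)) model_cov <- diag(length(mu))
  model_cov <- as.matrix(model_cov)
  if (!isSymmetric(model_cov, tol = 1e-10) ||
      any(eigen(model_cov, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("`model_cov` must be symmetric positive-definite.")
  }
  structure(list(pi = pi, mu = mu, model_cov = model_cov), class = "mixed_model")
}

#' Normal-reference diagonal bandwidth
#'
#' The plug-in bandwidth matrix for a `d`-dimensional normal kernel:
#' `H[j, j] = (4 / (n (d + 2)))^(2 / (d + 4)) * s_j^2` with `s_j` the sample
#' standard deviation of dimension `j`. For `d = 1` this is Silverman's
#' squared rule-of-thumb bandwidth.
#'
#' @param sample A [mixed_sample()] (or data frame / matrix of the
#'   continuous part).
#' @return A `d x d` diagonal bandwidth matrix.
#' @export
estimate_bandwidth <- function(sample) {
  y <- if (inherits(sample, "mixed_sample")) sample$values else as.matrix(sample)
  n <- nrow(y); d <- ncol(y)
  if (n < d + 2) stop("Need at least d + 2 observations to estimate a bandwidth.")
  s2 <- apply(y, 2, stats::var)
  if (any(s2 <= 0)) stop("Zero-variance dimension: bandwidth undefined.")
  factor <- (4 / (n * (d + 2)))^(2 / (d + 4))
  diag(factor * s2, nrow = d)
}

#' Tensor-product Simpson integration grid
#'
#' Uniform per-dimension node vectors with an odd number of nodes, carrying
#' the composite Simpson 1/3 weights. The default bounds extend the data
#' range by four kernel standard deviations per dimension so that the
#' smoothed data density is captured to well within the stated normalisation
#' tolerance.
#'
#' @param sample A [mixed_sample()] (used for the default bounds), or `NULL`
#'   when `lower`/`upper` are given.
#' @param H Bandwidth matrix (needed for the default bounds).
#' @param nodes Nodes per dimension (odd, >= 3). Default 41; Monte-Carlo
#'   runs use 21.
#' @param lower,upper Optional explicit bounds (length `d`).
#' @return An object of class `integration_grid`.
#' @export
integration_grid <- function(sample = NULL, H = NULL, nodes = 41,
                             lower = NULL, upper = NULL) {
  if (is.null(lower) || is.null(upper)) {
    sample <- as_mixed_sample(sample)
    hsd <- sqrt(diag(as.matrix(H)))
    lower <- apply(sample$values, 2, min) - 4 * hsd
    upper <- apply(sample$values, 2, max) + 4 * hsd
  }
  d <- length(lower)
  nodes <- rep(nodes, length.out = d)
  if (any(nodes < 3) || any(nodes %% 2 == 0)) {
    stop("Each dimension needs an odd number of nodes >= 3.")
  }
  node_list <- lapply(seq_len(d), function(j) seq(lower[j], upper[j], length.out = nodes[j]))
  new_integration_grid(node_list)
}

new_integration_grid <- function(node_list) {
  d <- length(node_list)
  step <- vapply(node_list, function(v) v[2] - v[1], numeric(1))
  for (v in node_list) {
    if (length(v) < 3 || length(v) %% 2 == 0) stop("Odd node counts >= 3 required.")
    if (max(abs(diff(diff(v)))) > 1e-8 * max(abs(v) + 1)) stop("Nodes must be uniformly spaced.")
  }
  w1 <- lapply(seq_len(d), function(j) {
    n <- length(node_list[[j]])
    w <- rep(c(2, 4), length.out = n)
    w[1] <- 1; w[n] <- 1
    w * step[j] / 3
  })
  w_full <- as.vector(Reduce(function(a, b) outer(a, b), w1))
  structure(
    list(nodes = node_list, step = step, d = d,
         sizes = vapply(node_list, length, integer(1)),
         weights = w1, w_full = w_full),
    class = "integration_grid"
  )
}

#' @export
print.integration_grid <- function(x, ...) {
  cat("<integration_grid> ", paste(x$sizes, collapse = " x "), " nodes over [",
      paste(sprintf("%.3g, %.3g", vapply(x$nodes, min, 0), vapply(x$nodes, max, 0)),
            collapse = "] x ["), "]\n", sep = "")
  invisible(x)
}

# grid nodes as a (prod sizes) x d matrix, first dimension varying fastest
grid_node_matrix <- function(grid) {
  as.matrix(do.call(expand.grid, grid$nodes))
}

#' Composite Simpson 1/3 integration on a tensor grid
#'
#' Exact for polynomials up to degree three separately in each dimension.
#'
#' @param values Numeric array (or vector in grid order) of integrand values
#'   at the grid nodes.
#' @param grid An [integration_grid()].
#' @return The integral (scalar).
#' @export
simpson_integrate <- function(values, grid) {
  v <- as.vector(values)
  if (length(v) != prod(grid$sizes)) stop("Value field does not match the grid.")
  sum(v * grid$w_full)
}

# tensor product of per-dimension vectors -> array-ordered vector
tensor_vec <- function(vlist) {
  as.vector(Reduce(function(a, b) outer(a, b), vlist))
}

#' Kernel-smoothed data density on the grid
#'
#' The kernel density estimate `f*(y) = (1/n) sum_i phi_H(y - y_i)` with a
#' mean-zero normal kernel of covariance `H`, pooled over the groups (the
#' groups share the continuous distribution under independence). Errors if
#' the grid captures less than 0.95 of its mass.
#'
#' @param sample A [mixed_sample()].
#' @param H Bandwidth matrix (diagonal for the fast tensor path).
#' @param grid An [integration_grid()].
#' @return Numeric vector of density values in grid order.
#' @export
smooth_data_density <- function(sample, H, grid) {
  sample <- as_mixed_sample(sample)
  H <- as.matrix(H)
  f <- kde_on_nodes(sample$values, H, grid)
  total <- simpson_integrate(f, grid)
  if (total < 0.95) {
    stop(sprintf("Integration grid too small: smoothed data mass %.3f < 0.95.", total))
  }
  f
}

is_diagonal <- function(M) all(abs(M[row(M) != col(M)]) < 1e-12)

kde_on_nodes <- function(y, H, grid) {
  n <- nrow(y); d <- ncol(y)
  if (is_diagonal(H) && d <= 3) {
    sd_j <- sqrt(diag(H))
    A <- lapply(seq_len(d), function(j) {
      outer(y[, j], grid$nodes[[j]], function(a, b) stats::dnorm(b - a, sd = sd_j[j]))
    })
    if (d == 1) {
      return(colSums(A[[1]]) / n)
    }
    if (d == 2) {
      return(as.vector(crossprod(A[[1]], A[[2]])) / n)
    }
    n1 <- grid$sizes[1]
    out <- array(0, dim = grid$sizes)
    for (a in seq_len(n1)) {
      out[a, , ] <- crossprod(A[[2]] * A[[1]][, a], A[[3]])
    }
    return(as.vector(out) / n)
  }
  # general covariance: accumulate per observation
  nodes <- grid_node_matrix(grid)
  L <- chol(H)
  out <- numeric(nrow(nodes))
  cst <- (2 * pi)^(-d / 2) / prod(diag(L))
  for (i in seq_len(n)) {
    z <- backsolve(L, t(nodes) - y[i, ], transpose = TRUE)
    out <- out + cst * exp(-0.5 * colSums(z^2))
  }
  out / n
}

#' Smoothed model density on the grid
#'
#' The normal kernel is transparent for a normal model: convolving
#' `N(mu, model_cov)` with the kernel `N(0, H)` gives exactly
#' `N(mu, model_cov + H)`, which is evaluated in closed form (no numerical
#' convolution).
#'
#' @param model A [mixed_model()].
#' @param H Bandwidth matrix.
#' @param grid An [integration_grid()].
#' @return Numeric vector of density values in grid order.
#' @export
smooth_model_density <- function(model, H, grid) {
  S <- model$model_cov + as.matrix(H)
  mvn_on_nodes(model$mu, S, grid)
}

mvn_on_nodes <- function(mu, S, grid) {
  d <- length(mu)
  if (is_diagonal(S)) {
    v <- lapply(seq_len(d), function(j) {
      stats::dnorm(grid$nodes[[j]], mean = mu[j], sd = sqrt(S[j, j]))
    })
    return(tensor_vec(v))
  }
  nodes <- grid_node_matrix(grid)
  L <- chol(S)
  z <- backsolve(L, t(nodes) - mu, transpose = TRUE)
  (2 * pi)^(-d / 2) / prod(diag(L)) * exp(-0.5 * colSums(z^2))
}

#' Smoothed disparity objective for mixed-scale data
#'
#' `rho = sum_x pi_x int G(delta(x, y)) m*(y) dy` with
#' `delta(x, y) = f*(y) (n_x / n) / (m*(y) pi_x) - 1`, evaluated by Simpson
#' integration on the grid. For the HD family this equals the squared-root
#' difference form `int sum_x (sqrt(f* n_x / n) - sqrt(m* pi_x))^2 dy`
#' (times 2) up to grid accuracy.
#'
#' @param sample A [mixed_sample()].
#' @param model A [mixed_model()].
#' @param family A [disparity_family()] or id string.
#' @param H Bandwidth matrix (default: [estimate_bandwidth()]).
#' @param grid An [integration_grid()] (default: built from the sample).
#' @param f_star Optional precomputed [smooth_data_density()] values.
#' @return The disparity value (scalar).
#' @export
mixed_objective <- function(sample, model, family, H = NULL, grid = NULL,
                            f_star = NULL) {
  sample <- as_mixed_sample(sample)
  family <- as_disparity_family(family)
  if (is.null(H)) H <- estimate_bandwidth(sample)
  if (is.null(grid)) grid <- integration_grid(sample, H)
  if (is.null(f_star)) f_star <- smooth_data_density(sample, H, grid)
  shares <- sample$group_counts / sample$n
  if (any(model$pi <= 0 & shares > 0)) {
    stop("`pi` must be strictly positive on observed categories.")
  }
  m_star <- pmax(smooth_model_density(model, H, grid), 1e-300)
  total <- 0
  for (k in seq_along(shares)) {
    delta <- f_star * (shares[k] / (m_star * model$pi[k])) - 1
    total <- total + model$pi[k] *
      sum(grid$w_full * g_value(family, delta) * m_star)
  }
  total
}

default_mixed_options <- function(options = list()) {
  utils::modifyList(
    list(grid_nodes = 41, restarts = 5L, maxit = 300L, grad_tol = 1e-6,
         rel_tol = 1e-12, polish = TRUE, logit_bound = 30),
    options
  )
}

mixed_obj_env <- function(f_star, shares, mu_dim, var_diag, grid, family) {
  K <- length(shares)
  nodes_mat <- grid_node_matrix(grid)
  w <- grid$w_full
  sd_diag <- sqrt(var_diag)
  unpack <- function(theta) {
    list(pi = softmax_ref(theta[seq_len(K - 1)]),
         mu = theta[K - 1 + seq_len(mu_dim)])
  }
  mstar_of <- function(mu) {
    v <- lapply(seq_len(mu_dim), function(j) {
      stats::dnorm(grid$nodes[[j]], mean = mu[j], sd = sd_diag[j])
    })
    pmax(tensor_vec(v), 1e-300)
  }
  obj <- function(theta) {
    par <- unpack(theta)
    ms <- mstar_of(par$mu)
    total <- 0
    for (k in seq_len(K)) {
      delta <- f_star * (shares[k] / (ms * par$pi[k])) - 1
      total <- total + par$pi[k] * sum(w * g_value(family, delta) * ms)
    }
    total
  }
  grad <- function(theta) {
    par <- unpack(theta)
    ms <- mstar_of(par$mu)
    gpi <- numeric(K)
    gmu <- numeric(mu_dim)
    for (k in seq_len(K)) {
      a <- raf_raw(family, f_star * (shares[k] / (ms * par$pi[k])) - 1)
      wam <- w * a * ms
      gpi[k] <- -sum(wam)
      for (j in seq_len(mu_dim)) {
        gmu[j] <- gmu[j] - par$pi[k] *
          sum(wam * (nodes_mat[, j] - par$mu[j])) / var_diag[j]
      }
    }
    lp <- par$pi * (gpi - sum(gpi * par$pi))
    c(lp[-K], gmu)
  }
  list(obj = obj, grad = grad, unpack = unpack)
}

#' Minimum disparity fit for mixed-scale data
#'
#' Estimates the category probabilities `pi` and the normal mean `mu` by
#' minimising the kernel-smoothed disparity between the data density and
#' the transparently smoothed model `N(mu, model_cov + H)`, subject to
#' `sum(pi) = 1`. The covariance of the continuous part is treated as known
#' (identity by default) and the bandwidth is estimated once from the data
#' and held fixed.
#'
#' Initial values default to uniform random `pi` (normalised) and `mu_j`
#' uniform between the first and third sample quartiles of dimension `j`;
#' up to `options$restarts` fresh starts are tried on failure.
#'
#' @param sample A [mixed_sample()] or data frame (first column = label).
#' @param family A [disparity_family()] or id string (default `"HD"`).
#' @param init Optional [mixed_model()] starting point.
#' @param options List: `grid_nodes` (default 41; use 21 for Monte-Carlo
#'   runs), `restarts` (5), `maxit` (300), `grad_tol` (1e-6), `polish`
#'   (TRUE), plus optional `bandwidth`, `grid`, `model_cov`.
#' @return An object of class `mixed_disparity_fit` with elements `pi`,
#'   `mu`, `model_cov`, `H`, `objective`, `converged`, `n_iter`, `family`,
#'   `levels`, `grid` and the fitted sample.
#' @examples
#' set.seed(7)
#' dat <- gen_mixed(mixed_scenario(mu = c(0, 0)), N = 150)
#' fit <- fit_mixed(dat, "HD", options = list(grid_nodes = 21))
#' tidy(fit)
#' @export
fit_mixed <- function(sample, family = disparity_family("HD"), init = NULL,
                      options = list()) {
  sample <- as_mixed_sample(sample)
  family <- as_disparity_family(family)
  opts <- default_mixed_options(options)
  K <- length(sample$levels)
  d <- sample$d
  if (K < 2) stop("Need at least two categories.")
  if (sample$n < 10) stop("Need at least 10 observations.")
  model_cov <- if (is.null(opts[["model_cov"]])) diag(d) else as.matrix(opts[["model_cov"]])
  if (!is_diagonal(model_cov)) stop("The fitting path assumes a diagonal known covariance.")
  H <- if (is.null(opts[["bandwidth"]])) estimate_bandwidth(sample) else as.matrix(opts[["bandwidth"]])
  grid <- if (is.null(opts[["grid"]])) {
    integration_grid(sample, H, nodes = opts$grid_nodes)
  } else {
    opts[["grid"]]
  }
  f_star <- smooth_data_density(sample, H, grid)
  shares <- sample$group_counts / sample$n
  var_diag <- diag(model_cov) + diag(as.matrix(H))
  fe <- mixed_obj_env(f_star, shares, d, var_diag, grid, family)

  q13 <- apply(sample$values, 2, stats::quantile, probs = c(0.25, 0.75))
  make_init <- function() {
    p0 <- stats::runif(K)
    mu0 <- stats::runif(d, q13[1, ], q13[2, ])
    c(probs_to_logits(p0 / sum(p0), opts$logit_bound), mu0)
  }
  theta0 <- if (!is.null(init)) {
    c(probs_to_logits(init$pi, opts$logit_bound), init$mu)
  } else {
    make_init()
  }
  lower <- c(rep(-opts$logit_bound, K - 1), rep(-Inf, d))
  upper <- c(rep(opts$logit_bound, K - 1), rep(Inf, d))

  best <- NULL
  for (try in seq_len(opts$restarts + 1L)) {
    res <- tryCatch(
      stats::nlminb(theta0, fe$obj, gradient = fe$grad, lower = lower, upper = upper,
                    control = list(iter.max = opts$maxit, eval.max = 4 * opts$maxit,
                                   rel.tol = opts$rel_tol)),
      error = function(e) NULL
    )
    if (!is.null(res)) {
      theta <- res$par
      if (opts$polish) theta <- newton_polish(theta, fe$grad, max_steps = 6L, tol = 1e-9)
      gnorm <- max(abs(fe$grad(theta)))
      cand <- list(theta = theta, objective = fe$obj(theta), grad_norm = gnorm,
                   n_iter = res$iterations, converged = gnorm < opts$grad_tol)
      if (is.null(best) || cand$objective < best$objective ||
          (cand$converged && !best$converged)) best <- cand
      if (best$converged) break
    }
    theta0 <- make_init()
  }
  if (is.null(best)) stop("Mixed-model optimiser failed on every restart.")
  par <- fe$unpack(best$theta)
  fit <- structure(
    list(pi = par$pi, mu = par$mu, model_cov = model_cov, H = H,
         objective = best$objective, converged = best$converged,
         n_iter = best$n_iter, grad_norm = best$grad_norm,
         family = family, levels = sample$levels, shares = shares,
         n = sample$n, grid = grid, sample = sample),
    class = "mixed_disparity_fit"
  )
  if (!best$converged) {
    cond <- structure(
      class = c("mindisp_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "fit_mixed did not reach stationarity (max |grad| = %.2e) after restarts; best iterate attached as `fit`.",
        best$grad_norm), call = sys.call(-1), fit = fit)
    )
    stop(cond)
  }
  fit
}

#' @export
print.mixed_disparity_fit <- function(x, ...) {
  cat("<mixed_disparity_fit> family = ", x$family$id,
      ", objective = ", format(x$objective, digits = 6),
      ", converged = ", x$converged, "\n", sep = "")
  cat("  pi: ", paste(format(x$pi, digits = 4), collapse = " "), "\n", sep = "")
  cat("  mu: ", paste(format(x$mu, digits = 4), collapse = " "), "\n", sep = "")
  invisible(x)
}
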