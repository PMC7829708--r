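#' Simulation scenarios for contingency tables
#'
#' Cell-probability matrices for the six multinomial table scenarios used in
#' the Monte-Carlo study:
#'
#' * `Ia`  balanced 5 x 5 design, all cells 1/25;
#' * `IIa` imbalanced 5 x 5 design with a structural zero at cell (1, 1),
#'   row marginals (0.04, 0.20, 0.20, 0.20, 0.36) and column marginals
#'   (0.16, 0.17, 0.17, 0.25, 0.25). The within-table construction
#'   (product of the marginals with the (1, 1) mass transferred to cells
#'   (1, 5) and (5, 1) and removed from (5, 5)) is a reconstruction that
#'   preserves those marginals exactly while forcing `P[1, 1] = 0`;
#' * `Ib`  balanced 2 x 3 design, all cells 1/6;
#' * `IIb` imbalanced 2 x 3 design with structural zeros at (1, 2) and
#'   (2, 1); given the marginals (0.6677, 0.3323) and
#'   (0.3342, 0.1660, 0.4998) the two zeros determine every cell, a
#'   reconstruction of the generator;
#' * `III` independence table: rows (0.2, 0.2, 0.2, 0.2, 0.2) times columns
#'   (0.1472, 0.2365, 0.3196, 0.2370, 0.0597);
#' * `IV`  independence table: rows (0.04, 0.20, 0.20, 0.20, 0.36) times
#'   columns (0.2171, 0.1676, 0.2347, 0.1178, 0.2628).
#'
#' @param id Scenario id: `"Ia"`, `"IIa"`, `"Ib"`, `"IIb"`, `"III"`, `"IV"`.
#' @return An object of class `table_scenario` with the cell matrix `P` and
#'   the true row/column marginals.
#' @export
scenario_cell_probs <- function(id) {
  P <- switch(id,
    Ia = matrix(1 / 25, 5, 5),
    Ib = matrix(1 / 6, 2, 3),
    IIa = {
      rowm <- c(0.04, 0.20, 0.20, 0.20, 0.36)
      colm <- c(0.16, 0.17, 0.17, 0.25, 0.25)
      Q <- outer(rowm, colm)
      t11 <- Q[1, 1]
      Q[1, 1] <- 0
      Q[1, 5] <- Q[1, 5] + t11
      Q[5, 1] <- Q[5, 1] + t11
      Q[5, 5] <- Q[5, 5] - t11
      Q
    },
    IIb = matrix(c(0.3342, 0, 0, 0.1660, 0.3335, 0.1663), 2, 3),
    III = outer(rep(0.2, 5), c(0.1472, 0.2365, 0.3196, 0.2370, 0.0597)),
    IV = outer(c(0.04, 0.20, 0.20, 0.20, 0.36),
               c(0.2171, 0.1676, 0.2347, 0.1178, 0.2628)),
    stop("Unknown table scenario '", id, "'.")
  )
  stopifnot(abs(sum(P) - 1) < 1e-12, all(P >= 0))
  structure(
    list(id = id, dims = dim(P), P = P,
         row_marg = rowSums(P), col_marg = colSums(P)),
    class = "table_scenario"
  )
}

#' @export
print.table_scenario <- function(x, ...) {
  cat("<table_scenario> ", x$id, " (", x$dims[1], " x ", x$dims[2], ")\n", sep = "")
  print(round(x$P, 4))
  invisible(x)
}

#' Draw a multinomial contingency table
#'
#' One table with fixed total `N`: `vec(counts) ~ Multinomial(N, vec(P))`.
#' Structural-zero cells have probability exactly zero and never receive
#' counts.
#'
#' @param scenario A [scenario_cell_probs()] object or scenario id string.
#' @param N Total sample size.
#' @return A [contingency_table()]. Uses the current RNG state.
#' @export
gen_table <- function(scenario, N) {
  if (is.character(scenario)) scenario <- scenario_cell_probs(scenario)
  stopifnot(N >= 1)
  counts <- matrix(stats::rmultinom(1, N, as.vector(scenario$P)),
                   scenario$dims[1], scenario$dims[2])
  contingency_table(counts)
}

#' Mixed-scale simulation scenario
#'
#' The data-generating design of the mixed-scale study: a 3-level ordinal
#' `X` with probabilities (1/3, 1/3, 1/3), obtained by cutting a latent
#' standard normal at its tertiles, generated jointly with
#' `Y ~ MVN(mu, I)` through the overall latent correlation matrix with
#' polyserial correlation `rho` between the ordinal's latent variate and
#' each `Y` component. Contamination replaces a Bernoulli(`1 - alpha`)
#' subset of the continuous part by draws from `MVN(mu_c, I)`.
#'
#' @param mu True mean vector of the continuous part (default `c(0, 0, 0)`).
#' @param rho Polyserial correlation `rho_ON` in `[0, 0.2]` typically.
#' @param alpha Proportion of clean observations in `(0, 1]` (1 = none
#'   contaminated).
#' @param mu_c Contamination mean (default `c(3, 3, 3)`).
#' @param pi True category probabilities (default equal thirds).
#' @return An object of class `mixed_scenario`.
#' @export
mixed_scenario <- function(mu = c(0, 0, 0), rho = 0, alpha = 1,
                           mu_c = rep(3, length(mu)), pi = NULL) {
  d <- length(mu)
  if (is.null(pi)) pi <- rep(1 / 3, 3)
  K <- length(pi)
  if (alpha <= 0 || alpha > 1) stop("`alpha` must lie in (0, 1].")
  Sigma <- diag(d + 1)
  Sigma[1, -1] <- rho
  Sigma[-1, 1] <- rho
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("Latent correlation matrix is not positive-definite.")
  structure(
    list(mu = mu, rho = rho, alpha = alpha, mu_c = mu_c, pi = pi,
         K = K, d = d, Sigma = Sigma,
         cuts = stats::qnorm(cumsum(pi)[-K])),
    class = "mixed_scenario"
  )
}

#' @export
print.mixed_scenario <- function(x, ...) {
  cat("<mixed_scenario> K = ", x$K, ", mu = (", paste(x$mu, collapse = ", "),
      "), rho = ", x$rho, ", alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Draw a mixed-scale sample
#'
#' Latent `(Z0, Z1, ..., Zd) ~ MVN(0, Sigma)` with unit diagonal and
#' correlation `rho` between `Z0` and each other component; `X` is the
#' tertile bin of `Z0` (equal-probability normal-quantile thresholds) and
#' `Y = mu + (Z1, ..., Zd)`. If `alpha < 1`, each observation's continuous
#' part is independently replaced with probability `1 - alpha` by a draw
#' from `MVN(mu_c, I)` (the categorical part is never contaminated).
#'
#' @param scenario A [mixed_scenario()].
#' @param N Sample size.
#' @return A [mixed_sample()]. Uses the current RNG state.
#' @export
gen_mixed <- function(scenario, N) {
  stopifnot(inherits(scenario, "mixed_scenario"), N >= 1)
  d <- scenario$d
  L <- chol(scenario$Sigma)
  Z <- matrix(stats::rnorm(N * (d + 1)), N, d + 1) %*% L
  x <- findInterval(Z[, 1], scenario$cuts) + 1L
  y <- sweep(Z[, -1, drop = FALSE], 2, scenario$mu, `+`)
  if (scenario$alpha < 1) {
    bad <- stats::runif(N) < (1 - scenario$alpha)
    n_bad <- sum(bad)
    if (n_bad > 0) {
      y[bad, ] <- matrix(stats::rnorm(n_bad * d), n_bad, d) +
        matrix(scenario$mu_c, n_bad, d, byrow = TRUE)
    }
  }
  colnames(y) <- paste0("y", seq_len(d))
  mixed_sample(factor(x, levels = seq_len(scenario$K)), y)
}

#' Reproducible substream seeds
#'
#' Derives a deterministic 32-bit seed for a (root seed, index) pair, so
#' that each Monte-Carlo replicate gets its own named stream and results
#' are identical regardless of execution order or worker count.
#'
#' @param root Root integer seed.
#' @param index Substream index (replicate number, etc.).
#' @return A positive integer seed below 2^31.
#' @export
substream_seed <- function(root, index) {
  m <- 2147483647
  s <- (abs(as.double(root)) %% m)
  s <- (s * 48271) %% m
  s <- (s + (abs(as.double(index)) %% m) * 9973) %% m
  s <- (s * 48271) %% m
  as.integer(max(s, 1))
}
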