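#' Disparity families
#'
#' A disparity (phi-divergence) between a data distribution `d` and a model
#' distribution `m` is built from a convex function `G` of the Pearson
#' residual `delta = d/m - 1` as `sum(G(delta) * m)`. The named families are
#'
#' * `"LD"`  likelihood disparity, `G(d) = (1+d)log(1+d) - d`; its minimiser
#'   is the maximum likelihood estimator,
#' * `"HD"`  twice-squared Hellinger distance, `G(d) = 2(sqrt(1+d) - 1)^2`,
#' * `"PCS"` Pearson's chi-squared divided by two, `G(d) = d^2/2`,
#' * `"SCS"` symmetric chi-squared, `G(d) = 2d^2/(d+2)`,
#' * `"NCS"` Neyman's chi-squared divided by two, `G(d) = d^2/(2(1+d))`,
#' * `"CR:<lambda>"` the Cressie-Read power divergence with exponent
#'   `lambda` (not 0 or -1; use the named `LD` / `NCS` forms at the
#'   singular exponents, and note `HD` is `lambda = -1/2`, `PCS` is
#'   `lambda = 1`).
#'
#' Each family carries a residual adjustment function (RAF)
#' `A(d) = (1+d) G'(d) - G(d)`, standardised so that `A(0) = 0` and
#' `A'(0) = 1`, and the weight function
#' `w(d) = min(pos(A(d) + 1) / (d + 1), 1)` used in the weighted
#' estimating equations. The shape of `A` at large residuals governs
#' robustness; `A(d) = d` (the LD) reproduces the likelihood score and
#' unit weights.
#'
#' @param id Family id: one of `"LD"`, `"HD"`, `"PCS"`, `"SCS"`, `"NCS"`,
#'   `"CR"` or a string `"CR:<lambda>"`.
#' @param lambda Cressie-Read exponent, required when `id = "CR"`.
#'
#' @return An object of class `disparity_family`.
#' @examples
#' hd <- disparity_family("HD")
#' g_value(hd, 3)   # 2
#' raf(hd, 3)       # 2
#' weight(hd, 3)    # 0.75
#' @export
disparity_family <- function(id, lambda = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  if (grepl("^CR:", id)) {
    lambda <- as.numeric(sub("^CR:", "", id))
    id <- "CR"
  }
  id <- toupper(id)
  named <- c(LD = 0, HD = -0.5, PCS = 1, SCS = NA_real_, NCS = -2)
  if (id == "CR") {
    if (is.null(lambda) || !is.finite(lambda)) {
      stop("CR family requires a finite `lambda`, e.g. \"CR:0.5\".")
    }
    if (abs(lambda) < 1e-12 || abs(lambda + 1) < 1e-12) {
      stop(
        "CR(lambda) is singular at lambda = 0 and lambda = -1; ",
        "use the named families \"LD\" (lambda = 0) or \"NCS\"/Kullback-Leibler ",
        "forms instead."
      )
    }
  } else if (id %in% names(named)) {
    lambda <- named[[id]]
  } else {
    stop("Unknown disparity family '", id, "'.")
  }
  structure(
    list(id = id, lambda = lambda),
    class = "disparity_family"
  )
}

#' @export
print.disparity_family <- function(x, ...) {
  lab <- switch(x$id,
    LD = "likelihood disparity (MLE)",
    HD = "twice-squared Hellinger distance",
    PCS = "Pearson chi-squared / 2",
    SCS = "symmetric chi-squared",
    NCS = "Neyman chi-squared / 2",
    CR = sprintf("Cressie-Read power divergence (lambda = %g)", x$lambda)
  )
  cat("<disparity_family> ", x$id, ": ", lab, "\n", sep = "")
  invisible(x)
}

as_disparity_family <- function(x) {
  if (inherits(x, "disparity_family")) x else disparity_family(x)
}

# (1+d)*log(1+d) with the 0*log(0) = 0 convention
xlogx1 <- function(delta) {
  u <- 1 + delta
  out <- numeric(length(u))
  pos <- u > 0
  out[pos] <- u[pos] * log(u[pos])
  out
}

#' Evaluate the disparity generator G
#'
#' @param family A [disparity_family()] (or id string).
#' @param delta Numeric vector of Pearson residuals, each `>= -1`. At
#'   `delta = -1` (an empty data cell against positive model mass) the
#'   right-limit value is returned; for the LD this is the continuous
#'   extension `G(-1) = 1`.
#' @return Numeric vector `G(delta)`, with `G(0) = 0`.
#' @export
g_value <- function(family, delta) {
  family <- as_disparity_family(family)
  check_delta(delta)
  switch(family$id,
    LD = xlogx1(delta) - delta,
    HD = 2 * (sqrt(1 + delta) - 1)^2,
    PCS = delta^2 / 2,
    SCS = 2 * delta^2 / (delta + 2),
    NCS = ifelse(delta == -1, Inf, delta^2 / (2 * (1 + delta))),
    CR = {
      l <- family$lambda
      ((1 + delta)^(l + 1) - 1) / (l * (l + 1))
    }
  )
}

#' Residual adjustment function A(delta)
#'
#' `A(d) = (1+d) G'(d) - G(d)`, centred and rescaled so `A(0) = 0` and
#' `A'(0) = 1`. For the LD this is the identity (the likelihood score);
#' boundedness or redescent of `A` at large `d` is what buys robustness.
#' The SCS raw RAF has slope 2 at zero and is divided by that constant.
#'
#' @inheritParams g_value
#' @return Numeric vector `A(delta)`, strictly increasing on `[-1, Inf)`.
#' @export
raf <- function(family, delta) {
  family <- as_disparity_family(family)
  check_delta(delta)
  switch(family$id,
    LD = delta,
    HD = 2 * (sqrt(1 + delta) - 1),
    PCS = delta + delta^2 / 2,
    SCS = delta * (3 * delta + 4) / (delta + 2)^2,
    NCS = ifelse(delta == -1, -Inf, delta / (1 + delta)),
    CR = {
      l <- family$lambda
      ((1 + delta)^(l + 1) - 1) / (l + 1)
    }
  )
}

#' Downweighting function w(delta)
#'
#' `w(d) = min(pos(A(d) + 1) / (d + 1), 1)`, always in `[0, 1]`, equal to 1
#' at `d = 0` and identically 1 for the LD. Values below 1 mark surprising
#' cells or observations that the estimating equations downweight. At
#' `d = -1` the right-limit is used (0 for HD/SCS/NCS, 1 for LD/PCS).
#'
#' @inheritParams g_value
#' @return Numeric vector of weights in `[0, 1]`.
#' @export
weight <- function(family, delta) {
  family <- as_disparity_family(family)
  check_delta(delta)
  if (family$id == "LD") {
    return(rep(1, length(delta)))
  }
  # evaluate just inside the boundary so 0/0 limits resolve correctly
  d_eff <- pmax(delta, -1 + 1e-9)
  a <- raf(family, d_eff)
  pmin(pmax(a + 1, 0) / (d_eff + 1), 1)
}

# Unstandardised RAF (1+d) G'(d) - G(d), the exact derivative
# -d rho / d(model mass); differs from raf() by the standardising
# constant (SCS: factor 2) and, for CR, an additive constant that is
# immaterial under the unit-mass constraints but kept for exactness.
raf_raw <- function(family, delta) {
  switch(family$id,
    LD = delta,
    HD = 2 * (sqrt(1 + delta) - 1),
    PCS = delta + delta^2 / 2,
    SCS = 2 * delta * (3 * delta + 4) / (delta + 2)^2,
    NCS = ifelse(delta == -1, -Inf, delta / (1 + delta)),
    CR = {
      l <- family$lambda
      (1 + delta)^(l + 1) / (l + 1) + 1 / (l * (l + 1))
    }
  )
}

check_delta <- function(delta) {
  if (any(!is.na(delta) & delta < -1)) {
    stop("Pearson residuals must be >= -1.")
  }
  invisible(delta)
}
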