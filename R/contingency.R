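#' Contingency tables
#'
#' A two-way table of nonnegative counts with rows indexing the levels of
#' the outcome variable `Y` and columns the levels of `X`. The observed cell
#' proportions `d(y, x) = n[y, x] / N` are the nonparametric density matched
#' against the independence model `m(y) * pi(x)`.
#'
#' @param counts An `R x C` matrix of nonnegative counts, or a data frame in
#'   the wide layout (first column = Y labels, remaining columns = integer
#'   counts under the X labels).
#' @param allow_real Permit non-integer counts (used for tables patched for
#'   empty cells); by default counts must be integral.
#' @return An object of class `contingency_table` with elements `counts`,
#'   `N`, `row_totals`, `col_totals` and `props`.
#' @examples
#' tab <- contingency_table(matrix(c(2, 1, 1, 1), 2, 2))
#' tab$props
#' @export
contingency_table <- function(counts, allow_real = FALSE) {
  if (is.data.frame(counts)) {
    labels <- as.character(counts[[1]])
    counts <- as.matrix(counts[, -1, drop = FALSE])
    rownames(counts) <- labels
  }
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("Counts must be finite and nonnegative.")
  }
  if (!allow_real && any(abs(counts - round(counts)) > 1e-8)) {
    stop("Counts must be integers (use `allow_real = TRUE` for patched tables).")
  }
  n_tot <- sum(counts)
  if (n_tot < 1) stop("Total count must be at least 1.")
  if (is.null(rownames(counts))) rownames(counts) <- paste0("y", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("x", seq_len(ncol(counts)))
  structure(
    list(
      counts = counts,
      N = n_tot,
      row_totals = rowSums(counts),
      col_totals = colSums(counts),
      props = counts / n_tot
    ),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> ", nrow(x$counts), "x", ncol(x$counts),
      ", N = ", format(x$N), "\n", sep = "")
  print(x$counts)
  invisible(x)
}

as_contingency_table <- function(x, allow_real = FALSE) {
  if (inherits(x, "contingency_table")) x else contingency_table(x, allow_real)
}

#' Read a contingency table from CSV
#'
#' Expects a header row carrying the X labels and a first column of Y
#' labels; cells must be nonnegative integers.
#'
#' @param path Path to the CSV file.
#' @return A [contingency_table()].
#' @export
read_table_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  contingency_table(df)
}

#' Write a contingency table to CSV
#'
#' @param table A [contingency_table()] or count matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(table, path) {
  table <- as_contingency_table(table, allow_real = TRUE)
  df <- data.frame(y = rownames(table$counts), table$counts, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Independence model for a two-way table
#'
#' The product model `m(y, x) = row_probs[y] * col_probs[x]`, the model the
#' disparities are minimised over; both probability vectors live on the
#' simplex.
#'
#' @param row_probs Probabilities of the Y levels (sum to 1).
#' @param col_probs Probabilities of the X levels (sum to 1).
#' @param tol Tolerance on the unit-sum checks.
#' @return An object of class `independence_model`.
#' @export
independence_model <- function(row_probs, col_probs, tol = 1e-8) {
  row_probs <- as.numeric(row_probs)
  col_probs <- as.numeric(col_probs)
  for (p in list(row_probs, col_probs)) {
    if (any(p < -tol) || any(p > 1 + tol)) stop("Probabilities must lie in [0, 1].")
    if (abs(sum(p) - 1) > tol) stop("Probabilities must sum to 1.")
  }
  structure(
    list(row_probs = pmin(pmax(row_probs, 0), 1),
         col_probs = pmin(pmax(col_probs, 0), 1)),
    class = "independence_model"
  )
}

#' @export
print.independence_model <- function(x, ...) {
  cat("<independence_model>\n  m(y):  ", paste(format(x$row_probs, digits = 4), collapse = " "),
      "\n  pi(x): ", paste(format(x$col_probs, digits = 4), collapse = " "), "\n", sep = "")
  invisible(x)
}

cell_probs <- function(model) outer(model$row_probs, model$col_probs)

#' Pearson residuals of a table against an independence model
#'
#' `delta(y, x) = n[y, x] / (N * m(y) * pi(x)) - 1`, in `[-1, Inf)`, zero
#' under a perfect fit. Cells with zero count and zero model mass get
#' `delta = 0`; a positive count over zero model mass is an error (infinite
#' residual).
#'
#' @param table A [contingency_table()] or count matrix.
#' @param model An [independence_model()].
#' @param family Disparity family used to fill the weight matrix
#'   (default LD, i.e. unit weights).
#' @return A list of class `residual_field` with matrices `delta` and
#'   `weights`.
#' @export
pearson_residuals_table <- function(table, model, family = disparity_family("LD")) {
  table <- as_contingency_table(table, allow_real = TRUE)
  family <- as_disparity_family(family)
  m <- cell_probs(model)
  d <- table$props
  delta <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  bad <- m <= 0 & d > 0
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "Positive count over zero model mass in cell (%d, %d): residual is infinite.",
      idx[1], idx[2]
    ))
  }
  ok <- m > 0
  delta[ok] <- d[ok] / m[ok] - 1
  w <- matrix(weight(family, as.vector(delta)), nrow(d), dimnames = dimnames(d))
  structure(list(delta = delta, weights = w, family = family$id),
            class = "residual_field")
}

#' Disparity between a table and an independence model
#'
#' `rho(d, m) = sum G(delta(y, x)) * m(y) * pi(x)`, nonnegative and zero iff
#' the observed proportions match the model. For the HD family this equals
#' `2 * sum (sqrt(d) - sqrt(m))^2` cellwise.
#'
#' @inheritParams pearson_residuals_table
#' @param family A [disparity_family()] or id string.
#' @return The disparity value (scalar).
#' @export
table_objective <- function(table, model, family) {
  table <- as_contingency_table(table, allow_real = TRUE)
  family <- as_disparity_family(family)
  res <- pearson_residuals_table(table, model)
  m <- cell_probs(model)
  g <- g_value(family, as.vector(res$delta))
  # zero model mass cells contribute G(0) * 0 = 0
  sum(g * as.vector(m))
}

#' Replace empty cells before likelihood-disparity fitting
#'
#' For the LD only, exact-zero counts are set to `1e-8` so that the
#' Kullback-Leibler objective and its score remain well behaved on tables
#' with structural zeros; all other families are returned unchanged.
#'
#' @param table A [contingency_table()] or count matrix.
#' @param family A [disparity_family()] or id string.
#' @return A `contingency_table` (real-valued counts when patched).
#' @export
patch_zero_cells <- function(table, family) {
  table <- as_contingency_table(table, allow_real = TRUE)
  family <- as_disparity_family(family)
  if (family$id != "LD" || !any(table$counts == 0)) {
    return(table)
  }
  counts <- table$counts
  counts[counts == 0] <- 1e-8
  contingency_table(counts, allow_real = TRUE)
}

#' Weighted update of the column probabilities
#'
#' One explicit step of the alternating algorithm for the weighted
#' estimating equations: `pi(x)` is the weighted column share
#' `sum_y w * n / sum_xy w * n`. With unit weights it reduces to the
#' observed column proportions (the MLE of `pi`).
#'
#' @param table A [contingency_table()] or count matrix.
#' @param weights A weight matrix in `[0, 1]` (or a `residual_field`).
#' @return A probability vector over the columns.
#' @export
pi_update <- function(table, weights) {
  table <- as_contingency_table(table, allow_real = TRUE)
  if (inherits(weights, "residual_field")) weights <- weights$weights
  weights <- as.matrix(weights)
  stopifnot(all(dim(weights) == dim(table$counts)))
  wn <- weights * table$counts
  tot <- sum(wn)
  if (tot <= 0) stop("Degenerate weights: all weighted counts are zero.")
  unname(colSums(wn) / tot)
}

#' Closed-form maximum likelihood fit of the independence model
#'
#' The MLE of the independence model is the product of the observed
#' marginal proportions; it coincides with the LD minimiser.
#'
#' @param table A [contingency_table()] or count matrix.
#' @return An [independence_model()].
#' @export
mle_table <- function(table) {
  table <- as_contingency_table(table, allow_real = TRUE)
  independence_model(table$row_totals / table$N, table$col_totals / table$N)
}
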