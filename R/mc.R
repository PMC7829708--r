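#' Monte-Carlo study of table estimators
#'
#' Repeats generate-table / patch-empty-cells / fit for each requested
#' disparity family and summarises the per-parameter estimate means,
#' standard deviations, Monte-Carlo standard errors and absolute biases,
#' plus the overall absolute bias `sum_l |mean(theta_hat_l) - theta_0l|`.
#' Each replicate draws its data from a named substream of the root seed,
#' so runs are bit-reproducible and order-independent; failed fits are
#' retried once with a fresh start and otherwise counted (a summary with
#' more than 5% failures is flagged invalid).
#'
#' @param scenario A [scenario_cell_probs()] object or id string.
#' @param families Character vector of family ids (default all four study
#'   distances).
#' @param N Total table count per replicate.
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Root seed.
#' @param options Solver options forwarded to [fit_table()].
#' @return An object of class `mc_summary`: tibbles `results` (per
#'   parameter) and `overall` (per family), the raw `estimates`, and the
#'   `config`.
#' @examples
#' run_mc_table("Ia", families = "HD", N = 200, reps = 5, seed = 1)
#' @export
run_mc_table <- function(scenario, families = c("LD", "HD", "PCS", "SCS"),
                         N, reps, seed, options = list()) {
  if (is.character(scenario)) scenario <- scenario_cell_probs(scenario)
  stopifnot(reps >= 1, N >= 1)
  R <- scenario$dims[1]; C <- scenario$dims[2]
  par_names <- c(paste0("m", seq_len(R)), paste0("pi", seq_len(C)))
  true <- c(scenario$row_marg, scenario$col_marg)

  estimates <- list()
  failures <- integer(length(families))
  names(failures) <- families
  n_fam <- length(families)

  for (f in seq_len(n_fam)) {
    family <- disparity_family(families[f])
    est <- matrix(NA_real_, reps, R + C, dimnames = list(NULL, par_names))
    for (i in seq_len(reps)) {
      set.seed(substream_seed(seed, i * (n_fam + 1L)))
      tab <- gen_table(scenario, N)
      tab_f <- patch_zero_cells(tab, family)
      set.seed(substream_seed(seed, i * (n_fam + 1L) + f))
      fit <- mc_try_fit(function() fit_table(tab_f, family, options = options))
      if (is.null(fit)) {
        failures[f] <- failures[f] + 1L
      } else {
        est[i, ] <- c(fit$model$row_probs, fit$model$col_probs)
      }
    }
    estimates[[families[f]]] <- est
  }

  config <- list(kind = "table", scenario = scenario$id, families = families,
                 N = N, reps = reps, seed = seed)
  summarise_mc(estimates, true, par_names, failures, reps, config)
}

mc_try_fit <- function(fit_fun) {
  run <- function() {
    tryCatch(fit_fun(),
             mindisp_nonconvergence = function(c) NULL,
             error = function(e) NULL)
  }
  fit <- run()
  if (is.null(fit)) fit <- run() # one retry with fresh restarts
  fit
}

summarise_mc <- function(estimates, true, par_names, failures, reps, config) {
  results <- purrr::map_dfr(names(estimates), function(fam) {
    est <- estimates[[fam]]
    ok <- stats::complete.cases(est)
    mu <- unname(colMeans(est[ok, , drop = FALSE]))
    sdv <- unname(apply(est[ok, , drop = FALSE], 2, stats::sd))
    tibble::tibble(
      family = fam,
      parameter = par_names,
      true = true,
      mean = mu,
      sd = sdv,
      mc_se = sdv / sqrt(sum(ok)),
      bias = mu - true,
      abs_bias = abs(mu - true)
    )
  })
  overall <- results |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(overall_abs_bias = sum(.data$abs_bias), .groups = "drop") |>
    dplyr::mutate(
      failures = as.integer(failures[.data$family]),
      reps = reps,
      valid = .data$failures <= 0.05 * reps
    )
  structure(
    list(results = results, overall = overall, estimates = estimates,
         config = config),
    class = "mc_summary"
  )
}

#' Monte-Carlo study of the mixed-scale estimator
#'
#' Repeats generate-sample / estimate-bandwidth / fit for the mixed-scale
#' minimum disparity estimator (HD by default) and summarises per-parameter
#' means, SDs, biases (`mean(pi_hat) - pi_true`, `mean(mu_hat) - mu_true`)
#' and the overall absolute bias.
#'
#' @param scenario A [mixed_scenario()].
#' @param N Sample size per replicate.
#' @param reps Number of replicates.
#' @param seed Root seed.
#' @param family Disparity family id (default `"HD"`).
#' @param options Options forwarded to [fit_mixed()]; `grid_nodes` defaults
#'   to 21 here (the Monte-Carlo grid).
#' @return An `mc_summary` object (see [run_mc_table()]).
#' @export
run_mc_mixed <- function(scenario, N, reps, seed, family = "HD",
                         options = list()) {
  stopifnot(inherits(scenario, "mixed_scenario"), reps >= 1)
  options <- utils::modifyList(list(grid_nodes = 21), options)
  K <- scenario$K; d <- scenario$d
  par_names <- c(paste0("pi", seq_len(K)), paste0("mu", seq_len(d)))
  true <- c(scenario$pi, scenario$mu)
  fam <- disparity_family(family)

  est <- matrix(NA_real_, reps, K + d, dimnames = list(NULL, par_names))
  failures <- 0L
  for (i in seq_len(reps)) {
    set.seed(substream_seed(seed, 2L * i))
    smp <- gen_mixed(scenario, N)
    set.seed(substream_seed(seed, 2L * i + 1L))
    fit <- mc_try_fit(function() fit_mixed(smp, fam, options = options))
    if (is.null(fit)) {
      failures <- failures + 1L
    } else {
      est[i, ] <- c(fit$pi, fit$mu)
    }
  }
  estimates <- list(est)
  names(estimates) <- fam$id
  config <- list(kind = "mixed", mu = scenario$mu, rho = scenario$rho,
                 alpha = scenario$alpha, mu_c = scenario$mu_c, N = N,
                 reps = reps, seed = seed, family = fam$id,
                 grid_nodes = options$grid_nodes)
  summarise_mc(estimates, true, par_names, stats::setNames(failures, fam$id),
               reps, config)
}

#' @export
print.mc_summary <- function(x, ...) {
  cat("<mc_summary> ", x$config$kind, " study, N = ", x$config$N,
      ", reps = ", x$config$reps, ", seed = ", x$config$seed, "\n", sep = "")
  print(x$results, n = Inf)
  print(x$overall)
  invisible(x)
}

#' Write / read a Monte-Carlo summary
#'
#' Writes the per-parameter summary as CSV (one row per parameter, plus an
#' `overall` footer row per family carrying the overall absolute bias) with
#' full double precision, and a JSON sidecar (`<path>.json`) holding the
#' configuration and seed needed for an exact rerun.
#'
#' @param summary An `mc_summary`.
#' @param path Output CSV path.
#' @return `path`, invisibly. `read_summary()` returns the tibbles back.
#' @export
emit_summary <- function(summary, path) {
  stopifnot(inherits(summary, "mc_summary"))
  num <- function(x) sprintf("%.17g", x)
  body <- summary$results |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), num))
  foot <- summary$overall |>
    dplyr::transmute(
      family = .data$family, parameter = "overall",
      true = "", mean = "", sd = "", mc_se = "", bias = "",
      abs_bias = num(.data$overall_abs_bias)
    )
  utils::write.csv(rbind(as.data.frame(body), as.data.frame(foot)),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(summary$config, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname emit_summary
#' @export
read_summary <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  body <- raw[raw$parameter != "overall", ]
  foot <- raw[raw$parameter == "overall", ]
  results <- tibble::as_tibble(body) |>
    dplyr::mutate(dplyr::across(c("true", "mean", "sd", "mc_se", "bias", "abs_bias"),
                                as.numeric))
  overall <- tibble::tibble(family = foot$family,
                            overall_abs_bias = as.numeric(foot$abs_bias))
  config <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(results = results, overall = overall, config = config)
}
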