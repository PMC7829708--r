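test_that("closed-form marginal MLE matches examples and the LD fit", {
  tab <- contingency_table(matrix(c(2, 1, 1, 1), 2, 2, byrow = TRUE))
  mod <- mle_table(tab)
  expect_equal(mod$row_probs, c(0.6, 0.4))
  expect_equal(mod$col_probs, c(0.6, 0.4))
  expect_equal(mle_table(contingency_table(matrix(3, 4, 4)))$row_probs,
               rep(0.25, 4))
  set.seed(51)
  for (i in 1:5) {
    tab <- random_table(sample(2:4, 1), sample(2:4, 1))
    fit <- fit_table(patch_zero_cells(tab, "LD"), "LD")
    expect_lt(max(abs(fit$model$row_probs - mle_table(tab)$row_probs)), 1e-6)
  }
})

test_that("Fisher information has the binomial closed form and 1/sqrt(N) SEs", {
  mod <- independence_model(c(0.5, 0.5), c(0.5, 0.5))
  I100 <- fisher_information(mod, 100)
  expect_equal(I100["m1", "m1"], 400)  # N / (m (1 - m))
  expect_equal(I100["pi1", "pi1"], 400)
  expect_equal(I100["m1", "pi1"], 0)
  se <- function(N) sqrt(diag(solve(fisher_information(mod, N))))
  expect_equal(se(400), se(100) / 2)
  expect_error(fisher_information(independence_model(c(1, 0), c(0.5, 0.5))),
               "Boundary")
})

test_that("Monte-Carlo SDs of the HD estimator track the information bound", {
  s <- run_mc_table("Ia", families = "HD", N = 10000, reps = 400, seed = 52)
  mod <- independence_model(rep(0.2, 5), rep(0.2, 5))
  se <- sqrt(diag(solve(fisher_information(mod, 10000))))
  ratios <- s$results$sd[c(1:4, 6:9)] / se
  expect_true(all(abs(ratios - 1) < 0.15))
})

test_that("the LD influence direction is the derivative of the marginals", {
  set.seed(53)
  tab <- random_table(3, 3, N = 400)
  inf <- influence_curve(tab, "LD", point = c(2, 3))
  # marginals are linear functionals: direction = indicator - marginal
  expected <- c((1:3 == 2) - tab$row_totals / tab$N,
                (1:3 == 3) - tab$col_totals / tab$N)
  expect_equal(unname(inf$direction), unname(expected), tolerance = 1e-5)
})

test_that("at the model the HD influence equals the MLE influence", {
  mod <- independence_model(c(0.6, 0.4), c(0.55, 0.45))
  d <- outer(mod$row_probs, mod$col_probs)
  tab <- contingency_table(d * 1000, allow_real = TRUE)
  info <- fisher_information(mod, N = 1)
  for (pt in list(c(1, 2), c(2, 1))) {
    inf <- influence_curve(tab, "HD", point = pt)
    free <- solve(info, mindisp:::independence_score(mod, pt[1], pt[2]))
    full <- c(free["m1"], -free["m1"], free["pi1"], -free["pi1"])
    expect_equal(unname(inf$direction), unname(full), tolerance = 1e-3)
    expect_lt(inf$extrapolation_error, 1e-3)
  }
})

test_that("contaminating mirrored cells of a symmetric table mirrors the influence", {
  tab <- contingency_table(matrix(c(10, 4, 4, 10), 2, 2))
  i12 <- influence_curve(tab, "HD", point = c(1, 2))
  i21 <- influence_curve(tab, "HD", point = c(2, 1))
  # swapping rows and columns maps one contamination into the other
  expect_equal(unname(i12$direction[c(2, 1, 4, 3)]), unname(i21$direction),
               tolerance = 1e-4)
})

test_that("weight reports rank surprising cells first", {
  set.seed(54)
  clean <- contingency_table(matrix(25, 3, 3))
  fit_clean <- fit_table(clean, "HD")
  expect_true(all(weight_report(fit_clean)$weight > 0.999))

  # against the hypothesized (uniform) model an inflated cell has the
  # largest residual, and the weight decreases monotonically in delta > 0
  counts <- matrix(10, 3, 3)
  counts[2, 3] <- 100
  uniform <- independence_model(rep(1 / 3, 3), rep(1 / 3, 3))
  res <- pearson_residuals_table(contingency_table(counts), uniform, "HD")
  expect_equal(unname(which(res$delta == max(res$delta), arr.ind = TRUE)[1, ]),
               c(2, 3))
  pos <- res$delta[res$delta > 0]
  expect_equal(order(res$weights[res$delta > 0]), order(-pos))
  expect_equal(min(res$weights), res$weights[2, 3])

  fit <- fit_table(contingency_table(counts), "HD")
  rep1 <- weight_report(fit)
  expect_true(all(diff(rep1$weight) >= 0))

  fit_ld <- fit_table(patch_zero_cells(contingency_table(counts), "LD"), "LD")
  expect_true(all(weight_report(fit_ld)$weight == 1))

  # permutation equivariance under simultaneous relabelling
  perm_r <- c(3, 1, 2); perm_c <- c(2, 3, 1)
  set.seed(55)
  fitp <- fit_table(contingency_table(counts[perm_r, perm_c]), "HD")
  repp <- weight_report(fitp)
  w1 <- matrix(NA_real_, 3, 3); w2 <- matrix(NA_real_, 3, 3)
  w1[cbind(rep1$y, rep1$x)] <- rep1$weight
  w2[cbind(repp$y, repp$x)] <- repp$weight
  expect_equal(w2, w1[perm_r, perm_c], tolerance = 1e-6)
})

test_that("mixed-fit weight reports flag contaminated observations", {
  set.seed(56)
  sc <- mixed_scenario(mu = c(0, 0, 0), alpha = 0.9, mu_c = c(4, 4, 4))
  smp <- gen_mixed(sc, 300)
  fit <- fit_mixed(smp, "HD", options = list(grid_nodes = 21))
  rep_m <- weight_report(fit)
  outlying <- rowSums(smp$values) > 6
  flagged <- rep_m$obs[seq_len(sum(outlying))]
  # most of the lowest-weight observations are true contaminants
  expect_gt(mean(outlying[flagged]), 0.8)
})
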