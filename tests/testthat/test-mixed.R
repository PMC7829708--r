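test_that("normal-reference bandwidth matches the plug-in formula", {
  set.seed(21)
  y <- matrix(rnorm(100), 100, 1)
  s2 <- var(y[, 1])
  expect_equal(estimate_bandwidth(y)[1, 1], (4 / (100 * 3))^(2 / 5) * s2)
  # at unit variance the squared bandwidth is (4/300)^(2/5) ~ 0.178
  expect_equal((4 / 300)^(2 / 5), 0.178, tolerance = 2e-3)

  y3 <- matrix(rnorm(300), 100, 3)
  H <- estimate_bandwidth(y3)
  expect_equal(estimate_bandwidth(3 * y3), 9 * H)
  y2 <- cbind(y3[, 1], y3[, 1] * -1)     # equal SDs
  H2 <- estimate_bandwidth(y2)
  expect_equal(H2[1, 1], H2[2, 2])
  expect_error(estimate_bandwidth(cbind(y[, 1], 0)), "Zero-variance")
  expect_error(estimate_bandwidth(y[1:2, , drop = FALSE]), "d \\+ 2")
})

test_that("composite Simpson rule is exact for cubics and normalises a normal", {
  g1 <- integration_grid(lower = 0, upper = 1, nodes = 5)
  expect_equal(simpson_integrate(g1$nodes[[1]]^3, g1), 0.25)
  gc <- integration_grid(lower = -2, upper = 3, nodes = 7)
  expect_equal(simpson_integrate(rep(1, 7), gc), 5)
  gn <- integration_grid(lower = -6, upper = 6, nodes = 121)
  expect_equal(simpson_integrate(dnorm(gn$nodes[[1]]), gn),
               pnorm(6) - pnorm(-6), tolerance = 1e-8)
  expect_error(integration_grid(lower = 0, upper = 1, nodes = 4), "odd")
})

test_that("kernel density on the grid matches pointwise and integrates to one", {
  smp <- mixed_sample(factor(1), matrix(0, 1, 3))
  g <- integration_grid(lower = rep(-5, 3), upper = rep(5, 3), nodes = 21)
  f <- smooth_data_density(smp, diag(3), g)
  f_arr <- array(f, dim = g$sizes)
  expect_equal(f_arr[11, 11, 11], (2 * pi)^(-3 / 2), tolerance = 1e-12)
  expect_true(all(f >= 0))

  set.seed(22)
  smp1 <- mixed_sample(factor(rep(1:2, 25)), matrix(rnorm(50), 50, 1))
  H <- estimate_bandwidth(smp1)
  g1 <- integration_grid(smp1, H, nodes = 101)
  f1 <- smooth_data_density(smp1, H, g1)
  expect_equal(simpson_integrate(f1, g1), 1, tolerance = 1e-3)
})

test_that("smoothed model density is the exact normal convolution", {
  mod <- mixed_model(c(0.5, 0.5), 0, model_cov = matrix(1))
  g <- integration_grid(lower = -8, upper = 8, nodes = 161)
  m <- smooth_model_density(mod, matrix(1), g)
  expect_equal(m[which(g$nodes[[1]] == 0)], 1 / sqrt(4 * pi), tolerance = 1e-12)
  # H -> 0 recovers the model density
  m0 <- smooth_model_density(mod, matrix(1e-12), g)
  expect_equal(m0, dnorm(g$nodes[[1]]), tolerance = 1e-6)
  # numerical convolution oracle on a fine 1-d grid
  h2 <- 0.3
  fine <- seq(-8, 8, length.out = 1601)
  dx <- fine[2] - fine[1]
  conv <- vapply(g$nodes[[1]], function(y) {
    sum(dnorm(y - fine, sd = sqrt(h2)) * dnorm(fine, mean = 0.4)) * dx
  }, numeric(1))
  mod2 <- mixed_model(c(0.5, 0.5), 0.4, model_cov = matrix(1))
  expect_equal(smooth_model_density(mod2, matrix(h2), g), conv, tolerance = 1e-4)
})

test_that("the HD mixed objective equals the root-difference form", {
  set.seed(23)
  smp <- gen_mixed(mixed_scenario(mu = c(0, 0)), N = 120)
  H <- estimate_bandwidth(smp)
  g <- integration_grid(smp, H, nodes = 31)
  f <- smooth_data_density(smp, H, g)
  mod <- mixed_model(c(0.3, 0.3, 0.4), c(0.1, -0.1), model_cov = diag(2))
  obj <- mixed_objective(smp, mod, "HD", H, g, f)
  mstar <- smooth_model_density(mod, H, g)
  shares <- smp$group_counts / smp$n
  direct <- sum(vapply(1:3, function(k) {
    simpson_integrate((sqrt(f * shares[k]) - sqrt(mstar * mod$pi[k]))^2, g)
  }, numeric(1))) * 2
  expect_equal(obj, direct, tolerance = 1e-8)
})

test_that("the mixed objective is invariant to relabelling groups with pi", {
  set.seed(24)
  smp <- gen_mixed(mixed_scenario(mu = c(0, 0)), N = 90)
  H <- estimate_bandwidth(smp); g <- integration_grid(smp, H, nodes = 21)
  f <- smooth_data_density(smp, H, g)
  pi0 <- c(0.2, 0.5, 0.3)
  mod <- mixed_model(pi0, c(0, 0), model_cov = diag(2))
  perm <- c(3, 1, 2)
  relab <- mixed_sample(factor(perm[as.integer(smp$labels)]), smp$values)
  mod_p <- mixed_model(pi0[order(perm)], c(0, 0), model_cov = diag(2))
  expect_equal(mixed_objective(smp, mod, "HD", H, g, f),
               mixed_objective(relab, mod_p, "HD", H, g), tolerance = 1e-12)
})

test_that("analytic gradient of the mixed objective matches finite differences", {
  set.seed(25)
  smp <- gen_mixed(mixed_scenario(mu = c(0.5, -0.5)), N = 100)
  H <- estimate_bandwidth(smp)
  g <- integration_grid(smp, H, nodes = 21)
  f <- smooth_data_density(smp, H, g)
  shares <- smp$group_counts / smp$n
  for (fam in c("HD", "LD", "SCS")) {
    fe <- mindisp:::mixed_obj_env(f, shares, 2, 1 + diag(H), g,
                                  disparity_family(fam))
    theta <- c(0.3, -0.2, 0.4, -0.3)
    gn <- vapply(seq_along(theta), function(j) {
      fd(function(z) { th <- theta; th[j] <- z; fe$obj(th) }, theta[j])
    }, numeric(1))
    expect_equal(fe$grad(theta), gn, tolerance = 1e-6, info = fam)
  }
})

test_that("LD mixed fit returns the group shares for pi", {
  set.seed(26)
  smp <- gen_mixed(mixed_scenario(mu = c(0, 0, 0)), N = 400)
  fit <- fit_mixed(smp, "LD", options = list(grid_nodes = 21))
  expect_lt(max(abs(fit$pi - smp$group_counts / smp$n)), 1e-4)
})

test_that("mixed fits are translation equivariant", {
  set.seed(27)
  smp <- gen_mixed(mixed_scenario(mu = c(0, 0)), N = 200)
  shift <- c(2.5, -1.5)
  shifted <- mixed_sample(smp$labels, sweep(smp$values, 2, shift, `+`))
  set.seed(301); fit1 <- fit_mixed(smp, "HD", options = list(grid_nodes = 21))
  set.seed(301); fit2 <- fit_mixed(shifted, "HD", options = list(grid_nodes = 21))
  expect_equal(fit2$mu, fit1$mu + shift, tolerance = 1e-5)
  expect_equal(fit2$pi, fit1$pi, tolerance = 1e-6)
})

test_that("estimation error shrinks with the sample size", {
  sc <- mixed_scenario(mu = c(0, 1))
  err <- vapply(c(100, 1000), function(N) {
    errs <- vapply(1:8, function(i) {
      set.seed(substream_seed(28, N + i))
      smp <- gen_mixed(sc, N)
      fit <- fit_mixed(smp, "HD", options = list(grid_nodes = 21))
      sum(abs(fit$mu - sc$mu)) + sum(abs(fit$pi - sc$pi))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("HD resists contamination better than the sample mean", {
  sc <- mixed_scenario(mu = c(0, 0, 0), alpha = 0.9, mu_c = c(3, 3, 3))
  bias_hd <- 0; bias_mean <- 0
  reps <- 12
  for (i in seq_len(reps)) {
    set.seed(substream_seed(29, i))
    smp <- gen_mixed(sc, 500)
    fit <- fit_mixed(smp, "HD", options = list(grid_nodes = 21))
    bias_hd <- bias_hd + mean(abs(fit$mu))
    bias_mean <- bias_mean + mean(abs(colMeans(smp$values)))
  }
  expect_lt(bias_hd / reps, bias_mean / reps)
  expect_equal(bias_mean / reps, 0.3, tolerance = 0.25)
})

test_that("mixed CSV round-trips", {
  set.seed(30)
  smp <- gen_mixed(mixed_scenario(mu = c(0, 0)), N = 25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mixed_csv(smp, path)
  back <- read_mixed_csv(path)
  expect_equal(back$values, smp$values, tolerance = 1e-12)
  expect_equal(as.integer(back$labels), as.integer(smp$labels))
})
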