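# shared fixtures and small numeric oracles, all built in code

study_families <- c("LD", "HD", "PCS", "SCS")

# random table with strictly positive expected cells
random_table <- function(R, C, N = 500) {
  P <- matrix(stats::rexp(R * C), R, C)
  P <- P / sum(P)
  contingency_table(matrix(stats::rmultinom(1, N, as.vector(P)), R, C))
}

# central finite difference
fd <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# brute-force oracle for the 2 x 2 independence fit: coarse grid then two
# local refinements around the incumbent (vectorised over the grid)
grid_oracle_2x2 <- function(tab, family) {
  d <- tab$props
  obj <- function(m1, p1) {
    total <- 0
    for (i in 1:2) {
      for (j in 1:2) {
        t <- (if (i == 1) m1 else 1 - m1) * (if (j == 1) p1 else 1 - p1)
        total <- total + g_value(family, d[i, j] / t - 1) * t
      }
    }
    total
  }
  ms <- seq(0.001, 0.999, by = 0.001)
  vals <- outer(ms, ms, obj)
  best <- arrayInd(which.min(vals), dim(vals))
  m1 <- ms[best[1]]; p1 <- ms[best[2]]
  for (step in c(1e-4, 1e-5)) {
    ms2 <- seq(max(m1 - 20 * step, 1e-4), min(m1 + 20 * step, 1 - 1e-4), by = step)
    ps2 <- seq(max(p1 - 20 * step, 1e-4), min(p1 + 20 * step, 1 - 1e-4), by = step)
    vals <- outer(ms2, ps2, obj)
    best <- arrayInd(which.min(vals), dim(vals))
    m1 <- ms2[best[1]]; p1 <- ps2[best[2]]
  }
  list(m1 = m1, p1 = p1, objective = obj(m1, p1))
}

# explicit twice-squared Hellinger forms, independent of g_value()
hd_table_direct <- function(tab, model) {
  mm <- outer(model$row_probs, model$col_probs)
  2 * sum((sqrt(tab$props) - sqrt(mm))^2)
}
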