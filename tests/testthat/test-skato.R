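# The optimal weighted-kernel region test.

test_that("Q statistic equals the dense quadratic form on random inputs", {
  set.seed(31)
  null <- fixed_binary_null(n = 10, frac_case = 0.5, seed = 31)
  for (i in 1:5) {
    G <- matrix(rbinom(50, 2, 0.3), 10, 5)
    u <- make_unit(snv = G)
    w <- runif(5, 0.5, 2)
    for (rho in c(0, 0.3, 1)) {
      R <- (1 - rho) * diag(5) + rho * matrix(1, 5, 5)
      W <- diag(w)
      r <- null$resid
      q_dense <- drop(t(r) %*% G %*% W %*% R %*% W %*% t(G) %*% r)
      expect_equal(q_statistic(u, null, w, rho), q_dense,
                   tolerance = 1e-10)
    }
    # rho = 1 is the squared weighted burden score
    Sw <- w * drop(crossprod(G, null$resid))
    expect_equal(q_statistic(u, null, w, 1), sum(Sw)^2, tolerance = 1e-10)
  }
})

test_that("a single-column unit reproduces the single-marker score test", {
  set.seed(32)
  n <- 150
  y <- rbinom(n, 1, 0.35)
  g <- rbinom(n, 2, 0.15)
  null <- fit_null(y, NULL, "binary")
  u <- make_unit(snv = matrix(g, ncol = 1))
  res <- skat_o(u, null)
  smt <- single_marker_test(g, null)
  expect_lt(abs(res$p_value - smt$p_value), 1e-6)
  # identical for every rho: the correlation structure is scalar
  expect_true(all(abs(res$p_rho - res$p_rho[1]) < 1e-12))
})

test_that("burden component is invariant to duplicating a column at half weight", {
  set.seed(33)
  null <- fixed_binary_null(n = 60, seed = 33)
  g <- rbinom(60, 2, 0.25)
  u1 <- make_unit(snv = matrix(g, ncol = 1))
  u2 <- make_unit(snv = cbind(g, g))
  q1 <- q_statistic(u1, null, 1, 1)
  q2 <- q_statistic(u2, null, c(0.5, 0.5), 1)
  expect_equal(q1, q2, tolerance = 1e-10)
})

test_that("forced single-rho p-values agree with a permutation null within 3 MC SE", {
  # six random n = 100 fixtures; the permutation oracle conditions on the
  # exact case/control split, an O(1/n) difference from the asymptotic
  # null, so a small fixed allowance accompanies the MC band
  n <- 100
  B <- 5000
  for (fix in 1:6) {
    set.seed(300 + fix)
    G <- cbind(sapply(runif(4, 0.1, 0.4), function(f) rbinom(n, 2, f)),
               sapply(runif(2, 0.1, 0.3), function(f) rbinom(n, 1, f)))
    y <- sample(rep(c(1, 0), each = n / 2))
    null <- fit_null(y, NULL, "binary")
    u <- make_unit(snv = G[, 1:4], cnv = G[, 5:6])
    cfg0 <- test_config(beta_weights = c(1, 1))   # flat weights
    w <- marker_weights(u, cfg0)
    for (rho in c(0, 0.5, 1)) {
      cfg <- unclass(cfg0); cfg$rho_grid <- rho
      p_ana <- skat_o(u, null, cfg)$p_value
      p_perm <- perm_pvalue_q(G, w, y, rho, B = B,
                              seed = 100 + fix * 10 + rho * 2)
      se <- sqrt(p_perm * (1 - p_perm) / B)
      expect_lt(abs(p_ana - p_perm), 3 * se + 0.02,
                label = sprintf("fixture %d rho = %.1f: |%.4f - %.4f|",
                                fix, rho, p_ana, p_perm))
    }
  }
})

test_that("omnibus p-values are uniform under permuted phenotypes", {
  set.seed(77)
  n <- 100
  y0 <- rep(c(1, 0), each = n / 2)
  # rare-leaning SNVs plus CNV columns whose weights are comparable, so
  # several columns contribute and the statistic is quasi-continuous
  G <- cbind(sapply(c(0.15, 0.12, 0.1, 0.08, 0.05),
                    function(f) rbinom(n, 2, f)),
             sapply(c(0.15, 0.1, 0.08), function(f) rbinom(n, 1, f)))
  u0 <- make_unit(snv = G[, 1:5], cnv = G[, 6:8])
  ps <- vapply(1:2000, function(i) {
    set.seed(3000 + i)
    y <- sample(y0)
    skat_o(u0, fit_null(y, NULL, "binary"))$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  # rejection rate at 5% is near nominal
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.02)
})

test_that("constant units give p = 1 with a warning; dispatch works", {
  null <- fixed_binary_null(n = 40, seed = 36)
  u <- make_unit(snv = matrix(1, 40, 2))
  expect_warning(res <- skat_o(u, null), "variance")
  expect_equal(res$p_value, 1)

  set.seed(37)
  G <- matrix(rbinom(40 * 3, 2, 0.3), 40, 3)
  u2 <- make_unit(snv = G[, 1:2], cnv = G[, 3, drop = FALSE] > 0 + 0)
  u2$cnv <- (G[, 3, drop = FALSE] > 0) + 0
  rb <- test_unit(u2, null, method = "burden")
  cfg <- unclass(test_config()); cfg$rho_grid <- 1
  expect_equal(rb$p_value, skat_o(u2, null, cfg)$p_value)
  expect_equal(rb$method, "burden")
  rs <- test_unit(u2, null, method = "skat")
  expect_equal(rs$rho, 0)
  # mixed unit is tested jointly: both block sizes recorded
  ro <- test_unit(u2, null)
  expect_equal(c(ro$q1, ro$q2), c(2L, 1L))
  expect_true(ro$p_value >= 0 && ro$p_value <= 1)
})

test_that("CNV columns carry a flat weight, independent of any MAF bookkeeping", {
  set.seed(38)
  u <- make_unit(snv = matrix(rbinom(60, 2, 0.2), 30, 2),
                 cnv = matrix(rbinom(60, 1, 0.5), 30, 2))
  w <- marker_weights(u, test_config())
  expect_equal(w[3:4], c(1, 1))
  w2 <- marker_weights(u, test_config(cnv_weight = 2.5))
  expect_equal(w2[3:4], c(2.5, 2.5))
  # SNV weights follow the Beta density on sample MAF
  maf <- pmin(colMeans(u$snv) / 2, 1 - colMeans(u$snv) / 2)
  expect_equal(w[1:2], dbeta(maf, 1, 25), ignore_attr = TRUE)
})
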