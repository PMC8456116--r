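# Missingness / Hardy-Weinberg QC and imputation.

test_that("HWE exact p-values match hand-derived small tables", {
  # n = 2, two minor alleles: only tables are (1 het pair) vs (hom pair)
  expect_equal(hwe_exact_pvalue(0, 2, 0), 1.0, tolerance = 1e-12)
  expect_equal(hwe_exact_pvalue(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_error(hwe_exact_pvalue(0, 0, 0), "undefined")
  expect_error(hwe_exact_pvalue(-1, 2, 0))
})

test_that("HWE exact test agrees with multinomial enumeration for all n <= 20", {
  for (n in c(2, 5, 9, 14, 20)) {
    for (m in seq(0, n)) {      # minor-allele copies up to n (maf <= 0.5)
      hs <- seq(m %% 2, min(m, 2 * n - m), by = 2)
      for (b in hs) {
        c_ <- (m - b) / 2
        a <- n - b - c_
        expect_equal(hwe_exact_pvalue(a, b, c_),
                     hwe_enum_oracle(a, b, c_),
                     tolerance = 1e-12,
                     info = sprintf("n=%d m=%d het=%d", n, m, b))
      }
    }
  }
})

test_that("qc_snv removes high-missingness and HWE-violating markers with reasons", {
  n <- 100
  set.seed(1)
  g_ok <- c(rep(0, 25), rep(1, 50), rep(2, 25))          # perfect HW
  g_hwe <- c(rep(0, 50), rep(2, 50))                     # no hets at all
  g_miss <- rbinom(n, 2, 0.3); g_miss[1:6] <- NA         # 6% missing
  mk <- data.frame(id = c("ok", "hwe", "miss"), chrom = "1",
                   pos = c(100L, 200L, 300L))
  panel <- snv_panel(sprintf("s%03d", 1:n), mk, cbind(g_ok, g_hwe, g_miss))
  qc <- qc_snv(panel, max_missing_rate = 0.05, hwe_alpha = 1e-6)
  expect_equal(qc$panel$markers$id, "ok")
  expect_setequal(qc$report$marker_id, c("hwe", "miss"))
  expect_equal(qc$report$reason[qc$report$marker_id == "miss"],
               "missing_rate")
  # (50, 0, 50) is astronomically far from HWE
  expect_lt(hwe_exact_pvalue(50, 0, 50), 1e-6)
  expect_gt(hwe_exact_pvalue(25, 50, 25), 1e-6)

  # idempotence: a clean panel passes through unchanged
  qc2 <- qc_snv(qc$panel, 0.05, 1e-6)
  expect_equal(qc2$panel$genotypes, qc$panel$genotypes)
  expect_equal(nrow(qc2$report), 0L)
})

test_that("imputation fills by marker mean (or zero) and drops void markers", {
  mk <- data.frame(id = c("a", "b"), chrom = "1", pos = c(1L, 2L))
  panel <- snv_panel(c("x", "y", "z"), mk,
                     cbind(c(0, 2, NA), c(1, 1, 0)))
  imp <- impute_missing(panel)
  expect_equal(unname(imp$genotypes[, "a"]), c(0, 2, 1.0))
  expect_equal(unname(imp$genotypes[, "b"]), c(1, 1, 0))  # identity
  imp0 <- impute_missing(panel, "zero")
  expect_equal(unname(imp0$genotypes[3, "a"]), 0)

  void <- snv_panel(c("x", "y"), mk, cbind(c(NA, NA), c(0, 1)))
  expect_warning(out <- impute_missing(void), "no observed")
  expect_equal(out$markers$id, "b")
})
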