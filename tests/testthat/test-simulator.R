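# Synthetic pool generation, the disease model and the metrics harness.

test_that("the generated pool honours the per-gene marker counts", {
  spec <- gene_pool_spec(pool_size = 50)
  pool <- generate_pool(spec, seed = 61)
  tab <- default_sim_genes()
  for (k in seq_len(nrow(tab))) {
    g <- pool$genes[k, ]
    expect_equal(sum(pool$snv$markers$chrom == g$chrom &
                       pool$snv$markers$pos >= g$start &
                       pool$snv$markers$pos <= g$end),
                 tab$q1[k], info = tab$gene_id[k])
    expect_equal(sum(incoloc:::cnv_overlaps_interval(
      pool$cnv$segments, g$chrom, g$start, g$end)),
      tab$q2[k], info = tab$gene_id[k])
  }
  # e.g. the last gene carries 20 SNVs and 10 segments
  expect_equal(sum(grepl("^LRRC63_snv", pool$snv$markers$id)), 20L)
  expect_equal(sum(grepl("^LRRC63_seg", pool$cnv$segments$id)), 10L)
  # causal pair confined to the first 0.5-kb window of the first gene
  cs <- pool$causal
  p1 <- pool$snv$markers[pool$snv$markers$id == cs$snv1, ]
  expect_lte(p1$pos, pool$genes$start[1] + 499)
  seg1 <- pool$cnv$segments[pool$cnv$segments$id == cs$cnv1, ]
  expect_equal(c(seg1$start, seg1$end),
               c(pool$genes$start[1], pool$genes$start[1] + 499))
})

test_that("genotype frequencies and LD structure follow the spec", {
  genes <- data.frame(gene_id = "g", chrom = "1", q1 = 10L, q2 = 1L)
  n <- 20000
  spec <- gene_pool_spec(genes = genes, maf_range = c(0.5, 0.5),
                         pool_size = n, causal_snv_maf = 0.5)
  pool <- generate_pool(spec, seed = 62)
  means <- colMeans(pool$snv$genotypes)
  se <- sqrt(2 * 0.5 * 0.5 / n)
  expect_true(all(abs(means - 1) < 4 * se))
  # independent markers: near-zero correlation
  cm <- cor(pool$snv$genotypes)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.05)

  spec_ld <- gene_pool_spec(genes = genes, maf_range = c(0.3, 0.3),
                            pool_size = n, causal_snv_maf = 0.3,
                            ld = list(block_size = 5, r = 0.9))
  pool_ld <- generate_pool(spec_ld, seed = 63)
  cl <- cor(pool_ld$snv$genotypes)
  within <- cl[1:5, 1:5][upper.tri(diag(5))]
  across <- cl[1:5, 6:10]
  expect_gt(min(within), 0.4)          # strong within-block correlation
  expect_lt(max(abs(across)), 0.05)    # blocks independent
  # carrier frequency of CNV segments
  expect_lt(abs(mean(pool$cnv$status) - 0.05), 4 * sqrt(0.05 * 0.95 / n))
})

test_that("the disease model recovers the baseline prevalence and effect structure", {
  spec <- gene_pool_spec(pool_size = 3000)
  pool <- generate_pool(spec, seed = 64)
  s_null <- sim_setting("A1")
  sim <- simulate_case_control(s_null, pool, n_per_group = 50, seed = 65)
  # all-null accrual: case fraction among draws estimates the prevalence
  n_cases_drawn <- 50
  expect_equal(length(sim$y), 100L)
  expect_equal(sum(sim$y), 50)
  p_hat <- sum(sim$y) / sim$n_draws   # lower bound; cases stop accruing
  expect_lt(p_hat, 0.01 + 3 * sqrt(0.01 * 0.99 / sim$n_draws))

  # direct check of the generative mean under the null
  expect_equal(plogis(qlogis(0.01)), 0.01)

  # A4: joint carriers have the largest disease odds (direction only)
  s4 <- sim_setting("A4")
  b0 <- qlogis(0.01)
  eta <- function(x, c) b0 + s4$beta[1] * x + s4$beta[2] * c +
    s4$beta[3] * x * c
  expect_gt(eta(1, 1), eta(1, 0))
  expect_gt(eta(1, 1), eta(0, 1))
  expect_gt(eta(1, 1) - eta(0, 0), 2)

  # B10: opposite-sign regions cancel exactly for joint carriers
  s10 <- sim_setting("B10")
  eta2 <- b0 + sum(s10$beta) + sum(s10$gamma)
  expect_equal(eta2, b0, tolerance = 1e-12)

  # literal-intercept audit flag: baseline probability plogis(0.01) ~ 0.5,
  # so cases accrue in far fewer draws than under the prevalence reading
  sim_lit <- simulate_case_control(s_null, pool, 1000, seed = 66,
                                   beta0_literal = TRUE)
  sim_log <- simulate_case_control(s_null, pool, 1000, seed = 66)
  expect_lt(sim_lit$n_draws * 10, sim_log$n_draws)

  # accrual budget errors are explicit
  s_rare <- sim_setting("A1", prevalence = 1e-5)
  expect_error(simulate_case_control(s_rare, pool, 200, seed = 67,
                                     max_draws = 2e4), "budget")
})

test_that("unverified placeholder settings are refused; tables match the bundle", {
  expect_error(sim_setting("B4"), "placeholder")
  expect_error(sim_setting("Z1"), "unknown")
  tab <- sim_settings()
  expect_equal(tab$beta3[tab$label == "A4"], 2)
  expect_equal(tab$gamma3[tab$label == "B10"], -1)
  bundled <- read.delim(system.file("extdata", "sim_settings.tsv",
                                    package = "incoloc"), na.strings = ".")
  expect_equal(bundled$label, tab$label)
  expect_equal(bundled$beta3, tab$beta3)
  expect_equal(bundled$gamma1, tab$gamma1)
  py <- yaml::read_yaml(system.file("extdata", "sim_gene_pool.yaml",
                                    package = "incoloc"))
  expect_equal(vapply(py$genes, `[[`, "", "gene_id"),
               default_sim_genes()$gene_id)
  expect_equal(vapply(py$genes, `[[`, 1L, "q1"), default_sim_genes()$q1)
})

test_that("the metrics harness is seed-deterministic and reports coherent rates", {
  genes <- default_sim_genes()[c(1, 4, 7), ]
  spec <- gene_pool_spec(genes = genes, pool_size = 400)
  m1 <- evaluate_methods("A1", n_per_group = 50, pool_spec = spec,
                         reps = 12, seed = 71)
  m2 <- evaluate_methods("A1", n_per_group = 50, pool_spec = spec,
                         reps = 12, seed = 71)
  expect_equal(as.data.frame(m1), as.data.frame(m2))
  expect_true(all(m1$fpr_gene >= 0 & m1$fpr_gene <= 1))
  expect_equal(m1$tnr_gene, 1 - m1$fpr_gene)
  expect_true(all(is.na(m1$tpr_gene)))          # no causal gene under A1
  expect_equal(m1$se_fpr_gene,
               sqrt(m1$fpr_gene * (1 - m1$fpr_gene) / m1$reps))

  # with signal, causal units get TPRs and TIU never beats TUU
  m3 <- evaluate_methods("A4", n_per_group = 50, pool_spec = spec,
                         reps = 12, seed = 72)
  expect_false(any(is.na(m3$tpr_gene)))
  tuu <- m3[m3$method == "tuu", ]; tiu <- m3[m3$method == "tiu", ]
  expect_lte(tiu$tpr_gene, tuu$tpr_gene)
  expect_lte(tiu$fpr_gene, tuu$fpr_gene)
})

test_that("reports round-trip and are reproducible under a fixed seed", {
  genes <- default_sim_genes()[c(2, 4), ]
  spec <- gene_pool_spec(genes = genes, pool_size = 300)
  tab <- evaluate_methods("A1", n_per_group = 40, pool_spec = spec,
                          reps = 8, seed = 73, methods = c("inco", "tuu"))
  d <- withr::local_tempdir()
  emit_report(tab, file.path(d, "m1"))
  emit_report(tab, file.path(d, "m2"))
  expect_identical(readLines(file.path(d, "m1.tsv")),
                   readLines(file.path(d, "m2.tsv")))
  back <- read_report(file.path(d, "m1"))
  expect_equal(back$fpr_gene, tab$fpr_gene, tolerance = 1e-12)
  expect_equal(back$method, tab$method)
  js <- jsonlite::read_json(file.path(d, "m1.json"))
  expect_equal(js$seed, 73)
})
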