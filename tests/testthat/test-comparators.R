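# Traditional union-union / intersection-union baselines.

test_that("single-marker score test matches the one-column region test and LRT calls", {
  set.seed(51)
  n <- 200
  y <- rbinom(n, 1, 0.4)
  g <- rbinom(n, 2, 0.3)
  null <- fit_null(y, NULL, "binary")
  smt <- single_marker_test(g, null, marker_id = "m", platform = "SNV")
  u <- make_unit(snv = matrix(g, ncol = 1))
  cfg <- unclass(test_config()); cfg$rho_grid <- 0; cfg$beta_weights <- c(1, 1)
  # unit weight: Beta(1,1) density is flat 1
  expect_lt(abs(smt$p_value - skat_o(u, null, cfg)$p_value), 1e-9)

  # agreement with a likelihood-ratio oracle on the rejection decision,
  # over a grid of crafted effect sizes
  for (b in c(0, 0.25, 0.6)) {
    set.seed(100 + b * 100)
    yy <- rbinom(n, 1, plogis(-0.5 + b * g))
    nn <- fit_null(yy, NULL, "binary")
    p_score <- single_marker_test(g, nn)$p_value
    lrt <- anova(glm(yy ~ 1, family = binomial),
                 glm(yy ~ g, family = binomial), test = "LRT")
    p_lrt <- lrt$`Pr(>Chi)`[2]
    expect_equal(p_score < 0.05, p_lrt < 0.05,
                 label = sprintf("b=%.2f score=%.3f lrt=%.3f",
                                 b, p_score, p_lrt))
  }

  # constant column: no information, p = 1
  expect_equal(single_marker_test(rep(1, n), null)$p_value, 1)
})

test_that("stage-1 union and intersection rules follow their definitions", {
  expect_true(stage1_select(c(0.01, 0.3), 0.2, "union"))
  expect_false(stage1_select(c(0.01, 0.3), 0.2, "intersection"))
  expect_true(stage1_select(0.01, 0.04, "intersection"))
  expect_true(stage1_select(0.01, 0.04, "union"))
  # a gene lacking one platform can never pass the intersection rule
  expect_false(stage1_select(c(0.001, 0.002), numeric(0), "intersection"))
  expect_true(stage1_select(c(0.001, 0.002), numeric(0), "union"))
  expect_false(stage1_select(numeric(0), numeric(0), "union"))
})

test_that("stage-2 windows are flagged by contained significant markers only", {
  pp <- random_panels(n = 20, q1 = 6, q2 = 2, seed = 52)
  gm <- build_gene_matrix(pp$snv, pp$cnv,
                          gene_annotation("G", "1", 1, 10000))
  ws <- build_window_matrices(gm, 2500, 2500)
  marker_p <- setNames(rep(1, 8), c(paste0("snv", 1:6), paste0("seg", 1:2)))
  expect_false(any(stage2_windows(ws, marker_p, 0.05)))
  # make one SNV significant: exactly the windows containing it light up
  marker_p["snv3"] <- 0.001
  flags <- stage2_windows(ws, marker_p, 0.05)
  holds <- vapply(ws, function(w) "snv3" %in% w$snv_info$id, logical(1))
  expect_equal(flags, holds)
  # empty windows are never significant
  empt <- vapply(ws, function(w) w$empty, logical(1))
  expect_true(all(!flags[empt]))
})

test_that("TIU selections are a subset of TUU selections for any p-values", {
  set.seed(53)
  for (i in 1:100) {
    q1 <- sample(0:5, 1); q2 <- sample(0:3, 1)
    sp <- runif(q1); cp <- runif(q2)
    a <- runif(1, 0.01, 0.2)
    tiu <- stage1_select(sp, cp, "intersection", a)
    tuu <- stage1_select(sp, cp, "union", a)
    expect_true(!tiu || tuu)
  }
})

test_that("run_traditional shares the pipeline schema and the stage-2 union rule", {
  fx_dir <- withr::local_tempdir()
  make_fixtures(fx_dir, seed = 4)
  cfg <- load_config(file.path(fx_dir, "config.yaml"))
  for (k in c("snv_file", "cnv_segments", "cnv_status", "genes_file",
              "pheno_file"))
    cfg[[k]] <- file.path(fx_dir, basename(cfg[[k]]))
  tuu <- run_traditional(cfg, "tuu")
  tiu <- run_traditional(cfg, "tiu")
  expect_setequal(names(tuu$genes),
                  c("gene_id", "q1", "q2", "min_snv_p", "min_cnv_p",
                    "selected"))
  # set inclusion at the gene level
  expect_true(all(tiu$genes$gene_id[tiu$genes$selected] %in%
                    tuu$genes$gene_id[tuu$genes$selected]))
  # stage 2 is the same union rule: flags agree on genes both select
  both <- intersect(names(tuu$windows), names(tiu$windows))
  for (g in both)
    expect_equal(tuu$windows[[g]]$significant,
                 tiu$windows[[g]]$significant)
})
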