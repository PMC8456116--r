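# Marker-to-gene/window mapping and the combined matrix layout.

test_that("gene matrix takes SNVs by position and CNVs by any 1-bp overlap", {
  n <- 10
  set.seed(2)
  mk <- data.frame(id = paste0("s", 1:20), chrom = "1",
                   pos = c(seq(1000, 1950, by = 50)))
  snv <- snv_panel(as.character(1:n), mk,
                   matrix(rbinom(n * 20, 2, 0.2), n, 20))
  segs <- data.frame(id = c("inL", "inR", "span", "out"), chrom = "1",
                     start = c(900L, 1900L, 1L, 3000L),
                     end = c(1000L, 2500L, 100000L, 3500L))
  cnv <- cnv_panel(as.character(1:n), segs,
                   matrix(rbinom(n * 4, 1, 0.3), n, 4))
  gene <- gene_annotation("G", "1", 1000, 1950)
  gm <- build_gene_matrix(snv, cnv, gene)
  # all 20 SNVs inside (both boundaries closed), 3 of 4 segments overlap
  expect_equal(unname(unit_dims(gm)), c(20L, 3L))
  expect_equal(gm$cnv_info$id, c("inL", "inR", "span"))
  expect_equal(marker_types(gm), rep(c(1L, 2L), c(20L, 3L)))
  # columns ordered SNVs then CNVs
  expect_equal(ncol(unit_matrix(gm)), 23L)

  # SNV exactly at gene end is included; one bp past is not
  gene2 <- gene_annotation("G2", "1", 1000, 1900)
  gm2 <- build_gene_matrix(snv, cnv, gene2)
  expect_equal(unit_dims(gm2)[["q1"]], 19L)

  # minimum-overlap-fraction flag drops barely-touching segments
  gm3 <- build_gene_matrix(snv, cnv, gene, min_overlap_frac = 0.9)
  expect_false("span" %in% gm3$cnv_info$id)
})

test_that("empty units carry the empty flag and cannot be tested", {
  pp <- random_panels(seed = 10)
  gene <- gene_annotation("nowhere", "2", 1, 100)
  gm <- build_gene_matrix(pp$snv, pp$cnv, gene)
  expect_true(gm$empty)
  null <- fixed_binary_null(n = 30)
  expect_error(test_unit(gm, null), "empty")
})

test_that("window tiling follows start/step arithmetic with short last windows", {
  pp <- random_panels(n = 5, q1 = 4, q2 = 1, seed = 4)
  gene <- gene_annotation("G", "1", 1, 2000)
  gm <- build_gene_matrix(pp$snv, pp$cnv, gene)
  expect_length(build_window_matrices(gm, 500, 500), 4L)

  gene2 <- gene_annotation("G", "1", 1, 1000)
  gm2 <- build_gene_matrix(pp$snv, pp$cnv, gene2)
  ws <- build_window_matrices(gm2, 500, 250)
  expect_length(ws, 4L)
  expect_equal(as.integer(ws[[4]]$region[["start"]]), 751L)
  expect_equal(as.integer(ws[[4]]$region[["end"]]), 1000L)
})

test_that("window membership matches a brute-force interval scan", {
  for (seed in 1:5) {
    pp <- random_panels(n = 8, q1 = 12, q2 = 5, seed = seed)
    gene <- gene_annotation("G", "1", 500, 9500)
    gm <- build_gene_matrix(pp$snv, pp$cnv, gene)
    # brute force on the panel tables
    in_gene_snv <- sum(pp$snv$markers$pos >= 500 & pp$snv$markers$pos <= 9500)
    in_gene_cnv <- sum(pmin(pp$cnv$segments$end, 9500) -
                         pmax(pp$cnv$segments$start, 500) >= 0)
    expect_equal(unname(unit_dims(gm)), c(in_gene_snv, in_gene_cnv))

    ws <- build_window_matrices(gm, 1000, 1000)
    for (w in ws) {
      lo <- as.integer(w$region[["start"]]); hi <- as.integer(w$region[["end"]])
      expect_equal(ncol(w$snv),
                   sum(gm$snv_info$pos >= lo & gm$snv_info$pos <= hi))
      expect_equal(ncol(w$cnv),
                   sum(pmin(gm$cnv_info$end, hi) -
                         pmax(gm$cnv_info$start, lo) >= 0))
      expect_equal(w$empty, ncol(w$snv) + ncol(w$cnv) == 0)
    }
    # a marker never lands in two tiling windows
    counts <- table(unlist(lapply(ws, function(w) w$snv_info$id)))
    expect_true(all(counts == 1))
  }
})

test_that("a segment larger than the window lands in every window it overlaps", {
  n <- 6
  snv <- snv_panel(as.character(1:n),
                   data.frame(id = "s1", chrom = "1", pos = 100L),
                   matrix(rbinom(n, 2, 0.3), n, 1))
  cnv <- cnv_panel(as.character(1:n),
                   data.frame(id = "big", chrom = "1",
                              start = 1L, end = 2000L),
                   matrix(rbinom(n, 1, 0.4), n, 1))
  gm <- build_gene_matrix(snv, cnv, gene_annotation("G", "1", 1, 2000))
  ws <- build_window_matrices(gm, 500, 500)
  expect_true(all(vapply(ws, function(w) "big" %in% w$cnv_info$id,
                         logical(1))))
})
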