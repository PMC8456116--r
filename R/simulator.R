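# Synthetic-data generator and evaluation harness. The generator emulates
# a biobank-derived marker pool: 21 genes with fixed per-gene SNV and CNV
# segment counts, a uniform MAF spectrum that includes rare variants, low
# CNV carrier frequencies, and optional LD blocks via a latent-Gaussian
# haplotype threshold model. Disease status is drawn from a logistic model
# on one (or two) causal SNV-CNV pairs, with the causal pair placed inside
# the first moving window of the causal gene so that a causal region is
# well defined.

#' The default simulated gene pool layout
#'
#' Twenty-one genes with their chromosome and per-gene numbers of SNVs
#' (q1) and CNV segments (q2), emulating a random draw of array-genotyped
#' genes from a population biobank.
#'
#' @return data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{q1}, \code{q2}.
#' @export
default_sim_genes <- function() {
  tab <- data.frame(
    gene_id = c("GNB1", "LOC102467217", "PDE5A", "C11orf48", "CTTNBP2NL",
                "PTCH1", "SLC25A25", "CCL15-CCL14", "CD164", "IGSF22",
                "CRBN", "VAMP1", "CLEC17A", "DMGDH", "LPA", "CD276",
                "MED13L", "KBTBD12", "HLA-DQB2", "GM2A", "LRRC63"),
    chrom = c("1", "5", "4", "11", "1", "9", "9", "17", "6", "11", "3",
              "12", "19", "5", "6", "15", "12", "3", "6", "5", "13"),
    q1 = c(15L, 7L, 11L, 2L, 5L, 12L, 4L, 9L, 7L, 10L, 9L, 5L, 7L, 21L,
           24L, 7L, 19L, 22L, 19L, 12L, 20L),
    q2 = c(10L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 6L, 6L, 7L, 7L,
           8L, 8L, 9L, 9L, 10L, 10L),
    stringsAsFactors = FALSE)
  tab
}

#' Specification of the synthetic marker pool
#'
#' @param genes data.frame (\code{gene_id}, \code{chrom}, \code{q1},
#'   \code{q2}); defaults to \code{\link{default_sim_genes}}.
#' @param gene_length_bp span of each simulated gene in bp.
#' @param maf_range range of the uniform MAF spectrum for background SNVs
#'   (includes rare variants at the lower end).
#' @param carrier_prob CNV carrier probability; a scalar, or a length-2
#'   range to draw per-segment probabilities from.
#' @param cnv_length_range length range (bp) of background CNV segments;
#'   CNVs are kb-scale structural events, so segments typically span
#'   several 0.5-kb windows.
#' @param ld \code{NULL} for independent markers, or
#'   \code{list(block_size =, r =)} for latent-Gaussian LD blocks of
#'   consecutive SNVs with within-block haplotype correlation \code{r};
#'   an optional \code{cnv_r} element correlates the carrier status of a
#'   gene's CNV segments through a shared latent factor (overlapping
#'   segment calls in real data largely share carriers).
#' @param pool_size number of pool individuals to generate.
#' @param causal_snv_maf,causal_cnv_carrier frequencies of the designated
#'   causal SNV(s) and CNV segment(s).
#' @param causal_window_bp width of the window the causal SNV-CNV pair is
#'   confined to (placed at the gene start; a second pair for two-region
#'   settings is confined to the gene end).
#' @return object of class \code{gene_pool_spec}.
#' @export
gene_pool_spec <- function(genes = default_sim_genes(),
                           gene_length_bp = 2000,
                           maf_range = c(0.01, 0.5),
                           carrier_prob = 0.05,
                           cnv_length_range = c(1000, 2000),
                           ld = NULL,
                           pool_size = 2000,
                           causal_snv_maf = 0.05,
                           causal_cnv_carrier = 0.05,
                           causal_window_bp = 500) {
  stopifnot(all(c("gene_id", "chrom", "q1", "q2") %in% names(genes)),
            all(genes$q1 >= 0), all(genes$q2 >= 0),
            maf_range[1] > 0, maf_range[2] <= 0.5,
            all(carrier_prob > 0), all(carrier_prob < 1),
            pool_size > 1, gene_length_bp >= causal_window_bp)
  if (!is.null(ld))
    stopifnot(is.list(ld), ld$block_size >= 1, ld$r >= 0, ld$r < 1)
  structure(list(genes = genes, gene_length_bp = gene_length_bp,
                 maf_range = maf_range, carrier_prob = carrier_prob,
                 cnv_length_range = cnv_length_range, ld = ld,
                 pool_size = pool_size,
                 causal_snv_maf = causal_snv_maf,
                 causal_cnv_carrier = causal_cnv_carrier,
                 causal_window_bp = causal_window_bp),
            class = "gene_pool_spec")
}

# two-haplotype latent-Gaussian genotypes for one gene: within-block
# latent correlation r, marginal Binomial(2, maf_j) per marker
gen_genotypes <- function(n, mafs, ld) {
  q <- length(mafs)
  g <- matrix(0, n, q)
  blocks <- if (is.null(ld)) as.list(seq_len(q)) else
    split(seq_len(q), ceiling(seq_len(q) / ld$block_size))
  r <- if (is.null(ld)) 0 else ld$r
  for (bl in blocks) {
    thr <- stats::qnorm(1 - mafs[bl])
    for (h in 1:2) {
      f <- stats::rnorm(n)
      e <- matrix(stats::rnorm(n * length(bl)), n, length(bl))
      z <- sqrt(r) * f + sqrt(1 - r) * e
      g[, bl] <- g[, bl] + (z > matrix(thr, n, length(bl), byrow = TRUE))
    }
  }
  g
}

#' Generate the synthetic marker pool
#'
#' @param spec a \code{\link{gene_pool_spec}}.
#' @param seed integer RNG seed.
#' @return list with \code{snv} (\code{\link{snv_panel}}), \code{cnv}
#'   (\code{\link{cnv_panel}}), \code{genes}
#'   (\code{\link{gene_annotation}}) and \code{causal} (ids of the
#'   designated causal SNV/CNV pair per region).
#' @export
generate_pool <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "gene_pool_spec"))
  set.seed(seed)
  n <- spec$pool_size
  L <- spec$gene_length_bp
  wb <- spec$causal_window_bp
  samples <- sprintf("pool_%05d", seq_len(n))

  genes <- gene_annotation(
    spec$genes$gene_id, spec$genes$chrom,
    start = 1e6 + (seq_len(nrow(spec$genes)) - 1) * 10 * L,
    end = 1e6 + (seq_len(nrow(spec$genes)) - 1) * 10 * L + L - 1)

  snv_info <- list(); snv_mafs <- list()
  cnv_info <- list(); cnv_probs <- list()
  causal <- list(gene = spec$genes$gene_id[1])
  for (k in seq_len(nrow(spec$genes))) {
    gid <- spec$genes$gene_id[k]
    q1 <- spec$genes$q1[k]; q2 <- spec$genes$q2[k]
    gs <- genes$start[k]; ge <- genes$end[k]
    if (q1 > 0) {
      pos <- sort(sample.int(L, q1)) + gs - 1
      mafs <- stats::runif(q1, spec$maf_range[1], spec$maf_range[2])
      if (k == 1) {
        # causal SNV pair confined to the first / last window
        pos[1] <- gs + sample.int(wb, 1) - 1
        mafs[1] <- spec$causal_snv_maf
        if (q1 >= 2) {
          pos[2] <- ge - wb + sample.int(wb, 1)
          mafs[2] <- spec$causal_snv_maf
        }
        ord <- order(pos)
        pos <- pos[ord]; mafs <- mafs[ord]
        causal$snv1 <- paste0(gid, "_snv", which(ord == 1))
        causal$snv2 <- if (q1 >= 2) paste0(gid, "_snv", which(ord == 2))
      }
      snv_info[[k]] <- data.frame(id = paste0(gid, "_snv", seq_len(q1)),
                                  chrom = genes$chrom[k], pos = pos,
                                  stringsAsFactors = FALSE)
      snv_mafs[[k]] <- mafs
    }
    if (q2 > 0) {
      len <- round(stats::runif(q2, spec$cnv_length_range[1],
                                spec$cnv_length_range[2]))
      st <- gs + sample.int(max(L - pmin(len, L) + 1, 1), q2,
                            replace = TRUE) - 1
      en <- pmin(st + len - 1, ge)
      pr <- if (length(spec$carrier_prob) == 2)
        stats::runif(q2, spec$carrier_prob[1], spec$carrier_prob[2])
      else rep(spec$carrier_prob, q2)
      if (k == 1) {
        # causal segment = exactly the first window; second causal segment
        # (two-region settings) = exactly the last window
        st[1] <- gs; en[1] <- gs + wb - 1
        pr[1] <- spec$causal_cnv_carrier
        causal$cnv1 <- paste0(gid, "_seg1")
        if (q2 >= 2) {
          st[2] <- ge - wb + 1; en[2] <- ge
          pr[2] <- spec$causal_cnv_carrier
          causal$cnv2 <- paste0(gid, "_seg2")
        }
      }
      cnv_info[[k]] <- data.frame(id = paste0(gid, "_seg", seq_len(q2)),
                                  chrom = genes$chrom[k],
                                  start = st, end = en,
                                  stringsAsFactors = FALSE)
      cnv_probs[[k]] <- pr
    }
  }
  snv_info <- do.call(rbind, snv_info)
  cnv_info <- do.call(rbind, cnv_info)
  mafs <- unlist(snv_mafs)
  probs <- unlist(cnv_probs)

  # genotypes gene-by-gene so LD blocks never straddle genes
  gmat <- matrix(0, n, nrow(snv_info))
  off <- 0
  for (k in seq_len(nrow(spec$genes))) {
    q1 <- spec$genes$q1[k]
    if (q1 == 0) next
    gmat[, off + seq_len(q1)] <- gen_genotypes(n, mafs[off + seq_len(q1)],
                                               spec$ld)
    off <- off + q1
  }
  cnv_r <- if (!is.null(spec$ld)) spec$ld$cnv_r %||% 0 else 0
  if (cnv_r > 0) {
    # shared per-gene latent factor; marginal carrier rate preserved
    status <- matrix(0, n, nrow(cnv_info))
    off <- 0
    for (k in seq_len(nrow(spec$genes))) {
      q2 <- spec$genes$q2[k]
      if (q2 == 0) next
      f <- stats::rnorm(n)
      e <- matrix(stats::rnorm(n * q2), n, q2)
      z <- sqrt(cnv_r) * f + sqrt(1 - cnv_r) * e
      thr <- stats::qnorm(1 - probs[off + seq_len(q2)])
      status[, off + seq_len(q2)] <-
        (z > matrix(thr, n, q2, byrow = TRUE)) + 0
      off <- off + q2
    }
  } else {
    status <- matrix(stats::rbinom(n * nrow(cnv_info), 1,
                                   rep(probs, each = n)),
                     n, nrow(cnv_info))
  }

  list(snv = snv_panel(samples, snv_info, gmat),
       cnv = cnv_panel(samples, cnv_info, status),
       genes = genes, causal = causal, mafs = mafs,
       carrier_probs = probs)
}

#' Simulation settings (effect-size grids)
#'
#' Part A uses one causal region (effects \code{beta1} on the SNV carrier
#' indicator, \code{beta2} on the CNV status, \code{beta3} on their
#' product); Part B adds a second region with \code{gamma1..3}. Settings
#' whose parameter values were only published in supplementary material
#' (B4, B7, B11, B14) are listed as unverified placeholders with NA
#' effects.
#'
#' @return data.frame of all settings with their effect sizes.
#' @export
sim_settings <- function() {
  a <- data.frame(
    label = paste0("A", 1:9),
    beta1 = c(0, 0.01, 0.01, 0.01, 0.5, 0.1, 0.5, 1, 2),
    beta2 = c(0, 0.01, 0.01, 0.01, 0.5, 0.1, 0.5, 1, 2),
    beta3 = c(0, 0.01, 1, 2, 1, 0, 0, 0, 0),
    gamma1 = NA_real_, gamma2 = NA_real_, gamma3 = NA_real_,
    verified = TRUE, stringsAsFactors = FALSE)
  b_lab <- paste0("B", 1:14)
  bvals <- rbind(
    B1 = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01),
    B2 = c(0.01, 0.01, 0.5, 0.01, 0.01, 0.5),
    B3 = c(0.01, 0.01, 1, 0.01, 0.01, 1),
    B4 = rep(NA_real_, 6),
    B5 = c(0.5, 0.5, 0.01, 0.5, 0.5, 0.01),
    B6 = c(1, 1, 0.01, 1, 1, 0.01),
    B7 = rep(NA_real_, 6),
    B8 = c(1, 1, 1, 1, 1, 1),
    B9 = c(0.01, 0.01, 0.5, -0.01, -0.01, -0.5),
    B10 = c(0.01, 0.01, 1, -0.01, -0.01, -1),
    B11 = rep(NA_real_, 6),
    B12 = c(0.5, 0, 0.01, 0, 0.5, 0.01),
    B13 = c(1, 0, 0.01, 0, 1, 0.01),
    B14 = rep(NA_real_, 6))
  b <- data.frame(label = b_lab, beta1 = bvals[, 1], beta2 = bvals[, 2],
                  beta3 = bvals[, 3], gamma1 = bvals[, 4],
                  gamma2 = bvals[, 5], gamma3 = bvals[, 6],
                  verified = !is.na(bvals[, 1]), stringsAsFactors = FALSE)
  rownames(b) <- NULL
  rbind(a, b)
}

#' Look up one simulation setting
#'
#' @param label e.g. \code{"A1"} or \code{"B10"}.
#' @param prevalence baseline disease probability (intercept on the
#'   probability scale).
#' @return list with \code{label}, \code{beta}, \code{gamma} (NULL for
#'   Part A) and \code{prevalence}.
#' @export
sim_setting <- function(label, prevalence = 0.01) {
  tab <- sim_settings()
  row <- tab[tab$label == label, ]
  if (nrow(row) != 1) stop("unknown setting: ", label, call. = FALSE)
  if (!row$verified)
    stop("setting ", label, " is an unverified placeholder ",
         "(parameters not published in the main text)", call. = FALSE)
  gamma <- if (!is.na(row$gamma1)) c(row$gamma1, row$gamma2, row$gamma3)
  list(label = label, beta = c(row$beta1, row$beta2, row$beta3),
       gamma = gamma, prevalence = prevalence)
}

#' Draw a case-control sample from the disease model
#'
#' Individuals are drawn with replacement from the pool; disease status is
#' Bernoulli with logit(p) = beta0 + beta1 SNV1 + beta2 CN1 +
#' beta3 SNV1 x CN1 (plus the gamma terms of a second region, if set).
#' SNV1 is the dominant carrier indicator of the causal SNV (1 if the
#' subject carries at least one minor allele) -- the generative coding --
#' while analysis matrices keep the additive 0/1/2 coding. Accrual
#' continues until \code{n_per_group} cases and controls are collected.
#'
#' The intercept is placed on the probability scale: beta0 =
#' logit(prevalence), so that baseline P(Y=1) equals the stated
#' prevalence. \code{beta0_literal = TRUE} instead uses the prevalence
#' value itself as the intercept on the logit scale, for auditing.
#'
#' @param setting a \code{\link{sim_setting}}.
#' @param pool a pool from \code{\link{generate_pool}}.
#' @param n_per_group cases (= controls) to collect.
#' @param seed optional RNG seed.
#' @param beta0_literal see above.
#' @param max_draws accrual budget; exceeded (e.g. effect sizes driving
#'   case probability to zero) raises an error with diagnostics.
#' @return list with \code{y} (1 = case), \code{idx} (pool row of each
#'   sampled individual) and \code{n_draws}.
#' @export
simulate_case_control <- function(setting, pool, n_per_group, seed = NULL,
                                  beta0_literal = FALSE, max_draws = 5e6) {
  if (!is.null(seed)) set.seed(seed)
  b0 <- if (beta0_literal) setting$prevalence else
    stats::qlogis(setting$prevalence)
  x1 <- as.numeric(pool$snv$genotypes[, pool$causal$snv1] > 0)
  c1 <- pool$cnv$status[, pool$causal$cnv1]
  eta <- b0 + setting$beta[1] * x1 + setting$beta[2] * c1 +
    setting$beta[3] * x1 * c1
  if (!is.null(setting$gamma)) {
    if (is.null(pool$causal$snv2) || is.null(pool$causal$cnv2))
      stop("two-region setting but the pool has no second causal pair",
           call. = FALSE)
    x2 <- as.numeric(pool$snv$genotypes[, pool$causal$snv2] > 0)
    c2 <- pool$cnv$status[, pool$causal$cnv2]
    eta <- eta + setting$gamma[1] * x2 + setting$gamma[2] * c2 +
      setting$gamma[3] * x2 * c2
  }
  p <- stats::plogis(eta)
  n_pool <- length(p)
  cases <- integer(0); controls <- integer(0)
  drawn <- 0
  batch <- min(max(5000, ceiling(2.5 * n_per_group / max(mean(p), 1e-6))),
               1e6)
  while (length(cases) < n_per_group || length(controls) < n_per_group) {
    take <- min(batch, max_draws - drawn)
    if (take <= 0)
      stop("case accrual budget exceeded after ", drawn, " draws ",
           "(mean disease probability ", signif(mean(p), 3),
           "); check effect sizes vs prevalence", call. = FALSE)
    idx <- sample.int(n_pool, take, replace = TRUE)
    y <- stats::rbinom(take, 1, p[idx])
    drawn <- drawn + take
    if (length(cases) < n_per_group) cases <- c(cases, idx[y == 1])
    if (length(controls) < n_per_group) controls <- c(controls, idx[y == 0])
  }
  idx <- c(cases[seq_len(n_per_group)], controls[seq_len(n_per_group)])
  list(y = rep(c(1, 0), each = n_per_group), idx = idx, n_draws = drawn)
}

# window layout + per-window marker membership for one pool, computed once
pool_layout <- function(pool, window_size_bp = 500,
                        step_bp = window_size_bp) {
  genes <- pool$genes
  lapply(seq_len(nrow(genes)), function(k) {
    g <- genes[k, ]
    si <- which(pool$snv$markers$chrom == g$chrom &
                  pool$snv$markers$pos >= g$start &
                  pool$snv$markers$pos <= g$end)
    ci <- which(cnv_overlaps_interval(pool$cnv$segments, g$chrom,
                                      g$start, g$end))
    starts <- window_starts(g$start, g$end, step_bp)
    wins <- lapply(seq_along(starts), function(w) {
      ws <- starts[w]; we <- min(ws + window_size_bp - 1, g$end)
      wsi <- si[pool$snv$markers$pos[si] >= ws &
                  pool$snv$markers$pos[si] <= we]
      wci <- ci[cnv_overlaps_interval(
        pool$cnv$segments[ci, , drop = FALSE], g$chrom, ws, we)]
      list(start = ws, end = we, snv = wsi, cnv = wci,
           nonempty = length(wsi) + length(wci) > 0)
    })
    list(gene_id = g$gene_id, gene = g, snv = si, cnv = ci, windows = wins)
  })
}

unit_from_cols <- function(pool, idx, layout_gene, snv_cols, cnv_cols,
                           unit_id, region) {
  new_unit_matrix(
    unit_id = unit_id,
    sample_ids = as.character(seq_along(idx)),
    snv = pool$snv$genotypes[idx, snv_cols, drop = FALSE],
    cnv = pool$cnv$status[idx, cnv_cols, drop = FALSE],
    snv_info = pool$snv$markers[snv_cols, , drop = FALSE],
    cnv_info = pool$cnv$segments[cnv_cols, , drop = FALSE],
    region = region, empty = length(snv_cols) + length(cnv_cols) == 0)
}

#' Monte-Carlo evaluation of INCO and the traditional baselines
#'
#' Runs the full two-stage analyses replicate by replicate under one or
#' more simulation settings and accumulates false-positive, true-positive
#' and true-negative rates at the gene and window (region) level. Gene-
#' and region-level rates average over non-causal (or causal) units and
#' replicates; window denominators count every non-empty window of every
#' gene, whether or not its gene passed stage 1 (windows of unscreened
#' genes are simply never flagged).
#'
#' @param settings character vector of setting labels (e.g. "A1").
#' @param n_per_group cases (= controls) per replicate.
#' @param pool_spec a \code{\link{gene_pool_spec}}.
#' @param reps replicates per setting.
#' @param seed master seed; the pool and every replicate derive child
#'   seeds from it.
#' @param methods subset of \code{c("inco", "tuu", "tiu")}.
#' @param alpha_gene,alpha_window INCO stage-1/stage-2 levels.
#' @param alpha_marker per-marker level of the traditional analyses.
#' @param window_size_bp,step_bp moving-window layout.
#' @param method region-test flavor for INCO.
#' @param config a \code{\link{test_config}}.
#' @param window_scan \code{"screened"} (default): windows are only
#'   examined for genes passing the stage-1 screen (the two-stage
#'   procedure, used for power and specificity); \code{"all"}: the window
#'   scan runs on every gene, measuring the standalone size/power of the
#'   region-level test; \code{"none"}: skip window testing (gene-level
#'   metrics only, region columns NA).
#' @param keep_pvalues if TRUE, attach all INCO gene-level p-values
#'   (attribute \code{"gene_pvalues"}) for distributional checks.
#' @return a \code{MetricsTable} data.frame: one row per method x setting,
#'   with rates, Monte-Carlo standard errors and replicate counts.
#' @export
evaluate_methods <- function(settings, n_per_group,
                             pool_spec = gene_pool_spec(), reps = 200,
                             seed = 1, methods = c("inco", "tuu", "tiu"),
                             alpha_gene = 0.05, alpha_window = 0.05,
                             alpha_marker = 0.05, window_size_bp = 500,
                             step_bp = window_size_bp, method = "skat-o",
                             config = test_config(),
                             window_scan = c("screened", "all", "none"),
                             keep_pvalues = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  window_scan <- match.arg(window_scan)
  pool <- generate_pool(pool_spec, seed = child_seed(seed, 1))
  layout <- pool_layout(pool, window_size_bp, step_bp)
  n_genes <- length(layout)
  win_gene <- unlist(lapply(seq_len(n_genes), function(k)
    rep(k, length(layout[[k]]$windows))))
  win_flat <- unlist(lapply(layout, function(lg) lapply(lg$windows,
                                                        identity)),
                     recursive = FALSE)
  nonempty <- vapply(win_flat, function(w) w$nonempty, logical(1))

  rows <- list()
  pvals_keep <- list()
  for (lab in settings) {
    setting <- sim_setting(lab)
    active1 <- any(setting$beta != 0)
    active2 <- !is.null(setting$gamma) && any(setting$gamma != 0)
    causal_gene <- logical(n_genes)
    causal_gene[1] <- active1 || active2
    cs <- pool$causal
    causal_win <- vapply(seq_along(win_flat), function(i) {
      if (win_gene[i] != 1) return(FALSE)
      w <- win_flat[[i]]
      ids_s <- pool$snv$markers$id[w$snv]
      ids_c <- pool$cnv$segments$id[w$cnv]
      (active1 && (cs$snv1 %in% ids_s || cs$cnv1 %in% ids_c)) ||
        (active2 && (cs$snv2 %in% ids_s || cs$cnv2 %in% ids_c))
    }, logical(1))

    gene_hits <- sapply(methods, function(m) numeric(n_genes),
                        simplify = FALSE)
    win_hits <- sapply(methods, function(m) numeric(length(win_flat)),
                       simplify = FALSE)
    pv_gene <- if (keep_pvalues) matrix(NA_real_, reps, n_genes)

    grid <- switch(method, "skat" = 0, "burden" = 1, config$rho_grid)
    n_snv <- ncol(pool$snv$genotypes)

    for (r in seq_len(reps)) {
      sim <- simulate_case_control(setting, pool, n_per_group,
                                   seed = child_seed(seed, 1000 + r))
      idx <- sim$idx
      null <- fit_null(sim$y, NULL, "binary")

      if (any(c("tuu", "tiu") %in% methods)) {
        p_snv <- marker_tests_matrix(pool$snv$genotypes[idx, , drop = FALSE],
                                     null)
        p_cnv <- marker_tests_matrix(pool$cnv$status[idx, , drop = FALSE],
                                     null)
      }
      if ("inco" %in% methods) {
        # one score computation for the whole panel; units are submatrices
        Gall <- cbind(pool$snv$genotypes[idx, , drop = FALSE],
                      pool$cnv$status[idx, , drop = FALSE])
        sp <- score_prep(null, Gall)
        maf <- colMeans(Gall[, seq_len(n_snv), drop = FALSE]) / 2
        maf <- pmin(maf, 1 - maf)
        w_snv <- stats::dbeta(maf, config$beta_weights[1],
                              config$beta_weights[2])
        w_snv[!is.finite(w_snv)] <- 0
        w_all <- c(w_snv, rep(config$cnv_weight, ncol(Gall) - n_snv))
        Sw_all <- w_all * sp$S
        core_p <- function(cols, id) {
          if (max(abs(sp$K[cols, cols])) < 1e-12) return(1)
          skat_o_core(id, 0L, 0L, Sw_all[cols],
                      sp$K[cols, cols, drop = FALSE] *
                        tcrossprod(w_all[cols]), grid)$p_value
        }
      }
      for (k in seq_len(n_genes)) {
        lg <- layout[[k]]
        wk <- which(win_gene == k)
        if ("inco" %in% methods) {
          cols <- c(lg$snv, n_snv + lg$cnv)
          pg <- core_p(cols, lg$gene_id)
          if (keep_pvalues) pv_gene[r, k] <- pg
          sel <- pg < alpha_gene
          if (sel) gene_hits$inco[k] <- gene_hits$inco[k] + 1
          if (window_scan == "all" || (sel && window_scan == "screened")) {
            for (j in seq_along(lg$windows)) {
              w <- lg$windows[[j]]
              if (!w$nonempty) next
              pw <- core_p(c(w$snv, n_snv + w$cnv),
                           paste0(lg$gene_id, ".w", j))
              if (pw < alpha_window)
                win_hits$inco[wk[j]] <- win_hits$inco[wk[j]] + 1
            }
          }
        }
        for (m in intersect(c("tuu", "tiu"), methods)) {
          ps <- p_snv[lg$snv]; pc <- p_cnv[lg$cnv]
          sel <- stage1_select(ps, pc,
                               if (m == "tuu") "union" else "intersection",
                               alpha_marker)
          if (sel) gene_hits[[m]][k] <- gene_hits[[m]][k] + 1
          if (window_scan == "all" || (sel && window_scan == "screened")) {
            for (j in seq_along(lg$windows)) {
              w <- lg$windows[[j]]
              if (!w$nonempty) next
              if (any(p_snv[w$snv] < alpha_marker) ||
                  any(p_cnv[w$cnv] < alpha_marker))
                win_hits[[m]][wk[j]] <- win_hits[[m]][wk[j]] + 1
            }
          }
        }
      }
    }

    for (m in methods) {
      gh <- gene_hits[[m]]; wh <- win_hits[[m]]
      nc_g <- !causal_gene; cg <- causal_gene
      nc_w <- nonempty & !causal_win; cw <- nonempty & causal_win
      rate <- function(hits, mask) {
        if (!any(mask)) return(NA_real_)
        sum(hits[mask]) / (reps * sum(mask))
      }
      fpr_g <- rate(gh, nc_g)
      fpr_r <- if (window_scan == "none") NA_real_ else rate(wh, nc_w)
      tpr_g <- rate(gh, cg)
      tpr_r <- if (window_scan == "none") NA_real_ else rate(wh, cw)
      se <- function(r) if (is.na(r)) NA_real_ else
        sqrt(r * (1 - r) / reps)
      rows[[paste(lab, m)]] <- data.frame(
        setting = lab, method = m, n_per_group = n_per_group, reps = reps,
        fpr_gene = fpr_g, fpr_region = fpr_r,
        tpr_gene = tpr_g, tpr_region = tpr_r,
        tnr_gene = 1 - fpr_g, tnr_region = 1 - fpr_r,
        se_fpr_gene = se(fpr_g), se_fpr_region = se(fpr_r),
        se_tpr_gene = se(tpr_g), se_tpr_region = se(tpr_r),
        stringsAsFactors = FALSE)
    }
    if (keep_pvalues) pvals_keep[[lab]] <- pv_gene
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metrics_table", "data.frame")
  if (keep_pvalues) attr(out, "gene_pvalues") <- pvals_keep
  attr(out, "seed") <- seed
  attr(out, "alphas") <- c(gene = alpha_gene, window = alpha_window,
                           marker = alpha_marker)
  out
}

#' Write a metrics table with provenance
#'
#' Writes \code{<prefix>.tsv} (the table) and \code{<prefix>.json}
#' (table + seed, alpha levels and replicate counts).
#'
#' @param table a \code{metrics_table} from \code{\link{evaluate_methods}}.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
emit_report <- function(table, prefix) {
  tsv <- paste0(prefix, ".tsv"); js <- paste0(prefix, ".json")
  write_tsv_dialect(as.data.frame(table), tsv)
  jsonlite::write_json(
    list(seed = attr(table, "seed"),
         alphas = as.list(attr(table, "alphas")),
         metrics = as.data.frame(table)),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, js))
}

#' Read back a metrics table written by \code{\link{emit_report}}
#' @param prefix the path prefix used when writing.
#' @return the metrics data.frame.
#' @export
read_report <- function(prefix) {
  read_tsv_checked(paste0(prefix, ".tsv"), "metrics")
}
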