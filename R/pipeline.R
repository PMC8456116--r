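# Two-stage integrative co-localization: (1) map markers to genes and
# screen each gene with the joint region test; (2) scan screened genes
# with moving windows, testing the combined matrix plus SNV-only and
# CNV-only skylines per window.

#' Screening / scanning policy
#'
#' @param gene_alpha gene-level significance level.
#' @param correction multiplicity correction across genes: \code{"none"},
#'   \code{"bonferroni"} or \code{"benjamini-hochberg"}.
#' @param window_alpha window-level significance level.
#' @param window_size_bp moving-window width in bp.
#' @param step_bp window step; defaults to the window size (tiling).
#' @return object of class \code{screen_policy}.
#' @export
screen_policy <- function(gene_alpha = 0.05, correction = c(
  "none", "bonferroni", "benjamini-hochberg"),
  window_alpha = 0.05, window_size_bp = 500,
  step_bp = window_size_bp) {
  correction <- match.arg(correction)
  stopifnot(gene_alpha > 0, gene_alpha < 1,
            window_alpha > 0, window_alpha < 1,
            window_size_bp > 0, step_bp > 0)
  structure(list(gene_alpha = gene_alpha, correction = correction,
                 window_alpha = window_alpha,
                 window_size_bp = window_size_bp, step_bp = step_bp),
            class = "screen_policy")
}

adjust_p <- function(p, correction) {
  meth <- switch(correction, none = "none", bonferroni = "bonferroni",
                 "benjamini-hochberg" = "BH")
  stats::p.adjust(p, method = meth)
}

#' Stage 1: gene-level screen
#'
#' Builds the combined matrix for every gene, tests it jointly, applies
#' the declared multiplicity correction and flags genes with adjusted
#' p below \code{policy$gene_alpha}. All genes are reported, selected or
#' not; genes with no mapped marker get an NA p-value.
#'
#' @param snv,cnv marker panels (\code{cnv} may be NULL).
#' @param genes a \code{\link{gene_annotation}}.
#' @param phenotype numeric phenotype vector, aligned to the panels.
#' @param covariates optional covariate matrix/data.frame.
#' @param kind \code{"binary"} or \code{"continuous"}.
#' @param policy a \code{\link{screen_policy}}.
#' @param config a \code{\link{test_config}}.
#' @param method region-test flavor (see \code{\link{test_unit}}).
#' @param flank_bp flanking bp added around gene bodies when mapping.
#' @return data.frame with one row per gene (\code{gene_id}, \code{q1},
#'   \code{q2}, \code{p_value}, \code{p_adj}, \code{selected}, \code{rho},
#'   \code{backend}); the fitted null model is attached as attribute
#'   \code{"null"}.
#' @export
screen_genes <- function(snv, cnv, genes, phenotype, covariates = NULL,
                         kind = c("binary", "continuous"),
                         policy = screen_policy(), config = test_config(),
                         method = "skat-o", flank_bp = 0) {
  kind <- match.arg(kind)
  stopifnot(nrow(genes) >= 1)
  null <- fit_null(phenotype, covariates, kind)
  rows <- lapply(seq_len(nrow(genes)), function(k) {
    gene <- genes[k, ]
    gm <- build_gene_matrix(snv, cnv, gene, flank_bp = flank_bp)
    if (gm$empty)
      return(data.frame(gene_id = gene$gene_id, q1 = 0L, q2 = 0L,
                        p_value = NA_real_, rho = NA_real_,
                        backend = NA_character_, stringsAsFactors = FALSE))
    res <- tryCatch(test_unit(gm, null, config, method),
                    error = function(e)
                      stop("gene ", gene$gene_id, ": ", conditionMessage(e),
                           call. = FALSE))
    data.frame(gene_id = gene$gene_id, q1 = res$q1, q2 = res$q2,
               p_value = res$p_value, rho = res$rho,
               backend = res$backend, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- NA_real_
  ok <- !is.na(tab$p_value)
  tab$p_adj[ok] <- adjust_p(tab$p_value[ok], policy$correction)
  tab$selected <- !is.na(tab$p_adj) & tab$p_adj < policy$gene_alpha
  tab <- tab[, c("gene_id", "q1", "q2", "p_value", "p_adj", "selected",
                 "rho", "backend")]
  attr(tab, "null") <- null
  tab
}

#' Stage 2: moving-window co-localization scan of one gene
#'
#' Every window is tested three ways for the skyline comparison: the
#' combined SNV + CNV matrix, SNV columns only, and CNV columns only.
#' Window significance is declared on the combined p-value at
#' \code{policy$window_alpha}. Empty windows are reported as sentinel rows
#' with NA p-values so skylines keep their gaps.
#'
#' @param gene single-row \code{\link{gene_annotation}}.
#' @param snv,cnv marker panels.
#' @param null fitted null model (shared with the screen).
#' @param policy a \code{\link{screen_policy}}.
#' @param config a \code{\link{test_config}}.
#' @param method region-test flavor.
#' @param flank_bp flanking bp, as in the screen.
#' @return data.frame of skyline rows ordered by window start.
#' @export
colocalize <- function(gene, snv, cnv, null, policy = screen_policy(),
                       config = test_config(), method = "skat-o",
                       flank_bp = 0) {
  gm <- build_gene_matrix(snv, cnv, gene, flank_bp = flank_bp)
  windows <- build_window_matrices(gm, policy$window_size_bp,
                                   policy$step_bp)
  rows <- lapply(windows, function(w) {
    base <- data.frame(
      gene_id = gm$unit_id, window = w$window_index,
      start = as.integer(w$region[["start"]]),
      end = as.integer(w$region[["end"]]),
      q1 = ncol(w$snv), q2 = ncol(w$cnv),
      p_combined = NA_real_, p_snv = NA_real_, p_cnv = NA_real_,
      significant = FALSE, stringsAsFactors = FALSE)
    if (w$empty) return(base)
    base$p_combined <- test_unit(w, null, config, method)$p_value
    if (ncol(w$snv) > 0) {
      w1 <- w; w1$cnv <- w$cnv[, 0, drop = FALSE]
      w1$cnv_info <- w$cnv_info[0, , drop = FALSE]
      base$p_snv <- test_unit(w1, null, config, method)$p_value
    }
    if (ncol(w$cnv) > 0) {
      w2 <- w; w2$snv <- w$snv[, 0, drop = FALSE]
      w2$snv_info <- w$snv_info[0, , drop = FALSE]
      base$p_cnv <- test_unit(w2, null, config, method)$p_value
    }
    base$significant <- !is.na(base$p_combined) &&
      base$p_combined < policy$window_alpha
    base
  })
  do.call(rbind, rows)
}

# shared input loading for run_inco / run_traditional
load_run_inputs <- function(config) {
  snv <- read_snv_panel(config$snv_file,
                        config$snv_format %||% "tsv-matrix")
  if (isTRUE(config$qc %||% TRUE)) {
    qc <- qc_snv(snv, config$max_missing_rate %||% 0.05,
                 config$hwe_alpha %||% 1e-6)
    snv <- qc$panel
  } else qc <- NULL
  snv <- impute_missing(snv, config$impute %||% "mean")
  cnv <- if (!is.null(config$cnv_segments))
    read_cnv_panel(config$cnv_segments, config$cnv_status,
                   config$cnv_status_format %||% "wide") else NULL
  if (!is.null(cnv) && !identical(snv$sample_ids, cnv$sample_ids)) {
    m <- match(snv$sample_ids, cnv$sample_ids)
    if (anyNA(m)) stop("CNV panel missing samples present in SNV panel",
                       call. = FALSE)
    cnv <- cnv_panel(snv$sample_ids, cnv$segments,
                     cnv$status[m, , drop = FALSE])
  }
  genes <- read_gene_bed(config$genes_file)
  ph <- read_pheno(config$pheno_file, snv$sample_ids)
  pheno_col <- config$pheno_column %||% "phenotype"
  if (!pheno_col %in% names(ph))
    stop("phenotype column not found: ", pheno_col, call. = FALSE)
  covars <- NULL
  if (!is.null(config$covariate_columns) &&
      length(config$covariate_columns)) {
    missing_cov <- setdiff(config$covariate_columns, names(ph))
    if (length(missing_cov))
      stop("covariate column(s) not found: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    covars <- as.matrix(ph[, config$covariate_columns, drop = FALSE])
  }
  kind <- config$phenotype_kind %||% "binary"
  null <- fit_null(ph[[pheno_col]], covars, kind)
  list(snv = snv, cnv = cnv, genes = genes, pheno = ph, null = null,
       qc = qc, kind = kind)
}

write_run_outputs <- function(out, config, command) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_dialect(out$genes, file.path(config$out_dir, "genes.tsv"))
  for (gid in names(out$windows)) {
    sky <- out$windows[[gid]]
    sizes <- unique(sky$window_size_bp %||% NA)
    write_tsv_dialect(sky, file.path(config$out_dir,
                                     paste0("skyline_", gid, ".tsv")))
  }
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("incoloc")),
    seed = config$seed %||% NA,
    policy = config[intersect(names(config), c(
      "gene_alpha", "correction", "window_alpha", "window_size_bp",
      "window_sizes_bp", "step_bp", "marker_alpha", "method", "one_stage",
      "flank_bp", "phenotype_kind", "qc", "max_missing_rate", "hwe_alpha",
      "impute"))],
    inputs = lapply(config[intersect(names(config), c(
      "snv_file", "cnv_segments", "cnv_status", "genes_file",
      "pheno_file"))], function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' Run the full two-stage integrative co-localization analysis
#'
#' Reads the input files named in \code{config}, performs marker QC and
#' imputation, fits the null model, screens genes (stage 1) and scans the
#' selected genes with moving windows (stage 2), one skyline table per
#' window size. With \code{config$one_stage = TRUE} the screen is skipped
#' and every gene is scanned. Outputs (when \code{config$out_dir} is set):
#' \code{genes.tsv}, one \code{skyline_<gene>.tsv} per scanned gene, and
#' \code{manifest.json}. Reruns with the same config and seed are
#' byte-identical (the manifest records input digests, not timestamps).
#'
#' @param config a validated configuration list; see
#'   \code{\link{load_config}} for the schema.
#' @return invisibly, a list with \code{genes}, \code{windows} and the
#'   output directory.
#' @export
run_inco <- function(config) {
  dat <- load_run_inputs(config)
  policy <- screen_policy(
    gene_alpha = config$gene_alpha %||% 0.05,
    correction = config$correction %||% "none",
    window_alpha = config$window_alpha %||% 0.05,
    window_size_bp = (config$window_sizes_bp %||% 500)[1],
    step_bp = config$step_bp %||% (config$window_sizes_bp %||% 500)[1])
  cfg <- test_config()
  method <- config$method %||% "skat-o"
  flank <- config$flank_bp %||% 0

  screen <- screen_genes(dat$snv, dat$cnv, dat$genes, dat$pheno[[
    config$pheno_column %||% "phenotype"]],
    covariates = if (!is.null(config$covariate_columns))
      as.matrix(dat$pheno[, config$covariate_columns, drop = FALSE]),
    kind = dat$kind, policy = policy, config = cfg, method = method,
    flank_bp = flank)
  null <- attr(screen, "null")

  scan_ids <- if (isTRUE(config$one_stage)) screen$gene_id else
    screen$gene_id[screen$selected]
  sizes <- config$window_sizes_bp %||% policy$window_size_bp
  windows <- list()
  for (gid in scan_ids) {
    gene <- dat$genes[dat$genes$gene_id == gid, ]
    per_size <- lapply(sizes, function(sz) {
      pol <- policy; pol$window_size_bp <- sz
      pol$step_bp <- config$step_bp %||% sz
      sky <- colocalize(gene, dat$snv, dat$cnv, null, pol, cfg, method,
                        flank_bp = flank)
      sky$window_size_bp <- sz
      sky
    })
    windows[[gid]] <- do.call(rbind, per_size)
  }
  out <- list(genes = screen, windows = windows,
              out_dir = config$out_dir %||% NULL)
  if (!is.null(config$out_dir)) write_run_outputs(out, config, "run")
  invisible(out)
}
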