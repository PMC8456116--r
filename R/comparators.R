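# Traditional parallel integration baselines. Each platform is analyzed
# marker-by-marker; a gene passes stage 1 by the union rule (any marker
# significant) or the intersection rule (at least one significant SNV AND
# at least one significant CNV segment). Stage 2 flags any window that
# contains a stage-1-significant marker of either platform: a union rule
# by construction, hence the names traditional union-union (TUU) and
# traditional intersection-union (TIU).

#' Score test of a single marker column under the null model
#'
#' Equivalent to the region test on the one-column matrix with unit
#' weight. A constant column yields p = 1.
#'
#' @param marker_column numeric vector (one marker, all samples).
#' @param null a fitted \code{\link{fit_null}}.
#' @param marker_id,platform metadata carried into the result.
#' @return a one-row data.frame (\code{marker_id}, \code{platform},
#'   \code{p_value}).
#' @export
single_marker_test <- function(marker_column, null, marker_id = "marker",
                               platform = "SNV") {
  g <- as.numeric(marker_column)
  stopifnot(length(g) == null$n)
  sp <- score_prep(null, matrix(g, ncol = 1))
  p <- if (sp$K[1] < 1e-12) 1 else
    stats::pchisq(sp$S[1]^2 / sp$K[1], df = 1, lower.tail = FALSE)
  data.frame(marker_id = marker_id, platform = platform, p_value = p,
             stringsAsFactors = FALSE)
}

# vectorized per-column score tests for a whole matrix
marker_tests_matrix <- function(G, null) {
  v <- null$v
  VG <- G * v
  XtVG <- crossprod(null$X, VG)                       # p x m
  kdiag <- colSums(G * VG) - colSums((null$XtVX_inv %*% XtVG) * XtVG)
  S <- drop(crossprod(G, null$resid))
  p <- ifelse(kdiag < 1e-12, 1,
              stats::pchisq(S^2 / pmax(kdiag, 1e-12), df = 1,
                            lower.tail = FALSE))
  as.numeric(p)
}

#' Per-marker score tests for both platforms
#'
#' @param snv an \code{\link{snv_panel}}.
#' @param cnv a \code{\link{cnv_panel}} or NULL.
#' @param null a fitted \code{\link{fit_null}}.
#' @return data.frame (\code{marker_id}, \code{platform}, \code{p_value}).
#' @export
marker_tests <- function(snv, cnv, null) {
  out <- data.frame(marker_id = snv$markers$id,
                    platform = rep("SNV", nrow(snv$markers)),
                    p_value = marker_tests_matrix(snv$genotypes, null),
                    stringsAsFactors = FALSE)
  if (!is.null(cnv))
    out <- rbind(out, data.frame(
      marker_id = cnv$segments$id,
      platform = rep("CNV", nrow(cnv$segments)),
      p_value = marker_tests_matrix(cnv$status, null),
      stringsAsFactors = FALSE))
  out
}

#' Stage-1 gene selection by the union or intersection rule
#'
#' @param snv_p,cnv_p per-marker p-values of the gene's SNVs and CNV
#'   segments (either may be empty).
#' @param mode \code{"union"} (any marker significant) or
#'   \code{"intersection"} (a significant SNV and a significant CNV).
#' @param alpha per-marker significance level.
#' @return logical: gene selected.
#' @export
stage1_select <- function(snv_p, cnv_p, mode = c("union", "intersection"),
                          alpha = 0.05) {
  mode <- match.arg(mode)
  any_snv <- length(snv_p) > 0 && any(snv_p < alpha)
  any_cnv <- length(cnv_p) > 0 && any(cnv_p < alpha)
  if (mode == "union") any_snv || any_cnv else any_snv && any_cnv
}

#' Stage-2 window flags for the traditional analyses
#'
#' A window is significant when it contains at least one marker (either
#' platform) whose stage-1 p-value is below \code{alpha}. Marker p-values
#' are the stage-1 values; no re-testing is done within windows.
#'
#' @param windows list of per-window \code{combined_gene_matrix} objects.
#' @param marker_p named vector of per-marker p-values (names are marker
#'   and segment ids).
#' @param alpha per-marker significance level.
#' @return logical vector, one flag per window (empty windows are FALSE).
#' @export
stage2_windows <- function(windows, marker_p, alpha = 0.05) {
  vapply(windows, function(w) {
    ids <- c(w$snv_info$id, w$cnv_info$id)
    length(ids) > 0 && any(marker_p[ids] < alpha, na.rm = TRUE)
  }, logical(1))
}

#' Run a traditional two-stage parallel analysis (TUU or TIU)
#'
#' Shares the input/output schema of \code{\link{run_inco}} so the two
#' families of methods can be compared head-to-head: a gene table with
#' selection flags and per-gene window tables for selected genes.
#'
#' @param config a validated configuration (see \code{\link{load_config}})
#'   or a list with the same fields.
#' @param mode \code{"tuu"} (union-union) or \code{"tiu"}
#'   (intersection-union).
#' @return invisibly, a list with \code{genes}, \code{windows} (per
#'   selected gene) and the output directory, if any.
#' @export
run_traditional <- function(config, mode = c("tuu", "tiu")) {
  mode <- match.arg(mode)
  dat <- load_run_inputs(config)
  alpha <- config$marker_alpha %||% config$gene_alpha %||% 0.05
  mt <- marker_tests(dat$snv, dat$cnv, dat$null)
  marker_p <- stats::setNames(mt$p_value, mt$marker_id)
  s1_mode <- if (mode == "tuu") "union" else "intersection"

  rows <- list(); wins <- list()
  for (k in seq_len(nrow(dat$genes))) {
    gene <- dat$genes[k, ]
    gm <- build_gene_matrix(dat$snv, dat$cnv, gene,
                            flank_bp = config$flank_bp %||% 0)
    if (gm$empty) {
      rows[[k]] <- data.frame(gene_id = gene$gene_id, q1 = 0, q2 = 0,
                              min_snv_p = NA, min_cnv_p = NA,
                              selected = FALSE, stringsAsFactors = FALSE)
      next
    }
    sp <- marker_p[gm$snv_info$id]; cp <- marker_p[gm$cnv_info$id]
    sel <- stage1_select(sp, cp, s1_mode, alpha)
    rows[[k]] <- data.frame(
      gene_id = gene$gene_id, q1 = length(sp), q2 = length(cp),
      min_snv_p = if (length(sp)) min(sp) else NA_real_,
      min_cnv_p = if (length(cp)) min(cp) else NA_real_,
      selected = sel, stringsAsFactors = FALSE)
    if (sel) {
      ws <- build_window_matrices(gm, config$window_size_bp %||% 500,
                                  config$step_bp %||%
                                    (config$window_size_bp %||% 500))
      flags <- stage2_windows(ws, marker_p, alpha)
      wins[[gene$gene_id]] <- data.frame(
        gene_id = gene$gene_id,
        window = vapply(ws, function(w) w$window_index, integer(1)),
        start = vapply(ws, function(w) as.integer(w$region[["start"]]),
                       integer(1)),
        end = vapply(ws, function(w) as.integer(w$region[["end"]]),
                     integer(1)),
        q1 = vapply(ws, function(w) ncol(w$snv), integer(1)),
        q2 = vapply(ws, function(w) ncol(w$cnv), integer(1)),
        significant = flags, stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, rows)
  out <- list(genes = genes, windows = wins, mode = mode)
  if (!is.null(config$out_dir))
    write_run_outputs(out, config, command = paste0("traditional-", mode))
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
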