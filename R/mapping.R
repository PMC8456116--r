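# Marker-to-unit mapping: builds the combined n x (q1 + q2) matrix for a
# gene or moving window. SNVs are assigned by position within the closed
# interval; CNV segments by interval overlap (default: any >= 1 bp).

snv_in_interval <- function(markers, chrom, start, end, flank = 0) {
  markers$chrom == chrom & markers$pos >= start - flank &
    markers$pos <= end + flank
}

cnv_overlaps_interval <- function(segments, chrom, start, end,
                                  min_overlap_frac = 0) {
  same <- segments$chrom == chrom
  ov <- pmin(segments$end, end) - pmax(segments$start, start) + 1
  hit <- same & ov >= 1
  if (min_overlap_frac > 0) {
    frac <- ov / (segments$end - segments$start + 1)
    hit <- hit & frac >= min_overlap_frac
  }
  hit
}

#' Build the combined SNV + CNV matrix for one gene
#'
#' SNVs are included when their position lies inside the gene interval
#' (closed, optionally extended by \code{flank_bp} on each side); CNV
#' segments when they overlap the interval by at least one bp (or by at
#' least \code{min_overlap_frac} of the segment length). Columns are
#' ordered all SNVs first, then all CNV segments.
#'
#' @param snv an \code{\link{snv_panel}}.
#' @param cnv a \code{\link{cnv_panel}}, or \code{NULL}.
#' @param gene a single-row \code{\link{gene_annotation}} (or a list with
#'   \code{gene_id}, \code{chrom}, \code{start}, \code{end}).
#' @param flank_bp flanking distance added to the gene interval for SNV
#'   assignment and window layout (default 0: gene body only).
#' @param min_overlap_frac minimum overlapping fraction of a CNV segment
#'   (default 0, i.e. any 1-bp overlap counts).
#' @return a \code{combined_gene_matrix}; its \code{empty} flag is TRUE
#'   when the unit contains no marker of either type.
#' @export
build_gene_matrix <- function(snv, cnv, gene, flank_bp = 0,
                              min_overlap_frac = 0) {
  stopifnot(inherits(snv, "snv_panel"))
  if (is.data.frame(gene)) {
    stopifnot(nrow(gene) == 1)
    gene <- as.list(gene)
  }
  if (!is.null(cnv)) {
    stopifnot(inherits(cnv, "cnv_panel"))
    if (!identical(snv$sample_ids, cnv$sample_ids))
      stop("SNV and CNV panels must share sample_ids in identical order",
           call. = FALSE)
  }
  lo <- gene$start - flank_bp
  hi <- gene$end + flank_bp
  si <- snv_in_interval(snv$markers, gene$chrom, gene$start, gene$end,
                        flank = flank_bp)
  ci <- if (is.null(cnv)) logical(0) else
    cnv_overlaps_interval(cnv$segments, gene$chrom, lo, hi,
                          min_overlap_frac)
  snv_block <- snv$genotypes[, si, drop = FALSE]
  cnv_block <- if (is.null(cnv))
    matrix(0, length(snv$sample_ids), 0) else
      cnv$status[, ci, drop = FALSE]
  new_unit_matrix(
    unit_id = gene$gene_id,
    sample_ids = snv$sample_ids,
    snv = snv_block, cnv = cnv_block,
    snv_info = snv$markers[si, , drop = FALSE],
    cnv_info = if (is.null(cnv)) NULL else
      cnv$segments[ci, , drop = FALSE],
    region = c(chrom = gene$chrom, start = lo, end = hi),
    empty = ncol(snv_block) + ncol(cnv_block) == 0)
}

window_starts <- function(start, end, step_bp) {
  seq.int(from = start, to = end, by = step_bp)
}

#' Tile a gene into moving windows and build per-window matrices
#'
#' Windows start at the gene start and advance by \code{step_bp}; each
#' window spans \code{window_size_bp} bp (the last may be shorter).
#' Per-window marker membership follows the same rules as
#' \code{\link{build_gene_matrix}}. Windows with no markers are emitted
#' with \code{empty = TRUE} so that positional skylines keep their gaps.
#'
#' @param gene_matrix a \code{combined_gene_matrix} from
#'   \code{\link{build_gene_matrix}}.
#' @param window_size_bp window width in bp (> 0).
#' @param step_bp step between window starts (> 0); defaults to the window
#'   size, i.e. non-overlapping tiling.
#' @return list of \code{combined_gene_matrix} objects, ordered by start.
#' @export
build_window_matrices <- function(gene_matrix, window_size_bp,
                                  step_bp = window_size_bp) {
  stopifnot(inherits(gene_matrix, "combined_gene_matrix"),
            window_size_bp > 0, step_bp > 0)
  gm <- gene_matrix
  chrom <- gm$region[["chrom"]]
  gstart <- as.integer(gm$region[["start"]])
  gend <- as.integer(gm$region[["end"]])
  starts <- window_starts(gstart, gend, step_bp)
  lapply(seq_along(starts), function(w) {
    ws <- starts[w]
    we <- min(ws + window_size_bp - 1, gend)
    si <- if (nrow(gm$snv_info)) gm$snv_info$pos >= ws & gm$snv_info$pos <= we
          else logical(0)
    ci <- if (!is.null(gm$cnv_info) && nrow(gm$cnv_info))
      cnv_overlaps_interval(gm$cnv_info, chrom, ws, we) else logical(0)
    snv_block <- gm$snv[, si, drop = FALSE]
    cnv_block <- gm$cnv[, ci, drop = FALSE]
    out <- new_unit_matrix(
      unit_id = paste0(gm$unit_id, ".w", w),
      sample_ids = gm$sample_ids,
      snv = snv_block, cnv = cnv_block,
      snv_info = gm$snv_info[si, , drop = FALSE],
      cnv_info = if (is.null(gm$cnv_info)) NULL else
        gm$cnv_info[ci, , drop = FALSE],
      region = c(chrom = chrom, start = ws, end = we),
      empty = ncol(snv_block) + ncol(cnv_block) == 0)
    out$window_index <- w
    out
  })
}
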