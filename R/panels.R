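#' SNV genotype panel
#'
#' Container for additively coded SNV genotypes: one row per sample, one
#' column per marker, values 0/1/2 counting copies of the minor allele
#' (non-integer values arise only after mean imputation), \code{NA} for
#' missing.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param markers data.frame with columns \code{id}, \code{chrom},
#'   \code{pos} (1-based bp).
#' @param genotypes numeric matrix, \code{length(sample_ids)} rows and
#'   \code{nrow(markers)} columns, values in \code{[0, 2]} or \code{NA}.
#' @return An object of class \code{snv_panel}.
#' @export
snv_panel <- function(sample_ids, markers, genotypes) {
  sample_ids <- as.character(sample_ids)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chrom", "pos") %in% names(markers)))
  if (nrow(genotypes) != length(sample_ids))
    stop("genotype matrix has ", nrow(genotypes), " rows but ",
         length(sample_ids), " sample ids", call. = FALSE)
  if (ncol(genotypes) != nrow(markers))
    stop("genotype matrix has ", ncol(genotypes), " columns but ",
         nrow(markers), " markers", call. = FALSE)
  bad <- !is.na(genotypes) & (genotypes < 0 | genotypes > 2)
  if (any(bad))
    stop("genotypes outside [0, 2] for marker(s): ",
         paste(unique(markers$id[col(genotypes)[bad]]), collapse = ", "),
         call. = FALSE)
  if (any(markers$pos < 1)) stop("marker positions must be >= 1 (1-based bp)",
                                 call. = FALSE)
  dimnames(genotypes) <- list(sample_ids, markers$id)
  structure(list(sample_ids = sample_ids, markers = markers,
                 genotypes = genotypes),
            class = "snv_panel")
}

#' CNV segment panel
#'
#' Per-sample copy-number status for a set of genomic segments, dichotomized
#' as 1 = copy-number gain or loss, 0 = no change.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param segments data.frame with columns \code{id}, \code{chrom},
#'   \code{start}, \code{end} (1-based inclusive bp).
#' @param status integer/numeric matrix of 0/1 status values, samples in
#'   rows, segments in columns.
#' @return An object of class \code{cnv_panel}.
#' @export
cnv_panel <- function(sample_ids, segments, status) {
  sample_ids <- as.character(sample_ids)
  status <- as.matrix(status)
  storage.mode(status) <- "double"
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chrom", "start", "end") %in% names(segments)))
  if (nrow(status) != length(sample_ids))
    stop("status matrix has ", nrow(status), " rows but ",
         length(sample_ids), " sample ids", call. = FALSE)
  if (ncol(status) != nrow(segments))
    stop("status matrix has ", ncol(status), " columns but ",
         nrow(segments), " segments", call. = FALSE)
  if (any(is.na(status)) || !all(status %in% c(0, 1)))
    stop("CNV status values must be 0 (no change) or 1 (gain or loss)",
         call. = FALSE)
  if (any(segments$start > segments$end))
    stop("segment start > end for: ",
         paste(segments$id[segments$start > segments$end], collapse = ", "),
         call. = FALSE)
  dimnames(status) <- list(sample_ids, segments$id)
  structure(list(sample_ids = sample_ids, segments = segments,
                 status = status),
            class = "cnv_panel")
}

#' Gene/region annotation table
#'
#' @param gene_id character vector.
#' @param chrom chromosome labels.
#' @param start,end 1-based inclusive bp coordinates.
#' @return data.frame of class \code{gene_annotation}.
#' @export
gene_annotation <- function(gene_id, chrom, start, end) {
  ann <- data.frame(gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  if (any(ann$start > ann$end))
    stop("annotation start > end for: ",
         paste(ann$gene_id[ann$start > ann$end], collapse = ", "),
         call. = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' @export
print.snv_panel <- function(x, ...) {
  cat("snv_panel:", length(x$sample_ids), "samples x",
      nrow(x$markers), "SNVs\n")
  miss <- mean(is.na(x$genotypes))
  cat("  missing:", format(miss, digits = 3), "\n")
  invisible(x)
}

#' @export
print.cnv_panel <- function(x, ...) {
  cat("cnv_panel:", length(x$sample_ids), "samples x",
      nrow(x$segments), "segments\n")
  cat("  carrier fraction:", format(mean(x$status), digits = 3), "\n")
  invisible(x)
}

# internal: light constructor without validation, for hot simulation loops
new_unit_matrix <- function(unit_id, sample_ids, snv, cnv, snv_info, cnv_info,
                            region, empty = FALSE) {
  structure(list(unit_id = unit_id, sample_ids = sample_ids,
                 snv = snv, cnv = cnv,
                 snv_info = snv_info, cnv_info = cnv_info,
                 region = region, empty = empty),
            class = "combined_gene_matrix")
}

#' Number of SNV / CNV columns of a combined matrix
#' @param x a \code{combined_gene_matrix}.
#' @return integer vector \code{c(q1, q2)}.
#' @export
unit_dims <- function(x) {
  stopifnot(inherits(x, "combined_gene_matrix"))
  c(q1 = ncol(x$snv), q2 = ncol(x$cnv))
}

#' Dense numeric matrix of a combined genomic unit
#'
#' Columns are ordered all SNVs first, then all CNV segments.
#'
#' @param x a \code{combined_gene_matrix}.
#' @return numeric matrix with \code{q1 + q2} columns.
#' @export
unit_matrix <- function(x) {
  stopifnot(inherits(x, "combined_gene_matrix"))
  cbind(x$snv, x$cnv)
}

#' Marker-type flags of a combined unit (1 = SNV, 2 = CNV)
#' @param x a \code{combined_gene_matrix}.
#' @return integer vector of length \code{q1 + q2}.
#' @export
marker_types <- function(x) {
  stopifnot(inherits(x, "combined_gene_matrix"))
  rep(c(1L, 2L), c(ncol(x$snv), ncol(x$cnv)))
}

#' @export
print.combined_gene_matrix <- function(x, ...) {
  d <- unit_dims(x)
  cat("combined_gene_matrix", x$unit_id, "(",
    x$region["chrom"], ":", x$region["start"], "-", x$region["end"], ")\n")
  cat(" ", length(x$sample_ids), "samples; q1 =", d[1], "SNVs; q2 =",
      d[2], "CNV segments", if (x$empty) "[empty]" else "", "\n")
  invisible(x)
}
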