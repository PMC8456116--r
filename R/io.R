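# Readers and writers for the plain-text interchange formats.
# Coordinate convention: 1-based closed intervals everywhere in memory;
# BED input is converted from 0-based half-open on read, and back on write.
# TSV dialect: tab-separated, header row, "." for missing.

read_tsv_checked <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", na.strings = ".",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read an SNV genotype panel
#'
#' Supported formats: \code{"traw"} (PLINK-style transposed table with
#' columns CHR, SNP, (C)M, POS, COUNTED, ALT followed by one column per
#' sample), \code{"vcf"} (GT field, parsed with \pkg{vcfR}), and
#' \code{"tsv-matrix"} (columns \code{marker_id}, \code{chrom}, \code{pos},
#' then one column per sample).
#'
#' Genotypes are re-oriented per marker so that the counted allele is the
#' minor allele in the data (sample allele frequency <= 0.5), regardless of
#' the file's REF/ALT or COUNTED designation.
#'
#' @param path input file.
#' @param format_name one of \code{"traw"}, \code{"vcf"}, \code{"tsv-matrix"}.
#' @return An \code{\link{snv_panel}}. Markers that were flipped to the
#'   minor allele carry \code{TRUE} in \code{markers$flipped}.
#' @export
read_snv_panel <- function(path, format_name = c("tsv-matrix", "traw", "vcf")) {
  format_name <- match.arg(format_name)
  switch(format_name,
         "traw" = read_snv_traw(path),
         "vcf" = read_snv_vcf(path),
         "tsv-matrix" = read_snv_tsv_matrix(path))
}

check_geno_values <- function(g, ids) {
  ok <- is.na(g) | g %in% c(0, 1, 2)
  if (!all(ok)) {
    bad <- unique(ids[col(g)[!ok]])
    stop("malformed genotype record (values must be 0/1/2/.): marker(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
}

orient_minor <- function(panel) {
  f <- colMeans(panel$genotypes, na.rm = TRUE) / 2
  flip <- !is.na(f) & f > 0.5
  if (any(flip))
    panel$genotypes[, flip] <- 2 - panel$genotypes[, flip]
  panel$markers$flipped <- flip
  panel
}

read_snv_traw <- function(path) {
  tab <- read_tsv_checked(path, "traw")
  fixed <- c("CHR", "SNP", "(C)M", "POS", "COUNTED", "ALT")
  if (!all(fixed %in% names(tab)))
    stop("traw parse error: expected header columns ",
         paste(fixed, collapse = " "), call. = FALSE)
  samples <- setdiff(names(tab), fixed)
  if (length(samples) == 0) stop("traw file has no sample columns",
                                 call. = FALSE)
  g <- t(as.matrix(tab[, samples, drop = FALSE]))
  suppressWarnings(storage.mode(g) <- "double")
  check_geno_values(g, tab$SNP)
  markers <- data.frame(id = as.character(tab$SNP), chrom = as.character(tab$CHR),
                        pos = as.integer(tab$POS), stringsAsFactors = FALSE)
  orient_minor(snv_panel(samples, markers, g))
}

read_snv_tsv_matrix <- function(path) {
  tab <- read_tsv_checked(path, "tsv-matrix")
  fixed <- c("marker_id", "chrom", "pos")
  if (!all(fixed %in% names(tab)))
    stop("tsv-matrix parse error: expected header columns ",
         paste(fixed, collapse = " "), call. = FALSE)
  samples <- setdiff(names(tab), fixed)
  if (length(samples) == 0) stop("tsv-matrix has no sample columns",
                                 call. = FALSE)
  g <- t(as.matrix(tab[, samples, drop = FALSE]))
  suppressWarnings(storage.mode(g) <- "double")
  check_geno_values(g, tab$marker_id)
  markers <- data.frame(id = as.character(tab$marker_id),
                        chrom = as.character(tab$chrom),
                        pos = as.integer(tab$pos), stringsAsFactors = FALSE)
  orient_minor(snv_panel(samples, markers, g))
}

read_snv_vcf <- function(path) {
  if (!file.exists(path)) stop("vcf file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(vcf@fix),
                                     dimnames = list(rownames(vcf@fix), NULL))
  # count ALT alleles in the GT string; "./." and "." -> NA
  count_alt <- function(s) {
    if (is.na(s)) return(NA_real_)
    alleles <- strsplit(s, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  }
  g <- apply(gt, c(1, 2), count_alt)
  if (any(!is.na(g) & g > 2))
    stop("multi-allelic VCF records are not supported", call. = FALSE)
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  markers <- data.frame(id = ids, chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        stringsAsFactors = FALSE)
  orient_minor(snv_panel(colnames(gt), markers, t(g)))
}

#' Write an SNV panel as a tsv-matrix file
#' @param panel an \code{snv_panel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_snv_panel <- function(panel, path) {
  stopifnot(inherits(panel, "snv_panel"))
  tab <- data.frame(marker_id = panel$markers$id,
                    chrom = panel$markers$chrom,
                    pos = panel$markers$pos,
                    t(panel$genotypes), check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv_dialect(tab, path)
}

write_tsv_dialect <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a CNV segment panel
#'
#' Segments come from a BED-like file (\code{chrom  start  end  segment_id},
#' 0-based half-open, converted to 1-based closed coordinates on read).
#' Status comes from a separate TSV, either wide (column \code{segment_id}
#' then one 0/1 column per sample) or long (columns \code{sample_id},
#' \code{segment_id}, \code{status}).
#'
#' @param segments_path BED-like segment definition file.
#' @param status_path per-sample 0/1 status table.
#' @param status_format \code{"wide"} or \code{"long"}.
#' @return A \code{\link{cnv_panel}}.
#' @export
read_cnv_panel <- function(segments_path, status_path,
                           status_format = c("wide", "long")) {
  status_format <- match.arg(status_format)
  segs <- read_bed4(segments_path, "segment")
  names(segs)[names(segs) == "name"] <- "id"
  tab <- read_tsv_checked(status_path, "CNV status")
  if (status_format == "wide") {
    if (!"segment_id" %in% names(tab))
      stop("wide CNV status table needs a segment_id column", call. = FALSE)
    samples <- setdiff(names(tab), "segment_id")
    m <- match(segs$id, tab$segment_id)
    if (anyNA(m)) stop("status table missing segment(s): ",
                       paste(segs$id[is.na(m)], collapse = ", "), call. = FALSE)
    status <- t(as.matrix(tab[m, samples, drop = FALSE]))
  } else {
    need <- c("sample_id", "segment_id", "status")
    if (!all(need %in% names(tab)))
      stop("long CNV status table needs columns ",
           paste(need, collapse = ", "), call. = FALSE)
    samples <- unique(as.character(tab$sample_id))
    status <- matrix(NA_real_, length(samples), nrow(segs),
                     dimnames = list(samples, segs$id))
    status[cbind(match(tab$sample_id, samples),
                 match(as.character(tab$segment_id), segs$id))] <- tab$status
    if (anyNA(status))
      stop("long CNV status table does not cover every sample x segment pair",
           call. = FALSE)
  }
  suppressWarnings(storage.mode(status) <- "double")
  if (any(is.na(status)) || !all(status %in% c(0, 1)))
    stop("CNV status values must be 0 or 1", call. = FALSE)
  cnv_panel(rownames(status), segs, status)
}

#' Write a CNV panel (BED-like segments + wide status table)
#' @param panel a \code{cnv_panel}.
#' @param segments_path,status_path output paths.
#' @return invisibly, the two paths.
#' @export
write_cnv_panel <- function(panel, segments_path, status_path) {
  stopifnot(inherits(panel, "cnv_panel"))
  bed <- data.frame(chrom = panel$segments$chrom,
                    start = panel$segments$start - 1L,  # back to 0-based
                    end = panel$segments$end,
                    name = panel$segments$id)
  utils::write.table(bed, segments_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tab <- data.frame(segment_id = panel$segments$id, t(panel$status),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_dialect(tab, status_path)
  invisible(c(segments_path, status_path))
}

read_bed4 <- function(path, what) {
  if (!file.exists(path)) stop(what, " BED file not found: ", path,
                               call. = FALSE)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4)
    stop(what, " BED parse error: need 4 columns (chrom start end name)",
         call. = FALSE)
  data.frame(chrom = as.character(tab[[1]]),
             start = as.integer(tab[[2]]) + 1L,  # 0-based half-open -> 1-based
             end = as.integer(tab[[3]]),
             name = as.character(tab[[4]]), stringsAsFactors = FALSE)
}

#' Read gene annotation from BED
#' @param path BED file (\code{chrom start end gene_id}, 0-based half-open).
#' @return a \code{\link{gene_annotation}}.
#' @export
read_gene_bed <- function(path) {
  tab <- read_bed4(path, "gene")
  gene_annotation(tab$name, tab$chrom, tab$start, tab$end)
}

#' Read a phenotype + covariate table
#'
#' @param path TSV with a \code{sample_id} column, one phenotype column and
#'   any number of covariate columns.
#' @param sample_ids if given, rows are checked and reordered to match.
#' @return data.frame keyed by \code{sample_id}.
#' @export
read_pheno <- function(path, sample_ids = NULL) {
  tab <- read_tsv_checked(path, "phenotype")
  if (!"sample_id" %in% names(tab))
    stop("phenotype table needs a sample_id column", call. = FALSE)
  tab$sample_id <- as.character(tab$sample_id)
  if (!is.null(sample_ids)) {
    m <- match(as.character(sample_ids), tab$sample_id)
    if (anyNA(m))
      stop("phenotype table missing sample(s): ",
           paste(sample_ids[is.na(m)], collapse = ", "), call. = FALSE)
    tab <- tab[m, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}
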