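# YAML configuration loading with schema validation, deterministic child
# seeds, and the bundled-fixture generator.

config_schema <- function() {
  num01 <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x < 1
  pos <- function(x) is.numeric(x) && all(x > 0)
  chr <- function(x) is.character(x) && length(x) == 1
  flag <- function(x) is.logical(x) && length(x) == 1
  list(
    snv_file = list(check = chr),
    snv_format = list(default = "tsv-matrix",
                      check = function(x) x %in% c("tsv-matrix", "traw",
                                                   "vcf")),
    cnv_segments = list(check = chr),
    cnv_status = list(check = chr),
    cnv_status_format = list(default = "wide",
                             check = function(x) x %in% c("wide", "long")),
    genes_file = list(check = chr),
    pheno_file = list(check = chr),
    pheno_column = list(default = "phenotype", check = chr),
    covariate_columns = list(check = is.character),
    phenotype_kind = list(default = "binary",
                          check = function(x) x %in% c("binary",
                                                       "continuous")),
    qc = list(default = TRUE, check = flag),
    max_missing_rate = list(default = 0.05, check = num01),
    hwe_alpha = list(default = 1e-6, check = num01),
    impute = list(default = "mean",
                  check = function(x) x %in% c("mean", "zero")),
    gene_alpha = list(default = 0.05, check = num01),
    correction = list(default = "none",
                      check = function(x) x %in% c(
                        "none", "bonferroni", "benjamini-hochberg")),
    window_alpha = list(default = 0.05, check = num01),
    marker_alpha = list(default = 0.05, check = num01),
    window_sizes_bp = list(default = 500, check = pos),
    step_bp = list(check = pos),
    method = list(default = "skat-o",
                  check = function(x) x %in% c("skat-o", "skat", "burden")),
    one_stage = list(default = FALSE, check = flag),
    flank_bp = list(default = 0, check = function(x)
      is.numeric(x) && length(x) == 1 && x >= 0),
    out_dir = list(check = chr),
    seed = list(default = 1,
                check = function(x) is.numeric(x) && length(x) == 1))
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected; missing keys take their documented defaults.
#'
#' @param path YAML file, or a named list already in memory.
#' @return validated configuration list of class \code{inco_config}.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    yaml::read_yaml(path)
  } else as.list(path)
  schema <- config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (key in names(schema)) {
    sc <- schema[[key]]
    if (is.null(cfg[[key]])) {
      if (!is.null(sc$default)) cfg[[key]] <- sc$default
      next
    }
    if (!isTRUE(all(sc$check(cfg[[key]]))))
      stop("invalid value for config key '", key, "'", call. = FALSE)
  }
  structure(cfg, class = c("inco_config", "list"))
}

#' Write a configuration back to YAML
#' @param config an \code{inco_config} (or plain list).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[order(names(unclass(config)))], path)
  invisible(path)
}

#' Deterministic child seed
#'
#' Fans a single global seed out into per-stage seeds via a counter-based
#' linear scheme, so that individual pipeline stages are independently
#' reproducible. Always below 2^31.
#'
#' @param seed integer master seed.
#' @param counter integer stage counter.
#' @return integer child seed.
#' @export
child_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 +
                as.numeric(counter) * 7919) %% 2147483647)
}

#' Generate a small bundled dataset for tests and documentation
#'
#' Writes a deterministic 200-sample, 3-gene SNV/CNV/gene/phenotype bundle
#' with one planted strong SNV-CNV concurrent signal (weak marginals,
#' strong interaction) in the first gene's first window, plus a YAML
#' config pointing at the files.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; the same seed reproduces identical bytes.
#' @return invisibly, the named vector of written paths.
#' @export
make_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genes <- data.frame(
    gene_id = c("geneA", "geneB", "geneC"),
    chrom = c("1", "2", "3"),
    q1 = c(15L, 7L, 11L), q2 = c(10L, 1L, 1L),
    stringsAsFactors = FALSE)
  # causal frequencies raised above the study default so the planted
  # signal is reliably visible at the bundle's sample size
  spec <- gene_pool_spec(genes = genes, pool_size = 600,
                         causal_snv_maf = 0.25,
                         causal_cnv_carrier = 0.25)
  pool <- generate_pool(spec, seed = child_seed(seed, 1))
  setting <- sim_setting("A4")
  sim <- simulate_case_control(setting, pool, n_per_group = 100,
                               seed = child_seed(seed, 2))
  ids <- sprintf("s%03d", seq_along(sim$idx))
  snv <- snv_panel(ids, pool$snv$markers,
                   pool$snv$genotypes[sim$idx, , drop = FALSE])
  cnv <- cnv_panel(ids, pool$cnv$segments,
                   pool$cnv$status[sim$idx, , drop = FALSE])
  paths <- c(snv = file.path(out_dir, "snv.tsv"),
             cnv_segments = file.path(out_dir, "cnv_segments.bed"),
             cnv_status = file.path(out_dir, "cnv_status.tsv"),
             genes = file.path(out_dir, "genes.bed"),
             pheno = file.path(out_dir, "pheno.tsv"),
             config = file.path(out_dir, "config.yaml"))
  write_snv_panel(snv, paths["snv"])
  write_cnv_panel(cnv, paths["cnv_segments"], paths["cnv_status"])
  bed <- data.frame(chrom = pool$genes$chrom,
                    start = pool$genes$start - 1L, end = pool$genes$end,
                    name = pool$genes$gene_id)
  utils::write.table(bed, paths["genes"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv_dialect(data.frame(sample_id = ids, phenotype = sim$y),
                    paths["pheno"])
  cfg <- list(snv_file = "snv.tsv", snv_format = "tsv-matrix",
              cnv_segments = "cnv_segments.bed",
              cnv_status = "cnv_status.tsv", cnv_status_format = "wide",
              genes_file = "genes.bed", pheno_file = "pheno.tsv",
              pheno_column = "phenotype", phenotype_kind = "binary",
              seed = as.numeric(seed))
  save_config(cfg, paths["config"])
  invisible(paths)
}
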