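# Marker-level quality control: missingness and exact Hardy-Weinberg test.

#' Exact Hardy-Weinberg equilibrium test p-value
#'
#' Conditional exact test on the heterozygote count. Given the observed
#' minor-allele count, the p-value is the total conditional probability of
#' all heterozygote counts whose probability does not exceed that of the
#' observed table (two-sided, probability ordering).
#'
#' @param n_hom_major,n_het,n_hom_minor genotype counts (scalars).
#' @return p-value in (0, 1].
#' @export
hwe_exact_pvalue <- function(n_hom_major, n_het, n_hom_minor) {
  a <- n_hom_major; b <- n_het; c <- n_hom_minor
  if (any(c(a, b, c) < 0) || any(c(a, b, c) != round(c(a, b, c))))
    stop("genotype counts must be nonnegative integers", call. = FALSE)
  n <- a + b + c
  if (n == 0) stop("all genotype counts are zero; HWE test undefined",
                   call. = FALSE)
  m <- b + 2 * c                     # minor-allele copies
  # P(het = h | n, m) = n! / (a! h! c!) * 2^h * m! (2n-m)! / (2n)!
  hs <- seq.int(m %% 2, min(m, 2 * n - m), by = 2)
  logp <- lfactorial(n) - lfactorial((m - hs) / 2) - lfactorial(hs) -
    lfactorial(n - (m + hs) / 2) + hs * log(2) +
    lfactorial(m) + lfactorial(2 * n - m) - lfactorial(2 * n)
  p_obs <- logp[match(b, hs)]
  sum(exp(logp[logp <= p_obs + 1e-10]))
}

#' Marker QC: missingness and Hardy-Weinberg filtering
#'
#' Removes markers whose missing fraction exceeds \code{max_missing_rate}
#' or whose exact HWE test p-value (computed on observed genotypes) falls
#' below \code{hwe_alpha}.
#'
#' @param panel an \code{\link{snv_panel}}.
#' @param max_missing_rate maximum tolerated missing fraction, in (0, 1).
#' @param hwe_alpha HWE exact-test significance threshold, in (0, 1).
#' @return list with the filtered \code{panel} and a \code{report}
#'   data.frame (\code{marker_id}, \code{reason}, \code{value}) of removals.
#' @export
qc_snv <- function(panel, max_missing_rate = 0.05, hwe_alpha = 1e-6) {
  stopifnot(inherits(panel, "snv_panel"),
            max_missing_rate > 0, max_missing_rate < 1,
            hwe_alpha > 0, hwe_alpha < 1)
  g <- panel$genotypes
  miss <- colMeans(is.na(g))
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    gj <- g[, j]; gj <- gj[!is.na(gj)]
    if (length(gj) == 0) return(NA_real_)
    hwe_exact_pvalue(sum(gj == 0), sum(gj == 1), sum(gj == 2))
  }, numeric(1))
  drop_miss <- miss > max_missing_rate
  drop_hwe <- !is.na(hwe_p) & hwe_p < hwe_alpha
  report <- rbind(
    data.frame(marker_id = panel$markers$id[drop_miss],
               reason = rep("missing_rate", sum(drop_miss)),
               value = miss[drop_miss], stringsAsFactors = FALSE),
    data.frame(marker_id = panel$markers$id[drop_hwe],
               reason = rep("hwe", sum(drop_hwe)),
               value = hwe_p[drop_hwe], stringsAsFactors = FALSE))
  keep <- !(drop_miss | drop_hwe)
  out <- snv_panel(panel$sample_ids,
                   panel$markers[keep, , drop = FALSE],
                   panel$genotypes[, keep, drop = FALSE])
  list(panel = out, report = report)
}

#' Impute missing genotypes
#'
#' Missing values are replaced by the marker mean of observed genotypes
#' (so imputed entries may be non-integer), or by zero. Markers with no
#' observed genotype at all are dropped with a warning.
#'
#' @param panel an \code{\link{snv_panel}}.
#' @param method \code{"mean"} (default) or \code{"zero"}.
#' @return the imputed \code{snv_panel}.
#' @export
impute_missing <- function(panel, method = c("mean", "zero")) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "snv_panel"))
  g <- panel$genotypes
  all_na <- colSums(!is.na(g)) == 0
  if (any(all_na)) {
    warning("dropping ", sum(all_na),
            " marker(s) with no observed genotypes: ",
            paste(panel$markers$id[all_na], collapse = ", "), call. = FALSE)
    g <- g[, !all_na, drop = FALSE]
    panel$markers <- panel$markers[!all_na, , drop = FALSE]
  }
  if (anyNA(g)) {
    fill <- if (method == "mean") colMeans(g, na.rm = TRUE) else
      rep(0, ncol(g))
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- fill[idx[, 2]]
  }
  snv_panel(panel$sample_ids, panel$markers, g)
}
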