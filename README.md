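# incoloc

Integrative co-localization of SNV and CNV association signals.

## What this is for

Association studies usually analyze single nucleotide variants (SNVs) and
copy-number variation (CNV) segments separately and merge the two hit
lists afterwards by set union or intersection. That parallel scheme
misses traits driven *concurrently* by a sequence variant and a
copy-number change in the same region, and it struggles with rare
variants. `incoloc` is for statistical geneticists who want to test both
marker types **jointly**, per gene and then per sub-gene window, under
one generalized linear model.

For each genomic unit the package builds the combined matrix

```
G = [ SNV block (n x q1, coded 0/1/2) | CNV block (n x q2, coded 0/1) ]
```

and tests it with an optimal weighted-kernel score test (SKAT-O family)
against the null model `g(E[Y]) = Z alpha`. The statistic

```
Q_rho = S_w' R_rho S_w,   S_w = W G'(y - mu),   R_rho = (1 - rho) I + rho 11'
```

interpolates between a variance-component test (`rho = 0`) and a weighted
burden test (`rho = 1`); p-values come from chi-square-mixture tails
computed by numerical inversion of the characteristic function, and the
omnibus test minimizes over a `rho` grid. The two-stage pipeline screens
genes first, then co-localizes the signal with a moving-window scan
(default 0.5 kb windows), reporting combined, SNV-only and CNV-only
skylines per window. The traditional union-union (TUU) and
intersection-union (TIU) parallel baselines are included for comparison,
along with a full simulation harness (21-gene synthetic pool, logistic
disease model with a SNV x CNV concurrent effect, FPR/TPR/TNR metrics).

## Worked example

The package ships a deterministic fixture generator: a 200-sample,
3-gene bundle with one planted strong SNV-CNV concurrent effect in the
first window of `geneA`.

```r
library(incoloc)
paths <- make_fixtures("fx_demo", seed = 7)
snv   <- read_snv_panel(paths[["snv"]], "tsv-matrix")
cnv   <- read_cnv_panel(paths[["cnv_segments"]], paths[["cnv_status"]], "wide")
genes <- read_gene_bed(paths[["genes"]])
ph    <- read_pheno(paths[["pheno"]], snv$sample_ids)

screen <- screen_genes(snv, cnv, genes, ph$phenotype)
print(screen, digits = 3)
#>   gene_id q1 q2 p_value  p_adj selected rho       backend
#> 1   geneA 15 10  0.0446 0.0446     TRUE   0 exact-mixture
#> 2   geneB  7  1  0.3281 0.3281    FALSE   1 exact-mixture
#> 3   geneC 11  1  0.0467 0.0467     TRUE   1 exact-mixture

sky <- colocalize(genes[genes$gene_id == "geneA", ], snv, cnv,
                  attr(screen, "null"), screen_policy(window_size_bp = 500))
print(sky[, c("window", "q1", "q2", "p_combined", "p_snv", "p_cnv",
              "significant")], digits = 3)
#>   window q1 q2 p_combined  p_snv    p_cnv significant
#> 1      1  4  7   5.24e-11 0.0818 4.30e-09        TRUE
#> 2      2  4  8   4.84e-01 0.6257 1.24e-01       FALSE
#> 3      3  2  8   8.78e-03 0.0430 1.24e-01        TRUE
#> 4      4  5  8   1.09e-01 0.8004 1.04e-01       FALSE
```

Reading the output: the screen flags `geneA` (joint p = 0.045 over its
15 SNVs + 10 CNV segments). The window scan then localizes the signal —
window 1, which holds the planted causal SNV-CNV pair, reaches a
combined p of 5e-11 while its SNV-only skyline alone (p = 0.082) would
not even have crossed 0.05: the joint test sees what the single-platform
view misses. Columns `q1`/`q2` count the markers mapped into each window
(CNV segments overlap several windows, so they recur).

The same analysis runs from the shell:

```sh
Rscript inst/cli/inco run --snv fx_demo/snv.tsv \
  --cnv-segments fx_demo/cnv_segments.bed --cnv-status fx_demo/cnv_status.tsv \
  --genes fx_demo/genes.bed --pheno fx_demo/pheno.tsv --out results/
```

writing `genes.tsv`, one `skyline_<gene>.tsv` per scanned gene and a
`manifest.json` with seeds and input digests. `inco simulate`,
`inco traditional` and `inco fixtures` cover the rest of the toolkit.

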