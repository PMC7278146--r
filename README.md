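# poolqtl

Molecular QTL mapping from **pooled** sequencing assays.

Instead of assaying tens of cell lines one by one, a pooled design mixes
material from all genotyped, phased lines into a single library —
ChIP-seq for transcription-factor binding, ATAC-seq for chromatin
accessibility, Hi-C for chromosomal looping — and sequences the pool
once. `poolqtl` is for analysts of such experiments: it deconvolves how
much each line contributed to the pool, predicts the allele frequency
every SNP *should* show, and flags the SNPs whose observed frequency
departs — the binding QTLs (bQTLs), accessibility QTLs (caQTLs) and
looping QTLs (clQTLs) of the assayed cell type.

## The model in brief

With pool proportions `π` (unknown, unequal) and dosage fractions
`g_ij`, the pre-assay frequency of SNP *i* is

    f_pre(i) = Σ_j π_j · g_ij

`π` is estimated by depth-weighted least squares of the observed
post-assay frequencies on the genotype matrix, constrained to the
probability simplex (accelerated projected gradient; unique minimizer
for full-rank genotypes). Because `π` is fit from the post-assay reads
themselves, genome-wide trans differences between lines cancel. A
cis-acting variant multiplies the allelic odds,

    f_post = f_pre·e^β / (f_pre·e^β + 1 − f_pre)

and each SNP is tested by a two-sided exact binomial (mid-p) of its
alternative-read count against `Binomial(depth, f_pre)`; significant
QTLs are called at `p < 1e-3`.

Around that core the package provides the standard pipeline stages:
allele-swap remapping to remove reference mapping bias
(`filter_biased_reads()`), allele-tagged Hi-C contact counting over
loop anchors (`loop_allele_counts()`), phased-haplotype LD
(`r2_phased()`), GWAS lead-SNP window enrichment and LD-pair analyses
(`window_enrichment()`, `pair_qtls_with_leads()`), exact/LD overlap and
directional concordance of QTL sets (`exact_overlap()`,
`directional_concordance()`), allele-specific motif enrichment
(`allele_specific_enrichment()`), loop-anchor QTL-to-gene assignment
(`assign_qtl_genes()`), and a seeded synthetic-data generator with
known ground truth (`sim_config()`, `simulate_*`). See the vignette
`vignettes/pooled-qtl-mapping.Rmd` for the full methods account.

## Worked example

Simulate a 65-line pool at 100x with cis-effects of |β| = log 2 at 5%
of 10,000 SNPs, then map QTLs:

```r
library(poolqtl)
cfg <- sim_config(n_individuals = 65, n_snps = 10000, qtl_fraction = 0.05,
                  mean_depth = 100, seed = 1)
geno   <- simulate_genotypes(cfg)
truth  <- simulate_truth(geno, cfg, effect_magnitude = log(2))
counts <- simulate_pool_counts(geno, truth, cfg)

records <- map_pool_qtls(geno, counts, phenotype_class = "binding")
attr(records, "proportions")
#> pool_proportions over 65 individuals (from 10000 SNPs)
#>   range 0.0012 .. 0.0345, residual norm 5.6804
cor(attr(records, "proportions")$proportions, truth$true_proportions)
#> [1] 0.9716189
```

The inferred pool composition correlates 0.97 with the hidden truth.
Calling QTLs at the default cutoff:

```r
qtls <- call_qtls(records, p_cutoff = 1e-3)
nrow(qtls)
#> [1] 243
head(qtls[, c("id", "pos", "pre_freq", "post_freq", "z", "p_value")], 3)
#>          id     pos  pre_freq post_freq         z      p_value
#> 1 snp000123   61500 0.2553992 0.5652174  6.814425 3.593102e-10
#> 2 snp006898 3449000 0.2795774 0.5673077  6.538192 9.643481e-10
#> 3 snp001461  730500 0.4934307 0.2242991 -5.568319 1.199712e-08
mean(qtls$id %in% truth$qtl_ids)
#> [1] 0.962963
```

243 SNPs pass `p < 1e-3`; each row shows the predicted pre-assay and
observed post-assay frequency whose divergence drives the call (the top
hit jumps from 0.26 to 0.57), and 96% of the calls are implanted
effects. A synthetic GWAS catalog whose target trait was planted near
the true QTLs is then recovered by window enrichment:

```r
catalog <- simulate_lead_snp_catalog(
  geno$variants$pos[match(truth$qtl_ids, geno$variants$id)], cfg,
  genome_length = max(geno$variants$pos))
enr <- window_enrichment(qtls, catalog,
         background_traits = unique(catalog$trait[!catalog$is_target]))
head(enr[, c("trait", "n_leads", "overlap_count", "fold", "p_value")], 3)
#>            trait n_leads overlap_count     fold      p_value
#> 1   target_trait      57            22 3.813093 7.651897e-09
#> 20 background_19      64            11 1.698018 4.055916e-02
#> 11 background_10      36             7 1.920990 4.566953e-02
```

The planted trait ranks first at 3.8-fold enrichment; the 27 uniform
background traits stay near fold 1 with unremarkable p-values.

A thin command-line wrapper is installed as `exec/poolqtl`
(subcommands `simulate`, `call`, `enrich`, `overlap`; every stage
writes a manifest with input/output hashes, parameters and seed).

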