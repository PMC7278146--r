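---
title: "Mapping molecular QTLs from pooled sequencing assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping molecular QTLs from pooled sequencing assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolqtl)
```

## The model

A pooled molecular-QTL experiment mixes material from $J$ genotyped,
phased diploid cell lines into a single assay library (ChIP-seq for
transcription-factor binding, ATAC-seq for chromatin accessibility, Hi-C
for chromosomal looping) and sequences the pool once.  Each line
contributes an unknown, unequal fraction $\pi_j \ge 0$, $\sum_j \pi_j =
1$, of the assayed material.  At SNP $i$ with alternative-allele dosage
fraction $g_{ij} \in \{0, \tfrac12, 1\}$, the allele frequency the
library *should* show, absent any cis-acting effect, is the pre-assay
frequency

$$ f^{\mathrm{pre}}_i = \sum_j \pi_j \, g_{ij}. $$

A cis-acting variant changes how much assayed material each allele
produces.  We model this as a multiplicative fold-change $e^\beta$ on
the allelic odds,

$$ f^{\mathrm{post}} = \frac{f^{\mathrm{pre}} e^{\beta}}
   {f^{\mathrm{pre}} e^{\beta} + 1 - f^{\mathrm{pre}}}, $$

which is symmetric in the alleles, keeps frequencies in $[0,1]$, and
leaves pool-monomorphic SNPs fixed.  A SNP whose observed post-assay
frequency departs from its predicted pre-assay frequency is a candidate
QTL for the assayed phenotype: a binding QTL (bQTL) from ChIP reads, an
accessibility QTL (caQTL) from ATAC reads, or a looping QTL (clQTL)
from allele-tagged Hi-C contacts inside loop anchors.

Two properties make the design robust.  First, $\pi$ is estimated from
the post-assay frequencies themselves (`estimate_pool_proportions()`),
so genome-wide (trans) differences between lines — one line simply
having more of the assayed factor — inflate pre- and post-assay
frequencies alike and cancel in the per-SNP comparison.  Second, each
SNP's test conditions on its own predicted pre-frequency, so only local
(cis) departures register.

## Estimating pool proportions

`estimate_pool_proportions()` solves the depth-weighted least-squares
problem

$$ \min_{\pi \in \Delta} \sum_i w_i \left( \hat f^{\mathrm{post}}_i -
   \textstyle\sum_j \pi_j g_{ij} \right)^2, \qquad
   w_i \propto \mathrm{depth}_i, $$

over the probability simplex $\Delta$.  The weights reflect that the
variance of an observed frequency scales as $1/\mathrm{depth}$.  We
deliberately solve the simplex-constrained problem rather than
unconstrained or nonnegative least squares followed by renormalization:
renormalizing an NNLS solution does not minimize the constrained
objective (on typical simulated pools the two differ by around $10^{-4}$
per coordinate, far above the reproducibility we target), whereas the
simplex problem has a unique minimizer whenever the genotype columns are
linearly independent.  The solver is an accelerated projected gradient
(FISTA with adaptive restart) on the precomputed normal equations, with
an exact sort-based simplex projection, iterated to a $10^{-13}$
fixed-point tolerance; the test suite checks it against an independent
plain projected-gradient solver to $10^{-6}$ elementwise.  Only SNPs
with at least `min_depth` (default 20) reads enter the regression; with
fewer usable SNPs than individuals the system is underdetermined and
the fit refuses to proceed.

## The per-SNP test

Given $\hat f^{\mathrm{pre}}_i$, the alternative-read count at SNP $i$
is compared with $\mathrm{Binomial}(\mathrm{depth}_i, \hat
f^{\mathrm{pre}}_i)$ by a two-sided exact binomial test.  By default we
report the **mid-p** value, which halves the probability mass of the
observed count in each tail before doubling the smaller tail.  With
discrete counts the classical doubled tail is strictly conservative at
every depth: on a null pool at depth 50 its rejection rate at nominal
$\alpha = 0.05$ is about 0.034, and its p-values are visibly
super-uniform.  The mid-p correction restores near-nominal type-I error
(the test suite checks $\alpha \in \{0.05, 0.01, 10^{-3}\}$ within
three binomial standard errors on 10,000 null SNPs, and
Kolmogorov–Smirnov uniformity of the null p-values) while remaining an
exact-distribution computation.  `method = "tail"` gives the classical
doubled tail.  The standardized shift
$z = (\hat f^{\mathrm{post}} - \hat f^{\mathrm{pre}}) /
\sqrt{\hat f^{\mathrm{pre}}(1 - \hat f^{\mathrm{pre}})/\mathrm{depth}}$
is reported for ranking and plotting only.  SNPs monomorphic in the pool
carry no information about allelic effects and are excluded.  No
overdispersion term is fitted; pooled read counts at a SNP are modeled
as binomial given the pool composition, and the calibration checks
above are the evidence this suffices at the simulated depths.

Significant QTLs are called at `p_cutoff` (default $10^{-3}$).  When a
previously published QTL set for a related cell type is available,
`optimize_cutoff()` chooses the cutoff maximizing the fold enrichment
of calls in that reference relative to clearly-null SNPs ($p > 0.5$),
ties broken toward the stricter cutoff.

## Upstream: reference mapping bias

Aligner indices contain reference alleles only, so alt-carrying reads
mismap more often, inflating reference-allele frequencies.
`filter_biased_reads()` implements allele-swap remapping: every mapped
read overlapping $k \le 5$ SNPs is rewritten with each of the $2^k - 1$
other allele combinations and remapped; the read survives only if every
rewrite maps uniquely back to its original position.  A biased locus
thus loses *all* of its reads rather than one allele's worth, which is
what removes the bias.  Reads covering more than five SNPs are dropped
outright (the swap set doubles per SNP), and paired ends are filtered
independently with a pair kept only when both mates pass.  The aligner
is an injected contract — any deterministic function from sequence to
candidate positions — and the package bundles a best-stratum
exact/1-mismatch matcher over a synthetic toy genome in which a chosen
fraction of SNP loci carries an alt-allele decoy elsewhere in the
genome, giving a deterministic, fully testable model of
reference-favoring misalignment.  Upstream of everything, SNPs at
pooled minor-allele frequency of 2.5% or below are excluded
(`filter_maf()`).

## The looping phenotype

Hi-C contact pairs are assigned a ref/alt tag from the phased SNPs
their reads cover (`assign_contact_alleles()`); pairs whose SNPs imply
conflicting alleles are discarded and counted.
`loop_allele_counts()` then counts, per SNP, the tagged contacts whose
two ends fall in the two anchors of a chromatin loop (read from BEDPE)
containing that SNP.  Anchor membership is half-open ($s < p \le e$)
both for SNPs and contact ends; contacts with both ends in one anchor
are counted by default (`both_in_one_anchor = FALSE` disables this);
a contact never counts more than once per SNP even when several
overlapping loops match.  A SNP's contacts are aggregated across all
its loops into a single count — one test per SNP, with the supporting
loop ids carried in the output — rather than tested per loop.  The
result is an ordinary allele-count table, and clQTLs are called by the
identical regression and test machinery; SNPs outside every anchor are
structurally never tested.

## Downstream analyses

**GWAS association.**  `window_enrichment()` counts, per trait, the
catalog lead SNPs within $\pm 1$ kb of any QTL (a lead counts once
however many windows it hits) and tests the count against the pooled
in-window rate of a set of background traits with an upper-tail
binomial test — mid-p again, for the same calibration reason, and the
background-trait rate rather than a genome-length fraction because the
background traits are the explicit null catalog.  `pair_qtls_with_leads()`
enumerates QTL/lead pairs separated by strictly less than 100 kb and
attaches phased-haplotype $r^2$ (`r2_phased()`, direct haplotype
counting, no EM); `r2_ratio_ranking()` ranks traits by the fraction of
pairs with $r^2 > 0.8$, and `r2_distribution_comparison()` contrasts
the $r^2$ distributions of pairs involving significant ($p < 10^{-3}$)
versus non-significant ($p > 0.5$) QTLs with a one-sided Mann–Whitney
test.

**Overlap.**  `exact_overlap()` intersects QTL sets by variant identity
(chromosome, position, alleles; a position-only switch exists because
some published tables omit alleles), and `ld_overlap()` extends
matching to proxies with $r^2 > 0.8$ within 100 kb.
`directional_concordance()` cross-tabulates favored alleles — the
allele whose post-assay frequency exceeds its prediction, i.e. the
bound allele of a bQTL or the open allele of a caQTL — over shared
variants and applies Fisher's exact test.  `density_profile()` and
`anchor_signal_comparison()` give the positional colocalization views:
QTL density around feature sites versus non-significant QTLs, and
coverage-like signal on loop anchors with versus without clQTLs.

**Motifs.**  `scan_pwm()` scores log2-odds position weight matrices
(JASPAR pfm or MEME minimal input) over both strands, with `N` scoring
as background.  A hit requires at least 80% of the PWM's maximum
achievable score — published scanners calibrate thresholds internally
and do not print them, so we use a deterministic, configurable rule —
after a 0.01 pseudocount per matrix cell.  `motif_enrichment()`
compares hit fractions between significant and non-significant QTL
windows ($\pm 50$ bp) by upper-tail binomial with the background
fraction as null rate and Benjamini–Hochberg FDR at 0.1%.
`allele_specific_enrichment()` builds $\pm 20$ bp windows around each
QTL that differ *only* at the center base (favored versus disfavored
allele; windows are $2 \cdot 20 + 1 = 41$ bp because a substituted
center base needs odd length), and tests both directions; any
significant motif therefore necessarily overlaps the variant itself.

**Gene assignment.**  `assign_qtl_genes()` pairs QTLs with genes whose
TSS shares a loop anchor (`same_anchor`) or sits in the opposite anchor
of the same loop (`cross_anchor`); both classes are emitted separately
so either reading of "overlapping the two anchors" is recoverable, and
gene-body membership is available as an option.  `shared_targets()`
intersects the target lists of several QTL classes.

## The synthetic-data generator

Because the original pooled libraries are raw sequencing data far
beyond desk scale, the package ships a generator whose defaults define
the study conditions every test runs under: 65 diploid individuals
(the pool size for the binding and looping assays; the accessibility
pool had 71), 20,000 biallelic SNPs at 500-bp spacing, MAF uniform in
$[0.05, 0.5]$, Poisson read depth with mean 50, pool proportions from a
symmetric Dirichlet with concentration 5 (unequal but exchangeable
lines, a few-fold spread), 5% of SNPs carrying effects with
$\mathrm{sd}(\beta) = \log 2$, LD blocks of 10 SNPs built by copying
haplotype alleles along a block with a 5% per-SNP flip probability
(blocks are unlinked; the two haplotypes of an individual are
independent, so Hardy–Weinberg holds by construction), and 200 loops
with 5-kb anchors and log-normal contact intensities with median 100.
Lead-SNP catalogs draw per-trait lead counts log-normally (median 100):
real catalog traits span orders of magnitude in association counts, and
the resulting mixture of trait sizes is also what makes discrete
binomial null p-values behave almost continuously.  The published pools'
empirical depth and proportion dispersions are not stated anywhere we
could verify, so these are calibration choices, made once.

Every `simulate_*` call derives an independent seed stream from
`config$seed`, so regeneration is bit-identical.  What the generator
does **not** emulate: sequencing error, overdispersed (non-Poisson)
depth, genotyping or phasing error, realistic genome-wide LD decay, GC
or fragment-length biases, and real aligner behavior beyond the toy
contract.  Passing tests therefore demonstrate correctness and
calibration of the statistical machinery under the stated model, not
robustness to artifacts the model excludes.

## Numerical choices and edge cases

* Coordinates: VCF, lead-SNP and QTL tables are 1-based; BED/BEDPE are
  0-based half-open; a variant at $p$ overlaps $(s, e)$ iff $s < p \le
  e$.  Chromosome-name style is harmonized by `normalize_chrom()`.
* Zero-background rates in any binomial enrichment (including
  `optimize_cutoff()`) are floored at $1/(n_{\mathrm{background}}+1)$
  and flagged rather than yielding undefined folds.
* Ties in `optimize_cutoff()` break toward the smaller cutoff; note
  that a reference defined exactly by a p-threshold then ties with
  every stricter cutoff.
* Monomorphic SNPs: excluded from testing; `r2_phased()` returns `NA`
  and pairings skip and count them.
* Degenerate inputs: duplicate genotype columns warn (proportions
  identifiable only in sum); loops with no anchor SNP yield untagged
  contacts that downstream counting drops; variants too close to a
  contig edge yield `NA` windows and are dropped from motif counts.
* Problem sizes in the tests — 10,000-SNP calibration pools, a
  20,000/40,000-SNP consistency pair, 1,000-window motif designs, 100
  null catalogs — are the package's chosen desk-scale study conditions.

## Known limitations

The per-SNP binomial ignores any extra-binomial variation a real pooled
library may show; a beta-binomial option is a natural extension.  The
proportion regression assumes the genotype matrix is column-full-rank
(near-duplicate lines weaken it).  Pool proportions are estimated per
assay, not shared across assays.  Trans effects, haplotype-level tests
and conditional secondary signals are out of scope, as are peak
calling, loop calling, alignment and genotyping themselves: the package
consumes their standard outputs.
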