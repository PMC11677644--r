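---
title: "Windowed selection scans for germplasm panels: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed selection scans for germplasm panels: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silkscan)
```

## What the package computes

`silkscan` compares two (or three) populations of diploid individuals —
typically panels of silkworm strains maintained as germplasm resources —
from biallelic SNP genotypes. The analysis surface is the classic
resequencing selection scan:

* **nucleotide diversity** $\pi$ per sliding window, per population;
* the **$\pi$ ratio** between the two populations per window;
* the **fixation index** $F_{ST}$ per window;
* empirical-quantile **outlier windows**, merged into candidate selection
  regions, annotated with genes and tested for GO-term over-representation;
* a **neighbor-joining tree** on a genotype distance, and
* **trait comparisons** (mean $\pm$ SEM, Student's *t*, significance stars).

Every stage can be exercised end to end on synthetic data with known ground
truth (`sim_config()` / `simulate_study()`), which is how the test suite
validates the pipeline.

## Statistical models

### Windowed $\pi$

For a window of span $L$ bp, with alt-allele frequency $p_s$ at each
polymorphic site $s$ in the window,

$$\pi = \frac{1}{L}\sum_s 2\,p_s(1-p_s).$$

The plug-in term $2p(1-p)$ is exactly the probability that two haplotypes
drawn *with replacement* from the population differ at the site, i.e. the
frequency-weighted pairwise-difference form of $\pi$; the test suite checks
this equivalence against an explicit haplotype-pair enumeration oracle to
$10^{-12}$. `unbiased = TRUE` applies the $2N/(2N-1)$ correction for
sampling haplotypes without replacement; the default stays with the plug-in
form because the windowed statistic is used comparatively (between
populations and between windows), where the common factor cancels. The
denominator is the full window span, not the SNP count, so windows are
comparable; a window with no variant site has $\pi = 0$, and windows with
fewer than `min_snps` SNPs are reported as undefined by the scan driver.

### Windowed $F_{ST}$

Two estimators are exposed. The default (`"nei"`) is the heterozygosity
ratio-of-sums

$$F_{ST} = 1 - \frac{\sum_s H_{S,s}}{\sum_s H_{T,s}},\qquad
H_{S,s} = \tfrac12\left(2p_{1s}(1-p_{1s}) + 2p_{2s}(1-p_{2s})\right),\qquad
H_{T,s} = 2\bar p_s(1-\bar p_s),$$

with $\bar p_s$ the *unweighted* mean of the two group frequencies. This is
the unique common estimator that satisfies the two defining endpoints
exactly: identical allele frequencies give $F_{ST}=0$ in every window, and
fixation for opposite alleles gives $F_{ST}=1$. Those endpoints are asserted
as exact equalities in the tests and recomputed from scratch by
`scripts/acceptance.R`.

The `"hudson"` estimator uses the between/within form

$$F_{ST} = \frac{\sum_s\left[(p_{1s}-p_{2s})^2
 - \frac{p_{1s}(1-p_{1s})}{n_{1s}-1} - \frac{p_{2s}(1-p_{2s})}{n_{2s}-1}\right]}
 {\sum_s\left[p_{1s}(1-p_{2s}) + p_{2s}(1-p_{1s})\right]},$$

with $n_{ks}$ the called allele counts. The numerator's correction removes
within-population sampling noise, which makes this the estimator whose
expectation equals the Balding–Nichols differentiation parameter $F$
(below). The two estimators answer different questions and both are kept:

* For **ranking windows** (outlier scanning) the Nei form is the default —
  it is bounded in $[0,1]$ and matches the endpoint definitions.
* For **estimating $F$ itself** the Hudson form must be used. With only
  $K=2$ demes the Nei plug-in has expectation $\approx F/(2-F)$ (about
  0.053 at $F=0.10$) plus a small sampling inflation, because the
  between-deme variance seen by two demes is half the among-deme variance
  and the within-deme heterozygosity is estimated with bias; the Hudson
  corrections cancel both effects. The parameter-recovery test therefore
  runs the scan with `estimator = "hudson"` and recovers $F = 0.10$ within
  $\pm 0.03$ from $2\times30$ diploids and 20\,000 SNPs.

Sites with an undefined frequency in either group are excluded; a window
with $\sum_s H_{T,s} = 0$ (or no informative site) is undefined, never
`NaN`.

### Outlier windows and regions

Thresholds are empirical quantiles of the defined window values, computed
by sorted-order linear interpolation (the type-7 convention of
`stats::quantile`), which keeps the procedure deterministic and citable.
$F_{ST}$ is scanned one-sided (default upper 5%); the $\pi$ ratio two-sided
(default 2.5% / 97.5%), the upper tail marking elevated relative diversity
in the numerator population and the lower tail in the denominator
population. Flagging is strict (`>` / `<`), so a degenerate distribution
where every window equals the threshold flags nothing, and undefined
windows are never flagged. Fewer than 20 defined values is treated as too
little data: a warning, no outliers. Whether the "95% interval" of such
scans is an empirical band or a parametric interval is a genuinely open
convention; the empirical quantile band was chosen because it makes no
distributional assumption about window statistics, which are strongly
non-normal.

Flagged windows of one direction are merged when they overlap **or are
bookended** (end equals next start): with 50%-overlapping sliding windows,
adjacency means the underlying signal is continuous. Genes are attached to
a region on at least 1 bp of overlap (the permissive bedtools-style rule),
with no flanking extension. Merging and intersection are delegated to
`GenomicRanges`.

### GO enrichment

Differentiation genes — genes in high-$F_{ST}$ regions — are tested per GO
term with the one-sided hypergeometric over-representation p-value
$P(X \ge k)$, computed by exact summation in log space and cross-checked in
the tests against the independent survival-function implementation to
$10^{-10}$. The universe is all GO-annotated genes in the supplied map;
genes without annotation are dropped from both sets before counting, so the
reported gene ratio $k/n$ uses the annotated foreground size. Q-values are
Benjamini–Hochberg (`stats::p.adjust`). Terms are tested exactly as
annotated — no ontology ancestor propagation — which keeps the test
assumptions minimal but means parent terms only appear if annotated
directly.

### Phylogeny

The tree stage works on the dosage distance
$d(i,j) = \mathrm{mean}_s\,|g_{is}-g_{js}|/2 \in [0,1]$ over co-called
sites, optionally after averaging dosages within strains
(`dosage_dist(gm, by = ...)`). Tree construction is classic neighbor
joining (Saitou–Nei $Q$ criterion), which is exact on additive distance
matrices — the property the tests verify against path-length recomputation
on random tree-derived matrices, with `ape::nj` as an independent
cross-check. Determinism is pinned down by breaking $Q$ ties on the
lexicographically smallest pair of cluster labels, and negative branch
lengths (possible on non-additive input) are clamped to zero with the
deficit moved to the sibling branch so the pair's summed length is
preserved. Maximum-likelihood tree building is deliberately out of scope:
the claim the pipeline supports — an admixed/intermediate population sits
*between* its two source populations — is purely topological, and
distance-based NJ tests it at a fraction of the cost. Note that the
intermediate group need not be monophyletic: with independently admixed
individuals NJ may attach them as a grade along the backbone between the
two parental clades, which still satisfies "between"; the tests therefore
assert monophyly of the parental groups (which forces every cross-parental
path through the intermediate attachments) plus the strain-mean distance
ordering, not monophyly of the admixed group.

### Trait statistics

Traits are summarised as mean $\pm$ SEM ($s/\sqrt n$; a single observation
is an error, not SEM 0). Group comparison is the pooled-variance two-tailed
Student's *t* with $n_A+n_B-2$ degrees of freedom — the stated convention
for this kind of trait panel — with Welch available behind `welch = TRUE`.
Stars follow `* p < 0.05, ** p < 0.01, *** p < 0.001, n.s.` with strict
inequalities, so a p exactly on a boundary takes the weaker label (the
published convention leaves $p = 0.05$ unlabelled; the strict rule resolves
it). Zero pooled variance is conventionally $p=1$ (equal means) or $p=0$
(unequal means, logged). Uniformity percentages classify as uniform
($>90$), relatively uniform ($80$–$90$ inclusive), non-uniform ($<80$).

## The synthetic-data generator

`sim_config()` defines the study conditions; its defaults are the
conditions under which the pipeline's guarantees are stated:

* **Allele-frequency model**: ancestral $p \sim U(0.05, 0.95)$; population
  frequencies $p_k \sim \mathrm{Beta}\!\left(p\frac{1-F}{F},
  (1-p)\frac{1-F}{F}\right)$, the Balding–Nichols model, giving
  $\mathrm{E}[p_k]=p$ and $\mathrm{Var}[p_k]=F\,p(1-p)$ so that $F$ *is*
  the expected differentiation. $F \le 10^{-6}$ degenerates to $p_k = p$
  exactly. Chosen over coalescent simulation because the closed-form link
  between $F$ and $F_{ST}$ gives an analytic acceptance surface with no
  external simulator.
* **Defaults**: 2 populations $\times$ 30 diploids, 20 000 SNPs on a 10-Mb
  chromosome, $F = 0.10$, 2% missing calls (typical of filtered
  resequencing genotypes), scanned with 100-kb windows stepped 50 kb.
  Sweep-detection checks plant five 100-kb windows at $F_{\mathrm{high}} =
  0.6$ over an $F = 0.05$ background across $\ge 200$ windows.
* **Genotypes**: dosage $\sim \mathrm{Binomial}(2, p_k)$ per individual,
  independent sites (no linkage disequilibrium), positions uniform without
  replacement. Annotation tiles disjoint genes uniformly and plants a
  "selected-linked" GO term at probability 0.9 inside selected windows vs
  0.05 outside, so enrichment is detectable by construction. Trait tables
  are Normal draws; the default specifications mirror the headline
  country contrasts (egg number 505 vs 631 with SD 60 at $n=15$, stage
  durations, normal-egg rates) with SDs chosen once as field-plausible.
* **Determinism**: the seed is mandatory and every stage derives a fixed
  sub-stream from it, so identical configs give byte-identical VCF / GFF3 /
  TSV outputs.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: linkage disequilibrium and local
correlation of window statistics, mutation-rate and recombination-rate
heterogeneity along chromosomes, sex-chromosome dosage (all chromosomes are
treated as autosomal diploid), genotyping error beyond missingness, and
demographic history beyond a single differentiation parameter. Empirical
thresholds on real genomes should be read with those caveats.

## Numerical and interface choices

* Coordinates are converted from 1-based (VCF, GFF3) to 0-based half-open
  exactly once, at read time; all window arithmetic is half-open.
* Multi-allelic records and indels are dropped, not split — the windowed
  statistics are defined for biallelic frequencies. Half-calls are missing;
  phased separators are accepted and ignored (all statistics are
  phase-free).
* The pooled frequency $\bar p$ is the unweighted mean of the defined group
  frequencies, which is what makes the $F_{ST}=1$ endpoint exact under
  unequal group sizes; call-count weighting is available via
  `site_frequencies(..., weighted = TRUE)`.
* Windows start at $0, s, 2s, \dots$ while the start advances coverage by a
  full step ($\mathrm{start} \le \mathrm{length} - s$); the trailing window
  is truncated at the chromosome end, and a chromosome shorter than one
  window yields the single window $[0, \mathrm{length})$.
* Undefined is always `NA` plus (where relevant) an explicit flag — never a
  propagated `NaN`; degenerate inputs (empty windows, all-missing groups,
  zero denominators) have defined, documented outcomes.
* The headline scan pools all samples of a country/group; per-strain $\pi$
  is available by passing a strain-level `population_set`.

## Problem sizes in the test suite

The shipped tests run the full stack at deliberately desk-scale sizes: the
parameter-recovery scan uses the default 2 $\times$ 30 diploids and 20 000
SNPs; sweep detection 201 windows; oracle equivalences 200 (π) and 100
(hypergeometric) random instances; NJ exactness 50 random additive matrices
of up to 8 taxa; and the end-to-end demo ~60 windows with one planted
sweep. These sizes were chosen so the whole suite completes in well under a
minute while keeping every Monte-Carlo band at three standard errors.

## Known limitations

Beyond the generator caveats above: no LD-aware statistics (XP-EHH, iHS),
no kernel smoothing of window values, no parametric confidence intervals,
no GO DAG handling, no bootstrap support on trees, and the sex chromosome
is not special-cased in diversity calculations (its effective population
size differs, so its $\pi$ and $F_{ST}$ levels are not directly comparable
to autosomes — a caveat, not a correction the package applies).
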