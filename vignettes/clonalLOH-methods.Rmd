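---
title: "Methods: detecting LOH and deconvolving its mechanisms in clonal hybrid genomes"
author: "clonalLOH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting LOH and deconvolving its mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Asexual hybrids and allopolyploids carry two (or three) divergent
parental subgenomes that are expected to stay heterozygous under strict
clonal reproduction. In practice heterozygosity erodes gene by gene:
at sites where the parental species are fixed for different alleles
("diagnostic SNPs") a hybrid sometimes turns up homozygous — a loss of
heterozygosity (LOH). Two mechanisms can produce an LOH call:

* **gene conversion** — one allele overwrites its homolog; total copy
  number is conserved, so sequencing depth is unchanged;
* **deletion** — one (hemizygous) or two (double, triploids only)
  allelic copies are physically lost; depth drops in proportion.

`clonalLOH` implements the full inference chain from genotype calls and
per-site read depth to mechanism proportions: quality filtering and
SNP categorisation, diagnostic-site discovery, clonal lineage (MLL)
assignment, LOH calling, a within-gene contiguity permutation test,
read-depth mixture deconvolution, GC-bias tests, and links between LOH
and gene function/expression. A synthetic genome generator with a
complete truth ledger makes every stage testable without external
data.

## Containers and conventions

Genotypes are *unordered allele sets* encoded as sorted strings
(`"A"`, `"A/G"`). This deliberately mirrors a diploid-style caller
applied to triploids: a site is heterozygous when at least two distinct
alleles are present, so loss of one copy of a doubled subgenome (e.g.
EET keeping E,E,T → E,T after losing one E) is *invisible* — only full
homozygosity counts as LOH. Coordinates are 1-based, VCF convention;
one contig per gene because the reference is a transcriptome, which is
also why tract events truncate at gene boundaries and why LOH
contiguity is measured in gene-internal site order rather than
physical distance.

Filtering defaults follow standard exome practice: per-call DP ≥ 10
and GQ ≥ 20 (sub-threshold calls become missing), and only sites with
at most two allele states across the whole data set are kept.

## Diagnostic sites and SNP categories

A site is diagnostic for a species pair when every non-missing
individual of side 1 is homozygous for one allele and every individual
of side 2 — *jointly* over its species for composite sides such as
E–TN — is homozygous for a different allele, with at least 2
non-missing individuals per side. Strict monomorphism is the default
(`max_minor_count = 0`); a tolerance is available for noisy data.

Hybrid SNPs are classified into the ten standard categories. Where the
category glosses underdetermine the scheme we chose: `pr1a`/`pr1b`
split private-asexual variants by het/hom state (both classes are
needed for statements like "almost all private SNPs are
heterozygous"); `prh2b` vs `prh2b1` distinguish which parental side
carries private heterozygosity. Diagnostic sites where the hybrid is
homozygous map to `sh3b11` (side-1 allele retained) or `sh3b12`
(side-2) — these are the LOH classes.

## Clonal structure

Pairwise distance is the mismatch proportion of genotype multisets
over jointly non-missing sites. The clone-defining threshold `d*` is
read off a Gaussian kernel density (Silverman's `nrd0` bandwidth) of
the off-diagonal distances as the *deepest internal valley*: among all
internal local minima, the one whose flanking peaks rise highest above
it. The naive "valley between the two tallest modes" rule fails when
within-clone pairs are few — both top modes can then sit on ripples of
the dominant between-clone mode. A unimodal density is an explicit
error unless the caller supplies a threshold; detection never fails
over silently. MLLs are single-linkage connected components under
`d*` (the natural match to thresholding raw pairwise distances;
complete linkage is available).

Expected hybrid heterozygosity splits each parental individual into
two pseudohaplotypes *without phasing* (alleles in fixed sorted order
at het sites) and crosses every side-A pseudohaplotype with every
side-B one. Phase does not affect the expectation over crosses, which
is all the statistic is used for.

## LOH calling and contiguity

`call_loh` emits one call per diagnostic site at which the hybrid is
homozygous for either parental allele; homozygosity for a third allele
is excluded (counted separately). On zero-noise simulator output the
calls equal the truth ledger exactly — that is an acceptance
criterion, not an assumption.

Within each gene the contiguity score is `S = sum_i n_i^2` over
maximal runs of consecutive diagnostic sites that are all LOH; squaring
up-weights uninterrupted tracts relative to the same number of
scattered sites. Missing genotypes break runs by default (an unknown
state never bridges a gap; a skip-missing mode exists). The
permutation test redistributes the observed LOH count uniformly over
the sample's non-missing diagnostic sites across all genes and uses
the add-one estimator `p = (1 + #{S_perm >= S_obs}) / (n_perm + 1)`,
so `p` is never 0; zero LOH returns `p = 1` by convention.

## Coverage deconvolution

Depth is normalized by total read count (`raw × mean(totals) /
sample_total`), which cancels library size *and* ploidy. Relative
coverage of a hybrid at an LOH site is its normalized depth divided by
the mean normalized depth of the parental panel at the same site; the
expectation is ≈1 for conversions, ≈0.5 for diploid hemizygous
deletions, ≈2/3 and ≈1/3 for triploid single and double deletions.
Values are clipped at 2.0 before binning (clipped count logged) and
binned by the Freedman–Diaconis rule `h = 2·IQR·n^(−1/3)`.

The binned density is fitted by nonlinear least squares at bin
midpoints (unweighted by default; Poisson-type weights available) with
mixtures of Gamma densities `sum_j A_j · Gamma(x; k_j, rate = k_j/mu_j)`
whose means are fixed at the mechanism values; shapes and amplitudes
are free, `A_j ≥ 0`. The deletion fraction is `B/(A+B)` (resp.
`(B+C)/(A+B+C)`). Optimisation is bounded L-BFGS-B with multi-start
(`k ∈ {5, 20, 80}`, amplitudes initialised from the histogram mass on
either side of the midpoint between component means, plus a degenerate
all-mass-on-component-1 start so the single-Gamma solution is always
in the candidate set and RSS nesting holds numerically). Parameter
covariance is the Gauss–Newton approximation with a numerical
Jacobian; the A/B ratio CI is delta-method. Free-parameter counts for
residual df are 2 per fixed-mean component (+1 for a free mean):
single = 2, two-component = 4, three-component = 6, free-mean single
= 3 — this bookkeeping reproduces published df pairs differing by 2
between single and two-component fits, and by 1 for the forced-ratio
contrast.

### Calibration of the model-comparison F test

`compare_variance_ratio` uses the residual-variance-ratio form
`F = (RSS_simple/df_simple) / (RSS_complex/df_complex)` against
`qf(1 − alpha, df_simple, df_complex)`, because exactly this form
reproduces the critical values printed alongside published fits of
this kind (e.g. 1.71 at df {40,38}). One should know what that buys:
the two RSS come from nested fits of the *same* histogram, so under
the null RSS_complex ≈ RSS_simple and F ≈ df2/df1 < ~1.1. We measured
the type-I error by simulation (single Gamma, n = 2000, k = 40, 1000
reps): it is ~0, not the nominal 5%. The test is therefore strongly
conservative — a rejection is trustworthy, a non-rejection is weak
evidence — and the acceptance check that asserts ≈5% type-I for this
statistic is knowingly left red rather than silently replaced by the
incremental-SS form, which would calibrate but would not match the
published critical values. The AICc comparison
(`n·ln(RSS/n) + 2K + 2K(K+1)/(n−K−1)`, `K` = free parameters + 1)
handles the non-nested mixture vs free-mean-single contrast.

The forced-ratio test refits the mixture with A/B pinned to the donor
fit's 95% CI bound nearest the acceptor's free estimate and compares
forced vs free fits by the same F form. The site-matched KS test
builds a conversion-only null from the parental panel itself —
leave-one-out relative coverages at exactly the hybrid's LOH sites —
and compares distributions two-sample; deletions show up as an excess
of low-coverage LOH sites.

## GC bias

Each LOH event is classified by the lost→retained substitution:
weak-to-strong (A/T→G/C), strong-to-weak, or GC-neutral (A↔T, G↔C).
Counts per retained-ancestry class are compared against the
interparental divergence baseline of matching polarity over all
diagnostic sites, in a 2×3 contingency table (2×2 with neutral
collapsed as an option) by chi-square, with a seeded Monte-Carlo p
when expected cells fall below 5, and Benjamini–Hochberg correction
across samples within an ancestry class. Note the baseline row should
dwarf the LOH row (as it does in real data, where it spans all
diagnostic sites); with a small reference row the independence
statistic becomes conservative.

## Functional links

TPM normalisation is exact (`columns sum to 1e6`). Expression, ASE
log2 fold change and dN/dS comparisons between LOH-positive and
LOH-negative genes use Wilcoxon–Mann–Whitney tests (dN/dS one-sided,
LOH-positive lower) with BH correction across strata; the dN/dS rank
test is a deliberate, flagged substitute for a linear mixed model with
individual pairs as a random factor. Gene-set enrichment is the exact
upper-tail hypergeometric restricted to genes in which LOH was
detectable, with a GO-structure-agnostic family-wise permutation
correction: the corrected p of a term is the fraction of size-matched
random test sets whose *minimum* per-term p is at or below the
observed one.

## The synthetic world

The generator states a world and the tests live in it:

| parameter | default | rationale |
|---|---|---|
| parental individuals | 10 per species | phylogeographically broad panel; enough to make accidental monomorphism negligible |
| genome | 9,500 genes × 20 sites = 190,000 SNPs (coverage experiments) | scale of a quality-filtered fish exome SNP set, so ~2,000 LOH events stay a ~1% perturbation of per-sample totals |
| depth per haploid copy | 50 | exome-capture scale; diploid sites average ~100× |
| capture efficiency | lognormal, log-SD 0.7, shared across individuals | capture probes behave consistently across libraries; this is exactly the variance relative coverage cancels |
| library size factor | lognormal, log-SD 0.3 (field added to the stated parameter set) | without library-size variation total-count normalization would be an untestable no-op |
| count dispersion | negative binomial, size 60 | together with Poisson noise gives relative-coverage shapes near the k ≈ 40 Gamma used in published fits; `Inf` = Poisson limit |
| tract length | geometric, mean in gene-internal sites, truncated at gene ends | standard conversion-tract model; no empirical tract-length law exists for this system, so it is a free simulator parameter |
| template bias | P(retain E) = 0.8 by default; GC template preference as multiplicative weight (1+g) per G/C-bearing tract site | reproduces the observed ~80–87% E retention and WS substitution excess |
| private mutations | rate `age` per ancestrally monomorphic site, heterozygous on one copy | matches the observation that nearly all private asexual SNPs are heterozygous |

Triploid semantics worth restating: conversions homogenize all
surviving copies at a site to the template side's allele (so one event
can produce either homozygote); deletions remove uniformly chosen
copies and never the last one. In an EET clone only deletions hitting
the single-copy subgenome surface as LOH — simulating "50% deletions
among LOH sites" therefore requires a hemizygous-deletion initiation
rate of 3× the conversion rate, and the acceptance machinery measures
the realized mechanism mixture from the truth ledger rather than
assuming it.

What the generator does **not** emulate: mapping error and paralogy
(the reference-transcriptome filtering that removes pseudo-paralogous
contigs is upstream of this package), indels, crossovers between
orthologs (excluded in the modelled system by karyotype evidence),
GC- or mappability-dependent capture bias, and ancestral-polymorphism
false positives. A green test therefore establishes correctness of the
inference chain on clean clonal data, not robustness to reference
artefacts.

## Numerical choices and degenerate inputs

* Every stochastic entry point takes an explicit integer seed and
  restores the caller's RNG state; identical seeds give identical
  output.
* `fd_histogram` falls back to a fixed bin count with a warning when
  the IQR is zero; fewer than 4 values is an error.
* Mixture fits refuse histograms with fewer bins than free parameters;
  AICc errors when `n − K − 1 ≤ 0`.
* Zero-overlap sample pairs give `NA` distances with a warning; a
  degenerate (all-equal) distance distribution is an explicit error
  unless a fallback threshold is supplied.
* The permutation p never reaches 0 (add-one); single-LOH and zero-LOH
  samples return p = 1.
* GC-bias tests with <2 events in a class, or degenerate margins, are
  skipped with a flag rather than guessed.

## Known limitations

* The mechanism labels in the truth ledger record the *net* outcome at
  a site; when tract events overlap (rare at realistic rates), a
  converted-then-deleted site is ledgered as a deletion.
* Relative-coverage means carry a small (~1%) upward shift from the
  hybrid's own lost copies entering its normalization total; at the
  default genome scale this is well inside the ±0.02 acceptance band,
  and the effect exists in real data too.
* `classify_snps` is O(sites × samples) with per-site allele pooling;
  it is meant for filtered matrices (10^5 sites), not raw genome-wide
  call sets.
* The variance-ratio F test is conservative by construction (see
  above); treat non-rejections accordingly.
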