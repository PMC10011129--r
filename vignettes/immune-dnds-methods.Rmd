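---
title: "Estimating immune selection with ON/OFF-immunopeptidome dN/dS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating immune selection with ON/OFF-immunopeptidome dN/dS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunodnds)
```

## The model

Somatic point mutations that change a protein (nonsynonymous) can create
neoantigens: peptides presented on MHC class I molecules and visible to
T cells. If the immune system removes cells carrying such mutations, the
surviving tumor shows a *deficit* of nonsynonymous mutations specifically
inside the regions whose peptides its MHC alleles can present -- the
immunopeptidome. This package quantifies that deficit as a ratio of two
dN/dS values:

* **ON-target dN/dS** -- the nonsynonymous/synonymous rate ratio restricted
  to mutations inside the immunopeptidome;
* **OFF-target dN/dS** -- the same quantity outside it;
* **immune dN/dS = ON / OFF**.

Each dN/dS is `(n_N / L_N) / (n_S / L_S)`, where `n` are observed mutation
counts and `L` are context-weighted expected site counts for the same
region. Dividing ON by OFF cancels dataset-wide artifacts (germline
contamination, over-filtering, caller bias) that push a raw dN/dS away
from 1, under the working assumption that mutations outside the
immunopeptidome are mostly non-antigenic and therefore effectively
neutral. Immune dN/dS below 1 indicates immune editing; approximately 1
with mutated antigen-presentation genes indicates immune escape.

### The 192-class trinucleotide correction

Mutation rates in tumors depend strongly on the local trinucleotide
context (most famously, C>T at CpG). A naive count of possible
synonymous/nonsynonymous changes therefore mis-states the neutral
expectation. The site model classifies every possible single-nucleotide
change by its 64 contexts x 3 alternative bases = 192 classes, estimates a
relative rate per class as `observed / available` (normalized so the
availability-weighted mean is 1), and computes

* `L_N` = sum of class rates over all nonsynonymous changes in the region,
* `L_S` = the same over synonymous changes,
* `mu_ratio = L_N / L_S`, the neutral nonsynonymous:synonymous expectation.

With all rates set to 1 this reduces to naive change counting, which is
how the implementation is tested against a brute-force enumeration
oracle. The first and last CDS base have no in-CDS flanking context and
are excluded from both availability and observed counts, keeping the
numerator and denominator consistent. Changes that create or destroy a
stop codon count as nonsynonymous (and are flagged `stop_relevant`);
stop-to-stop changes are synonymous.

Two estimation choices are deliberate defaults rather than unique
answers. First, the spectrum is estimated from *all* OFF-target
single-nucleotide substitutions, not synonymous ones only: the OFF region
is assumed neutral anyway, and using all classes quadruples the counts.
`spectrum_subset = "synonymous"` gives the purer estimator. Second,
zero-count classes get rate 0 rather than a pseudocount; a sparse cohort
can opt into `pseudocount > 0`. Both choices only matter for thinly
mutated inputs.

### Confidence intervals

No interval method is canonical for this ratio-of-ratios. We use the Katz
log-ratio normal approximation: `exp(log v +/- 1.96 * sqrt(1/n_N + 1/n_S))`
for a single dN/dS and all four counts summed in quadrature for the
ON/OFF ratio. A percentile bootstrap (`bootstrap_resample()`, resampling
mutations or patients) is provided as a cross-check; the two agree well on
the synthetic cohorts in the test suite. With `n_N = 0` the point estimate
is 0 and the interval is one-sided; with `n_S = 0` the estimate is
undefined and reported as such rather than patched with pseudocounts --
this matches the analysis-level exclusion filters below.

### Intronic background mode

In `exonic-intronic` mode the OFF-target synonymous per-site rate is
averaged (arithmetic mean) with the intronic per-base rate
`n_intronic / intronic_length`, and OFF-dN/dS is recomputed with the
averaged denominator. Averaging a rate with a *ratio* would be ill-typed,
so the averaging is done on per-base rates; the `off-only` setting
disables the correction without changing anything else. A documented
consequence of the arithmetic mean: with zero observed intronic mutations
the background rate halves. The interval keeps the exonic counting model;
the correction shifts the point estimate only.

## Analysis levels and exclusion rules

`run_cohort()` pools mutations across samples (pooling is tested as an
invariant: splitting or relabeling samples cannot change the estimate)
and refuses to estimate when fewer than 10 mutations fall in the target
region. `run_patient()` estimates per sample against a shared or
per-patient immunopeptidome and reports patients with fewer than
`min_on_synonymous` (default 1, sensitivity range 2-4) ON-target
synonymous mutations as "not estimable -- edited vs escape
indistinguishable": with no synonymous anchor inside the target, a low
nonsynonymous count cannot be told apart from a low mutation rate.
Driver transcripts can be excluded up front (`exclude_transcripts`), and
`randomize_target()` provides the negative control of re-placing the
target intervals uniformly in the exonic universe (placements keep a 1-nt
separation so the interval-length multiset is conserved exactly under
merging).

Patient-level context models are fitted from the pooled cohort OFF
mutations rather than per patient: a single patient rarely has enough
mutations to populate 192 classes, and the model describes the mutational
process, not the patient's selection.

## Downstream interpretation

* `edited_fraction(x)` converts immune dN/dS `x <= 1` into the removed
  fraction `1 - x` (an immune dN/dS of 0.6 means 40% of the expected
  antigenic nonsynonymous mutations were removed); values above 1 return
  0 with an enrichment flag.
* `edited_neoantigens(n_a, n_s, mu_ratio)` reports the signed difference
  from the neutral expectation `n_s * mu_ratio` and the nonnegative
  `removed = max(0, -signed)`. The signed form is the primitive; the
  removed count is a lower bound because OFF-target editing is invisible
  to it.
* `categorize_selection()` labels estimates low / neutral / high with an
  inclusive neutral band [0.82, 1.21] -- 1.21 being the reciprocal of
  0.82 as printed, both configurable -- and reports `d_immune = |x - 1|`.
* `classify_escape()` calls a patient escaped+ on any
  missense/truncating (optionally splice) mutation in a curated
  antigen-presentation gene list, OR-ed with HLA LOH / full-homozygosity
  flags. Synonymous hits never count. The bundled
  `escape_genes_synthetic.txt` is a reconstruction of the usual 88-gene
  antigen processing and presentation set (KEGG hsa04612 plus ERAP1,
  ERAP2, IRF1, PDIA3, FAS, MEX3B); it is a synthetic stand-in and should
  be replaced by a curated list for real cohorts.

## The immunopeptidome builder

Binder tables are an input contract, not something this package
predicts: which peptides bind which alleles depends on the predictor and
its version, which is outside the method. The builder consumes
precomputed records (transcript, 27-nt window, allele, %rank), keeps
records matching the patient's up-to-six class I alleles with
`percent_rank` strictly below the threshold (0.5 = strong binders,
2 = strong + weak), optionally intersects with positive-assay peptides
(exact 9-mer substring of an assay peptide of length >= 9) and an
expression filter (keep transcripts strictly above 1 FPKM by default, or
above 0 for patient-specific expression), and merges the surviving
windows per transcript. Monotonicity (lower rank threshold never enlarges
the set; adding alleles never shrinks it) and the union property (a
multi-allele build equals the union of single-allele builds) are tested
as properties.

## The tumor simulator

`simulate_tumor()` grows a tumor in synchronous generations from 5
founder cells: every cell divides, each daughter draws
`Poisson(mu_per_division = 1)` mutations labeled ON-target with
probability 0.1 and nonsynonymous with probability 0.75; a new ON-target
nonsynonymous mutation is recognized with probability 0.1; each
generation, cells carrying a recognized mutation are killed with
probability `pattack`; the run stops after 100 generations or as soon as
the population exceeds 2,000 cells (a stopping rule, not a logistic
brake). Final cell fractions are computed exactly on a genealogy forest,
over surviving cells only, and mutations below 1% frequency are
discarded. Cohorts keep tumors ending above 1,000 cells and pool retained
counts; because class labels are emitted directly, the neutral
expectation is analytic (`mu_ratio = p_nonsyn / (1 - p_nonsyn)`) and no
context correction is involved.

Unstated mechanistic details are fixed as defaults and exposed in
`sim_config()`: synchronous division of every cell, recognition assigned
once at a mutation's birth (a per-generation re-draw is available via
`recognition = "per-generation"`), and fractions computed over survivors.
One empirical subtlety the tests encode: any positive `pattack` purges
recognized lineages from the *retained* (>= 1% frequency) mutation set
almost completely -- an attacked lineage is a critical-or-subcritical
branching process that rarely reaches 1% of a 2,000-cell tumor -- so the
pooled ON nonsynonymous count drops sharply from `pattack = 0` to 0.5 but
is nearly flat from 0.5 to 1, and the monotonicity test treats the latter
comparison as a near-tie with sampling tolerance.

## Synthetic fixtures and what passing tests mean

`fixture_spec()` + the generators build toy inputs with known ground
truth: stop-free random transcriptomes (default 8-10 transcripts x 300
nt), binder tables whose strong binders cover a requested CDS fraction
(default 0.3-0.4, within one 27-nt window of granularity), and mutation
cohorts drawn from the enumerated single-nucleotide changes, uniformly or
with a CpG-like skew (25x weight on NCG>T changes). Depletion removes
each ON-target nonsynonymous *draw* with probability `d`, so the expected
immune dN/dS is `1 - d` while the site model is untouched -- the
estimator is tested against a process it did not assume. The skewed
neutral fixtures are the regression test for the context correction:
naive counting gives a background dN/dS near 0.82 on them, the 192-class
model restores 1.

The fixtures emulate the input contracts, not real data: no signature
mixtures, no germline variation, no sequencing error, no expression
covariation, and toy-scale transcripts. Passing tests therefore
demonstrate correctness of the machinery and statistical calibration
under the stated generative processes, not performance on real cohorts.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately small
scale, chosen to keep every property testable while each cohort still
carries thousands of mutations: 200 neutral cohorts of 2,000 mutations
for CI calibration, 20 cohorts of 5,000 mutations for depletion
recovery (stochastic means asserted within +/- 0.05 of the target),
simulator arms of up to 1,000 tumors, and 100 transcripts for the
enumeration oracle. Interval arithmetic is 0-based half-open throughout
(BED convention); the 1-based mutation coordinate is converted in exactly
one place. Ties at filter boundaries follow the printed rules: rank
`< 0.5` strict, expression `> 1` strict, neutral band inclusive at both
ends, frequency filter `>= 1%` retained.

## Known limitations

Only already-annotated transcript-space mutation tables are accepted; a
genomic front-end (MAF/VCF + annotation) is future work. Binding
prediction, HLA typing, clonal deconvolution, driver discovery and
survival modelling are out of scope. The cohort-relative copy-number
escape rule is not implemented (it has no principled absolute threshold);
HLA LOH and homozygosity enter only as caller-supplied flags. Parity with
any particular reference implementation's CI method is not claimed.
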