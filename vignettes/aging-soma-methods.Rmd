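---
title: "Models and methods: somatic mutation signatures and transcriptome aging in single brain cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scSomaAging)
```

# The scientific setting

Post-mitotic neurons accumulate somatic single-nucleotide variants (sSNVs)
throughout life. Single-cell whole-genome sequencing of cortical neurons
shows a clock-like accumulation of roughly 15-16 sSNVs per neuron per year,
decomposable into two mutational processes: a dominant, flat-ish,
T>C-weighted process resembling COSMIC SBS5, and a minor C>T-dominant
process resembling SBS30 (the signature of base-excision-repair deficiency).
At the same time, single-nucleus RNA-seq of the same tissue shows that
elderly cells preferentially lose expression of broadly expressed
"housekeeping" genes -- most strongly the shortest ones -- while
neuron-identity genes stay stable, and that a common module of genes is
downregulated across many cell types at once.

This package implements that integrated analysis as reusable, tested
components: trinucleotide-context spectra and their comparison, de novo
signature extraction with rank selection and exposure refitting,
burden-versus-age regression, matched-spectrum random controls for
genic/intergenic and expression-quantile enrichment, transcriptional strand
bias, gene-length-resolved mutation rates, elderly-versus-adult
differential expression with percent-expressed filters, gene-program
classification, a cross-cell-type shared-downregulation permutation test,
and composition/gene-set statistics. Because the underlying human data are
not redistributable, the package ships a synthetic-data generator that
reproduces the statistical structure those analyses assume, so every stage
is verifiable at desk scale.

# The generator and what it emulates

`generatorConfig()` fixes the study conditions. Its defaults are not free
knobs; they encode the published study design and fitted values:

* **Donors and cells.** The 13 packaged donor ages (0.4-104 years; 2 infants, 7
  adults, 4 elderly) with 5 sequenced neurons per donor, matching the
  packaged donor table
  (`donorTable()`; 290,814 snRNA-seq nuclei, 59 scWGS neurons).
* **Clock rates.** Two mutational components accrue `rate_a1 = 13.8` and
  `rate_a2 = 1.8` sSNVs per neuron per year -- the fitted per-signature
  rates -- for a total of 15.6/yr.
* **Birth intercepts.** `intercept_a2 = 25` places a small C>T-dominant
  mutation load at age 0. Neurons are born carrying developmental sSNVs,
  and infant genomes are proportionally dominated by the C>T-rich process;
  without any across-age variation in the signature mix, a two-component
  factorization of per-cell spectra would be unidentifiable (every cell
  would present the same mixture and the mean matrix would be exactly rank
  one).
* **Burden noise.** Per-cell, per-component burdens are negative binomial
  around the age trend (`disp_a1 = 50`, `disp_a2 = 1.4`). Real single-neuron
  fits show clear extra-Poisson scatter (coefficients of determination of
  roughly 0.94 for the major component, ~0.3 for the minor one and ~0.92 for
  the total); pure Poisson noise would give R^2 above 0.99 at these burdens.
  The chosen dispersions reproduce the total-burden R^2 (~0.90) and give the
  minor component the wide per-cell scatter that real data show, which is
  also what renders the two components separable. `disp = Inf` switches to
  Poisson for calibration tests.
* **Signature shapes.** The packaged `referenceSignature()` vectors are
  synthetic 96-context distributions with the qualitative geometry of
  COSMIC SBS5 (T>C-weighted, flat-ish, modest AT-flanked C>T) and SBS30
  (strongly C>T-dominant, CG-flanked). Two geometric facts matter and were
  imposed at construction time: the expected corpus mixture has cosine
  greater than 0.96 to the SBS5-like vector (the printed similarity of the
  aggregate neuronal spectrum to SBS5), and the two vectors have low
  collinearity (cosine ~0.14, comparable to the real SBS5/SBS30 pair).
  Collinear drafts of these fixtures let the factorization shear its
  vertices along the shared direction and mis-attribute exposures; that is
  a property of the geometry, not of the optimizer.
* **Placement.** Mutations are placed only on callable sites carrying the
  drawn trinucleotide, re-weighted by expression quintile for component 1
  (`genic_weight_by_quintile`, increasing), toward intergenic sites for
  component 2, and -- for genic T>C mutations -- onto template-strand
  pyrimidines with probability `strand_asymmetry = 0.65`, emulating
  transcription-coupled repair bias. Because weighting acts within
  trinucleotide strata, the catalog's 96-context mixture equals the
  configured signature mixture exactly, whatever the placement weights.
* **Expression.** Six synthetic cell types (excitatory, inhibitory,
  oligodendrocyte, astrocyte, microglia, endothelia) with negative-binomial
  counts (size 2, ~5,000 counts/cell, 20 cells per donor per type). Planted
  effects in elderly cells: housekeeping genes decline linearly in length
  decile from `hk_decline_max = -1` (shortest) to 0 (longest); a module of
  30 well-expressed genes is downregulated by `shared_down_lfc = -1.5` in
  one excitatory, one inhibitory and two glial types. The shared module's
  log2FC is set clear of the 0.5 detection threshold because the pseudocount
  in the fold-change formula attenuates measured fold changes at moderate
  expression; the module emulates genes that were *observed* to be
  significantly shared, so it must be detectable by construction.

What the generator does **not** emulate: amplification artifacts and
allelic dropout of PTA, doublets, ambient RNA, batch effects, real genome
composition (the toy genome is i.i.d. uniform), linked mutations, indels
and CNVs. Tests passing on this corpus therefore validate the statistical
machinery, not robustness to those artifacts.

# Spectra and signatures

Spectra live on the fixed 96-bin pyrimidine-centered context layout
(`contextLabels()`; substitution class slowest, then 5' and 3' flank).
`buildSpectrum()` annotates each mutation's context from the reference and
counts; mutations with non-ACGT flanks are dropped, never imputed.

`nmfDecompose()` implements multiplicative-update non-negative matrix
factorization under the generalized Kullback-Leibler divergence -- the
Poisson maximum-likelihood objective appropriate for count spectra -- with
seeded random restarts (the best objective is kept), signature columns
normalized to probability vectors, and the scale folded into exposures.
Components are named `A1`, `A2`, ... by decreasing T>C mass, so the
T>C-dominant clock-like component is always `A1`. Convergence uses a
relative-objective tolerance of 1e-6 with a 2,000-iteration cap; the
objective is non-increasing by construction and this is asserted in tests.

`selectRank()` scores each candidate rank by cross-restart stability (mean
cosine of signatures matched to the best restart by exhaustive one-to-one
pairing; ranks up to 8 keep the permutation search trivial) and by mean
reconstruction divergence. The chosen rank is the largest one with
stability above 0.9 whose error improves on the next-smaller rank by more
than 10%. The improvement threshold deserves a note: at desk scale a
spurious extra rank still absorbs ~5% of the divergence by fitting noise,
so a 5% cutoff sits inside the noise floor; genuine structure (one
component versus two) improves the fit by 30% or more, so 10% separates the
two regimes with a wide margin.

`refitExposures()` performs per-cell nonnegative least squares against
fixed signatures, giving exposures in mutation-count units;
`burdenAgeRegression()` is ordinary least squares with a free intercept,
reporting slope (sSNVs/yr), R^2 and the two-sided slope p-value. Exposure
attribution defaults to the refit path rather than the factorization's own
loading matrix; on exact mixtures the two agree and the refit is the
identity on mixing weights.

**A known limitation, quantified.** With a minor component at ~12-15% of
mutations, de novo extraction followed by refit recovers the major
component's per-year rate to within a few percent, but inflates the minor
component's rate by roughly +0.2 to +0.8 sSNVs/yr at the 59-325 cell
scale. The cause is geometric: an NMF vertex cannot lie outside the cone
spanned by the data, and the purest minor-component cells (infants) still
carry ~18% of the major process, so the estimated minor vertex absorbs a
slice of the major signature and its exposures inherit a corresponding
share of the major clock. Refitting against the *true* signatures is
unbiased, isolating the effect in the vertex estimate. Users comparing
small co-occurring clock processes should treat de novo minor-component
rates as upper bounds or refit against externally fixed signatures.

# Enrichment, strand bias and gene-length analyses

`sampleMatchedControls()` draws, per observed mutation, a configurable
number (default 10) of callable positions sharing its exact canonical
trinucleotide on either strand, carrying the same substitution -- so the
control spectrum equals the observed spectrum times the multiplier
*exactly*, and any genic/intergenic or expression-quantile enrichment in
the observed catalog is measured against a context- and depth-matched
null. Enrichment ratios are observed-fraction over control-fraction with
seeded bootstrap confidence intervals (default 1,000 resamples of the
observed catalog). Per-signature ratios split mutations by per-context
responsibilities under fixed signatures; soft (fractional) attribution is
the default, hard argmax attribution is available.

Transcriptional strand is assigned by the pyrimidine convention: a genic
mutation is "transcribed-strand" when its canonical-context pyrimidine
lies on the gene's template strand. A mutation overlapping several genes
goes to the gene for which it is uniquely template-stranded, else to the
longest gene. `strandBias()` tabulates transcribed/untranscribed counts per
substitution class and expression quintile; under the generator's
asymmetry parameter the T>C transcribed fraction recovers that parameter.

`snvRateByLength()` and `lengthDecileFoldChange()` rank genes of one class
by length into deciles (ties broken by identifier, so the assignment is
total and deterministic) and regress per-bp mutation rate, respectively
median log2 fold change, on the decile index. `classSpectrumTest()`
compares the substitution-class composition of two catalogs with two-sided
exact binomial tests (plus a pooled C>N aggregate), and
`stopgainProfile()` enumerates the codon table: the three stop codons
carry 7 A/U bases out of 9, T>C changes can never create a stop, and among
cytosine classes C>A and C>T carry the most stop-creating events.

# Transcriptome aging analyses

`logNormalize()` computes `ln(1 + 10,000 x count / cell_total)`; the
"logged CPM" profiles used for gene classification are means of this
quantity, an interpretation choice since the base and pseudocount of the
published definition are not fully specified. `differentialExpression()`
tests genes passing a percent-expressed filter (two presets: expressed in
at least 25% of either group, the differential-expression filter; or 25%
of adult and 20% of elderly cells, the "expressed gene" definition used by
the permutation test) with a two-sided Wilcoxon rank-sum test on
normalized values, and flags genes with |log2FC| > 0.5 and raw p < 0.05 --
raw by design, mirroring the published thresholds; a BH column is emitted
for users but never used in calls.

`classifyGenePrograms()` applies the strict-threshold rules on four
reference cell types (housekeeping: spread < 0.1 and all means > 0.1;
neuron-specific: neuron means > 0.2, microglia/endothelia < 0.1). A spread
of exactly 0.1 is excluded, with a 1e-9 representation-error guard so that
printed boundary cases behave as written.

`sharedDownPermutation()` counts genes down in at least one excitatory, one
inhibitory and two glial cell types, and compares against draws of
equally-sized random subsets of each type's expressed genes
(`p = (1 + #{perm >= obs}) / (n_perm + 1)`, so p is never zero and never
below `1/(n_perm+1)`). `geneSetEnrichment()` (Fisher's exact test over an
active-gene background), `compositionTrend()` (exact two-sided rank-sum
for small donor groups; the extreme 2-versus-11 split yields exactly
2/C(13,2) = 0.0256) and `fisherRtoZ()` (comparing two length-trend
correlations) round out the stage. All permutation and bootstrap
procedures take explicit seeds.

# Numerical and design choices

* One internal coordinate convention: 1-based closed `GRanges` everywhere;
  BED's 0-based half-open convention is converted at import/export only.
* Spectra and signatures are serialized by context label, never by bare
  index; external signature TSVs (e.g. real COSMIC v3 vectors) can be
  supplied anywhere a packaged fixture is used. Spectra are compared as raw
  frequencies; no genome-composition renormalization is applied (an
  explicit non-goal), which users should remember when comparing across
  genomes with different trinucleotide content.
* Ties: quintile and decile assignment break ties by gene identifier;
  signature matching breaks ties by column index; the A1/A2 naming rule is
  total because T>C masses are continuous.
* Degenerate inputs fail loudly with named errors: all-zero cells in
  normalization, constant ages in regression, zero vectors in cosine
  similarity, empty partition classes in enrichment, inverted intervals in
  annotation files.
* Problem sizes: the default corpus (2 Mb genome, 1,000 genes, 65 neurons,
  ~50,000 mutations, 1,560 nuclei) runs each stage in seconds on one core;
  burden regressions in the acceptance machinery pool five replicate
  catalogs over one reference so the Monte-Carlo error of a fitted slope
  (~0.25/yr) sits well below the tolerances being checked. These sizes are
  the package's chosen desk-scale study conditions.
* The command surface is the R API plus `scripts/acceptance.R`;
  `runPipeline()` orchestrates the stages end-to-end with a validated
  config, writing per-stage TSVs and a deterministic JSON report, which is
  the package's pipeline entry point.

# What passing tests do and do not show

The test suite validates exact conventions (coordinates, contexts,
spectrum arithmetic), calibration (null enrichment ratios cover 1, null
differential expression holds its type-I error, strand fractions are
binomial around 0.5 under symmetric placement), oracle agreement (exact
binomial, hypergeometric and rank-sum tails against brute-force
enumeration), and parameter recovery on the synthetic corpus (clock rates,
signature shapes, asymmetry, planted expression effects). It does not
certify behavior on real scWGS/snRNA-seq data with amplification
artifacts, nor the accuracy of de novo minor-component rates (see the
limitation above), nor any biological conclusion beyond the faithfulness
of the implemented procedures.
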