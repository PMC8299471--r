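---
title: "Quantifying tumor mass dormancy and its mutational context"
author: "dormscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor mass dormancy and its mutational context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dormscan)
```

## The problem

Tumor mass dormancy (TMD) is the transient equilibrium in which tumor
cell proliferation is balanced by cell death, maintained externally by
immune cytotoxicity (immunological dormancy, ID) and/or failed
vascularization (angiogenic dormancy, AD). Because the state is
temporary and no dedicated model systems exist, it has to be inferred
from bulk molecular snapshots. `dormscan` implements a complete,
testable inference pipeline: per-sample transcriptional program scores
and a rule-based dormancy classification, robustness procedures for the
scores, 96-channel mutational-signature analysis with explicit
signature-selection rules, consensus labelling of APOBEC-driven
hypermutation, driver-mutation enrichment statistics, microenvironment
and hypoxia scores, and survival models. Everything runs end-to-end on a
synthetic multi-modal cohort with planted ground truth, so each stage's
recovery behavior is a tested property rather than an assumption.

## Program scores

Programs are signed gene sets (`GeneProgram`): upregulated symbols
`E_u` and optionally downregulated symbols `E_d`. Three scores are
provided:

* **Scaled difference of means** (the primary score):
  `S = (sum(E_u) - sum(E_d)) / (N_u + N_d)` on log2(FPKM+1) values.
  It is linear in expression and invariant to gene order; leave-one-out
  and noise-injection experiments (module `robustness`) show it is at
  least as stable as the PCA alternative, which is why it drives the
  classification.
* **PCA score**: the sample coordinate on the first principal component
  of the program genes (genes centered). A PC1 axis has an arbitrary
  sign, so the score is oriented to correlate non-negatively with the
  scaled difference.
* **Mean expression**: for all-upregulated programs (APOBEC,
  exhaustion).

The proliferation/apoptosis ratio divides the mean log expression of an
E2F-target-style proliferation program by that of an apoptosis program;
values below 1 indicate restrained expansion.

### Classification rules

A sample is TMD-high when its TMD score is in the upper quartile of the
cohort distribution *and* its proliferation/apoptosis ratio is below 1.
TMD-high samples subdivide by the AD and ID quartiles into `AD`, `ID`
or `A/ID`; samples in the lower TMD quartile with ratio above 1 are
expanding (`NO`); everything else is `MID`. Decisions taken where the
rules leave room:

* "Upper quartile of the score range" is read as the 75th percentile of
  the cohort score distribution (robust to outliers); a `quartileMode =
  "range"` switch provides the literal min + 0.75·range reading.
* Quartile boundaries are inclusive (score == Q3 counts as high), which
  keeps the rule deterministic.
* A sample can pass the TMD gate yet sit in neither the AD nor the ID
  upper quartile; the taxonomy has no name for it, so it is reported as
  `MID` with an `unassignedHigh` audit flag rather than silently
  inventing a category.
* A ratio exactly equal to the threshold satisfies neither `< 1` nor
  `> 1` and falls to `MID`.
* Quartiles are computed pan-cohort by default (matching the pan-cancer
  reading of the dashed quartile thresholds); per-tissue operation is a
  caller-side stratification.
* The ratio uses log-scale means, consistent with all expression being
  log-transformed on input.

### Hypoxia and microenvironment

The hypoxia score follows the Buffa-style procedure: per signature gene,
+1 if the sample is above the cohort median, -1 below, 0 at the median;
genes shared with the dormancy/exhaustion programs are removed first;
scores are binned with width 10 (`floor(score/10)`). The cohort-median
sample scores exactly 0 by construction.

Cell-type infiltration uses a single-sample GSEA running-sum statistic
with rank-weight exponent 0.25. The raw Barbie-style statistic is
positively biased even for random gene sets (the rank-power weights make
the expected weighted in-set CDF exceed the uniform CDF), so the score
is centered by its uniform-membership baseline — a deterministic
function of the rank multiset — making a random set score ≈ 0 while
leaving monotone-invariance intact. Combined categories (cytotoxic, Th,
dendritic) are scored on the union of their member marker sets.

### Placeholder gene lists

Dormancy gene signatures are manually curated, study-specific products
that the package deliberately does not try to reconstruct;
`defaultPrograms()` instead ships small, clearly-labelled placeholder
lists built from canonical markers of each process (interferon/chemokine genes for ID,
plasminogen/uPAR-axis genes for AD, checkpoint genes for exhaustion,
APOBEC3 family members, E2F targets, caspases, hypoxia-inducible genes).
Real analyses should load full curated lists from GMT via `readGMT()`;
signed programs are encoded as `<name>_up` / `<name>_down` line pairs.
Gene identity is by case-sensitive symbol with no alias resolution.

## Robustness procedures

* **Leave-one-out**: remove each program gene in turn, recompute scores,
  and report per-sample fold changes (new/original). Samples with an
  original score of exactly 0 are recorded as missing.
* **Jitter**: uniform noise of amplitude `factor × d/10` per gene, where
  `d` is the smallest nonzero spacing of the gene's values, repeated 100
  times per factor for factors in 1..200. An `amplitude` override
  exposes the exact zero-noise limit (all fold changes equal 1). The
  fold changes are pooled per sample and then summarized.
* **Random-program null**: 1,000 random draws of 35 genes scored by mean
  expression, correlated with a target score; the empirical p-value uses
  the add-one rule and is one-sided in the direction of a positive
  association, so it can never be 0.

## Mutational signatures

Catalogues count SNVs over the 96 pyrimidine-centered trinucleotide
channels in a fixed lexicographic order (substitution class, then 5'
base, then 3' base). Purine-reference variants are reverse-complemented;
records whose stated reference allele disagrees with the genome are
rejected and reported; only samples with at least 50 usable SNVs are
analysis-eligible. Channel sums always equal accepted SNV counts.

**Refitting** solves, per sample, a least-squares problem on the
probability simplex (`w >= 0`, `sum(w) = 1`) by accelerated projected
gradient with the Duchi simplex projection. The iterative
forward-selection heuristics of common refitting tools are deliberately
replaced by this one-shot fit followed by the explicit selection rule,
because the rule — not a package's internals — defines the result:
retain SBS1 and SBS5 unconditionally, any reference signature
cosine-matched by a stable de novo factor, and any signature
contributing on average at least 5% of mutations (inclusive); when no
stable de novo solution exists, the rule falls back to SBS1/SBS5 plus
the 5% criterion. Tests verify the fit against a brute-force grid search
on the 1-simplex.

**De novo extraction** runs KL-objective NMF (multiplicative updates,
200 iterations, relative tolerance 1e-6) on Poisson-resampled catalogues
and clusters the pooled factors with a run-matched partition (each
bootstrap contributes exactly one factor per cluster). Stability is the
average silhouette width under cosine distance; the minimum stability is
the worst per-cluster average. The chosen rank is the largest K with
(average + minimum > 1) and (minimum >= 0.4). Two numerical guards
matter: for K = 1 the silhouette is undefined and the mean cosine to the
factor centroid is used instead; and a rank whose consensus factors are
mutually near-identical (pairwise cosine > 0.95) is rejected as
redundant — without the run-matched partition and this guard, a rank-1
catalogue can masquerade as a "stable" rank-2 solution by splitting its
dominant channels consistently.

**APOBEC enrichment** is the Roberts-style fold enrichment of cytosine
mutagenesis at tCw motifs (w ∈ {A, T}), `E = (m_tCw / c_tCw) / (m_C /
c_C)`, with motif and cytosine availability counted on both strands
within ±20 bp of each cytosine mutation. The mutated site's own
trinucleotide is excluded from the availability counts and edge
cytosines keep their full context via 1 bp padding; both corrections are
needed for the estimator to be unbiased (E = 1) under uniform
deamination-type mutagenesis, which the tests verify by simulation.

The shipped reference panel (`syntheticSignatures()`) is synthetic: it
reuses SBS names and qualitative channel preferences (N[C>T]G for the
clock-like deamination signature, T[C>T]W / T[C>G]W for the APOBEC
pair) so that selection rules and APOBEC analyses can be exercised, but
the profiles are not the COSMIC reference signatures.

## Consensus APOBEC clustering

Per-sample signature exposure profiles are embedded in 2-D with exact
t-SNE (O(n²), adequate at cohort scale; perplexity calibrated by binary
search, early exaggeration 12 for 100 iterations, momentum gradient
descent) and clustered with a 10-component full-covariance Gaussian
mixture (EM from a seeded k-means start; degenerate fits are
re-initialized up to 5 times). Per run, the APOBEC cluster is the one
with the highest median SBS2+SBS13 exposure; across 100 runs with
derived per-run seeds, samples appearing in that cluster strictly more
than 50 times are labelled APOBEC-enriched.

Granularity choices: k = 10 by default, set where the log-likelihood
gain from additional clusters flattens and, more importantly, low enough
that the APOBEC cluster is not segmented (an optional elbow report
supports re-deriving it on other cohorts).
For consensus runs the embedding perplexity defaults to n/4 (capped
below the n/3 validity bound) rather than the exploratory default of 30:
a larger perplexity preserves global structure, which keeps the APOBEC
cluster in one piece against t-SNE's tendency to expand any
equal-density blob until the mixture carves it up. Consensus embeddings
use 300 gradient iterations — island structure stabilizes long before
the fine layout — while `embedProfiles()` defaults to the conventional
1000. Each of the 100 repetitions re-runs both the embedding and EM
(`fixedEmbedding = TRUE` gives EM-only repeats).

## Association statistics

Driver enrichment compares TMD-high samples (union of A/ID, AD, ID)
against the `NO` category (MID excluded by default, matching the
high/low framing; `includeMid` widens the low group). Genes pass a
frequency filter first (≥1% of samples pan-cohort or ≥5% within a
study; only missense, nonsense, nonstop, frameshift and in-frame
indel classes count). P-values are two-sided Fisher exact tests; the
odds ratio is the sample OR `(ad)/(bc)` with a Haldane–Anscombe +0.5
correction when a cell is zero — the closed-form quantity usually
plotted on a log2 scale — rather than the conditional MLE. Hotspot
tests parse `p.<ref><pos><alt>` protein changes and match on the
residue regardless of the alternate amino acid. BH correction is
applied once per analysis family. Random-forest rankings use balanced
subsamples, impurity (Gini) importances averaged over repeats, and a
held-out AUC (stratified 70/30 split inside each balanced subsample;
out-of-bag votes are pessimistically biased on balanced designs).
Median-shift screens use Wilcoxon rank-sum tests with a q < 0.01 flag.

## Survival

Kaplan–Meier estimates, K-group log-rank tests (χ², K-1 df) and Cox
proportional-hazards models with Efron tie handling (Breslow via
`ties`), reference level `NO`, under the staged covariate sets
{}, {age, gender}, {+study}, {+stage}, {+study, +stage}.

## The synthetic cohort

The generator is first-class, tested code; its defaults are the study
conditions under which every recovery property is asserted, chosen once:

* 500 samples, 12 tissues, ~2,000 genes (program + marker + driver genes
  plus background). Twelve tissues keeps more background tissue
  structures than consensus clusters, the regime of real pan-cancer
  cohorts, which span ~30 tissue types; cohort and gene counts keep the
  full test suite at desk scale (runtimes in minutes on one CPU).
* Dormancy label frequencies follow the prevalences the method is meant
  to resolve: A/ID 7%, AD 4.4%, ID 5%, NO 25%, MID the remainder.
* Expression: log2-space additive model (baseline N(4,1) per gene,
  per-gene-by-tissue shift N(0, 0.5), planted program shift ±2, noise
  N(0, 0.5), floored at 0 so `log = log2(FPKM+1)` holds exactly). The
  component AD/ID programs are planted; the TMD score emerges from its
  constituent genes. Dormant samples get apoptosis up / proliferation
  down (planted ratio < 1), expanding samples the reverse plus the
  hypoxia program; APOBEC-high samples get the APOBEC and exhaustion
  programs.
* Signatures: 20% of samples are APOBEC-high with SBS2+SBS13 = 0.6
  (SBS2:SBS13 near 1:1, tightly concentrated) over a clock-like
  residual; the clock-like residual reflects the observation that
  heavily APOBEC-mutagenized tumors cluster together across tissues.
  Other samples carry at most 0.05 APOBEC exposure over a
  tissue-specific Dirichlet profile (ring of characteristic-signature
  blends). 1,000 mutations per sample are placed at genome positions
  whose trinucleotide context matches the drawn channel, on a 2×60 kb
  uniform toy genome that replaces a real genome build.
* Drivers: CASP8/HRAS planted enriched and TP53/KRAS depleted in
  dormant samples at odds ratio 5 over a 10% baseline rate; half the
  RAS hits carry hotspot protein changes (Q61/G13/G12).
* Survival: exponential times (baseline hazard 1/1000 per day), hazard
  ×2 for `NO` samples, 20% uniform censoring; age N(60,10) clipped to
  [30, 90], balanced gender, stage early/late at 1/2, independent.

What the generator does **not** emulate: copy-number and purity
variation, isoform structure, realistic gene-gene correlation, mutation
rate heterogeneity along the genome, exome-vs-genome context
composition (the toy genome is its own context universe; a hook accepts
context weights), or calibrated effect sizes — the planted separations
are free parameters, not fitted to real cohorts. Passing recovery tests
therefore demonstrates correctness of the machinery under the stated
model, not performance on real tumors.

## Numerical notes

* Every generator and stochastic stage is a pure function of
  (parameters, seed); per-run seeds are derived as master + offset, and
  the RNG state of the caller is always restored.
* Simplex least squares: FISTA with step 1/L from the Gram spectrum,
  ≤5,000 iterations, stall tolerance 1e-12 — orders of magnitude below
  the 2e-3 reporting tolerance of the grid-search cross-check.
* Empirical p-values use the add-one rule; BH families are exactly the
  vector passed in.
* Fisher p-values use the hypergeometric two-sided sum with the
  conventional (1 + 1e-7) tie tolerance; tests sweep all margins ≤ 30
  against a direct enumeration oracle.
* t-SNE determinism comes from seeding both the perplexity-calibrated
  affinities (deterministic) and the N(0, 1e-2) layout initialization.

## Known limitations

* The placeholder gene programs are illustrative; conclusions about real
  tissue require the full curated signatures.
* The synthetic signature panel shares only names and coarse channel
  structure with the COSMIC reference set; cosine matching against a
  real reference TSV is supported via `readSignatureMatrix()`.
* dN/dS selection analysis is out of scope; externally computed results
  can be joined to the enrichment tables by gene.
* Exact t-SNE scales as O(n²) memory/time and is intended for cohorts of
  up to a few thousand samples.
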