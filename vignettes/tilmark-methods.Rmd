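---
title: "Methods behind tilmark: filtering, scoring and classifying tumour-reactive TIL biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind tilmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tilmark` re-implements, as plain auditable code, the computational
decisions behind a TIL-therapy biomarker workflow in ovarian cancer: who,
judged from a baseline tumour sample, is likely to yield a tumour-reactive
(TR) TIL product. This vignette explains each stage's model and
assumptions, the tunable parameters and why their defaults are what they
are, the numerical conventions, and what the synthetic-data generator does
and does not emulate.

## Tumour-only somatic filtering and TMB

Panel sequencing of tumour tissue without a matched normal cannot
distinguish somatic mutations from germline polymorphisms directly; the
workflow therefore combines site-quality filters with a population-based
germline heuristic.

Site filters (all evaluated independently, so one record can fail for
several reasons):

| predicate | default | boundary convention |
|---|---|---|
| read depth | ≥ 100 | 99 fails, 100 passes |
| call quality | ≥ 40 | strict `<` fails |
| no-call fraction (SNVs only) | < 0.03 | 0.03 fails (inclusive) |
| strand-bias score | ≤ −80 | −80 passes (more negative = cleaner) |
| VAF | ≥ 0.05 | 0.05 passes (strict `<` fails) |

The germline heuristic removes variants whose allele frequency is
consistent with a heterozygous (VAF in the closed window [0.40, 0.60]) or
homozygous (VAF strictly > 0.80) inherited genotype **and** which are
known to the population database (European non-Finnish MAF > 0). A
variant absent from the database (`pop_maf_enf = NA`) is always retained:
absence is evidence of a somatic origin, and collapsing it to MAF = 0
would silently change the rule's meaning, which is why the reader refuses
to impute zeros. Where the quoted thresholds are printed without bracket
conventions, we chose the closed inner window and strict upper arm, and
made every bound configurable in `filter_thresholds()`. Two deliberate
toggles address genuinely open readings:

- `maf_always_excludes`: the conservative reading under which *any*
  positive population MAF removes a variant regardless of VAF. The default
  (`FALSE`) is the strict two-sentence reading — MAF only disqualifies
  variants already inside a germline VAF band.
- `count_only_nonsynonymous`: mutational load is counted over all somatic
  SNVs by default; oncoprint-style summaries conventionally restrict to
  non-synonymous changes, so the restriction is available but not silently
  applied.

Only SNVs enter the burden estimate — tumour-only indel calls on FFPE
material have a high false-positive rate and contribute a small minority
of true variants in this tumour type — but indels are kept in the audit
trail and in gene-list reports. TMB is `n_somatic_snv / 0.524` per Mb,
the targeted footprint of the TST170 panel, reported at full precision and
conventionally displayed at one decimal. A panel this small overestimates
whole-exome TMB and is noisy at low burden; the package treats it as a
*ranking* biomarker, not a calibrated rate.

Records missing a metric needed by a predicate fail closed with a distinct
`MISSING_METRIC` reason (configurable to fail open): reproducibility over
permissiveness. Manual read-level review of candidate calls is a human
step and is not modelled; automated counts can therefore differ from a
curated call set.

## Expression normalisation and signature scores

Probe-count matrices are normalised in three steps, the standard nCounter
scheme, fully specified here so no vendor software is needed:

1. **Positive controls.** Each sample is scaled by
   `target / geomean(positive controls)`. Spike-in controls report lane
   efficiency, so this removes technical intensity differences.
2. **Background.** Per-sample floor at `mean(neg) + 2·SD(neg)`
   (sample SD), never below 1 so log₁₀ stays nonnegative; endogenous and
   housekeeping values below the floor are raised to it.
3. **Housekeeping genes.** Samples are scaled by
   `target / geomean(HK genes)` using the `k` most stable housekeeping
   genes (default 10), ranked by ascending coefficient of variation of
   log₁₀ positive-control-normalised counts — a simple deterministic
   criterion chosen over geNorm-style pairwise stability.

For the standalone functions the `target` defaults to the cohort mean of
the per-sample geometric means, which keeps values on the familiar count
scale. The full chain `normalize_counts()` instead anchors both targets to
fixed constants (512 for positive controls, 1000 for housekeeping genes,
both configurable). The distinction matters: with a cohort-mean target the
normalised matrix retains one global factor that depends on the whole
cohort's raw scale, so absolute scores would drift when samples are
rescaled or cohorts recombined. With fixed anchors each sample's factor is
a function of that sample's own controls alone, making signature scores
exactly invariant to per-sample rescaling of the raw counts (verified to
10⁻¹⁰ in the tests) and comparable across cohorts. The anchor values only
set the global scale; group contrasts and fold changes are unaffected by
the choice.

The GEP score of a sample is the arithmetic mean of log₁₀ normalised
expression over a signature's genes (IFN-γ, Expanded immune and
T-cell-inflamed lists ship as editable YAML; the code treats them as
data). Genes missing from the matrix are reported, and scoring refuses to
proceed below 80% coverage rather than silently averaging a different
gene set.

Differential expression uses Welch's t-test on log₁₀ values by default —
matching the t-test convention of nCounter analysis software — with the
exact Mann–Whitney selectable for consistency with the rest of the
analysis. Fold change is the ratio of group geometric means on the linear
scale. Flags follow the volcano-plot convention: `up` iff FC > 2 and
p < 0.05, `down` iff FC < 0.5 and p < 0.05. Raw p-values gate the flags
(the source analysis used uncorrected p < 0.05 on a 770-gene panel);
Benjamini–Hochberg q-values are reported alongside so the reader can apply
multiplicity control. A gene with identical values in both groups returns
p = 1 with a warning rather than an error. Heatmap preparation z-scores
each gene across samples ("standardised by the mean of the samples" is
read as per-gene standardisation; plain centring is available via
`standardise = "center"`) and clusters rows and columns with Euclidean
distance and average linkage; leaf order is deterministic, with ties
resolved by input order.

## ELISPOT reactivity

The specific-spot statistic is `mean(target) − 2 × mean(medium)`:
doubling the background is a deliberately conservative correction for
spontaneous secretion. Replicates are aggregated by arithmetic mean
(median selectable); negative values are reported as-is, never clipped. A
response is positive iff specific spots > 30 (strictly; exactly 30 is
negative). Two qualitative calls published without numeric criteria are
given declared, configurable conventions:

- **HLA-I restriction**: blockade must remove at least half of the
  specific signal (`reduction_fraction = 0.5`), with a positive unblocked
  response required.
- **CD137 upregulation**: at least a 2-fold increase over the
  no-target culture and an absolute floor of 1% CD137⁺ of gated CD8
  blasts. The CD137 readout is advisory — it confirms, but never
  overrides, the ELISPOT-based label.

A patient is TR iff at least one fraction's product is positive against
autologous tumour. A positive but non-HLA-restricted response still makes
the patient TR and is flagged, mirroring how such responses are reported.

## Tissue quantification

Cytometry subset frequencies are percentages against either the immediate
parent population or the living-cell gate; an empty reference yields a
missing value, not 0 — a frequency of an empty parent is undefined, and
fabricating zeros would bias group comparisons. The gating-tree invariant
(child ≤ parent) is validated on load.

Multiplex-IF summaries are the *unweighted mean of per-field percentages*
(20 fields per compartment), exactly as the quantification is described,
not the pooled-count ratio: the two differ when field totals vary, and
the mean-of-fields convention weights each sampled region equally.
Fields without the phenotype contribute 0%. FOXP3 is quantified but
excluded from group comparisons by default, matching its reported
null result.

## Exact small-sample tests

With 5 patients per group, asymptotic p-values are unreliable; every test
here is enumerative:

- `exact_mann_whitney()` computes U from mid-ranks and enumerates all
  `choose(nx+ny, nx)` group assignments of the observed pooled multiset,
  which handles ties exactly. Two-tailed p is the arrangement probability
  of `|U − nx·ny/2|` at least as large as observed. Beyond 12 per group
  enumeration is pointless and the function switches to the seeded
  Monte-Carlo estimator with a warning.
- `monte_carlo_p()` uses the add-one estimator `(1 + k)/(1 + n_perm)`,
  which is a valid permutation p-value and never returns 0, with a normal
  95% CI on the estimate; default `n_perm = 1e5`.
- `wilcoxon_signed_rank_exact()` enumerates all `2^n` sign assignments.
  Zero differences are dropped with a warning (the classical convention);
  Pratt's method — rank first, then drop — is selectable.

Figure-legend confidence levels (95% two-tailed, 90% one-tailed
Monte Carlo) are carried as reporting metadata; they do not alter the
p-value computation.

## TMB/GEP stratification

A patient is predicted TR when TMB exceeds its cut **or** the GEP score
exceeds its cut — the low/low quadrant is the only predicted-NTR one.
The source analysis draws no numeric thresholds, so cuts are explicit
arguments; `suggest_cuts()` scans midpoints of the observed values for
the concordance-maximising pair but is labelled exploratory and never
applied automatically (on ten patients such cuts are over-fitted by
construction). Missing biomarkers follow the OR-rule semantics: a patient
with TMB above the cut is predicted TR even without a GEP score; a
patient missing both is excluded with a warning.

## What the synthetic cohorts emulate

The generator's defaults are the study conditions: 10 patients, 5 TR /
5 NTR; per-patient somatic SNV counts `{8,7,2,1,2 | 2,1,0,2,1}`, giving a
cohort TMB median of 3.8 and range 0–15.3 per 0.524 Mb; TR patients split
into high-TMB/low-GEP and low-TMB/high-GEP sub-scenarios so the OR rule
is genuinely exercised rather than trivially satisfied by one biomarker.
Somatic variants are drawn with VAF in [0.05, 0.35] and no population
MAF; germline variants sit in the heterozygous or homozygous VAF band
with positive MAF; artifact records each violate exactly one named site
filter. Expression is negative-binomial with a shared per-sample size
factor (so housekeeping normalisation can undo it), a +0.5 log₁₀ shift of
signature genes in GEP-high samples, a fixed geometric positive-control
ladder and low-mean Poisson negatives. ELISPOT replicates are Poisson
(target 150 vs medium 10 for reactive products, 10 vs 10 otherwise, 3
replicates); gating counts come from a binomial cascade that respects the
tree invariant; IF fields are multinomial with a TR-enriched epithelial
CD137⁺PD-1⁺CD8⁺ phenotype. Every stage draws from its own seed derived
from the master seed, so regenerating one assay leaves the others
byte-identical.

What it does **not** emulate — and hence what green tests do not show
about real data: FFPE artifact structure beyond single-predicate
violations, correlated gene–gene expression, batch effects, plate edge
effects, imaging segmentation error, and any relationship between a
patient's true antigenicity and the biomarkers other than the planted
shifts. Recovery results (recall/precision 1.0, concordance 1.0) certify
the *implementation* against its ground truth, not clinical performance.

## Problem sizes and numerical conventions

The test suite runs the recovery properties at the cohort sizes above,
the ELISPOT accuracy check over 1000 simulated products, replicate-cohort
direction checks over 40–60 cohorts, and enumeration cross-checks
exhaustively for pooled sizes up to 8 — sizes chosen to make the checks
sharp while keeping the whole suite fast on a laptop. Floating-point
comparisons in the enumerative tests use an absolute guard of 10⁻⁹ on
rank statistics (mid-ranks are multiples of 0.5, so this only absorbs
representation error). Degenerate inputs are handled explicitly: empty
call sets give TMB 0; a single sample skips column clustering with a
warning; all-zero differences give p = 1; an empty reference gate yields
a missing frequency.

## Known limitations

Cohort-scale conclusions from ten patients are fragile regardless of
implementation quality; the exact tests quantify, but cannot remove,
that. The germline heuristic cannot rescue a somatic variant that
happens to sit at VAF 0.5 in a database-known position, nor reject a
germline variant absent from the reference population — a matched normal
would. TMB from a 0.524 Mb panel is a ranking statistic with wide
uncertainty at low counts. The stratification cuts are analysis choices;
the package deliberately refuses to pick them for you outside the
clearly-labelled exploratory helper.
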