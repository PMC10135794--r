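---
title: "Quantifying pain-model effects and treatment reversal in pooled TMT matrisome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pain-model effects and treatment reversal in pooled TMT matrisome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scsmatrisome)
```

## The design and its contrasts

The package analyzes a four-arm rodent neuropathic-pain experiment measured
by pooled tandem-mass-tag (TMT) proteomics and phosphoproteomics. The arms
are uninjured controls (`NoSNI`), injured untreated animals (`NoSCS`), and
injured animals treated with one of two spinal cord stimulation therapies:
differential target multiplexed programming (`DTMP`) or conventional
low-rate stimulation (`LRSCS`). Because biological samples are pooled into a
single TMT channel per arm, there are no biological replicates; replication
comes from peptides (proteomic branch) and technical runs (phospho branch).

Three ratios carry all inference:

* the **pain contrast** `NoSCS / NoSNI` — what the injury did;
* the **treatment contrasts** `DTMP / NoSCS` and `LRSCS / NoSCS` — what each
  therapy did to the injured state.

A treatment **back-regulates** an entity when it moves expression opposite
to the pain-model change, i.e. back toward uninjured levels.

## Quantification model

**Proteins.** Each protein is quantified through the peptides uniquely
assigned to it. For a contrast, the per-peptide log2 ratio is the difference
of the peptide's normalized log2 intensities in the two channels, restricted
to peptides measured in both; the protein's log2 fold change is the mean of
those ratios, and significance is a one-sample two-tailed t-test of the
ratios against zero with `n_peptides - 1` degrees of freedom. A protein with
one usable peptide keeps its fold change but has no p-value — it can appear
in heatmaps but can never be called significant. The pooled design leaves
the t-test form genuinely open (no biological replicates exist); peptide-level
ratios are the only replication the data carry, which is why the test is
one-sample on ratios rather than two-sample on intensities.

**Phospho-isoforms.** Each phosphorylation state (site combination) of a
protein is quantified separately. Ratios are formed run-by-run (technical
runs paired across channels by run id) and averaged on the log2 scale.
Duplicates admit no useful significance test, so the spread is summarized
instead: each channel's coefficient of variation (CV = sd/mean of the linear
intensities across runs, `n - 1` denominator even at n = 2), propagated to
the ratio as

$$\mathrm{CV}_{A/B} = \sqrt{\mathrm{CV}_A^2 + \mathrm{CV}_B^2}.$$

CVs are reported for quality assessment but do not gate classification by
default: no CV cut-off is part of the decision rules, and
`quantify_phospho()` exposes them so users can filter if they wish.

**Normalization.** `normalize_channels()` median-centers each channel on the
log2 scale to the grand median (the median of the per-channel medians). The
shift is constant per channel, so it is exact for channel-loading offsets,
order-preserving, and idempotent. Like every global centering method it
assumes most features are unchanged between channels; see "Benchmarking
against planted truth" for the consequence.

## Decision rules

Two rule sets mirror the two branches' replication structure
(configurable through `analysis_config()`):

* **Phospho (threshold-gated).** An isoform is *affected* when its
  pain-contrast linear ratio changes by at least `affected_threshold`
  (default 0.10): `|r_pain - 1| >= 0.10`, boundary inclusive. An affected
  isoform is *back-regulated* by a treatment when the treatment ratio also
  changes by at least the threshold in the opposite direction.
* **Proteins (significance-gated).** A protein is *affected* when the pain
  contrast is significant at `alpha` (default 0.05), and *back-regulated*
  when a treatment contrast is also significant with opposite-signed fold
  change.

A same-direction treatment change meeting the magnitude/significance
condition is flagged `further_modulated_*` instead — e.g. a protein
down-regulated by injury and pushed further down by treatment is modulated,
not reversed.

Three deliberate readings of the rules, each genuinely open:

* **The 10% is linear-scale.** "A 10% change in expression value" is read on
  the linear ratio: affected iff `r <= 0.90` or `r >= 1.10`. The two sides
  are asymmetric on the log scale (log2 0.9 = -0.152 vs log2 1.1 = +0.138);
  that asymmetry is inherent to the linear reading and is carried through
  the synthetic generator.
* **Direction versus magnitude.** Back-regulation measures magnitude against
  the untreated injured state (`NoSCS`) and direction toward the uninjured
  state (`NoSNI`). A reversal that overshoots past uninjured levels still
  counts by default; `overshoot_allowed = FALSE` disqualifies reversals
  whose final level crosses to the far side of `NoSNI`.
* **No multiple-testing correction.** Significance is per-test at `alpha`,
  matching the design the counts are defined under; this is a scientific
  caveat, not an oversight — with hundreds of proteins at α = 0.05 the
  affected set contains false positives, and users wanting FDR control
  should adjust `quantify_proteins()` p-values before classification.

Numerical tie-breaks: the threshold comparison treats values within 1e-9 of
the boundary as on it (so a ratio of exactly 0.90 counts as affected despite
floating-point representation); a significant fold change of exactly zero
has no direction and produces no reversal call.

## Category rollups and overlap counts

Proteins carry functional category annotations — `structural`, `adhesion`,
`junction`, `signaling` — supplied as an input table (the package never
computes them from ontologies). Phospho-isoforms inherit every category of
their parent protein, and an entity belonging to several categories counts
in each, so category totals may exceed the number of distinct entities.
`venn_counts()` reports exact set overlaps between category groups, by
default the three classes used in the overlap figure (structural, combined
adhesion/junction, signaling).

Percentage formatting follows the reporting conventions the counts are
printed under: whole percent, rounded half-up, at category level (81.52%
prints as 82) and one decimal at overall level (83.578% prints as 83.6).
Base R's `round()` is round-half-even and cannot reproduce these, so the
package uses an explicit half-up rounding.

## The synthetic generator

`generate_phospho_dataset()` and `generate_proteomic_dataset()` produce
input tables with planted, machine-checkable ground truth; every entity is
assigned one of nine classes (unaffected; affected up/down; optionally
reversed by DTMP, by LR-SCS, or both — reversal classes exist only inside
affected classes). `plant_composition()` converts reported marginal counts
into class counts, nesting the two reversal sets maximally (always
feasible). The truth is written as a `truth.tsv` sidecar by
`write_synthetic_dataset()`; real datasets simply lack the sidecar.

**Ratio placement.** Planted pain ratios sit a multiplicative `margin`
beyond the decision boundary: `1.10 * (1 + margin)` for up,
`0.90 / (1 + margin)` for down. A symmetric log-scale placement was
rejected: mirroring the up-ratio (`1/(1.10(1+margin))`) falls *inside* the
linear 10% boundary for margins below about 0.011, which would make
noiseless datasets misclassify their own truth. The asymmetric placement is
beyond the boundary for every `margin > 0`.

**Noise.** Measurement noise is multiplicative log-normal — each observed
intensity is the planted abundance times `2^e` with `e ~ N(0, noise_sd)` —
the standard model for spectral intensities. The study reports no noise
magnitudes, so `noise_sd` defaults to 0 (noiseless) and benchmark datasets
are exact by construction; noisy settings are exercised by the recovery
tests below.

**Proteomic peptide dispersion.** With `noise_sd = 0` a naive generator
would give every peptide an identical ratio, zero sample variance, and an
undefined t-test. Instead the generator plants a deterministic
peptide-response heterogeneity: an exactly centered, unit-sd pattern across
each protein's peptides, scaled by a per-channel coefficient times
`scatter_sd` (default 0.1 on log2). Because the pattern is exactly centered,
an unplanted contrast has mean ratio exactly zero (t = 0, p = 1), while a
planted shift of

$$\delta = t_{crit}\,\frac{s_\Delta}{\sqrt{k}}\,(1 + \text{margin}),
\qquad s_\Delta = \sqrt{(c\,\sigma_{scatter})^2 + 2\sigma_{noise}^2}$$

(`c` the contrast's channel-coefficient difference) is significant by
construction at `noise_sd = 0` and with high probability at small noise.
This closed-form calibration avoids an iterative power search; a fixed
`pain_shift_log2` can override it for power studies.

**Benchmarking against planted truth.** Generated tables are
channel-balanced by construction — the generator plants biological effects,
not loading offsets. Re-estimating offsets with `normalize_channels()` on
such data perturbs every fold change by the median-estimation drift (about
0.02 log2 units on the 186-protein benchmark), which is comparable to the
knife-edge calibration slack and flips borderline significance calls. The
benchmark round-trips therefore run quantification on the generated tables
directly — they satisfy the normalized-input precondition by construction —
while `normalize_channels()` is tested separately for the properties it
actually guarantees: exact removal of constant per-channel shifts and
idempotence. Separating offset estimation from inference testing is the
same discipline as testing size-factor estimation apart from differential
testing.

**What the generator does not emulate.** Missing values, isobaric
interference, batch effects, peptide misassignment, and raw spectra are all
out of scope. Passing round-trip tests therefore demonstrates that the
classification arithmetic and counting conventions are correct — not that
the pipeline is robust to those real-data pathologies.

**Feasible noise for recovery.** With two runs, the standard deviation of an
isoform's estimated log2 ratio equals `noise_sd`. A planted up-ratio sits
`log2(1.155/1.10) = 0.0705` log2 units beyond the boundary at
`margin = 0.05`, so the probability of missing an affected isoform is
`pnorm(-0.0705/noise_sd)`: about 0.9% at `noise_sd = 0.03` but already 7.9%
at 0.05. Recovering the affected fraction to within 2 percentage points on
an 83.6%-affected composition therefore requires `noise_sd` below roughly
0.035; the recovery tests run at 0.03, where the analytic expectation is
within 0.8 points.

**Annotation fixtures.** `generate_annotation()` realizes requested Venn
marginals and overlaps exactly via inclusion–exclusion (rejecting infeasible
requests). The benchmark overlap composition in
`benchmark_venn_composition()` — 48 structural, 112 adhesion/junction, 102
signaling, pairwise overlaps 7/15/69, triple overlap 4 — is the unique
solution consistent with all the reported overlap fractions (18/48
structural, ~64% of 112, ~78% of 102, 69 junction-signaling, 4 in all
three).

## Benchmark compositions

`benchmark_compositions()` returns the planted class counts used by the
round-trip benchmarks: the overall phospho composition (883 isoforms, 738
affected, 559/428 reversed), the four per-category compositions
(69/56/46/29, 111/92/75/59, 790/664/509/390, 394/325/237/197), and the ECM
protein composition. The protein dataset comprises 186 proteins with
reversal *percentages* of 83% (DTMP) and 67% (LR-SCS) of pain-affected
proteins; the affected count itself is not part of the reported composition,
so the benchmark plants 100 affected proteins (83 and 67 reversed), which
realizes the percentages exactly while keeping integer counts. The split of
affected classes between up- and down-regulation is likewise unreported and
defaults to half and half; none of the benchmarked quantities depend on it.

Problem sizes in the test suite are the compositions themselves (883, 186,
69–790 entities) — small enough that the full suite runs in under a minute —
with noisy-recovery properties averaged over 20 seeds and rule invariants
exercised on thousands of randomized entities.

## Reporting artifacts

`encode_protein_heatmap()` emits the tri-state matrix behind the protein
expression figures: per contrast, `+1` significant increase, `-1`
significant decrease, `0` otherwise. `encode_phospho_heatmap()` emits
percent changes, by default only for each protein's most pain-affected
isoform (`select_top_isoforms()`, ties broken lexicographically by isoform
id — the one documented tie-break). Row order everywhere is alphabetical by
entity id; the numeric TSV matrix is the canonical artifact and graphical
rendering is deliberately out of scope, keeping outputs bit-exact and
diffable. `write_summary()` writes `classification.tsv`,
`category_rollup.tsv`, `heatmap.tsv`, and `summary.json` (counts,
percentages, configuration echo, seed provenance).

## Worked example

```{r example}
comp <- benchmark_compositions()
spec <- planted_spec(comp$phospho_overall, noise_sd = 0, seed = 1)
ds <- generate_phospho_dataset(spec)
quants <- quantify_phospho(ds$table)
cls <- classify_dataset(quants)
str(cls$summary)
```

With `noise_sd = 0` the planted composition is recovered exactly: 738 of
883 isoforms affected (83.6%), 559 reversed by DTMP (75.7% of affected),
428 by LR-SCS (58.0%).

## Known limitations

* Pooled channels mean all "significance" rests on peptide-level pseudo-
  replication; the t-test detects consistent peptide behavior, not
  biological reproducibility.
* No FDR control by default (documented above).
* Phospho CVs are computed and reported but not used as a filter; whether a
  CV cut-off should precede classification is left to the user.
* Annotations are consumed, never derived; protein inference from shared
  peptides is out of scope (`unique_assignment` is taken at face value).
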