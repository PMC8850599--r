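---
title: "Screening and validating ceRNA triads with triadscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and validating ceRNA triads with triadscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadscreen)
```

## The problem

Long non-coding RNAs can act as competing endogenous RNAs (ceRNAs): by
carrying binding sites for a miRNA they sequester ("sponge") it, lowering
its free pool and thereby de-repressing that miRNA's mRNA targets. In a
biomarker study this motivates searching for *triads* — an lncRNA, a miRNA
and an mRNA wired as lncRNA ⊣ miRNA ⊣ mRNA — whose members shift in
opposite directions in patients. `triadscreen` packages the full desk-to-
bench workflow of such a study for Parkinson-disease-style case-control
designs: knowledge-base screening, qRT-PCR quantification and statistics,
network summarization, and seed-site / dual-luciferase validation
analytics, all testable on synthetic data with planted ground truth.

## The screening cascade

`run_cascade()` applies seven stages in a fixed order, each a pure
set-filter driven by `screen_config()`; no stage carries a numeric literal
of its own:

| stage | filter | config field (default) |
|---|---|---|
| A | disease-related miRNAs with strong experimental validation | `strong_evidence_methods` ({reporter-assay, western-blot, qPCR}) |
| B | miRNA→lncRNA interactions above the score gate | `min_lncbase_score` (0.7, strict) |
| C | lncRNAs expressed in every required tissue | `required_tissues` ({blood, brain}) |
| D | drop literature-known disease lncRNAs and low-degree candidates | `pd_disease_label`, `min_mirna_degree` (2) |
| E | lncRNAs whose miRNAs hit a key disease gene above the gate | `pd_gene_set`, `min_gene_prediction_score` (80, strict) |
| F | drop lncRNAs associated with other excluded diseases | `excluded_disease_labels` |
| G | emit triads whose lncRNA/gene loci are cis-proximal | `max_cis_gap_bp` (50,000, strict) |

Design choices where the workflow is genuinely underdetermined:

* **Score gates are strict inequalities.** "Above 0.7" and "above 80" are
  read literally, so boundary values fail. The filters are set-valued, so
  no tie-breaking is ever needed.
* **"Distance" between gene loci is the inter-interval gap** on 0-based
  half-open coordinates: 0 for overlapping or abutting intervals, otherwise
  the count of bases strictly between the nearer ends; `Inf` across
  chromosomes; strand-agnostic. This is the weakest assumption consistent
  with a "distance below a threshold" criterion and is monotone under
  interval extension. Whether such a criterion should instead compare
  transcription start sites is exposed as a convention choice, not
  hard-coded. The gap gate is strict (`gap < max_cis_gap_bp`).
* **"Strong validation" is an evidence-method whitelist**, defaulting to
  the reporter-assay / western-blot / qPCR trio conventionally labelled
  strong evidence in curated miRNA-target databases, and configurable
  because conventions differ between database versions.
* **The degree filter counts only cascade-surviving miRNAs** (stage-A
  survivors whose interactions pass the score gate), matching the cascade's
  narrative order. It is therefore order-sensitive and fixed at its
  position; the tissue, specificity and known-disease filters commute and
  are covered by an order-insensitivity test.
* **Missing annotations fail, never error.** An lncRNA without a tissue
  record fails stage C; an entity without a locus cannot pair at stage G
  and is recorded in the audit trail as `"no locus"`. A screen over
  heterogeneous database snapshots must be total.
* **Interaction-score gates can be disabled** (`apply_lncbase_gate`,
  `apply_gene_score_gate`) because published screens sometimes quote such
  scores only as post-hoc commentary; the default applies both as filters.

Every eliminated entity is attributed to the first stage that removed it,
and `|survivors| + |eliminated|` equals the stage input size at every
stage. On any small knowledge base the cascade provably equals a one-pass
brute-force conjunction over all (lncRNA, miRNA, gene) triples; the test
suite and acceptance script re-verify this on 100 random knowledge bases
per run.

```{r cascade-demo}
res <- run_cascade(demo_knowledge_base(), demo_screen_config())
res$triads
```

The demonstration fixture is a labelled *reconstruction* of the named
entities and printed scores of the study this workflow emulates — it is
not a database snapshot, and its genomic coordinates are illustrative
values satisfying the cis criterion (the real loci of these genes are
megabases apart).

## Comparative-CT quantification

`collapse_replicates()` averages technical replicates arithmetically and
flags (never drops) entries whose replicate SD exceeds 0.5 cycles; a
single replicate has undefined SD and is left unflagged. The aggregation
rule and QC threshold are package choices — triplicate designs rarely
publish one.

`relative_expression()` implements the comparative-CT method:
ΔCt = Ct~target~ − mean(Ct~references~), ΔΔCt = ΔCt − mean(ΔCt over the
baseline group), rq = 2^−ΔΔCt^. Multi-reference normalization uses the
arithmetic mean of reference Cts, which is geometric-mean normalization on
the quantity scale. The marker→reference map is configuration, defaulting
to standard practice: miRNAs normalize to U6; mRNAs and lncRNAs to
GAPDH + 18S. By construction the geometric mean of rq over the baseline
group is exactly 1. No amplification-efficiency correction is applied —
the method assumes doubling per cycle.

## Adaptive statistics

`select_test()` mirrors the desktop-statistics workflow: every group must
pass a D'Agostino–Pearson omnibus normality test for the parametric branch
(unpaired pooled-variance t test for two groups; ordinary one-way ANOVA
with Tukey HSD for three or more), otherwise the nonparametric branch is
used (Mann–Whitney; Kruskal–Wallis with Dunn post hoc). Numerical choices:

* The K² omnibus statistic is implemented in-package (skewness z per
  D'Agostino, kurtosis z per Anscombe–Glynn) and matches an independent
  reference implementation to 10 decimals on frozen cases. The transforms
  are unreliable below n = 8, so smaller groups route nonparametric
  (`min_n_for_normality = 8`).
* Mann–Whitney effects are Hodges–Lehmann median differences with
  distribution-free 95% CIs; Kruskal–Wallis post hoc effects are Dunn
  mean-rank differences (no CI — the effect lives on the rank scale) with
  Bonferroni family-wise adjustment, the classical Dunn correction.
* Effects are always oriented *second group minus first group* of the
  comparison label; published tables sometimes mix orientations between
  test families, so one convention is imposed throughout.
* Significance is `p < α` with α = 0.05 by default. No correction is made
  across markers by default, mirroring common practice in small panels; a
  Benjamini–Hochberg option exists for honest reuse
  (`qpcr_config(p_adjust = "BH")`).
* The select-then-test procedure is mildly miscalibrated by construction
  (the branch is chosen on the same data); over 2,000 null simulations its
  empirical type-I error at nominal 0.05 stays within [0.025, 0.085], and
  the acceptance checks assert exactly that band rather than pretending
  exact calibration.

`roc_curve()` computes the AUC by the rank method with ties counted half,
re-orienting scores (with an explicit flag) whenever the raw AUC is below
0.5, since a biomarker may discriminate in either direction. On tie-free
data AUC = U/(n₁n₂) exactly, which the tests assert to 1e-12, and the AUC
is invariant under strictly monotone transforms of the marker.

## Seed sites and reporter analytics

`find_seed_sites()` scans for canonical seed classes (6mer, 7mer-A1,
7mer-m8, 8mer) defined by Watson–Crick complementarity to miRNA positions
2–7 with the m8 and A1 upgrades; each core window is reported once at its
maximal class, overlapping windows are all reported, U/T are equivalent
and case is ignored. This deterministic canonical-site definition is the
desk-scale stand-in for thermodynamic duplex predictors: the biological
claim it supports is validated by the reporter assay, not by the scan
itself. No G:U wobble seeds are considered. A hook for an external duplex
predictor is a declared non-goal rather than a half-implementation.

`normalize_reporter()` takes per-well dual-luciferase readings. In the
psiCHECK-2 design the tested fragment is fused to the *Renilla* 3′ UTR and
firefly normalizes transfection efficiency, so `signal = "renilla"` is the
default; the switch exists because method sections sometimes state the
inverted ratio. `compare_reporter_conditions()` reports
`100 × (1 − mean_R/mean_R_ref)` percent change — invariant to common
rescaling of all wells — with an unpaired t test per condition; on a
noise-free plate with zero variance the comparison degenerates and is
reported as exact (p = 0 or 1) rather than erroring.

## What the generators emulate

`synth_config()` defaults encode the emulated study conditions: 20
controls and 38 patients split 27 early (stage I n=10, II n=17) / 11 late
(III n=10, IV n=1); six markers with the observed directions (linc01128,
miR-24-3p, miR-30c-5p down; linc00938, LRRK2, ATP13A2 up) as ±0.5-cycle
ΔΔCt shifts; triplicate wells; a 70% wild-type reporter inhibition at 5%
CV with 6 replicates; 140-nt constructs with one implanted 8mer for the
mature miR-30c-5p sequence. Choices the emulated study does not pin down:

* **Effect sizes are in Ct-shift units**, not fold change, because
  relative-expression studies print directions and significance rather
  than magnitudes; ±0.5 cycles with 0.5-cycle biological SD makes all six
  markers significant at this design in most seeds, which matches the
  reported outcome qualitatively.
* **Noise defaults**: biological SD 0.5 cycles per sample, technical SD
  0.15 cycles per replicate, reference-gene SD 0.1 cycles (housekeeping
  genes modelled as stable). With a planted shift δ and biological SD σ
  the control-vs-patient AUC then concentrates near the binormal closed
  form Φ(δ/(σ√2)), which the acceptance checks use as an oracle at
  δ = σ = 1.
* **Metadata distributions** match the reported subgroup summaries
  (`demo_demographics()`): age and BMI truncated normal; disease duration
  lognormal, because its reported SD is of the order of its mean,
  indicating right skew; MoCA always ≥ 26 (lower scores were an exclusion
  criterion); the UPDRS percent ranges are I [0,25), II [25,50],
  III (50,75], IV (75,100] — the source table's "> 25" header for stage I
  is read as a typo for "< 25", since stage I is the mildest state.
* **Knowledge-base decoys** each violate exactly one cascade predicate
  (seven modes, one per elimination stage); background lncRNAs are absent
  and background miRNAs always fail stage A, so planted-triad recovery is
  exact by construction rather than probabilistic.

What the generators deliberately do **not** emulate: real database
content (identifiers are synthetic outside the labelled demonstration
fixture), inter-marker correlation, plate/batch effects, amplification-
efficiency drift, outlier wells, and patient dropout. Passing the
recovery tests therefore shows the machinery is correct under the stated
model, not that the model captures every failure mode of real qPCR data.

## Problem sizes of the automated checks

The test suite and `scripts/acceptance.R` use: 100 random knowledge bases
(~8 lncRNAs × 8 miRNAs × 6 genes) for cascade-oracle equivalence; 200
seeded cohorts at the 20/38 design for AUC and ΔΔCt recovery; 2,000 null
simulations for type-I calibration; 200 seeded plates for inhibition
recovery; 500 random sequences up to 2 kb for the seed-scan oracle. These
sizes give stable Monte-Carlo estimates at the asserted tolerances while
keeping a full run in the low minutes on one CPU.

## Known limitations

* The cascade is a faithful re-implementation of a published screening
  *procedure*; its biological validity is bounded by the knowledge-base
  snapshots fed to it, and database-scale candidate counts are not
  reproducible from synthetic data.
* The seed scanner is sequence-only: no accessibility, free energy, or
  conservation. Sites it reports are necessary-condition candidates.
* Dunn post hoc p-values use Bonferroni control, which is conservative for
  three groups.
* The Mann–Whitney CI is distribution-free but assumes a location-shift
  alternative when read as a median difference.
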