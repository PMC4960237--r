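---
title: "Inferring an outer-membrane proteome from fractionation LFQ data"
author: "omprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring an outer-membrane proteome from fractionation LFQ data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omprofiler)
```

## The problem

Subcellular fractionation of a Gram-negative bacterium — a
sarkosyl-resistant membrane preparation, sucrose density gradients, an
intracellular fraction and whole-cell lysate — followed by LC-MS/MS gives
a protein-by-sample table of label-free quantification (LFQ) intensities.
LFQ intensity is a proxy for absolute protein abundance, but no fraction
is pure: abundant cytoplasmic proteins contaminate membrane preparations,
and genuinely surface-exposed proteins may be scarce. Deciding which
proteins constitute the outer membrane (OM) proteome therefore combines
two kinds of evidence: *where the mass spectrometer finds the protein*
(abundance in the OM-enriched fraction) and *what its sequence predicts*
(signal peptides, lipoprotein anchors, beta-barrels, localization
predictors). `omprofiler` implements that combination as an explicit,
configurable decision procedure, together with the LFQ preprocessing it
needs and a synthetic benchmark that makes every stage testable against
ground truth.

## The model and its assumptions

**Scales.** Intensities are stored as log10 values. All *share*
computations (composition, enrichment) happen on the linear scale,
because intensities are linear quantities and compartment compositions
are sums of them; log10 is for storage, display and thresholds. Whether
an input table is linear or log10 must be known at ingestion —
`read_lfq_table()` expects linear intensities and takes the log.

**Missing values.** A protein without enough quantified peptides has no
LFQ value. Such cells are imputed *per sample* at
`max(min_detected − δ, floor)`: a value below the least abundant
quantified protein of that sample. The offset δ is not identifiable from
data — the convention only says "lower than the minimum" — so it is a
parameter (default 0.5 log10 units). The floor (default 4.0) is the
abundance at which undetected proteins are displayed in comparative
plots; imputation never goes below it, and the constructor enforces that
imputed values stay strictly below each sample's detected minimum. The
detection mask is kept separately from the values, so every downstream
rule can distinguish "measured" from "filled in": the preliminary-list
threshold ignores imputed cells entirely, and share denominators exclude
them by default (`detected_only = TRUE`), which prevents imputed floors
from dominating sparse samples.

**Composition and enrichment.** The compartment composition of a sample
is the linear-scale abundance share summed per predicted compartment; it
sums to 1 by construction. The enrichment factor of a compartment between
two fractions is the ratio of its *shares*, not of raw summed
intensities, so differences in total protein load between runs cancel.
An alternative reading — ratio of protein counts — is possible but
discards abundance information; the share-ratio reading is the one
implemented and tested. A reference share of exactly zero makes the
factor undefined and raises an error rather than returning infinity.

**The classifier.** The preliminary candidate list is the *union* of the
abundance arm (detected above log10 8.5 in at least one OM-fraction
sample) and the predictor arm (CELLO or PSORTb says OM). A union is used
deliberately: abundant cytoplasmic contaminants *should* enter the
preliminary list and then be rejected by the confirmation criteria — an
intersection would silently discard them before the rules ever saw them,
and would also exclude the abundant-but-unpredicted proteins the screen
is designed to catch. "Above 8.5" is read as a strict inequality and
applied per sample (any OM sample qualifies); both choices are
configurable (`classifier_config`). Confirmation fires on any of four
independent criteria — dual OM prediction, lipoprotein, beta-barrel,
or non-classical secretion without a signal peptide (SecretomeP score
strictly above 0.5, the tool's conventional Gram-negative cutoff) —
and is monotone: adding evidence can never demote a confirmed protein.
Proteins with a signal peptide but no criterion are assumed periplasmic
(exported, but with no OM evidence); proteins with neither keep their
CELLO label, which is how unconfirmed cytoplasmic contaminants end up
reported under their own compartment. Lipoprotein means the
lipoprotein-anchor class specifically; ordinary signal-peptidase-I
cleaved proteins do not satisfy C2. Predicted extracellular proteins are
reported under their own label rather than folded into `om_confirmed`,
so the OM set stays strictly criteria-defined. The genome-wide screen
applies the same criteria to every protein never detected in the
proteomics data, flagging the resulting calls as not experimentally
observed.

**Condition response.** With one sample per condition (the usual design
for these fractionation studies) no significance test is meaningful, so
the pipeline reports descriptive linear fold changes with a strict,
two-sided >10-fold rule. Condition-exclusive proteins are defined by the
detection mask, not by the ratio: a protein detected only under one
condition is flagged `only_a`/`only_b`, and its numeric ratio — computed
against the imputed floor of the absent condition — is reported but
separable. Replicate handling (averaging log10 values) exists but is off
by default to match the single-sample design.

## The PEP-CTERM scanner

The PEP-CTERM sorting signal of the exosortase/EpsH system is formally
defined by profile HMMs (TIGRFAM). This package instead implements a
transparent heuristic with three testable parts, scanned over the
C-terminal region (default last 35 residues): a literal Pro-Glu-Pro
motif; a transmembrane segment beginning within 5 residues after the
motif; and at least 2 basic residues (K/R) within 10 residues after that
segment. The TM detector computes a centered sliding-window
Kyte–Doolittle hydropathy profile (window 11), takes maximal runs of
positions at or above 1.6, merges runs separated by at most 2
sub-threshold positions, and then expands each run outward over
contiguous residues whose own hydropathy is at or above the threshold.
The expansion step matters: window smoothing erodes roughly half a
window from each end of a genuine hydrophobic stretch, so the run of
above-threshold *centers* under-measures helix length; expansion
recovers the physical segment, which is then required to span 15–25
residues (+5 slack). Because the smoothed extent of a real TM segment can
touch the motif itself, the segment's start is clipped to the first
position after the motif before the gap rule is applied. Ties between
candidate motifs go to the leftmost qualifying PEP. The scanner is a pure
function of sequence and configuration.

This heuristic is *not* expected to reproduce HMM-based genome counts on
real proteomes: it has no position-specific scoring and no model of the
funnel-shaped conservation of the real domain. Its contract, verified in
the tests, is 100% recall on constructs that meet all thresholds with
margin and a false-positive rate of at most 1 per 100 random hydrophilic
sequences.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws a proteome whose defaults mirror the shape of
a real single-organism study: 2176 proteins; compartment proportions
cytoplasmic 0.55, inner membrane 0.20, periplasmic 0.11, OM 0.04,
extracellular 0.10; log10 intensities normal around compartment-by-
fraction means with σ = 0.8 and censoring below 6.0. The fraction means
encode the fractionation physics: a common whole-proteome baseline
(7.5), an OM-depleted intracellular fraction, and a sarkosyl fraction
with OM proteins raised by +1.3 log10 and cytoplasmic/inner-membrane
proteins depleted — values chosen so that the closed-form expected OM
enrichment (truncated log-normal partial means,
`E[10^X; X>L] = 10^μ e^{c²σ²/2} Φ((μ + cσ² − L)/σ)`, c = ln 10) lands
near 18-fold, the order of magnitude a successful sarkosyl preparation
shows. Predictor truth follows deterministically from the compartment
(OM proteins get dual OM labels, a lipoprotein class with probability
0.3 and a barrel with probability 0.6); each field is then independently
replaced, with probability ε (default 0.05), by a uniform draw over its
domain. This redraw model is deliberately simple so that classifier
recovery has a closed-form expectation by per-field enumeration, which
the acceptance tests check to 3 binomial standard deviations.

Planted structure: 20 responsive OM proteins with true 20-fold
(±1.301 log10) condition effects applied to all mucin-condition samples;
4 exclusives per condition, simulated by forcing censoring in the other
condition (detection-limit semantics, not literal zeros); 17 OM proteins
censored everywhere (recoverable only by the genome screen); 23 proteins
with planted PEP-CTERM tails. All planted sets live in the OM stratum,
as in the real studies, and the generator errors if that stratum cannot
host them. Sequences are drawn from a hydrophilic-weighted amino-acid
background — a deliberate *non*-realism: real membrane proteomes contain
hydrophobic stretches that this background suppresses, so scanner tests
against the generator measure recall of planted signals, not real-world
specificity. Similarly, the log-normal independence of cells ignores the
peptide-level correlation structure of real LFQ data, and predictor
errors are independent across fields, whereas real predictors fail in
correlated ways on the same hard proteins. Passing tests on this
generator therefore validate the *logic* of the pipeline, not the
field performance of the external predictors it consumes.

## Numerical and design choices

- Problem sizes in the test suite: the benchmark scenarios run at the
  full 2176-protein scale; oracle-equivalence and invariant suites run
  on 1000 randomized small tables/sequences, chosen so the whole suite
  completes in well under two minutes on one CPU.
- Tolerances: share conservation and reciprocity to 1e-9;
  brute-force oracle equivalence to 1e-12 relative; stochastic
  recoveries to 3 SD of their closed-form expectations.
- Ties and degenerate inputs: leftmost PEP motif wins; a sample with no
  detected values makes imputation fail loudly (no defined minimum); an
  imputation floor at or above a sample's minimum is an error rather
  than a silent invariant violation; constant gradient profiles return
  monotonicity 0; empty proteomes/hit tables round-trip as valid empty
  outputs.
- Interchange formats are tab-separated with fixed column names;
  undetected cells are written as empty strings and read back from
  either empty or `0` cells. Detected values round-trip through TSV to
  better than 1e-6 on the log10 scale.
- The sucrose-gradient monotonicity statistic is the sign of the
  Spearman correlation between density rank and OM share — a
  deliberately coarse summary; the per-fraction shares are returned for
  anything finer.
- `sessionInfo()`-level reproducibility: every stochastic component
  (generator, test fuzzing, acceptance script) is seeded explicitly, and
  generation is byte-identical under a fixed seed.

## Known limitations

- The classifier consumes external predictor outputs; it cannot be more
  accurate than they are, and it implements no sequence-based
  localization prediction of its own.
- With n = 1 per condition, fold changes are descriptive; the >10-fold
  rule has a substantial false-positive rate under σ = 0.8 noise
  (closed-form: ~38% for a null protein), which is why responsive calls
  should be read as a screen, not as inference.
- The PEP-CTERM scanner is a heuristic stand-in for profile-HMM
  screening and will miss divergent motifs (e.g. non-literal PEP) by
  construction.
- The shipped PilQ record is a synthetic stand-in at the documented
  length (907 residues); analyses of its *sequence content* would be
  meaningless.
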