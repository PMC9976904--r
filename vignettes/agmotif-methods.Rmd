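---
title: "Methods: purine-motif-directed unwinding analyses in agmotif"
author: "agmotif authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: purine-motif-directed unwinding analyses in agmotif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agmotif)
```

# Scope and biological background

eIF4A1 is the DEAD-box RNA helicase of the eIF4F translation-initiation
complex. mRNAs whose translation is strongly eIF4A1-dependent tend to carry
stable secondary structure in their 5'UTRs, and single-stranded AG/purine-rich
motifs adjacent to such structure can recruit and activate the helicase
locally. `agmotif` implements the three quantitative layers used to study
this mechanism — transcriptome-wide DMS structure probing anchored on purine
motifs, pulsed-SILAC measurement of translation-rate changes under eIF4A
inhibition, and the in-vitro enzymology of the purified helicase — together
with seeded generators that emulate each data type.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic data do and do not
establish.

# Motif-anchored structure probing

## Containers and coordinates

Transcripts live in a `TranscriptSet` (a `DNAStringSet` plus a region
annotation with 5'UTR/CDS/3'UTR lengths and an abundance estimate; RNA
input is normalised U→T). Per-nucleotide DMS reactivities live in a
`ReactivitySet`: DMS methylates unpaired A and C only, so G/T positions are
`NA` by construction and `validateReactivity()` enforces the base/NA
correspondence. Internally coordinates are 1-based (the Bioconductor
convention for `GRanges`/`IRanges`); every output table uses 0-based
half-open coordinates, stated in the column documentation.

## Motif scan

`scanMotifs()` finds non-overlapping 10-nt windows whose bases all lie in
{A,G} ("R10"; the analogous {G,C} class is available as "GC5"). Two rules
shape the hit set:

* **Composition cap** (`composition_cap = 7`): at most 7 of the 10 bases
  may be the same purine, excluding A₁₀/G₁₀ and near-homopolymers. The two
  published phrasings of this rule ("maximum of 7/10" and "more than 8")
  conflict; the package applies the stricter reading, count(A) ≤ 7 and
  count(G) ≤ 7, and exposes the cap as a parameter so the looser reading
  (cap 8) is one argument away.
* **Edge distance** (`min_edge_distance = 50`): hits must lie at least
  50 nt from their region's boundaries, which for terminal regions includes
  the transcript ends. This keeps the offset windows (below) inside the
  same region and away from translation-start/stop effects.

"Non-overlapping" is resolved greedily left-to-right within each region:
after accepting a window the scan resumes at its end. Greedy resolution is
deterministic, order-independent and matches how run-based motif scanners
behave; the test suite pins it to an independent brute-force enumerator on
hundreds of random transcripts.

## Offset windows and the ΔDMS statistic

For each motif, `motifWindowDelta()` averages reactivity over defined A/C
positions in a 20-nt window at inclusive distances 31–50 nt downstream of
the motif's last base (and mirrored upstream of its first base), in both
conditions, and reports `delta = mean(treated) − mean(control)`. Windows
need at least `min_defined = 5` defined positions — an unstated constant in
the source analyses; five keeps single-nucleotide noise from dominating a
window mean while discarding few windows (a 20-nt window has ~10 A/C
positions in expectation). Windows that would leave the transcript are
flagged invalid rather than dropped, so the caller controls pairing.

Because DMS reactivity measures single-strandedness,
`classifyStructureChange()` maps delta < 0 to *gain* of structure and
delta > 0 to *loss*; exactly zero is excluded.

## Random-window controls and testing

Controls are 20-nt windows on a 10-nt step grid anchored at the region
start, under the same 50-nt edge rule, sampled uniformly without
replacement — the same number per transcript and region as there are motif
hits (`matchedRandomWindows()`). The motif and control deltas are compared
with a paired two-sided Wilcoxon test (`compareMotifVsRandom()`); pairs in
which either window is invalid are removed jointly. The Wilcoxon
implementation drops zero differences, uses the exact distribution up to
n = 25 (no ties) and the continuity-corrected normal approximation above.

`joinStructureTranslation()` inner-joins per-gene window deltas with a
translation-rate table to produce the structure-class versus
log2-fold-change association; genes missing from the rate table are counted,
not silently lost.

# Pulsed-SILAC translation rates

Peptide-level TMT reporter intensities are aggregated by
`aggregatePeptidesToProteins()`: duplicate peptide sequences are combined
per channel by median, peptides are combined into protein groups by sum
(median available; the published combining operator is unstated, and sum is
the usual choice for reporter intensities as it weights peptides by signal).
Peptides mapping to multiple protein groups are excluded and counted.

The labelling model is first-order: the heavy fraction
F_H = I_heavy/(I_heavy + I_light) grows toward 1, and the fitted form is
the linearisation ln F_H = k·t + offset (natural log), with the slope k the
apparent translation rate in h⁻¹. Points with F_H ≤ 0 are removed before
the log (t = 0 under a fresh pulse); replicates enter as separate points;
at least three usable points are required. Fit quality is gated by the
F-test against k = 0 at p < 0.1 in *both* conditions, then per-protein
differences k_treat − k_ctrl are tested with a z-statistic using the two
slope standard errors (a Welch t-test on per-replicate slopes is available
via `difference_test = "welch"`), and BH FDRs are computed across proteins.
The published analyses name no specific difference test, only "standard
procedures" and FDRs; the slope-SE z-test is the minimal-assumption choice
and is documented as such. Classification uses FDR < 0.1 (dependent) and
FDR > 0.7 (independent), leaving an unclassified band between.

Upstream batch normalisation of reporter channels is out of scope; the
generators produce already-normalised intensities, and real data should be
normalised before import.

# Enzymology models

All fits are ordinary or Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with explicit starting values and bounds:

* **Unwinding progress**: F(t) = A·(1 − e^(−k_obs·t)); amplitude A is the
  total fraction unwound and A·k_obs the initial rate. A linear
  early-window fit (default 5 points) is provided as the alternative
  initial-rate estimator, since both conventions are in use. Raw
  fluorescence is converted to fraction unwound with user-supplied 0%/100%
  controls (`normalizeProgressSignal()`).
* **Hill titrations**: y = y_max·c^h/(K½^h + c^h). Initialisation: y_max
  from the response maximum, K½ by interpolating the half-maximal
  concentration, h = 1; bounds h ∈ (0, 6] and K½ within the tested range
  ×[0.01, 100]. The fitted curve passes y_max/2 at K½ identically, which
  the tests assert as the defining property.
* **Decays**: y = A·e^(−rate·t), half-life ln2/rate; constant traces
  short-circuit to rate 0 with a non-convergence flag instead of a
  platform-dependent NLS error.
* **ATPase**: in the pyruvate-kinase/LDH coupled assay each hydrolysed ATP
  oxidises one NADH, so rate = −slope(A340 vs t)/ε with ε(NADH) = 0.62
  absorbance·mM⁻¹ as the instrument default.
* **Subunit mixing**: mixtures of active and catalytically dead protein at
  inactive fraction f follow 1 − f for any enzyme without subunit
  cooperativity (the x + y = 1 line) and (1 − f)^n for an obligate
  n-subunit enzyme poisoned by a single dead subunit. `fitMixing()` selects
  integer n by least squares over n = 1..6 and reports the full
  model-comparison table; intermediate-cooperativity models are
  deliberately out of scope.
* **Buoyancy**: the partial specific volume of a PₙR complex is the
  mass-weighted mean (n·M_P·ṽ_P + M_R·ṽ_R)/(n·M_P + M_R), monotone from the
  RNA value at n = 0 toward the protein value.
* **Reporter rates**: maximum sliding-window OLS slope of luciferase
  activity (window 5 readings — unstated in the source protocols,
  configurable), normalised so a reference reporter maps to exactly 1; for
  dual-luciferase time courses the rate is the OLS slope of the per-time
  FL/RL ratio.
* **mRNA concentration**: copies/(N_A·V); 300 000 copies in 2425 µm³ give
  ≈ 0.21 µM, the basis for treating cellular eIF4A1 (10–20 µM) as in
  large excess over mRNA.

# Synthetic data: what it emulates and what it does not

The generators define the study conditions the tests run under.

**Transcriptomes** (`simulateTranscriptome()`): one transcript per gene,
uniform base composition, region lengths uniform on 150–400 nt (UTRs) and
300–900 nt (CDS) — compact relative to real transcriptomes but long enough
for every planted motif to satisfy the 50-nt edge rule. One motif is
planted per region by default; planted motifs are drawn with 3–7 of each
purine and flanked by forced pyrimidines so that greedy scanning cannot
merge them with background purine runs, giving an exact recovery guarantee
the tests exploit. Background sequence still produces spurious motifs at a
low rate, as in real data.

**Reactivity pairs** (`simulateReactivityPair()`): baseline reactivity per
A/C position is truncated-at-zero normal (mean 0.5, sd 0.15), with
independent truncated-normal noise (sd 0.1) per condition; the treated
condition subtracts the planted effect (mean −0.15) only at A/C positions
in the 31–50-nt downstream window of planted motifs, never upstream —
mirroring the asymmetry the motif-anchored analysis is designed to detect.
The truncation at zero rectifies a small fraction of treated values and
biases the realised mean delta upward by ≲0.01, which the ±0.02 generator
checks absorb. Real reactivities are heavier-tailed and spatially
correlated (stacking, local structure); a gamma noise option is the planned
extension, and rank-based testing keeps the inference insensitive to the
marginal shape.

**Pulsed-SILAC cohorts** (`simulatePsilac()`): 100 proteins, times
0/2/4/8 h, 4 replicates (the published design), lognormal channel noise at
10% CV, labelling rates k ~ U(0.05, 0.3) h⁻¹, a 25% dependent subset with
the treated rate halved. Two modes exist because the fitted model is the
linearisation: the default `"loglinear"` mode makes ln F_H = k·t + offset
hold exactly (baseline heavy fraction ≈ 0.1), so rate recovery is limited
only by noise; the `"mechanistic"` mode generates F_H = 1 − e^(−kt), whose
log is *not* linear in t (for k·t ≪ 1, ln F_H ≈ ln k + ln t), so the
ln-linear slope is a biased estimate of k there. Cohort-level recovery and
classification properties are therefore defined against the log-linear
mode; the mechanistic mode documents how far the linearisation bends under
realistic kinetics. The default rate range was fixed by an a priori power
analysis of the classifier design (4 replicates, 10% CV, z-test + BH at
FDR 0.1): rates of 0.05–0.3 h⁻¹ — proteins with appreciable label
incorporation over an 8-h pulse, the fraction of the proteome a short-pulse
TMT experiment actually quantifies — give ≈ 0.9 expected sensitivity,
whereas extending the range down to 0.02 h⁻¹ leaves slow-turnover proteins
undetectable within the pulse and drops design sensitivity below 0.8.

**Enzymology fixtures** (`simulateEnzymology()`): each curve family is
generated from its stated model (defaults: A = 0.8, k_obs = 0.05 min⁻¹;
y_max = 1, K½ = 2, h = 2 on an 8-point log grid; decay rate 0.1; mixing
n = 3; ATPase 0.1 mM·min⁻¹ at ε = 0.62), noise-free by default so fits
must round-trip exactly, with optional seeded relative Gaussian noise.

Passing tests on these cohorts establishes that the estimators and tests
are correct and well calibrated under the stated models — not that real
libraries are free of coverage artefacts, normalisation batch effects or
correlated structure, which the generators deliberately do not model.

# Problem sizes, determinism and numerical conventions

The test suite runs the scanner-vs-oracle comparison on 200 random
transcripts, the type-I calibration on 500 no-effect cohorts of 24 paired
windows (exact Wilcoxon regime), the power check on 100 cohorts of 300
planted motifs, and the classification performance on 50 pulsed-SILAC
cohorts of 100 proteins — sizes chosen so each property is measured with
useful Monte-Carlo precision while the whole suite stays desk-runnable.
Every stochastic step takes an explicit seed, pipeline runs record the seed
and a config hash in `manifest.json`, and reruns are byte-identical.

Numerical conventions worth knowing: an exact line (rss = 0, nonzero
slope) reports a slope p-value of 0 rather than NaN; a slope of exactly 0
reports p = 1 (F = 0); BH adjustment, Wilcoxon and t-tests delegate to the
standard R implementations and are pinned against independent enumeration
oracles in the tests; abundance ties in primary-transcript selection break
to the lexicographically smallest transcript id; coverage thresholds
default to pass-through because the original cut-offs live in a prior
study's processing chain — they are plain configurable columns here.

# Known limitations

* The random-window class is scored as full 20-nt windows (per the
  sliding-window construction); trimming controls to 10 nt to mirror the
  motif length is configurable but not the default, and the two choices
  differ slightly in window-mean variance.
* The generators draw reactivity i.i.d. across positions; spatially
  correlated reactivity would widen the null of the paired test relative
  to these simulations.
* The slope-SE z-test treats per-point residuals as independent; with few
  time points and replicate structure, a mixed model would be the heavier
  alternative.
* GC5 motifs reuse the R10 machinery over {G,C}; no claim is made that
  the same composition cap is the field's convention for GC-rich windows.
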