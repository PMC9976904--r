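# agmotif

Quantitative analyses for studying how AG/purine-rich 5'UTR sequence motifs
direct localized unwinding by the DEAD-box helicase eIF4A1 and shape
eIF4A1-dependent translation. The package is aimed at computational
biologists working with transcriptome-wide RNA structure probing
(DMS/Structure-seq-style reactivities), TMT pulsed-SILAC proteomics, and
in-vitro helicase enzymology, and bundles three analysis arms behind one
set of Bioconductor-style containers:

1. **Motif-anchored structure probing.** Non-overlapping polypurine
   ("R10") motifs — 10-nt windows with every base in {A,G}, at most 7/10
   of either base (excluding near-homopolymers), and at least 50 nt from
   any UTR/CDS boundary or transcript end — are scanned per annotated
   region. For each motif, the change in DMS reactivity
   ΔDMS = mean(treated) − mean(control) is computed over 20-nt windows at
   inclusive distances 31–50 nt up- and downstream of the motif edge,
   compared against matched random sliding windows (20 nt / 10-nt steps,
   same constraints) by a paired two-sided Wilcoxon test. Since DMS
   reactivity measures single-strandedness, ΔDMS < 0 is a *gain* of
   structure.

2. **Pulsed-SILAC translation rates.** Heavy-label incorporation
   F_H = I_heavy / (I_heavy + I_light) is fitted per protein and condition
   with the linearised first-order labelling model
   ln F_H = k·t + offset; fits are filtered by an F-test against k = 0
   (p < 0.1 in both conditions), condition differences are scored
   (difference, log2 fold change, BH FDR), and proteins are classified
   helicase-dependent (FDR < 0.1) or -independent (FDR > 0.7).

3. **Enzymology curve models.** Duplex-unwinding progress curves
   F(t) = A·(1 − e^(−k_obs·t)) with initial rate A·k_obs; Hill titrations
   y = y_max·c^h / (K½^h + c^h); single-exponential decays and half-lives;
   NADH-coupled ATPase rates (−slope(A340)/ε, ε = 0.62 mM⁻¹); relative
   FRET F665/(F565+F665); wt/catalytically-dead subunit-mixing models
   (noncooperative line 1 − f vs the n-subunit poisoning model (1 − f)^n);
   AUC partial specific volumes of protein:RNA complexes; and reporter
   translation-rate extraction.

Seeded generators (`simulateTranscriptome()`, `simulateReactivityPair()`,
`simulatePsilac()`, `simulateEnzymology()`) emulate every input with known
ground truth, so the whole pipeline is testable without any downloads.

## Worked example

Simulate a transcriptome with planted 5'UTR purine motifs and a localized
downstream structure gain, then run the structure arm:

```r
library(agmotif)

spec <- simulationSpec(n_genes = 50)
sim  <- simulateTranscriptome(spec, seed = 7)
rp   <- simulateReactivityPair(sim$transcripts, sim$truth, spec, seed = 8)

res <- runStructurePipeline("out_structure",
                            transcripts = sim$transcripts,
                            ctrl = rp$ctrl, treat = rp$treat)
#> structure: 50 transcripts in, 50 primary retained
#> structure: 162 R10 motifs (5UTR: 54, CDS: 57, 3UTR: 51)
subset(res$test_summary, region == "5UTR")
#>  region       side n_pairs            p median_motif_delta median_random_delta
#>    5UTR   upstream      53 7.190541e-01       -0.009229455         -0.00890834
#>    5UTR downstream      52 2.546735e-09       -0.151096180         -0.01377861
```

The downstream motif windows show a median reactivity change near the
planted −0.15 (a gain of structure) while upstream windows and random
windows do not; the paired Wilcoxon p-value reflects the localized,
motif-directed effect. The pulsed-SILAC arm works the same way:

```r
ps  <- simulatePsilac(simulationSpec(), seed = 3)
out <- runPsilacPipeline("out_psilac", ps$data)
#> psilac: input 100 proteins, p < 0.1 in both conditions: 100, removed: 0
#> psilac: dependent 23, independent 40 (FDR thresholds 0.1/0.7)
```

Each run writes TSV result tables (all transcript coordinates 0-based
half-open) and a `manifest.json` with the configuration hash, seed, input
checksums and per-stage counts.

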