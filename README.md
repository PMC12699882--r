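# mitoscope

Inference of a candidate mitochondrial proteome for non-model
eukaryotes (built around the diplonemid *Diplonema papillatum* use
case), combining three lines of evidence per protein:

1. **Localization ensemble.** Three predictors' mitochondrion scores
   are combined into a weighted average,
   `WA = (2.5 s_sec + 1.5 s_ter + 6 s_pri) / 10`,
   with two categorical overrides: a protein assigned to the
   mitochondrion only by the secondary predictor is downgraded by a
   factor of 0.25, and a protein assigned by neither defaults to
   WA = 0. Scores map to confidence bands
   (`non_mitochondrial` = 0, `low_probability` (0, 0.25),
   `likely` [0.25, 0.5), `very_likely` [0.5, 0.75),
   `almost_certainly` [0.75, 1]), whose likelihood ratios are
   calibrated against curated positive/negative reference proteins.
2. **MS enrichment.** From spectral counts or ion intensities across
   whole-cell / cytosol / mitochondria fractions, a protein is
   *detected in mitochondria* when
   `mito/whole > cyto/whole` **and** `mito/whole > 1.5`, with the
   divisor floored at the dataset's minimal non-zero value when the
   protein is absent from whole cell, and a complex-association
   override for respirasome/mitoribosome members. iBAQ quantification
   (intensity / observable tryptic 7–30-mers) is included.
3. **Motif evidence.** An iterative, F1-calibrated discovery of
   pentatricopeptide-repeat (PPR) motifs — threshold selection
   against curated motif references by precision/recall/F1
   (`F1 = TP/(TP + 0.5(FP+FN))`), rescue of motifs hidden in
   30–40-residue inter-motif gaps via helix-turn-helix
   secondary-structure criteria, rebuild of a lineage-specific
   profile, and a second calibrated search — plus twin-Cx9C motif
   scanning with spacer reporting and an Ala/Lys-composition screen.

A first-class synthetic-data module (`synth_config()`,
`synth_dataset()`) generates every input format with known ground
truth — class-conditional predictor scores, separable i-E-value
populations, planted repeat arrays, noisy structure labels, enriched
MS profiles — so the entire pipeline runs and is validated without
any external tools or downloads. See the methods vignette
(`vignettes/mitoproteome-inference.Rmd`) for the model details and
design decisions.

## Worked example

```r
library(mitoscope)

cfg <- synth_config(n_proteins = 300, n_ref_pos = 80, n_ref_neg = 80,
                    n_ref_motif_pos = 60, n_ref_motif_neg = 100,
                    seed = 42)
d <- synth_dataset(cfg)

res <- run_pipeline(list(
  proteins = d$proteins, predictors = d$predictors,
  hits = d$hits, tracks = d$tracks, quants = d$quants,
  reference_pos = d$reference$protein$positives,
  reference_neg = d$reference$protein$negatives,
  motif_reference = d$reference$motif,
  null_decoys = 20L, seed = 1L))
print(res)
```

```
Mitoproteome inference run
  proteins: 300 
  localization bands:
    non_mitochondrial  156
    low_probability    8
    likely             1
    very_likely        47
    almost_certainly   88
  candidates (>= selection band): 135 
  candidates with WA > 0.5: 100.0%
  detected in mitochondria (MS): 99 
  PPR-containing proteins: 50 
  twin-Cx9C proteins: 13 | AK-rich proteins: 5 
```

135 of the 300 synthetic proteins reach the candidate bands
(`very_likely` or better, i.e. WA ≥ 0.5 — hence the 100% line); the
pipeline recovers exactly the 50 proteins with planted PPR arrays, 13
proteins with chained twin-Cx9C motifs and all 5 planted AK-rich
proteins. The motif-threshold calibration achieves perfect separation
of the planted references:

```r
print(res$ppr$calibration1)
```

```
Motif i-E-value threshold calibration
  reference: 60 positive / 100 negative motifs
  thresholds evaluated: 498
  selected threshold: 0.3131811  (perfect separation)
  at selection: TP=60 FP=0 FN=0  P=1.000 R=1.000 F1=1.000
```

and the band likelihood ratios rise monotonically with the band
(`res$band_odds`), from 0.014:1 for `non_mitochondrial` through 12:1
for `very_likely` to effectively infinite odds in the top band.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/mitoscope.R` with subcommands `synth`, `locscore`,
`enrich`, `scan` and `all` (YAML-configured; see the script header).

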