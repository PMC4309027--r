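# phosphoscan

Phosphopeptide identification and phosphosite localization from CID
LC-MS/MS spectra.

Protein phosphorylation on serine and threonine is the workhorse of
cellular signalling, and mapping it by tandem mass spectrometry is
routine — but hard to do well. Under collision-induced dissociation
(CID), phospho-S/T peptides characteristically shed H₃PO₄ (97.977 Da
neutral), producing a dominant neutral-loss peak, while the phosphate
itself moves the peptide and its fragments by +79.966 Da (HPO₃).
`phosphoscan` turns these facts into a complete, scriptable analysis
pipeline for proteomics labs working from Sequest-style `dta` spectra
and a protein FASTA:

1. **Database construction** — in silico tryptic digestion (≤ 2 missed
   cleavages by default), fixed Cys carbamidomethylation (+57.02 Da),
   variable phospho-S/T (+79.97 Da), monoisotopic masses; decoys by
   protein sequence reversal; a single composite target+decoy table.
2. **Spectrum preprocessing** — charge filter (z ≤ 4), base-peak
   normalization to 100, removal of the 50 least intense peaks of every
   100-peak m/z bin, and the neutral-loss prescreen: a spectrum is
   analyzed further only if a peak of intensity ≥ *t* lies within
   3/z Da of `precursor_mz − k·97.976896/z` for some k ≥ 1. The
   threshold *t* ∈ [0, 100] is the pipeline's single
   performance-related tuning knob.
3. **Search and site localization** — candidate peptides by precursor
   mass (7 ppm default), all C(#S/T, n) phosphosite isomers expanded,
   b/y theoretical spectra with −H₂O/−NH₃/−H₃PO₄ variants, and the
   sigmoid match score

   Score = Σ_{j=1..M} [ 2/(1 + e^(−I_j)) − 1 ]

   over the M matched experimental peaks of normalized intensity I_j,
   so noise-prone low-intensity peaks weigh less.
4. **Statistical validation** — per-spectrum decoy score distributions
   give each target hit a p-value P(S ≥ s) (smoothed empirical or
   Gumbel-tail estimator), tested against the Bonferroni-corrected
   critical value α = α_whole / K, with K the number of target peptide
   entries (e.g. 0.05 / 10⁷ = 5·10⁻⁹ at proteome scale).
5. **Evaluation** — confusion counts and the six standard indexes
   (sensitivity, specificity, accuracy, FDR, precision, F-measure),
   plus sequence/site correctness checks against a truth table.

A ground-truthed synthetic CID spectrum generator (bundled synthetic
FASTA, planted neutral-loss peaks, uniform noise) makes every stage
testable end-to-end without external downloads.

## Worked example

```r
library(phosphoscan)

db  <- build_composite(parse_fasta(synthetic_fasta()))   # 20 proteins
sim <- simulate_dataset(5, 5, tempdir(), sim_config(seed = 7))
res <- identify_spectra(sim$spectra, db, nl_threshold = 30)
res$summary[, c("spectrum_id", "passed_nl", "n_hits",
                "n_significant", "best_modseq", "best_p")]
```

```
    spectrum_id passed_nl n_hits n_significant      best_modseq   best_p
1  sim_0001.dta      TRUE      2             0          LsCLNTK 3.33e-01
2  sim_0002.dta      TRUE      1             0 LMMFtELEVsVLAAVK 5.00e-01
3  sim_0003.dta      TRUE      1             0     KVLVCDGsDGFD 5.00e-01
4  sim_0004.dta      TRUE      4             0    DGsTSHLMKSLIE 1.00e+00
5  sim_0005.dta      TRUE      3             2     DGHIsQTGESLK 8.94e-09
6  sim_0006.dta     FALSE      0             0             <NA>       NA
...
```

All five planted phosphopeptides pass the neutral-loss check and are
identified rank-1 with the correct site (lower-case `s`/`t` marks the
localized phosphoresidue); all five non-phospho spectra are screened
out. Scoring against the truth table:

```r
truth <- sim$truth; truth$is_phospho <- nzchar(truth$modseq)
cc <- confusion(res$summary, truth[, c("spectrum_id", "is_phospho")])
metrics(cc)
#> sensitivity specificity    accuracy         fdr   precision   f_measure
#>           1           1           1           0           1           1
bonferroni_alpha(0.05, db_K(db))   # K = 2972 target entries here
#> [1] 1.682369e-05
```

The same pipeline is available as subcommands (`build-db`, `merge`,
`identify`, `evaluate`, `simulate`) through `phosphoscan_main()`, with
a flat key=value config file and exit codes 0/1/2
(success/input error/config error):

```sh
Rscript -e 'quit(status = phosphoscan::phosphoscan_main())' \
  identify --db_path db.tsv --spectra_dir dta/ --out_dir out \
  --nl_threshold 30
```

## Scope

CID spectra only (ETD produces no neutral loss); phosphotyrosine is
deliberately not a variable modification (pY rarely shows neutral loss
under CID); raw-to-`dta` conversion and vendor formats are upstream of
this package.
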