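---
title: "Identifying phosphopeptides from CID MS/MS spectra with phosphoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying phosphopeptides from CID MS/MS spectra with phosphoscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoscan)
```

## The problem

A phosphoproteomic LC-MS/MS run yields thousands of tandem (MS/MS)
spectra, each a list of fragment m/z values with intensities, plus the
precursor's mass and charge. Three questions have to be answered per
spectrum: is the underlying peptide phosphorylated at all; what is its
sequence; and on *which* serine or threonine does the phosphate sit?
The last question is the hard one — positional isomers (`FsAASSASK`
vs `FSAAsSASK`) have identical precursor masses and share most
fragments, differing only in the few site-determining ions between the
candidate residues.

`phosphoscan` answers all three with a five-block pipeline: composite
database construction, spectrum preprocessing with a neutral-loss
prescreen, isomer-resolved database search, decoy-based statistical
validation, and performance evaluation. A synthetic-spectrum generator
closes the loop for testing.

## The model and its assumptions

**Fragmentation.** Under low-energy CID, peptides cleave along the
backbone into b- (N-terminal) and y- (C-terminal) ions; fragments may
additionally lose water (−18.011 Da), ammonia (−17.027 Da) or, if they
carry a phosphoresidue, H₃PO₄ (−97.977 Da). Theoretical spectra
contain the full b/y series at 1+ (configurable up to
min(2, precursor z)) with loss variants gated on residue content:
−H₂O only for fragments containing S/T/E/D, −NH₃ only for R/K/N/Q,
−H₃PO₄ only for fragments covering a phosphosite. The gating is a
design choice (standard CID chemistry; it reduces spurious matches);
emitting losses ungated would only add near-random fragment positions.

**Neutral-loss prescreen.** The phosphate ester bond is weaker than
backbone bonds, so phospho-S/T precursors often shed intact H₃PO₄,
producing a dominant peak at `precursor_mz − k·97.976896/z`. We test
k = 1..4 (multiply phosphorylated precursors can lose several
phosphates) at the precursor charge only, with tolerance `3/z` Da, and
select a spectrum when a matching peak has normalized intensity at or
above the user threshold (inclusive comparison, so threshold 100 can
still accept a base-peak loss). Even at threshold 0 an actual matched
peak is required — this is what screens out most non-phosphopeptides
at permissive settings. Consequence, by design: phosphotyrosine (no
neutral loss under CID) and ETD data are out of scope.

**Scoring.** A candidate's score is the sum over matched experimental
peaks of the sigmoid weight `2/(1+exp(−I))−1` of their normalized
intensity `I ∈ [0,100]`. Each experimental peak counts at most once,
matched if within the fragment tolerance (0.8 Da default) of any
theoretical fragment; hence `0 ≤ score ≤ M`. The sigmoid discounts
low-intensity (noise-prone) peaks, though it saturates quickly: peaks
above intensity ~10 weigh essentially 1, so the score behaves mostly
like a weighted match count. Ranked ties are broken by matched-peak
count, then modified-sequence string — output order is fully
deterministic.

**Validation.** Searching the composite (target+decoy) database gives
each spectrum two ranked hit lists. The decoy list calibrates chance:
a target hit's p-value is the probability that a decoy hit scores at
least as high. With K target peptide entries tested, the per-test
critical value is Bonferroni-corrected to `α = α_whole/K` (0.05/10⁷ =
5·10⁻⁹ at human-proteome scale).

## Numerical and estimator choices

* **Masses** are monoisotopic throughout: H₂O 18.010565, NH₃
  17.026549, H₃PO₄ 97.976896, HPO₃ 79.966331, carbamidomethyl
  57.021464, proton 1.0072765. Peptide neutral mass = Σ residues +
  H₂O + fixed/variable deltas.
* **p-value estimator.** The tail probability P(S ≥ s) needs an
  estimator; two ship. `empirical`: the add-one-smoothed count
  `(1 + #{d ≥ s})/(1 + N)` — never 0, defined for empty decoy lists,
  ties counted against the target. Its floor `1/(N+1)` means it can
  never reject below a proteome-scale α with realistic per-spectrum
  decoy lists, so the default is `gumbel`: a type-I extreme-value
  right tail fitted to the spectrum's decoy scores by moments
  (`β = sd·√6/π`, `μ = mean − γβ`), evaluated analytically via
  `-expm1(-exp(-z))` for numerical stability; with < 3 decoys or zero
  variance it falls back to the empirical estimate. Max-score
  distributions are the natural habitat of the Gumbel family, but the
  moment fit on small decoy lists is rough — tail p-values far below
  1/N are extrapolations and should be read as such.
* **Binned denoising.** Peaks are binned by count (100 per bin in m/z
  order), not by fixed m/z width — the reading we adopted of "bins of
  one hundred peaks". A final partial bin of n peaks loses its
  ⌊n/2⌋ least intense, extending "half per bin" proportionally.
  Intensity ties at the cut rank keep the higher-m/z peak
  (deterministic). The base peak always survives.
* **Tolerances** are inclusive (≤) everywhere, matching the precursor
  match definition `|x − y| ≤ δ`.
* **Digestion.** Trypsin cleaves C-terminal to K/R except before P; up
  to 2 missed cleavages by default; peptides of 5–60 residues retained
  (sub-5-mers are unidentifiable by CID and inflate K); N-terminal Met
  is not specially cleaved; chymotrypsin (low specificity) is the
  second built-in rule. Variable phospho count is capped at 4 per
  peptide to bound the isomer combinatorics — at 7 ppm precursor
  tolerance, higher counts effectively never match anyway.
* **Database entries** are mass-level (sequence + phospho count);
  positional isomers are expanded at search time. Duplicate
  (sequence, count) pairs from different proteins collapse to one
  entry per target/decoy class, and K counts distinct target entries.

## What the simulator emulates — and what it does not

`simulate_spectrum()` emits: a sampled subset (coverage 0.8 by
default) of the 1+ b/y fragments with Gaussian m/z jitter (sd 0.1 Da);
for phosphopeptides a planted neutral-loss peak at
`precursor_mz − 97.976896/z`; and 30 uniform noise peaks. Raw
intensities are drawn so that normalization lands the base peak on a
planted peak: fragments uniform in [40, 90], the neutral-loss peak at
100 (dominant, as in real phospho-CID spectra), noise below 20.
Charges are drawn 2+/3+/4+ with probabilities 0.76/0.22/0.02 — the
composition of a typical curated phosphopeptide test set. The
precursor carries 2 ppm jitter (modern instrument accuracy, within the
7 ppm search window). The peptide source is a bundled synthetic FASTA
of 20 invented sequences drawn once from typical amino-acid
frequencies; it is labelled synthetic and has no relation to any real
proteome. All defaults were fixed a priori and are not tuned to test
outcomes.

Not emulated: isotope envelopes, chimeric spectra, realistic
fragment-intensity structure (proline effect, charge-directed
cleavage), semi-tryptic peptides, and co-eluting modifications. A
green end-to-end test therefore establishes that the pipeline
correctly recovers planted signal under calibrated noise — not that it
matches any particular instrument's behaviour on real biological
spectra.

## Degenerate inputs and edge behaviour

FASTA records with ambiguity codes (B/X/Z) are rejected with a
warning, mirroring standard dataset curation. dta records without
fragment peaks are skipped with a warning; all-zero-intensity spectra
are rejected at normalization. Empty candidate or decoy lists are
legal: the empirical p-value degrades to 1 (conservative), and
metrics with zero denominators are reported `NA` with a warning, never
silently 0. The dta precursor line is read as (M+H)⁺ by default (the
de-facto convention); instruments exporting precursor m/z are handled
by `dta_precursor = "mz"`.

## Known limitations

* The Gumbel tail is an extrapolation device; its absolute p-values at
  proteome-scale α depend on a distributional assumption the decoy
  list cannot itself verify.
* One-match-per-experimental-peak is greedy and unweighted by mass
  error; a closest-assignment bipartite match would differ in rare
  dense-spectrum cases.
* Fragment charges default to 1+; 2+ fragments of 3+/4+ precursors are
  only generated if configured, and a/c/x/z ions (ETD) never.
* Site localization confidence is implicit in the hit ranking; no
  dedicated localization probability (e.g. site-determining-ion FLR)
  is computed.
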