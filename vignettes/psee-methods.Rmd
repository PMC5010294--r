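---
title: "Position specific estimated energy: model, choices, and limits"
author: "PSEE package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position specific estimated energy: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PSEE)
```

## The model

A folded protein buries hydrophobic residues into a tightly packed core
held together by favourable inter-residue contacts; intrinsically
disordered regions (IDRs) stay solvent-exposed and never settle into a
stable fold. The position specific estimated energy (PSEE) of residue
$i$ estimates, from sequence alone, how much favourable contact energy
that residue contributes to the fold:

$$
\mathrm{PSEE}(i) \;=\; p_{\mathrm{bur}}(i)\,
\frac{\sum_{j \in N_i} P(a_i, a_j)\, p_{\mathrm{bur}}(j)}{2\,\mathrm{CR}},
$$

where $N_i$ is the sequence neighbourhood of CR residues on either side
of $i$ (excluding $i$, truncated at the chain ends), $P$ is a 20 x 20
pairwise contact potential derived from sequence statistics, and
$p_{\mathrm{bur}} = 1 - p_{\mathrm{exp}}$ is the proportional burial:
predicted accessible surface area divided by the residue's reference
area in an extended Gly-X-Gly tripeptide, complemented. Negative PSEE is
energetically favourable (ordered, core-like); values near zero or
positive mark unstable, disorder-prone positions. Burial enters twice —
for the target and for each partner — so a fully exposed residue
contributes nothing no matter how favourable its contacts could be.

The package ships the contact potential and the reference-area table as
plain TSV resources (`loadContactEnergyMatrix()`,
`loadASANormalization()`), diffable against their printed sources.

## Parameters that matter

* **Contact radius CR** (default 9, dimensionless residue count). The
  neighbourhood holds 2 CR partners. `sweepContactRadius()` re-derives
  the choice on any labelled dataset: for each CR it recomputes all
  PSEE values, takes the ordered/disordered class means, classifies at
  their midpoint and scores MCC; the argmax is the selected CR, with
  ties broken toward the smaller (cheaper) radius — a tie-break the
  method's description leaves open.
* **Divisor** — always $2\,\mathrm{CR}$, even in truncated terminal
  neighbourhoods, because that is how the formula is printed. The
  consequence is that terminal PSEE magnitudes shrink toward the chain
  ends; `normalizeByCount = TRUE` in `pseeConfig()` switches to dividing
  by the actual partner count.
* **Exposure clipping** (default on). Predicted ASA can exceed the
  Gly-X-Gly reference; clipping $p_{\mathrm{exp}}$ to $[0,1]$ keeps
  burial a proportion. Disable with `clipExposure = FALSE`.
* **Symmetrization** (default off). The packaged contact table is
  asymmetric in 12 cells (e.g. Q/V: 0.38 vs -1.91) — plausibly
  transcription artifacts in the printed source, since one row partially
  duplicates another. The default looks up the as-printed entry with the
  target residue on the row, exactly as the formula indexes $P$;
  `symmetrize = TRUE` averages the two ordered entries.
  `matrixAsymmetryReport()` lists the affected pairs.
* **Classifier** — RBF-kernel SVM with cost $C = 0.5$ and
  $\gamma = 2^{-7}$, the published grid-search optimum, with sigmoid
  probability calibration; the calibration's internal cross-validation
  folds derive from the training seed, which is the package's
  reproducibility contract (identical seed, identical probabilities).
* **Decision threshold** (default 0.79). Chosen in the original study by
  Youden's J on an independent set; `youdenOptimalThreshold()`
  re-derives it on any scored set by exhaustively scanning midpoints
  between consecutive distinct probabilities (plus 0 and 1), breaking
  ties toward higher specificity and then the lower threshold. Raw
  probabilities are rescaled so the threshold lands on 0.5
  (`rescaleProbability()`): $[0,\theta) \to [0, 0.5)$ and
  $[\theta, 1] \to [0.5, 1]$, piecewise linear and invertible.

## Numerical and degenerate-input choices

* A residue whose PSEE equals the separation threshold exactly is
  assigned to the ordered (favourable) side — the boundary must be
  deterministic.
* Non-standard residue codes (X, B, Z, U) mark their positions
  *unavailable* (`NA`) rather than zero, and such positions are skipped
  both as targets and as partners, with a warning. `strict = TRUE`
  rejects the sequence instead, mirroring pipelines that drop whole
  chains. Unavailable positions are excluded from class means, metrics
  and training; annotation label `X` likewise.
* Cysteine-rich stretches can produce extreme PSEE because the C-C
  potential (-39.58) dwarfs every other entry; the package computes
  normally but warns when $|\mathrm{PSEE}|$ exceeds a configurable
  magnitude (default 10), leaving exclusion to the caller.
* Disordered-region length strata are $\le 5$, 6–20, 21–40, $\ge 41$
  residues; the two printed upper brackets overlap at 40, so the split
  at 40/41 is fixed here once.
* MCC with a zero denominator factor returns 0 (undefined-as-neutral).
* ROC/AUC use the trapezoidal rule over all distinct-score thresholds,
  which equals the pairwise rank statistic with ties counted one half.
  Precision-recall sweeps descending thresholds and stops at full
  recall; under perfect ranking every reported point has precision 1.
* Predictor ranking uses competition ranks per metric (ties share the
  best rank, the next rank is skipped), summed into the cumulative
  score $S_c$, final rank by ascending $S_c$. Published comparisons are
  not internally consistent about tied $S_c$ — one benchmark table
  resolves them densely, others competitively — so the final-rank tie
  policy is an explicit argument (`finalTies`), defaulting to
  competition. Tie detection uses exact equality on the metric values
  as given, with no epsilon.
* Sliding-window feature vectors zero-pad outside the sequence; the
  terminal-indicator feature (−1.0 … −0.2 / +0.2 … +1.0 over the five
  residues at each end, 0 inside) already encodes end proximity. For
  chains shorter than ten residues the two terminal rules overlap; the
  N-terminal value wins over the first $\lceil L/2 \rceil$ positions.

## The synthetic generator

`generateDataset()` emulates exactly the contrast the energy analysis
relies on: sequences alternate ordered and disordered segments; ordered
segments draw residues hydrophobic-biased (70% of compositional weight
on the ten hydrophobic residues) with Beta-distributed relative exposure
of mean 0.25 — the conventional burial cut — and disordered segments
hydrophilic-biased with mean exposure 0.67. ASA is sampled exposure
times the reference area, so proportional exposure recovers the sampled
value exactly (a designed round trip). All of this is seed-determined.

What it does **not** emulate: evolutionary profiles (PSSMs), real
secondary-structure propensity, torsion dynamics, or the long-range
contact structure of real folds — the non-PSEE feature columns produced
by `generateFeatureTable()` are label-correlated Gaussian noise, stand-ins
for externally computed features. Tests passing on this generator
therefore demonstrate that the machinery is correct and that PSEE
carries class signal under the assumed composition/exposure contrast;
they do not certify predictive performance on real proteins, which in
the original study depends on curated training data and external
predictors for ASA and secondary structure.

## Problem sizes in the shipped tests

The test-suite runs at deliberately small scale: 40 sequences of 80–160
residues for dataset-level properties, 200 random sequences of length
at most 60 for the brute-force PSEE oracle, 16 sequences with a
10-feature window-9 schema for the classifier ablation (3 repeats), and
$10^4$ draws for the stochastic metric properties. These sizes give
stable verdicts for every property asserted while keeping the whole
suite inside a minute or two.

## Known limitations

* The hydrophobicity index shipped for correlation analysis is the
  Kyte–Doolittle hydropathy scale; the original analysis cites a
  different (unprinted) source for its index, so correlation values on
  real data are comparable in sign and rough magnitude, not digit by
  digit. Tests on the scale are therefore property-based only.
* PSEE depends on *predicted* ASA; the package deliberately does not
  predict ASA or secondary structure, and its accuracy inherits the
  upstream predictor's.
* The published benchmark tables are reproduced from their printed
  metric values wherever those are self-consistent; two tables print
  ranks that can only have come from unrounded internal values, and the
  package makes no attempt to guess those.
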