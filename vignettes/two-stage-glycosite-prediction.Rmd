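---
title: "Two-stage prediction of N-linked glycosylation sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage prediction of N-linked glycosylation sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glysite)
```

## The problem and the model

N-linked glycosylation is restricted (apart from rare N-X-C cases, which
this package deliberately ignores) to N-X-S/T sequons with X ≠ proline, yet
the motif is weakly predictive on its own: a large fraction of sequon
asparagines are never glycosylated. glysite treats the problem at two
scales, on the premise that the two kinds of evidence are complementary:

1. **Is the protein a glycoprotein at all?** Homologs of glycoproteins tend
   to be glycoproteins. Stage 1 turns a homology-search hit list into the
   similar-protein set $S(P)$ (hits with probability $\ge 0.5$, self-hits
   removed) and lets labelled training proteins vote. A training protein
   $P$ is a *template* for query $Q$ when $|S(Q) \cap S(P)| \ge k$; its
   vote is the squared overlap, so strong homology counts disproportionately:
   $$V_G = \sum_{i:\,\text{glyco}} |S(Q) \cap S(P_i)|^2, \qquad
     V_{NG} = \sum_{j:\,\text{non-glyco}} |S(Q) \cap S(P_j)|^2,$$
   and the protein score is $V_G / (V_G + V_{NG})$, in $[0,1]$, undefined
   when no template qualifies.

2. **Which sequons in it carry the glycan?** Stage 2 classifies each sequon
   from a 25-mer window centred on the asparagine (padded with the dummy
   residue `X` near termini), using an RBF-kernel support vector classifier
   over three feature families described below.

Final scores multiply the stage-2 probability by 0.8 when the stage-1 score
is below 0.4 and by 1.1 (capped at 1) when it is above 0.8 — strict
inequalities, so boundary scores are left alone — and a sequon is called a
glycosite when the final score exceeds 0.6. An undefined stage-1 score
applies no adjustment: absence of homology evidence is treated as absence
of evidence, not as evidence against.

### Gapped dipeptide ratios

A gapped dipeptide pairs the central N with one flanking residue at gap
$k$ ($0 \le k \le 11$): $AkN$ upstream, $NkA$ downstream. The two
downstream gap-1 dipeptides N1S and N1T are the sequon's own third residue
and carry no discriminative information, leaving 23 dipeptides per window
and $12 \times 20 + 11 \times 20 = 460$ realizable types. A type is
identified by the triple (side, gap, residue): note the printed names
collide for residue N, where "N5N" reads the same from either side, so all
internal bookkeeping uses the triple.

For each type, the GDR is the ratio of its occurrence share among
glycosite windows to its share among non-glycosite windows — an odds-ratio
style statistic. Two conventions matter and are deliberate:

* **No smoothing by default.** Types absent from negatives have undefined
  GDR rather than an arbitrarily large smoothed value, so fitted tables are
  reproducible directly from raw counts (an optional pseudocount is
  exposed). Undefined types are excluded from the normalisation ranking.
* **Neutral fallback 0.5.** Per (gap, side) class the defined GDRs are
  min-max rescaled to $[0,1]$; a window dipeptide that is undefined,
  unseen, or involves padding/ambiguity letters (X, B, Z, U, O) encodes as
  the midpoint 0.5, so terminal padding cannot push a prediction either
  way. A degenerate class (all defined GDRs equal) also maps to 0.5.

The occurrence-share denominator is equivalent, up to a constant that the
min-max normalisation cancels, to a per-window-count denominator; the test
suite asserts this equivalence rather than assuming it.

### Pattern-based SA/SS encoding

Exposure and local structure matter — glycosylation favours exposed,
non-helical sequons — but a 25-residue one-hot encoding of predicted
classes would be far wider than the usual training sets can support. The
window is instead split into an N-terminal region ending at position 12, the
sequon region (positions 13–15, fixed length 3), and a C-terminal region
starting at position 16; both terminal regions are anchored at the
sequon-proximal end. For each region the annotation substring of length
$w$ is a *pattern*; patterns occurring in fewer than
$\lceil 0.01 N \rceil$ of the $N$ training windows (boundary counts
retained), patterns containing the pad character, and patterns never seen
in negatives are merged into a single "other" bucket.

The terminal pattern length $w^\* \in \{3,\dots,11\}$ is chosen per region
and feature type by maximising the average pattern deviation
$$APD_w = \frac{\sum_i |e_i/n_i - z|\,(e_i + n_i)}{\sum_i (e_i + n_i)},$$
with $e_i$, $n_i$ the pattern's class counts and $z$ the glycosite /
non-glycosite window ratio. The other bucket participates as one pattern;
if its negative count is zero (only possible when every merged occurrence
is positive) it is dropped from both sums to keep the statistic finite.
Ties in the sweep break toward smaller $w$ — the simpler vocabulary.
Encoding is one-hot per region block (matched pattern, else the other
bucket), so a full encoding always contains exactly six ones. When a
training vocabulary retained every possible pattern and merged nothing,
the block has no bucket slot; an unmatched pattern at prediction time then
encodes as an all-zero block, which in practice can only be provoked
artificially (the sequon region is always inside the protein, and real
terminal regions always produce rare patterns).

### Classifier and training protocol

Features are concatenated as GD ‖ SA ‖ SS. Training follows a two-step
protocol: an $n$-fold cross-validated grid search over
$C \in \{2^{-5}, 2^{-3}, \dots, 2^{15}\}$ and
$\gamma \in \{2^{-15}, 2^{-13}, \dots, 2^{3}\}$ (110 cells) selects the
cell with the highest pooled accuracy; then, at the selected cell, each
fold model chooses its decision threshold from $\{0.25, 0.30, \dots,
0.75\}$ by maximum MCC on its training folds, and the fold model with the
highest held-out-fold MCC is kept as the final classifier. Probability
scores are Platt-style estimates from the underlying libsvm fit.

Two reproducibility details are worth stating. First, all randomness (fold
assignment and the internal probability-calibration folds) derives from
the required `seed` argument, making training bit-reproducible. Second,
cross-validation folds are grouped by protein id by default
(`group_by_protein = TRUE`): sequons of one protein share flanking
sequence, and sequon-level folds would leak that overlap into held-out
estimates. Plain sequon-level folds remain available for comparison. In
`cv_glysite()` the featurizers (GDR table, pattern vocabularies) are
refitted inside every training fold, so held-out windows never contribute
counts; the test suite verifies this by comparing fold models against
fresh fits.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `l` | 25 | window length (odd); centre is the sequon N |
| `prob_threshold` | 0.5 | hit-probability floor for $S(P)$ membership |
| `k_min` | 5 | minimum set overlap for a template |
| `rare_threshold` | 0.01 | rare-pattern frequency floor |
| `C_grid`, `gamma_grid` | $2^{-5..15}$, $2^{-15..3}$ | SVM grid (110 cells) |
| `threshold_grid` | 0.25–0.75 | candidate decision thresholds |
| stage-1 bounds | 0.4 / 0.8 | below: ×0.8; above: ×1.1 (capped) |
| `final_threshold` | 0.6 | glycosite call cutoff (strict >) |
| `pseudocount` | 0 | optional GDR smoothing |

The adjustment is multiplicative because "reduced by 20%" most naturally
reads as a relative change of the score; an additive variant
(`additive = TRUE`, −0.2/+0.1 clamped to $[0,1]$) is provided since the
distinction cannot be settled from score semantics alone.

## What the synthetic generators emulate

The generators exist so the entire pipeline — file formats included — can
be exercised and calibrated without any external predictor or database.
One master seed fans out into one fixed stream per generator op, so adding
an op never shifts another op's draws.

* `generate_proteins()` plants N-X-S/T sequons at well-separated interior
  positions of i.i.d.-uniform sequences (40 + 40 proteins of 150–400
  residues, 4 sequons each by default; 66% of a glycoprotein's sequons are
  glycosites, mirroring the roughly 2:1 ratio in curated sequon data).
  Ten informative gapped dipeptides (six enriched ×3, four depleted ×3 in
  glycosite windows — aromatic enrichment and proline/lysine depletion in
  spirit) are planted by resampling single flank positions.
* `generate_annotated_windows()` draws SA/SS classes per position, with a
  class-conditional shift (±0.3 by default) at the sequon-proximal
  positions 9–19 only: glycosites favour E and C, negatives B and H.
  Because the effect is concentrated next to the sequon, the $APD_w$ sweep
  should — and in tests does — prefer short pattern windows.
* `generate_homolog_universe()` splits a 200-id universe into two halves
  and lets each protein draw $0.5 + \text{boost}/2$ of its ~40 members
  from its own label's half (boost 0.6 by default), yielding the squared
  overlap structure stage 1 exploits.

What they do *not* emulate: real amino-acid composition, homologous
sequence families, position-specific motif structure beyond single planted
dipeptides, correlated SA/SS tracks, or realistic profile-HMM probability
distributions. Passing the recovery tests therefore demonstrates that the
machinery extracts exactly the kinds of signal it models, at the planted
strengths — not that it attains any particular accuracy on real
proteomes. Conversely, the null-model tests (all effects switched off)
check that the pipeline does not manufacture signal from noise.

## Numerical choices and degenerate inputs

* Sequons whose X position is an ambiguity letter are skipped by default
  (flag to include); ambiguity letters elsewhere are kept in windows and
  treated like padding by the featurizers.
* MCC returns 0 when any denominator factor is zero; precision,
  sensitivity and specificity return `NA` on empty denominators.
* The ROC curve evaluates sensitivity and 1 − specificity at 1000 evenly
  spaced cutoffs in $[0,1]$ (positive when score ≥ cutoff), anchors the
  curve at (0, 0), and integrates by the trapezoidal rule; on continuous
  scores of a few hundred points this agrees with the exact rank-based
  AUC to well within 0.01.
* Grid-search ties resolve to the first cell in grid order; $w^\*$ ties to
  the smaller length; the probability/decision-value ranking is asserted
  monotone rather than assumed.
* An all-X window encodes as the all-0.5 GD vector plus the six bucket
  bits — the model's representation of "no usable evidence".

## Problem sizes used in the shipped studies

The packaged simulation studies (tests and the end-to-end certification)
train on 60 + 60 proteins (~640 sequons) and evaluate on 55 + 55 held-out
proteins (~550 sequons), with a 3 × 3 hyperparameter grid and 5 folds —
sizes chosen to make the planted-signal recovery (MCC ≥ 0.6 planted,
|MCC| ≤ 0.15 null) a stable, quick certification of the whole pipeline.
The full 110-cell grid and 10-fold protocol remain the defaults for real
training runs. An `l`-selection sweep is a loop over
`build_dataset(l = ...)` + `cv_glysite()`; its outcome depends on the
upstream SA/SS predictor and dataset, so no particular optimum is asserted
here.

## Known limitations

* Stage 1 consumes precomputed hit lists; running the profile-HMM search
  (and the SA/SS predictor) is out of scope by design — adapters define
  the contract instead. Hit-set properties such as pairwise similarity
  limits are taken on faith from the upstream tool.
* N-X-C sequons and non-human idiosyncrasies are out of scope.
* GDR statistics need both classes well populated; very small training
  sets leave many types undefined and the encoding drifts toward the
  uninformative 0.5 vector.
* The reference vocabulary sizes reported for curated human data
  (36/8/35 SA, 18/12/24 SS patterns; 156 features in total) depend on the
  specific upstream predictor outputs and are not bit-reproducible
  identities; the package asserts the structural invariants (block sizes,
  one-hot, conservation) instead.
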