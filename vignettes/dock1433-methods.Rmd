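---
title: "Ranking 14-3-3 docking phosphosites: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking 14-3-3 docking phosphosites: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dock1433)
```

## The problem

14-3-3 proteins are dimeric adaptors that bind phosphorylated Ser/Thr
residues on hundreds of client proteins. A typical client carries dozens of
phosphorylatable Ser/Thr residues, only one or two of which actually mediate
14-3-3 binding. Classical predictors score each candidate against the mode I
(`RXXpS/TXP`) and mode II (`RXF/YXpSXP`) consensus motifs, but many
experimentally validated docking sites match these motifs poorly, and
cutoff-based consensus output leaves many sites essentially tied.

dock1433 ranks, rather than classifies. For every Ser/Thr on a protein it
combines three kinds of evidence in a random-forest ranker and emits an
ordered candidate list per protein:

1. **Consensus-sequence scores** (`ann`, `svm`, `pssm`): per-site outputs of
   pretrained sequence models, ingested from TSV when available. When they
   are not, a built-in position-specific scoring matrix (PSSM) stands in.
2. **Intrinsic disorder** (`disorder`): the per-residue disorder score at
   the phosphosite, ingested from any external predictor (IUPred2A-style
   TSV) or computed by a built-in charge/hydropathy proxy. Docking sites
   concentrate in or near disordered regions.
3. **PTM observation frequency** (`ptm_score`): validated docking sites tend
   to be among the most frequently observed phosphorylations on their
   protein in unbiased mass-spectrometry archives.

## The PTM score

For a site $s$ on protein $P$ with $n_s$ independent MS observations,

$$\mathrm{PTM\,score}(s) \;=\; \frac{n_s}{\sum_{t \in P} n_t},$$

the site's observation count normalized by the total observation count of
all phosphorylations on the same protein. Normalizing per protein removes
protein-abundance and detectability effects, making scores comparable
between proteins. Over a protein's observed sites the scores sum to 1; a
site never observed by MS (or a protein with no observed phosphosites)
scores 0 and carries a `flag_missing_ptm` — such sites are kept in the
ranking rather than excluded, because dropping them would silently change
the candidate universe.

## The built-in sequence model

When no external sequence-model scores are supplied, candidate windows are
scored by a **fixed canonical consensus PSSM** (`canonical_pssm()`): a
log-odds matrix over window offsets $-5\ldots+4$ (0 excluded — the
phosphosite itself is always S/T and carries no information) encoding the
classical determinants, Arg at $-3$ (strong) and $-4$ (moderate) and Pro
at $+2$ (strong) for mode I, Phe/Tyr at $-2$ (moderate) for mode II, with
all other window positions neutral. This matrix plays the role of a
*pretrained* consensus predictor: because it is fixed in the package,
nothing about the dataset under study leaks into a site's own sequence
score — exactly as with externally ingested predictor output — and the
evaluation protocols can treat sequence scores as fixed inputs while only
the forest is retrained.

The corpus-fitting route also exists: `build_pssm()` /
`build_pssm_from_dataset()` estimate a matrix from a set of validated
docking-site windows,

$$\mathrm{cell}(o, a) = \log_2
  \frac{(c_{o,a} + \kappa\, b_a)/(N + \kappa)}{b_a},$$

with counts $c_{o,a}$, background frequencies $b_a$, pseudocount
$\kappa = 1$ (one background-distributed pseudo-observation) and $N$
positive windows. The default background for fitted matrices is the pooled
residue composition of the positive windows themselves (Laplace-smoothed):
docking sites sit in disordered, compositionally biased regions, and a
uniform background would let the matrix score that composition rather than
positional preferences. Even composition-corrected, though, a matrix fit
to a study's own positives remains partly a composition detector (letters
rare among the positives are penalized wherever they occur), which is why
the pipeline's default scorer is the fixed canonical matrix — see the
non-canonical discussion below.

A site's score is the sum of its window cells; positions beyond the
sequence ends, and unknown `X` residues, score 0 (background). For use as
a model feature the log-odds score is mapped through a logistic into
$[0,1]$ and replicated into all three sequence slots — the forest sees the
same information either way, and this keeps the tool free of any external
sequence-model dependency. The provenance flag `flag_builtin_seq` records
the substitution.

## The built-in disorder proxy

External per-residue disorder tables take precedence. Without one, the
package computes, for each residue over a clipped ±25-residue window, the
mean Kyte–Doolittle hydropathy rescaled to $[0,1]$ ($\langle H \rangle$) and
the absolute mean net charge ($|\langle q \rangle|$, K/R = +1, D/E = −1),
combines them with the FoldIndex closed form

$$\mathrm{fi} = 2.785\,\langle H \rangle - |\langle q \rangle| - 1.151,$$

and maps $\mathrm{disorder} = \mathrm{logistic}(-k\,\mathrm{fi})$ with
$k = 10$, so windows predicted unfolded ($\mathrm{fi} < 0$) score above 0.5.
This is a deliberately simple charge/hydropathy heuristic — it captures the
low-hydropathy/high-charge signature of disorder that the ranker needs, not
the pairwise energy estimation of modern predictors, which is out of scope.

## The ranker

Three probability forests (default 500 trees, `ranger` backend, Gini/
impurity importance) are trained on feature subsets of the same training
matrix:

| column   | features                              |
|----------|---------------------------------------|
| `total`  | ann, svm, pssm, disorder, ptm_score   |
| `ptmdis` | ptm_score, disorder                   |
| `seq`    | ann, svm, pssm                        |

plus a fourth, `adapted`, the plain arithmetic mean of the three sequence
scores turned into a rank list — the cutoff-style consensus baseline the
forest columns are compared against. Positives are the validated docking
sites; negatives are every other candidate S/T *on the same client
proteins*, not random proteome background, so the forest learns to separate
docking sites from their within-protein competitors — which is exactly the
ranking task. Class imbalance is handled by inverse-frequency class weights
(downsampling is available). Within each protein each column's scores are
ranked 1…n, deterministically: ties in the `total` and `ptmdis` columns
break toward the higher PTM score, then the lower residue position; ties
in the sequence-derived `seq` and `adapted` columns break by position
only. The asymmetry is deliberate — the sequence-only columns exist to
show what sequence evidence achieves on its own, and breaking their ties
by PTM score would covertly hand them the PTM channel whenever the
(discrete-valued) consensus scorer produces tied scores.

Every training run requires a seed, and (dataset, config, seed) fully
determines the fitted forests and all downstream predictions. Saved models
embed a format version, the config, and a digest of the observation table;
scoring features built from a different table triggers a warning.

## Evaluation protocols

* **Leave-one-protein-out**: each client protein is removed, the ranker
  retrained, and the rank of its true site(s) recorded in all four columns.
  A site is a top-$k$% hit when its rank is within
  $\lceil k \cdot n_{\mathrm{candidates}} \rceil$ — ceiling, so a rank-1
  site on a 5-candidate protein is a top-10% hit (the rounding rule was an
  open choice; ceiling is the permissive reading).
* **Repeated holdout**: 20% of client proteins held out, 200 repetitions by
  default. Splits are at the protein level, never the site level, so a
  protein's positive and negative sites can never straddle the split.
* **Non-canonical analysis**: validated sites whose adapted consensus score
  falls below a cutoff (0.5, or 0.8 for a laxer superset) are re-predicted
  de novo after removal from training, with an absolute top-15 hit
  criterion, stratified by the missing-PTM flag.
* **Enrichment**: Welch's unequal-variance t test compares features between
  docking and other sites, with the relative mean difference
  $|(\bar{x}_a - \bar{x}_\mathrm{ref})/\bar{x}_\mathrm{ref}| \times 100$.
  By default only the two continuous protein-level features (ptm_score,
  disorder) are tested: the built-in sequence scores are near-two-point
  distributed, and t-based p-values on such mixtures are badly
  anti-conservative (we observed shuffle-null p-values below $10^{-8}$), so
  they are opt-in and descriptive only.

Proteins with two validated sites are counted per site in the headline
rates; per-protein ("either site hits") rates are reported alongside in the
same table, since the protocol description is ambiguous on this point.

Two traps discovered while validating the protocols are worth recording.
First, a *data-fit* PSSM cannot serve as the sequence scorer inside the
retraining protocols: fit once on the full dataset, each held-out site's
own window inflates its consensus score (about +0.25 log-odds per window
position at $N \approx 100$), breaking the no-signal calibration; refit
per split, the matrix turns into a composition detector — fit to positives
that sit in disordered regions it penalizes letters rare among them, and
on motif-free docking sites it still ranked ~97% into the top 15 purely
from local composition. The fixed canonical matrix has neither pathology,
which is the deeper reason it is the default: pretrained consensus
predictors are fixed inputs, and so is their stand-in. Second, under the
ceiling threshold the *chance* top-10% hit probability is
$\lceil 0.1\,n\rceil/n$, about 0.13 for proteins with ~20 candidates — the
no-signal calibration check must compare against that exact chance level,
not against 0.10.

## The synthetic-data generator

The generator emulates the statistical structure the method assumes, so the
whole pipeline is testable offline:

* Sequences of 300–600 residues drawn from a uniform background over the 20
  amino acids (UniProt-like frequencies are configurable). At ~10% Ser/Thr
  this yields a few dozen candidates per protein, enough that the absolute
  top-15 criterion is non-trivial.
* 0, 1 or 2 docking sites per protein with probabilities 0/0.8/0.2 — every
  simulated client has at least one site, and dual-site clients exercise
  the per-site vs per-protein accounting.
* Motif emission at docking sites: Arg at −3 with probability 0.85, Pro at
  +2 with 0.7, Phe/Tyr at −2 with 0.3 — a strong but imperfect mode I
  signal with a mode II admixture.
* Disorder-favorable composition: within ±10 residues of a docking site,
  each residue is replaced with probability 0.8 by a draw from the
  disorder-promoting pool {E,K,S,P,Q,G,D}.
* Observation counts: docking sites are observed with probability 0.95 with
  counts 1 + NegBin(mean 19, size 1); decoy S/T are observed with
  probability 0.3 with counts 1 + NegBin(mean 2, size 1). This mirrors the
  strong upward count shift of real docking sites while keeping the two
  distributions overlapping — the PTM channel alone is informative but not
  separable.
* Signal switches (`motif_on`, `disorder_on`, `ptm_on`) disable individual
  channels; with a switch off the corresponding feature is exchangeable
  between docking and decoy sites, which underpins the chance-level
  calibration test. `simulate_noncanonical()` keeps PTM and disorder
  signals but suppresses motif emission for a configurable fraction of
  sites.

Each protein is generated from its own derived seed, so a protein's content
is independent of how many proteins follow it, and the same master seed
reproduces the dataset byte-for-byte.

What the generator does *not* emulate: real kinase motif grammars beyond
the mode I/II determinants, homology between proteins, composition biases
of real proteomes, isoform/coordinate drift, or MS acquisition physics.
Passing tests therefore demonstrate that the machinery recovers the signals
it assumes, at the planted effect sizes — not that those effect sizes match
any particular organism's proteome.

## Numerical and degenerate-input choices

* Missing PTM evidence scores 0 with a flag — never an exclusion.
* A protein whose only candidates are its positives trains with a warning.
* Zero-variance Welch comparisons return t = 0, p = 1 with a `degenerate`
  flag instead of NaN.
* All randomness flows from explicit integer seeds through derived
  per-task seeds (kept below $2^{31}$); forests run single-threaded, so
  results are bit-stable across runs.
* Window positions beyond sequence ends and `X` residues score as
  background (0 log-odds) rather than being imputed.

## Problem sizes used in the shipped checks

The package's own test suite and `scripts/acceptance.R` run the evaluation
protocols on simulated datasets of 30–100 proteins with forests of 100–200
trees, and the holdout protocol at up to 100 repetitions. These sizes were
chosen as the smallest at which the rank-hit rates stabilize (denominators
of roughly 100–250 evaluated sites); the package defaults (500 trees, 200
repetitions) remain what an analysis of real data should use.

## Known limitations

* The built-in sequence stand-in replicates one PSSM score into the three
  sequence slots; the `total` and `seq` ensembles then effectively see one
  sequence feature plus duplicates, which is flagged in output metadata but
  does mean importances split arbitrarily among the three duplicated slots.
* The disorder proxy is a window heuristic; for real analyses, supply
  external predictor output via `--disorder`.
* No probability calibration is attempted; forest probabilities are used
  only to order sites within a protein.
* No isoform mapping: input coordinates must match the supplied sequences,
  and a residue-letter mismatch is a hard error by design.
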