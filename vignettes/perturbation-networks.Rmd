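---
title: "Amino-acid perturbation networks: model, parameters and design choices"
author: "aaperturb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amino-acid perturbation networks: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaperturb)
```

## The model

A protein structure is reduced to a weighted contact graph. At
distance threshold $t$ (Å), the amino-acid network $G(t)$ has the
residues as nodes, and the weight of edge $(i, j)$ counts the atom
pairs $(a \in i, b \in j)$ with $\lVert a - b \rVert < t$. The
inequality is strict, and sequence-adjacent residues are treated like
any other pair: the graph models structural neighbourhoods, not
chemical bonds, which is why thresholds well beyond
chemical-interaction range (up to 10 Å) are useful.

A point mutation is represented by a second structure (an external
mutagenesis model, or a synthetic displacement; the package never runs
a mutagenesis engine). With $A$ and $B$ the wild-type and mutant
adjacency matrices over the union of their residue sets — residues are
matched by chain/number/insertion-code only, since the mutated residue
changes amino-acid type — the perturbation network $P(t)$ is defined by
$C = |A - B|$ after deleting all-zero rows and columns. Four measures
summarise it: nodes, edges, total weight and diameter (hop count).
Each captures a different aspect of the rearrangement: how many
residues are touched, how many contacts change, how many atom pairs
are gained/lost, and how far the change propagates.

Per protein and threshold, each measure is z-scored across all
non-synonymous mutations (synonymous entries are removed first so they
do not compress the scale). A mutation is *sensitive* for a measure
when its z-score strictly exceeds that measure's cutoff; a position is
a structurally sensitive position (SSP) when at least `minCount` of
the measures used have a sensitive mutation there. The SSPs are the
predictions for the functionally sensitive positions (FSPs): the
bottom `functionalPercent` (default 40%) of positions by mean
deep-mutational-scanning score, with $k = \lfloor n \cdot p / 100
\rfloor$ and ties broken by the lower position number.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `t` | 9 Å | contact threshold; the per-position structure–function correlation is flat and high for ~4–10 Å, and 9 Å balances precision and recall |
| `cutoffs` | (1.5, 1.5, 1.5) | per-measure sensitivity cutoffs in standard deviations above the mean |
| `minCount` | 2 | measures required for an SSP call; raising it trades recall for precision |
| `measures` | nodes, edges, weight | the diameter is computed and reported, but excluded from prediction: adding or removing a single edge can change the longest shortest path drastically, making it noisy under small threshold changes |
| `functionalPercent` | 40 | FSP percentile; percentile-based selection is used because DMS score distributions vary too much across experiments for a common SD-based cutoff |
| `atomPolicy` | heavy | which atoms enter pair counts; mutagenesis engines may emit hydrogens, which would change weights, so the choice is explicit and must match between wild type and mutants |

Grids: `thresholdGrid()` spans 3–10 Å in 0.1 Å steps (71 values);
`cutoffGrid()` spans 1–2 in 0.02 steps (51 values); the ROC sweep uses
100 evenly spaced cutoffs from 0.03 to 3 by default (the endpoints are
the conventional sweep range; the density only needs to make the
trapezoid AUC stable).

## Numerical and convention choices

- **Strict inequalities.** Atom pairs count when $d < t$; a mutation is
  sensitive when $z > c$. Boundary cases are excluded in both, fixing
  reproducible behaviour.
- **Population standard deviation.** z-scores use the $N$ denominator
  ("standard deviations from the mean of the distribution"); at DMS
  scale the difference from $N-1$ is negligible but the convention must
  be fixed for exact tests.
- **Diameter of a disconnected perturbation network.** Defined as the
  diameter of the largest connected component (most nodes; first found
  on ties); this is always finite and reduces to the usual diameter in
  the connected case. An empty network reports all four measures as 0.
- **Degenerate score columns.** The column-level `zstandardize()`
  errors on zero spread. The table-level `standardizeScores()` instead
  maps a degenerate (threshold, measure) group — e.g. the diameter at a
  threshold where nothing is perturbed — to `NA` z-scores with a
  warning, so a 71-threshold sweep is not aborted by one column.
  Positions without any usable z-score at a threshold are excluded from
  the SSP/SRP universe and from evaluation denominators.
- **Chain averaging order.** Multi-chain scores are averaged over
  chains first, then synonymous entries are removed, then the array is
  standardized — one score per mutation is the unit of
  standardization. A mutation modelled in only some chains averages
  over the chains where it is available; missing mutations stay
  missing, never 0.
- **Sign consensus.** Per position, the percentage of non-zero-sign
  scores sharing the majority sign; zeros count toward neither sign.
- **Null scores and improvement.** Under random prediction,
  precision converges to the functional percentage and recall to the
  prediction percentage; the improvement factor
  $tp \cdot n / (|FSP| \cdot |SSP|)$ equals both ratios exactly, which
  the tests verify to $10^{-12}$.
- **Undefined values.** Precision (and improvement) are `NA`, not 0,
  when nothing is predicted. Spearman p-values are two-sided, exact
  for small $n$ without ties, asymptotic otherwise, with average ranks
  for ties.

## Structure input conventions

PDB reading keeps the 20 standard amino acids only (waters, ligands
and other hetero records never enter the networks), uses model 1 of
multi-model files, and keeps the first-listed conformer of alternate
locations. No repair, protonation or missing-residue modelling is
attempted. Insertion codes are part of the residue identity throughout.

## What the synthetic generator emulates — and what it does not

`generateStructure()` places residue centers on a self-avoiding random
walk with a fixed 3.8 Å step (the C$\alpha$–C$\alpha$ distance), with
`atomsPerResidue` atoms jittered (sd 1 Å) around each center.
`generateMutant()` displaces the atoms of one residue by Gaussian
vectors whose per-mutant scale is `mutationDisplacement` times a
lognormal severity factor (sdlog 0.5): mutants at the same position
differ in severity, as substitutions to different amino acids do, while
the *expected* severity is a property of the position — emulating the
empirical finding that structural and functional change are position-
dependent and largely independent of the mutant amino acid.
`generateFunctionalTable()` writes mean-effect-per-position plus
Gaussian noise, with synonymous cells at 0.

The generator reproduces the *logic* of the data, not its physics: no
secondary structure, no side-chain packing, no force field, no
energetics. Passing tests therefore demonstrate that the machinery —
network construction, differencing, standardization, classification,
evaluation — is correct and recovers planted position-dependent
signal; they do not certify prediction accuracy on real proteins,
which depends on the quality of the external mutagenesis models.

The end-to-end recovery setting used in the tests: 30 residues, 4
atoms each, the designated 40% of positions displacing atoms by ~2 Å
per mutation and the rest by 0.02 Å (structurally silent at these
scales), one threshold (9 Å), 19 mutants per position (570 mutant
structures). This size keeps the full pipeline in seconds while giving
the z-score distributions enough mass in both groups; the designated
positions are recovered with perfect precision/recall and AUC 1 at the
default parameters. All generator randomness derives from a single
integer seed (per-mutant seeds are derived arithmetically from it), so
every dataset is reproducible bit-for-bit.

## Known limitations

- Prediction quality on real proteins is bounded by the external
  mutagenesis models consumed; the package only quantifies the
  structural difference between the coordinate sets it is given.
- The diameter measure is reported for completeness but is noisy by
  construction; it is excluded from prediction by default.
- mmCIF input is not supported; convert to PDB first.
- No confidence bands or bootstrap over proteins; sweeps return tidy
  tables and plotting is left to the user.
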