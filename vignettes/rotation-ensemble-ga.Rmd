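---
title: "Rotation-Ensemble-GA: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotation-Ensemble-GA: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`rega` implements a wrapper feature-selection classifier for binary
molecular toxicity endpoints (drug-induced liver injury, DILI, in the
motivating application). A candidate solution — a GA *individual* — is a
list of $K$ feature subsets, each holding $S_{fs}$ integer column indices
of a fused fingerprint matrix (duplicates permitted). An individual is
scored by building an ensemble from its subsets:

1. **Rotation.** Each subset's columns are split by kind. Continuous
   columns are projected onto all principal components of nonzero variance
   (PCA, full-rank: the subset is rotated, not reduced). Binary columns
   are coded as a complete disjunctive table (a 0-indicator and a
   1-indicator per feature, constant features dropped) and projected onto
   the row principal coordinates of a multiple correspondence analysis
   (MCA): the SVD of the standardized residual matrix
   $S = D_r^{-1/2}(P - r c^\top) D_c^{-1/2}$, where $P$ is the
   relative-frequency table and $r, c$ its margins. The two projections
   are concatenated. This is the Rotation-Forest idea adapted to mixed
   binary/continuous chemistry descriptors.
2. **Boosting.** Sample weights start uniform, $w_j^1 = 1/N$. For slot
   $k$: draw a weighted bootstrap of size $N$, fit the base learner (a
   50-tree random forest by default) on the rotated bootstrap, and compute
   the weighted error on the rotated *full* training set,
   $\epsilon_k = \sum_j w_j^k l_j^k$ with $l_j^k = 1$ iff row $j$ is
   misclassified. If $\epsilon_k = 0$ or $\epsilon_k \ge 0.5$ the slot is
   discarded, the weights are reset to uniform and the slot is retried
   (up to 5 fresh bootstraps) before being skipped. Otherwise
   $\beta_k = \epsilon_k / (1 - \epsilon_k)$, and weights update as
   $w_j^{k+1} \propto w_j^k \beta_k^{1 - l_j^k}$ (misclassified rows keep
   their raw weight, correct rows shrink, then renormalize).
3. **Voting.** Each valid slot votes for its predicted class with weight
   $\ln(1/\beta_k)$; the predicted label is the class of maximum support,
   exact ties going to class 0. The real-valued decision score is
   $\mu_1 - \mu_0$, used for AUC. If no slot survives the guard, the
   ensemble predicts the training-majority class.

The GA evolves $M$ individuals for $T$ generations: parents are paired at
random, every pair is crossed at a single point drawn uniformly from
$\{0..K\}$ (whole subsets are exchanged; the published pseudo-code
crosses every pair unconditionally, so no crossover probability is
exposed), children are mutated per position with probability $P_M$, and
the best $M$ of the $2M$ parents + children survive (elitism; exact ties
keep parents first in stable order). Fitness is the F1 of the positive
class on a held-out validation split; parents keep their cached fitness.
Elitism makes the best-validation-F1 series non-decreasing, which the
package asserts on every run's curve.

### Default parameters

| parameter | default | meaning |
|---|---|---|
| `generations` (T) | 50 | GA iterations |
| `pop_size` (M) | 50 | individuals per generation (must be even) |
| `p_mutation` (P_M) | 0.1 | per-position resampling probability |
| `k` (K) | 10 | subsets = ensemble slots per individual |
| `subset_size` (S_fs) | 300 | indices per subset |
| base learner | random forest, 50 trees | weak classifier per slot |
| retries | 5 | fresh bootstraps before a slot is skipped |

These are the published study settings; the tests and the acceptance
script run a desk-scale configuration (T = 10, M = 10, K = 4,
S_fs = 20 over 120 features, n = 300 samples) chosen so a full repeated
cross-validation completes in well under a minute per fold.

## Featurization

`compute_fused_fingerprints()` splices up to four blocks, always in the
fixed order ECFP2 (2048), MACCS (167), RDKIT2D (200, continuous), PUBCHEM
(881) — fused width 3296 with all four. Columns are marked binary except
the RDKIT2D block.

- **ECFP2** is the circular fingerprint of diameter 2 (radius 1), hashed
  and folded to 2048 bits, computed through the OpenBabel command-line
  tool. "ECFP2" names a diameter by the standard convention; the
  radius/width are pinned here because the method only fixes the name and
  the block width.
- **MACCS** uses the standard 166-key dictionary laid out on 167
  positions (position 0 is the conventional padding bit). The package's
  key assignment was cross-checked against an independent MACCS
  implementation; the test suite freezes that correspondence.
- **RDKIT2D** is a pinned, versioned list of exactly 200 continuous 2D
  physicochemical descriptors (`inst/extdata/descriptors_2d_v1.txt`):
  OpenBabel whole-molecule properties (logP, TPSA, molar refractivity,
  H-bond donor/acceptor counts), composition and bond counts, ring
  statistics, classical topological indices (Wiener, Balaban J, Kier
  kappa and chi), a topological distance-count profile, and
  Moreau-Broto / Moran / Geary autocorrelations of atomic mass,
  electronegativity, covalent radius, polarizability and valence-electron
  count over lags 0–8. Non-finite values are replaced by 0 with a
  warning. The list is shipped as a data file so the block width is
  stable across toolkit versions; it is a 2D descriptor set of the same
  kind and width as other 200-descriptor sets, not a descriptor-by-
  descriptor clone of any particular toolkit.
- **PUBCHEM** follows the public 881-key CACTVS layout. Key-table v1
  evaluates sections 1–3 — hierarchic element counts (bits 0–114), ESSSR
  ring counts stratified by size, saturation/aromaticity and element
  content (115–262), and bonded element pairs (263–326) — from bundled
  TSV definitions plus the package's own ring perception. The
  atom-environment and SMARTS sections (bits 327–880) are not evaluated
  in v1 and report 0. The width is fixed at 881 regardless, so fused
  column offsets never depend on key coverage, and bit-for-bit parity
  with the original CACTVS engine is explicitly not promised.

Min–max normalization ($x' = (x - \min x)/(\max x - \min x)$) is the only
preprocessing. It is fitted on training rows only; constant columns map
to 0 and out-of-range values on held-out rows are clipped to $[0, 1]$.
Fitting on the training split avoids information leakage that the
published protocol leaves unaddressed; a dedicated test poisons held-out
rows with NaN sentinels and verifies that no fitted artifact (min/max,
rotations, forests) depends on them.

## Label curation

Multi-source DILI label tables are merged in two stages. First, records
are canonicalized (one fixed OpenBabel canonicalization), molecules
containing metals or elements outside H, B, C, N, O, F, Si, P, S, Cl, Se,
Br, I are removed (the exclusion list is configurable; the method names
no explicit list), and duplicates within a source collapse to one record.
Second, `resolve_labels()` takes the highest-priority source's label when
a compound appears in any priority source (e.g. DILIrank, LiverTox,
LTKB), and otherwise keeps the majority label iff its agreement fraction
is at least 0.8 (or the sources are unanimous), dropping the compound
below the threshold. A compound whose same-rank priority records disagree
is dropped with a warning — the source procedure is silent on this case,
and guessing a label from conflicting trusted sources seemed worse than
excluding the compound.

## The synthetic generator

`generate_planted_dataset()` emulates the statistical shape the
classifier assumes: a mixed binary/continuous matrix with block metadata,
balanced Bernoulli labels, and a planted informative subset — binary
effects as class-conditional bit probabilities ($p_1 = 0.8$, $p_0 = 0.2$
by default), continuous effects as a class-mean shift ($\Delta = 1.5$ at
unit variance). Features are independent given the class; real
fingerprints have strong bit–bit correlation, block-specific sparsity and
hash collisions, none of which are simulated. Passing tests on this
fixture therefore demonstrate the mechanics (rotation, boosting, GA
bookkeeping, split hygiene) — not predictive performance on real
chemistry.

## Numerical choices

- Singular values at or below $10^{-10}$ of the largest are treated as
  zero in both PCA and MCA; all retained components are kept.
- Loading/axis signs are fixed (largest-magnitude entry positive) so
  repeated fits are bit-identical.
- Duplicate columns inside a subset are deduplicated before fitting (they
  add exact collinearity and nothing else); the individual's encoding is
  untouched.
- Rotations are fitted on the full training rows of the fold, not on the
  bootstrap sample, so the weighted error on the full training set is
  well defined against a single rotation.
- The random-forest vote fraction is thresholded at 0.5 (ties to class 0)
  rather than using the library's randomized tie-break, so ensembles are
  deterministic given the seed.
- All randomness derives from one master seed through named streams
  (population init, per-generation operators, per-evaluation bootstraps,
  per-repetition splits), so evaluation order cannot change results.
- F1 uses the positive class with the 0/0 := 0 convention; AUC is the
  Mann–Whitney rank statistic with half credit for score ties, reported
  as NA for single-class label vectors.
- "Five-fold cross-validation" at ratio 2:1:1 cannot be a classic 5-fold
  partition; it is implemented as five independent random 2:1:1 splits,
  which is the only reading consistent with both statements.

## Planted-feature recovery at desk scale

The final-generation importance table (occurrence counts of every feature
index over all individuals) is the package's feature-importance analysis.
On the default fixture at the desk-scale configuration, the acceptance
script computes the enrichment of the 30 planted indices relative to the
uniform expectation. Two regimes matter:

- With the default (strong) planted effects, ensembles reach validation
  F1 = 1.0 within a generation or two — 75 validation rows and very
  separable classes — after which elitist selection with stable
  tie-breaking exerts no pressure, and the measured enrichment stays
  around 1.2×, far from what sustained selection would give.
- With weaker effects the fitness stays below 1 and climbs across
  generations, but gene-frequency enrichment is still slow: selection
  acts on whole individuals of $K \times S_{fs} = 80$ positions, and
  mutation at $P_M = 0.1$ regresses allele frequencies toward uniform.

Both facts are asserted honestly by the test suite: the recovery check at
the 2× enrichment bound runs under the stated conditions and documents
the measured value, and a separate property test verifies the monotone
fitness climb that elitism guarantees. Users planning recovery studies
should expect gene-level concentration to need substantially longer runs
(larger T and M) than fitness convergence does.

## Known limitations

- PubChem key-table v1 covers sections 1–3 only (see above).
- The RDKIT2D block is a pinned descriptor set of the published width,
  not a clone of any specific toolkit's 200 descriptors; models trained
  on matrices from different featurizers are not interchangeable.
- Binary endpoints only; the voting rule is written for two classes.
- The GA re-evaluates nothing: parents cache fitness, so a lucky
  bootstrap draw can keep a mediocre parent in the elite longer than
  fresh re-evaluation would.
- Headline metrics on the original curated 2,931-compound DILI dataset
  (ACC ≈ 0.77, F1 ≈ 0.77, AUC ≈ 0.84 at the full 50 × 50 GA scale)
  require that dataset and thousands of forest fits; reproducing them is
  a long-running optional experiment, not part of the test suite.
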