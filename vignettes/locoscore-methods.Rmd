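---
title: "Local-coordinate main-chain scoring: model, training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local-coordinate main-chain scoring: model, training and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locoscore)
```

## The model

`locoscore` implements a coarse-grained, knowledge-based potential for
discriminating native-like protein main-chain conformations from decoys.
The unit of information is a *directed residue pair*: an **observing**
residue and a **partner** residue. The observing residue anchors a local
Cartesian frame built entirely from its own main-chain atoms:

* the C&alpha; is the origin;
* the +y axis points through the N atom;
* the C atom fixes the xz plane: it lies at z = 0 with x > 0;
* the frame is right-handed (rotation determinant +1).

The partner is represented only by its C&alpha; position, expressed in the
observer's frame and discretised into a 1 &#8491; cubic bin. Because the
frame turns with the residue, the bin captures the *relative orientation*
of the pair, not just its distance — the feature that separates this family
of potentials from plain distance-based contact potentials. And because the
frame is constructed right-handed from chiral backbone geometry, mirror
images of a structure produce different bins: the score is
chirality-aware, while being exactly invariant under rigid motions.

Scoring is inverse-Boltzmann log-odds. For observer type $i$, partner type
$j$ and bin $xyz$,

$$S \;=\; \sum_{i=1}^{N_1}\sum_{j=1}^{N_2}
  -\ln\!\frac{j_{obs}(xyz)}{j_{exp}(xyz)}$$

where $j_{obs}(xyz)$ is the number of times an $i$-type residue observed a
$j$-type partner in that bin in the training corpus, and the reference
state $j_{exp}(xyz)$ is the *mean* count over all $20\times20 = 400$
ordered type pairs at that bin (zero-count pairs included in the mean).
$N_1$ runs over every residue of the chain; $N_2$ over the eligible
partners of each observer. Every unordered pair is counted and scored
twice — once from each perspective — so no halving is applied anywhere.
Lower totals are more native-like.

Cells never seen in training cannot enter the logarithm, and silence in a
large corpus is itself evidence of an unfavourable geometry. Such lookups
receive a **zero-count penalty**: `penalty_mult` times the worst (most
positive) observed score of that type pair.

## Tunable parameters

Three parameters control eligibility and the penalty, and they apply
*identically* during training and scoring (a single code path generates
the observations for both, so the two can never disagree):

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 14 &#8491; | maximum C&alpha;–C&alpha; distance for a partner |
| `exclude_neighbors` | 1 | chain neighbours per side never scored |
| `penalty_mult` | 3 | zero-count penalty, in units of the pair's worst observed score |

The defaults are the values selected by repeated tenfold cross-validation
over the canonical 84-version grid (cutoffs 8–20 &#8491; in 2 &#8491;
steps × 1–4 excluded neighbours × 1–3× penalty), which
`parameter_grid()` enumerates and `cross_validate()` re-runs on any corpus
and decoy collection. Sequence neighbours are excluded because the
peptide bond fixes their C&alpha; separation: they carry almost no
discriminative signal. The exclusion is *not* applied across a chain
break, where that fixed geometry is absent.

## Binning convention

Bins are 1 &#8491; cubes counted from the origin with signed, nonzero
labels: on each axis bin $+k$ covers $[k-1, k)$ and bin $-k$ covers
$[-k, -k+1)$; there is no bin 0. The published description of the method
fixes only that bin labels are signed and nonzero, not which half-open
orientation the boundaries take, so this convention is declared once,
named (`bin_convention()`), and written into every database header —
`read_db()` refuses a database whose convention does not match the
running build. Bins outside the cutoff sphere are never stored and never
requested, because eligibility is distance-gated before binning.

## Training and the penalty fallbacks

`accumulate_counts()` builds the sparse $(i, j, \text{bin})$ count table;
`reference_state()` divides per-bin totals by 400; `compile_potential()`
turns counts into scores and fills the 20×20 penalty table. The per-pair
penalty rule is undefined in two corner cases, which we resolve
conservatively so that a penalty is never favourable:

* a pair was observed but its worst score is ≤ 0 (common in small
  corpora, where no bin accumulates enough mass for a positive score):
  the penalty falls back to `penalty_mult` × the *global* worst positive
  score across all pairs;
* no positive score exists anywhere (pathologically small corpora): the
  fallback is `penalty_mult` × the largest score magnitude.

Databases serialize to a single JSON container with a header (format
version, bin convention, parameters, provenance, checksum) and
full-precision score records (`%.17g`, so the round trip is bit-exact).
A TSV export is provided for inspection.

## Evaluation suite

`set_metrics()` computes the thirteen per-set measures used to compare
main-chain scoring functions: five for native recognition (the native's
score rank; the RMSD of the best-scoring structure; the native's Z-score,
oriented so better-than-mean is positive and using the sample SD; the
Pearson correlation of score with RMSD; the fraction enrichment, with
top-10% counts of $k = \lceil 0.1N \rceil$) and eight for decoy
discrimination with the native excluded (the RMSD rank of the
best-scoring decoy and the best RMSD rank among the ten best-scoring
decoys; the best-scoring decoy's RMSD; the lowest-RMSD decoy's score
Z-score; correlation and enrichment; and the common-log probabilities of
the two rank measures). Rank ties take the minimum rank; with fewer than
ten decoys the ten-best measure uses all of them and is flagged. All
RMSDs are C&alpha; RMSDs after Kabsch optimal superposition (proper
rotations only — the community default for decoy work, since the method's
own literature does not pin the alignment down).

Functions are compared across a collection of decoy sets with a paired,
one-tailed Wilcoxon signed-rank test on a per-set measure (canonically
the best-scoring decoy's RMSD rank). Zero differences are handled by
Pratt's method, ties get average ranks, the tail is exact (a
dynamic-programming enumeration over sign assignments) up to 25 nonzero
pairs and a continuity-corrected normal approximation beyond. The paired
form is the default because competing functions score the same decoy
sets; an unpaired rank-sum mode sits behind `paired = FALSE`.

`cross_validate()` partitions decoy sets into folds whose sizes differ by
at most one, selects per fold the grid version minimising the mean
best-scoring-decoy RMSD over held-in sets, measures it on the held-out
fold, and repeats the whole procedure with fresh random partitions. The
winner is the version selected most often across repeats (ties broken by
held-out mean). All partitioning is deterministic given `seed`.

## The omega-angle baseline

As a deliberately crude comparator, `omega_set_scores()` implements a
discriminator that uses only peptide-bond planarity: for each structure,
take the sample standard deviation of the &omega; dihedrals within 15° of
planar trans (180°; angles are unwrapped around 180° first), then score
each structure by the absolute difference between its SD and the set
mean. Decoy generators leave characteristic &omega; signatures, so this
baseline can spot natives while being nearly useless at ranking decoys
among themselves. Two choices the published description leaves open:
the SD is the sample (n−1) form on unwrapped angles, and the default
ranking direction is descending (largest deviation first) — exposed as an
explicit choice for the caller, since either direction is consistent with
the published summary tables. A structure with fewer than two qualifying
angles has no defined SD; it is flagged missing and excluded from the set
mean (the contract nominally requires only one qualifying angle, but a
sample SD of a single value is undefined).

## Synthetic data: what it does and does not establish

The package is self-contained: `build_backbone()` places N/C&alpha;/C
atoms from per-residue (&phi;, &psi;, &omega;) by internal-coordinate
(NeRF) chaining with fixed ideal bond lengths (N–C&alpha; 1.458 &#8491;,
C&alpha;–C 1.525 &#8491;, C–N 1.329 &#8491;) and angles (111.2°, 116.2°,
121.7°); recomputing dihedrals from the coordinates recovers the
specification to below 10⁻⁶ degrees. `make_training_corpus()` chains
helix/strand/coil segments (basin means −57/−47, −120/130, and a
three-component Ramachandran-like coil mixture; 5° Gaussian jitter on
basin angles by default), and `make_decoys()` perturbs a native's &phi;/&psi;
with Gaussian noise of chosen SD — the simplest perturbation with a
tunable RMSD dial; mean decoy RMSD increases monotonically with the
noise SD.

These generators emulate the *geometry* of real chains, not their
physics: there is no packing, no sterics, no side chains, and decoy
error is homogeneous along the chain rather than concentrated in loops.
A green test therefore establishes that counting, binning, compilation,
scoring and the metrics are mutually consistent and that the potential
discriminates idealised natives from dihedral-noise decoys at desk
scale. It does not reproduce published benchmark numbers, which require
the curated training corpus (thousands of non-redundant domains) and the
external decoy archives; with those inputs on disk, the same
`train`/`evaluate` commands run the full procedure unchanged.

## Numerical choices and degenerate inputs

* Observers whose N/C&alpha;/C are within 10⁻⁶ of collinear cannot
  define a frame; they are skipped *as observers* but remain eligible
  partners (a partner needs only its C&alpha;).
* Residues missing any main-chain atom are dropped at parse time with a
  warning, and a chain break is recorded between their neighbours;
  breaks are also inferred from gaps in author residue numbering.
* Alternate locations resolve to the highest occupancy, then first
  listed; modified residues map to their parent type via MODRES records
  plus a built-in table; unmappable residues are dropped, not guessed.
* Chains shorter than two residues score 0 with a warning.
* Rank ties use the minimum rank everywhere, making every rank-based
  measure deterministic.
* Z-scores use the sample (n−1) SD; zero-variance score vectors flag the
  Z and correlation measures as missing rather than inventing a value.
* Dihedrals are reported in (−180°, 180°], with the −180° boundary folded
  onto +180°.

## Limitations

Single chains only (the first chain of a file, or one selected by ID);
no mmCIF; no side-chain atoms beyond a tolerated C&beta;; no
secondary-structure-specific potentials; no docking adaptation. The
synthetic generator's idealised geometry means desk-scale scores are not
comparable in magnitude to scores from experimentally derived corpora.
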