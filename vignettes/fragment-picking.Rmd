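---
title: "Fragment picking from structural alphabet profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment picking from structural alphabet profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sapick)
```

This vignette explains the model behind `sapick`, the choices that were
genuinely open when it was built, and what the synthetic test bed does
and does not demonstrate.

## The structural alphabet model

A protein backbone is reduced to its Cα trace and read as overlapping
4-residue windows (an *N*-residue chain has *N*−3 of them). Each window
is summarised by four rigid-motion-invariant descriptors: the three
"skipping" distances d13, d14, d24 (Å) and the signed volume of the
Cα tetrahedron (Å³). The sign of the volume comes from the scalar
triple product, so mirror-image conformations are distinguished — an
alphabet blind to chirality would conflate left- and right-handed
turns. The exact descriptor set of historical 27-letter alphabets is
not fully standardized; this 4-vector is the natural minimal choice
for 4-residue windows and the extractor is a single function
(`fragment_descriptors()`) that can be swapped.

A hidden Markov model with one state per letter (default 27),
multivariate Gaussian emissions over the descriptors and a dense
transition matrix ties consecutive windows together. Three standard
computations on it:

* `encode_viterbi()` — the jointly most probable letter string;
* `posterior_profile()` — per-window posterior letter probabilities by
  forward–backward, the *SA profile*;
* `fit_baum_welch()` — EM fitting of all parameters, initialised by
  seeded k-means, covariances ridged by 1e-6 Å² so near-degenerate
  clusters stay positive-definite.

All recursions run scaled (forward–backward) or in natural-log space
(Viterbi), with a per-row offset on emission log-densities, so chains
of 10⁴ windows do not underflow. Chain breaks (consecutive Cα–Cα
distance outside [2.0, 4.5] Å) restart the Markov chain; windows
spanning a break are never encoded and never matched.

The package ships a **toy 27-letter model** fitted by
`fit_baum_welch()` on 40 synthetic chains (regenerated by
`tools/make_fixtures.R`). It is a *stand-in*: published 27-letter
parameter sets were fitted on real structure collections whose
parameter values are not available here, so nothing about the toy
model's letters should be read as a statement about real local
conformational space. Users with a real alphabet load it from JSON
(`read_sa_model()`).

An important, easily-missed property of posterior profiles: they are
functions of the *whole* chain, not of the window alone. Two copies of
the same 9-mer embedded in different contexts have almost — but not
exactly — identical profile columns (differences decay quickly away
from the flanks, typically to ~1e-2 bits at the first column and
vanishing further in). Exactly identical profiles arise only for
identical chains, which is why the planted-recall tests that require
MJS = 0 plant whole proteins.

## Profile comparison

Profile columns are compared with the Jensen–Shannon divergence in log
base 2, so a column score lives in [0, 1]; two fragments are scored by
the *maximum* over their paired columns (MJS). The maximum, not the
mean: a single locally incompatible conformation should disqualify a
match, because one wrong local geometry breaks a fragment's usefulness
for assembly. A consequence worth knowing is that MJS is monotone in
window length — extending a window can only raise the score — which is
what makes the per-size acceptance thresholds necessarily
size-dependent.

The JS form (not its square root) is used, and the divergence rather
than a letter-equivalence-aware distance: probability mass on two
*different but geometrically similar* letters counts as divergence.
This makes the score conservative (sensitivity is sacrificed, matches
that are found are reliable), and is the main known limitation of the
score.

Numerics: JS is evaluated through the entropy identity
H(M) − (H(P)+H(Q))/2 with a `pmax(·, .Machine$double.xmin)` guard.
Posterior rows routinely contain denormal numbers (1e-300 and below),
and the textbook Σ p log(p/m) form then produces spurious `Inf` from
denormal division — this was observed in practice, not hypothesized.
`kl_divergence()` keeps the textbook convention (0·log(0/q) = 0;
+∞ when P has mass where Q has none) because callers only ever pass a
mixture as Q.

## The search protocol

For every fragment size *n* in 6–27 and every admissible query
position, every same-length bank window is scored (ungapped — an
insertion or deletion changes local conformation too drastically for
gapped SA alignment to be meaningful). Then:

1. hits = windows with MJS ≤ threshold(*n*), capped at the `top_n` =
   500 lowest scores (ties broken by bank id, then start, for full
   determinism);
2. incremental clustering in MJS order: a hit joins the first cluster
   whose representative superposes within the per-size cRMSD cut-off,
   else founds a cluster — so representatives are by construction the
   lowest-MJS member, and weights sum to the hit count;
3. only the heaviest cluster survives per cell (ties: lowest
   representative MJS, then span order).

The per-size clustering cut-off defaults to 0.5 + 0.04(*n* − 6) Å
capped at 1.5 Å: tight enough at small sizes to separate conformations
that differ by a single flipped turn, loosening with length because
random same-fold fragments drift apart roughly linearly in cRMSD over
this size range. It is a `search_config()` field, not a constant.

Internally the scan is a sliding maximum over the diagonals of the
column-pair JS matrix, computed once per (query, bank entry) pair and
reused across all sizes and positions; the per-column JS values are
never recomputed per window.

## Calibration

Two data-driven maps turn raw scores into decisions:

* **Per-size MJS thresholds** (`calibrate_mjs_thresholds()`): the
  largest threshold *t* on a 0.001 grid such that the precision of
  scored pairs with MJS ≤ *t* stays ≥ 0.95. Sizes with too few
  labeled pairs inherit by linear interpolation between neighbouring
  sizes (constant extension at the ends). Under the synthetic study
  conditions no pair scores below the cap for sizes ≥ 16 — the maximum
  over ≥ 13 columns of independently noised profiles is almost surely
  large — so those sizes use the extension. This is a property of the
  noise regime, not of the method.
* **Expected-precision grid** (`calibrate_precision_grid()`): clusters
  from calibration queries are binned by representative MJS (step
  0.001) and weight (step 1); a cell (x, y) holds the cumulative
  precision over clusters with MJS ≤ x and W ≥ y, defined only where
  at least `min_support` = 10 clusters accumulate. The *served* value
  (`expected_precision()`) is the isotonic envelope of the raw
  cumulative precision — running minimum along MJS, then running
  maximum along W. The envelope exists because raw cumulative
  precision is not mathematically monotone (a TP-rich batch at higher
  MJS can raise it), while the quantity the filter needs — "how
  trustworthy is a cluster at least this good" — should be. Cumulative
  support *is* monotone, so the defined region is a staircase and both
  passes are well-defined; `tidy()` on the grid exposes raw and
  enveloped values side by side. Cells outside the defined region fall
  back to just below the lower filter threshold, i.e. unknown regions
  are treated as unreliable rather than optimistic.

The final filter keeps candidates with expected precision ≥ 0.99,
discards those < 0.82, and admits the mid-band greedily (by descending
expected precision, then ascending MJS, then longer size, then span
order) only where residues are still uncovered; nested same-protein
hits are dropped. The 0.99/0.82 pair is the `"strict"` preset of
`filter_config()`; a `"broad"` preset (0.995/0.65) trades precision
for coverage on larger, more redundant banks.

## Assessment

A hit is a true positive when its Kabsch cRMSD to the query fragment
is below max(μₙ − k·σₙ, 0.5 Å), with μₙ, σₙ the mean and SD of the
cRMSD of random same-size fragment pairs drawn from the bank
(`background_stats()`), k = 2 by default. The multiplier is a
first-class parameter because the literature is not unanimous on it;
the 0.5 Å floor keeps the rule from becoming vacuous on tight
backgrounds (e.g. a helix-dominated bank). `evaluate()` reports Cov,
TPCov and Prec in percent, with Prec = NA (not 0 or 100) on empty hit
sets. The Kabsch implementation rotates and measures residuals rather
than using the singular-value identity, which loses ~1e-7 Å to
cancellation; rigid motions therefore score 0 to 1e-9 Å, and the
determinant correction guarantees a chiral fragment keeps a strictly
positive cRMSD to its mirror image.

## The synthetic test bed

`make_motif()` generates idealized Cα geometry (helix: radius 2.3 Å,
rise 1.5 Å/residue, 100°/residue; strand: 3.46 Å-rise zig-zag;
hairpin: two antiparallel strands 5 Å apart joined by a 4-residue
out-of-plane arc; coil: smooth 3.8 Å-step random walk) plus isotropic
Gaussian coordinate noise. `build_bank()` chains motifs into proteins
and encodes them; `pseudo_predict()` emulates a sequence-based
predictor by redrawing every profile row from a Dirichlet centred on
it (parameter = concentration × row + 0.01). `plant_fragment()` splices
a fragment into a bank entry rigidly, re-anchoring the junctions so no
chain break is introduced, and re-encodes the entry.

Study conditions, chosen once: coordinate noise 0.15 Å (realistic
thermal/packing jitter for Cα positions); concentration 50 (gives the
qualitative smearing of predicted vs. decoded profiles: argmax letters
mostly preserved, substantial mass spread); calibration bank of 12
proteins of 40–70 residues; 8 calibration queries for the grid; 3
held-out test queries of 45–55 residues; 300 background pairs per
size; 50 seeds for the planted-recall experiment. These sizes keep the
full calibration-plus-evaluation cycle at a few minutes on one CPU.

What the passing tests show: the scoring machinery agrees with
independent brute-force oracles; the protocol's contracts (partition,
representative, selection, filtering order) hold on randomized inputs;
under the stated noise regime the pipeline recovers planted fragments,
its calibrated thresholds deliver their promised raw-hit precision,
and the filtering cascade (clusters → best cluster → redundancy
elimination) concentrates accuracy while keeping most of the
coverage.

What they do not show: anything about real predicted profiles (an SVM
trained on sequence profiles has error structure a Dirichlet does not
capture — errors correlate along the chain and with secondary
structure); anything about real conformational diversity (four
idealized motif families versus the continuum of loops); and no claim
that the toy alphabet's letters resemble a published one. One
behaviour deserves an explicit caveat: the *unweighted* mean cRMSD of
cluster representatives is typically worse than that of the raw hits,
because raw hits contain many near-duplicates of the correct
conformation and deduplication removes that multiplicity. The
protocol's value shows from the clustering stage onward — each
subsequent filter lowers mean cRMSD and raises precision — and in the
final candidate count being two orders of magnitude below the raw hit
count.

## Known limitations

* Letter equivalences are ignored by the score (deliberately, see
  above); sensitivity is underestimated for conformations that
  straddle similar letters.
* Posterior context effects mean profile identity — hence MJS = 0 —
  is only achieved for identical chains; recall experiments must plant
  context along with the fragment or accept small non-zero scores.
* The expected-precision grid is only as good as its calibration
  support; with small calibration sets most large-size cells are
  undefined and their candidates are (conservatively) discarded.
* The brute-force scan is O(query × bank × sizes); memoizing the
  column-pair JS matrix makes desk-scale work instant, but mining a
  real PDB-scale bank would need the same pruning any production
  picker employs.
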