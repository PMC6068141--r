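---
title: "pH-constrained metabolic modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pH-constrained metabolic modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phifba)
```

## The model in one paragraph

Enzymes have bell-shaped pH-activity curves, and cancer cells keep their
cytosol alkaline while normal cells sit near neutrality.  `phifba` makes
that interplay computable: each enzyme's curve is reduced to six critical
pH points — the pH at 0%, 50% and 100% of maximal activity on the acidic
(A) and basic (B) flanks — and linearly interpolated between them.  At a
given intracellular pH (pHi) every gene receives a fractional activity
$W_G \in [0,1]$; gene-protein-reaction (GPR) boolean rules combine these
into a per-reaction weight $W_R$ (AND $\to$ min across complex subunits,
OR $\to$ max across isozymes); and each reaction's flux bounds in a
constraint-based metabolic model are scaled by $W_R$.  Flux balance
analysis (FBA) under steady state ($S\,v = 0$, $LB \le v \le UB$) then
gives the maximal biomass flux — the proliferation proxy — and flux
variability analysis (FVA) under a biomass floor gives exchange-rate
readouts, including the anti-Warburg ratio OCR/ECAR (oxygen consumption
over lactate secretion).  An in-silico knockout screen compares
normalized post-knockout biomass $nB = B_{KO}/B_{WT}$ across a panel of
cancer and normal cell models at low (6.7) and physiological (7.3) pHi,
scoring each target for selectivity ($SEL = nB^{normal} - nB^{cancer}$
at low pHi) and pH-specificity ($PHS = nB_{7.3} - nB_{6.7}$ in cancer
cells).

## Profile curation and imputation

Activity records (enzyme, pH, % of maximal activity, optimum/range kind)
are binned to the three levels before curation: up to 25% counts as a 0%
point, (25, 75] as 50%, and above 75% as 100%.  The boundary convention
is closed on the left level — exactly 25% is a 0% point and exactly 75%
a 50% point — chosen because "up to 25%" reads inclusively; any
deterministic convention would do, but it must be fixed once.

When several records report the same critical point, their median pH is
used.  The 100%-level records form the optimum plateau: they are split
into an acidic and a basic side at the midpoint of their span and the
per-side *median* gives A100 and B100.  Medians, not the min/max
extremes, because the generator-roundtrip requirement (below) rules out
order statistics: the minimum of $n$ noisy replicates of the same true
point is biased low by roughly two standard deviations.  A single
optimum record yields the degenerate plateau A100 = B100.  0%/50%
records are assigned to a flank by their position relative to the
plateau midpoint; when an enzyme has no 100% record at all, the median
of its record pHs serves as the split point.  Profiles whose assembled
points violate the ordering A0 ≤ A50 ≤ A100 ≤ B100 ≤ B50 ≤ B0 are
flagged and excluded, never silently re-sorted — a disordered profile
means contradictory records, and the conservative downstream treatment
of an unknown enzyme (constant 100% activity) is safer than a fabricated
curve.

Missing points are imputed in two stages, homologs first: each absent
point takes the median of that point over the $k = 5$ closest hits (by
rank in a precomputed homology table) that carry it; $k$ is
configurable since no canonical value exists.  Remaining gaps are filled
by per-point ordinary-least-squares regressors trained on complete
profiles, refit at prediction time on exactly the predictor subset the
partial profile offers.  The regressor interface is deliberately
pluggable — the feature set is the part of such pipelines that most
benefits from domain-specific curation, and OLS on the other five points
is the transparent default.  `cross_validate()` scores the predictors
under three protocols of increasing stringency: plain k-fold, all
profiles of a taxon held out together, and all profiles of an EC class
held out together, reporting per-point Pearson r and RMSE.

## Constraint injection

Gene weights are $W_G = \mathrm{activity}(pHi)/100$ for profiled genes
and 1 (full activity) for unprofiled ones — absence of evidence must not
shut a reaction down.  Bound scaling is direction-aware: bidirectional
reactions scale both bounds ($LB = W_R v_{min}$, $UB = W_R v_{max}$);
forward-only reactions scale only the upper bound, guarded so that
$UB \ge v_{min}$, and mirror-image for reverse-only reactions.  The
guards guarantee $LB \le UB$ for every weight, so a constrained model is
always well-formed (possibly infeasible, which is reported as zero
biomass rather than an error — acidic extremes legitimately kill a
model).

Organelles are assumed well buffered, so constraints apply to cytosolic
enzymes only by default.  A gene counts as cytosolic when any reaction
it catalyzes touches a cytosolic metabolite — a deliberate superset that
includes membrane transporters in and out of the cytosol; the flag
column of the constrained state makes the gating auditable, and
`cytosol_only = FALSE` constrains everything for buffering-sensitivity
analyses.  One asymmetry is intentional: an explicit gene-weight
*override* (a knockout) applies in every compartment, because a
knockout perturbs the gene itself, not the buffering of its
surroundings — otherwise mitochondrial genes could never be screened.

## Simulation choices

The LP core is a dense two-phase primal simplex with Bland's
anti-cycling rule, written for this package: deterministic
smallest-index pivoting makes every readout byte-reproducible, and the
dense tableau is entirely adequate at the tens-of-reactions scale the
package targets.  Internal tolerance is 1e-9; any reported flux below
|1e-7| is clamped to exactly zero, and scores are compared against the
same threshold, so "zero selectivity" means zero, not 1e-12.  Model
readers cap infinite bounds at ±1000 (the usual convention), so the LP
is never unbounded.  An exhaustive vertex-enumeration oracle in the test
suite — sharing no code with the simplex — verifies every fixture
optimum to 1e-6.

FVA readouts fix biomass at ≥ 80% of its maximum (robust over 70–90%,
which the tests probe) and report, per exchange role, the extreme flux:
the minimum (most negative, i.e. maximal uptake) for oxygen and glucose,
the maximum for lactate and ROS, signs following the uptake-negative
convention.  "Total ATP" and "total NADPH" are production flux-sums
($\sum_j \max(0, S_{ij} v_j)$ over matching metabolite rows) evaluated
at the deterministic biomass-re-maximizing solution under the floor;
a flux-sum is the standard proxy for a metabolite's turnover when no
single reaction represents it.  Whether exchange rates should be FVA
extrema or one FBA solution's values is a genuine fork; extrema were
chosen (FVA is the stated machinery) and the biomass-floor fraction and
readout conventions are arguments, not constants.

The anti-Warburg ratio is |oxygen uptake| / lactate secretion.  A fully
oxidative state (no lactate) returns `Inf` with meaning — "no
acidification at all" — and two zero rates return `NaN`, since a
non-growing silent model has no ratio.

## The knockout screen

A knockout sets the target's $W_G$ to a residual in [0, 0.1] (0 by
default) or, at reaction level, forces the bounds to (0, 0).  Reaction
knockouts matter because isozymes mask gene knockouts: an OR rule
rescues each single-gene deletion, while the shared step's deletion is
felt — the toy fixture reproduces this masking.  Scores are averaged
over all cancer × normal pairs (SEL) and over cancer cells (PHS), with
mean rather than median aggregation so that a large effect in a minority
of pairs is not erased.  A recurrence filter (fraction of pairs with
score strictly above the zeroing threshold, minimum 12.5% — 12 of 96
pairs, 1 of 8 cells on a full-size panel) separates recurrent effects
from single-model quirks, and targets land in four quadrants:
selective and pH-specific, selective only, pH-specific only, neither.

The divide-and-conquer modulator search applies profiles to successively
bisected gene subsets, keeping halves that preserve at least θ = 0.8 of
the full-set phenotype difference (biomass gap between unconstrained and
constrained at low pHi by default).  Both θ and the bisection order
(model gene order) are package decisions — the search is "standard"
without canonical parameters.  Pure bisection can drag a bystander gene
along when a redundant pair straddles a split, so a greedy minimality
pass drops every gene whose removal keeps the effect; on fixtures small
enough for exhaustive subset enumeration the result matches the true
minimal set, which the tests verify.

Robustness runs in two modes.  *Perturb* adds Gaussian noise (sd σ, in
pH units) to every critical point, restoring the ordering by re-sorting
(each re-sort is counted) — rejection would bias Monte-Carlo runs toward
quiet profiles.  *Randomize* permutes the profile-to-gene assignment and
recomputes the cancer-minus-normal gap of the pH response; a real pH
architecture should collapse under wrong assignment, and the engineered
fixtures do (collapse ratio ≈ 0.14 at 100 permutations, seed 0).

## What the synthetic fixtures emulate — and what they cannot

`make_toy_model()` builds a lumped cell: glucose uptake (bound 10) →
glycolysis (2 pyruvate + 2 ATP per glucose) → either lactate export or a
mitochondrial pyruvate carrier (bound 5, the deliberate respiratory
bottleneck) feeding oxidative phosphorylation (15 ATP and 3 O2 per
pyruvate, capacity 6), plus a small NADPH-producing shunt (bound 2) and
a biomass reaction consuming 10 ATP + 1 pyruvate.  The numbers are round
on purpose: the unconstrained optimum is 9.5 (carrier saturated at 5),
fermentation alone gives 2.0 with 18 lactate secreted, and a glycolysis
knockout leaves 1.2 through the shunt — all checkable by hand and frozen
in the tests.  Internal capacities are finite and near the fluxes they
carry; artificial 1000-bounds would make partial inhibition a no-op
(10% of 1000 constrains nothing) and would let a randomized profile
assignment act only through complete shutdowns.

`make_profiles()` assigns class templates: glycolytic genes get
alkaline-shifted plateaus (optimum 7.3–7.9), the pyruvate carrier and
oxidative genes a narrow neutral plateau (7.0–7.4), and the
lactate-export machinery — which operates under acidosis — an
acid-shifted plateau (6.0–6.8).  Mixing acid- and alkaline-optimum
enzymes mirrors the spread of real pH optima across compartments and is
what makes the randomization control meaningful: with a one-sided pool,
any wrong assignment would still suppress acidic growth.  Normal-like
cells get flat 6.6–7.8 plateaus everywhere, so their biomass is
pH-insensitive across the physiological range.  Per-profile rigid
shifts (sd 0.03 pH units) individualize cells without ever breaking the
point ordering.

These fixtures reproduce, at toy scale, the qualitative phenotypes the
method is about: cancer-like biomass peaks at alkaline pHi (argmax ≥
7.3) and loses more than half its maximum at 6.7; the anti-Warburg
ratio is higher at 6.7 than at 7.4; the pyruvate carrier emerges as the
selective-and-pH-specific target; randomized assignment collapses the
cancer-normal gap.  Passing these tests says the machinery transmits
pH effects through GPR logic into flux space correctly.  It does *not*
say anything about real enzymes: the profiles are generated, not
fitted to measured data; the network has no redundancy beyond one
isozyme pair; and a genome-scale model's thousands of alternative
pathways buffer knockouts in ways a five-reaction energy core cannot.
One concrete granularity limit: target rankings here are stable under
partial inhibition only up to a residual weight of about 0.05, because
a 10% residual of the *single* respiratory bottleneck changes the toy's
energy budget appreciably, whereas in a genome-scale model any one
gene's residual flux is marginal — the tests therefore assert ranking
stability over {0, 0.02} and boundedness at 0.1.

## Numerical and degenerate-input conventions

* Interpolation at coincident critical points (a zero-length segment)
  takes the larger node activity, keeping `activity_at` well defined
  for step-like profiles.
* `normalized_biomass` with a non-growing wild type returns 1 when the
  knockout does not grow either (nothing changed) and `NA` otherwise.
* Zero-spanning degenerate bounds (min = max = 0) are untouched by
  scaling.
* Cross-validation shuffling, profile jitter, record noise,
  perturbation and permutation all take explicit seeds (default 0);
  repeated calls are bit-identical.
* Ties in the screen output are broken by target id after the
  PHS/SEL sort, so result files are byte-stable.

## Problem sizes

The test-suite and acceptance runs use the default toy (13–16
reactions, 8 genes), panels of 2 cancer-like + 3 normal-like cells,
sweeps of 21 pH points, 100 assignment permutations, 10 perturbation
seeds, 200 nesting draws, 500 random GPR trees, and a 50-enzyme
synthetic record database at 25 records per point — sizes chosen so the
whole suite completes in about a minute while every oracle comparison
stays exhaustive.
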