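---
title: "tierbn: models, synthetic world, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tierbn: models, synthetic world, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tierbn)
```

## The problem and the model

Local recurrence after neoadjuvant chemoradiation and total mesorectal
excision for locally advanced rectal cancer is rare (order 5–10% at two
years) but clinically grave. `tierbn` models the joint distribution of
categorical clinical variables and a binary recurrence outcome per time
point (2, 3, 5 years) as a discrete Bayesian network: a DAG `G` plus one
conditional probability table (CPT) per node, factorizing
`P(X) = prod_v P(X_v | pa_G(X_v))`. Risk prediction is the exact posterior
`P(outcome = True | all observed variables)`.

Two routes produce `G`:

1. **Expert elicitation.** Candidate cause–effect arcs pass through a staged
   protocol: two experts propose independently; only the direction-sensitive
   intersection survives; two reviewers vote, unanimity required; a final
   validator approves each remaining arc. Every stage is a set reduction, so
   the protocol is monotone by construction. Arcs must respect a *tier map*
   ordering variables by clinical availability (patient baseline →
   diagnostic staging → neoadjuvant treatment → surgery → pathology →
   follow-up): within-tier arcs are allowed in either direction, forward
   arcs may skip tiers, backward arcs are invalid. The final structure is
   checked for cycles.
2. **Score-based learning.** Hill climbing from the empty graph under the
   Bayesian Information Criterion, with the tier map's backward arcs as a
   blacklist. BIC here is log-likelihood *minus*
   `(log N / 2)(r - 1) q` per node (`r` node cardinality, `q` parent
   configuration count), so **higher is better** — note many references use
   the negated convention.

## Packaged fixtures are reconstructions

The source study publishes its tier assignment and its 19-arc expert
structure only as figures, which cannot be redistributed here. The packaged
`tier_map_synthetic.json` and `expert_arcs_synthetic.csv` are
reconstructions that satisfy every textual constraint: 19 arcs over 10
non-outcome variables; six parents of the outcome including CRM and
pathological T and N stage (the arcs the text reports as shared with the
learned structures); exclusion of exactly age, gender, adjuvant chemotherapy
and overall treatment time; staging precedes treatment precedes surgery
precedes pathology (so `clinical_t -> age` is forbidden while
`age -> clinical_t` and the within-tier `clinical_t -> clinical_n` are
acceptable). Individual non-outcome arcs beyond those constraints are the
package authors' clinically-plausible choices, not a transcription, and the
summary statistics — not the identity of every arc — are what the tests pin
down. `elicitation_votes_synthetic.csv` is a demonstration vote log whose
protocol run reproduces the packaged arc list.

"`t + n`" is read as *any* later tier, not only the adjacent one: direct
arcs from early variables to the final-tier outcome are integral to the
expert structure and would be impossible under an adjacent-only reading.

## The synthetic world

The real 14-trial cohort (6,754 patients, 1993–2014) is not deposited, so
all analyses run against `clinical_generator_spec()`, a declared ground
truth with:

* **Category marginals** equal to the published training-cohort counts
  renormalised over non-missing patients (e.g. cT3 = 4002/4852 = 0.825;
  CRM positive = 435/978 = 0.445).
* **Continuous-variable marginals** derived from the published mean (sd)
  under a normal assumption at the default cut points, e.g. age
  ~ N(61.4, 9.6) with cuts 50/65 gives (<50, 50–65, >65) =
  (0.118, 0.529, 0.354); dose ~ N(47.7, 3.6) cut at 45 Gy gives
  P(>45 Gy) = 0.773; treatment time ~ N(37, 6.6) cut 38 d; distance
  ~ N(6, 3.1) cut 5 cm; interval ~ N(0.9, 0.4) cut 1 wk.
* **Outcome prevalences** among outcome-complete patients: 385/4553 = 0.085
  (2 y), 487/3932 = 0.124 (3 y), 599/2635 = 0.227 (5 y).
* **Missingness fractions** per variable as published (CRM 0.819, interval
  0.367, clinical N 0.342, ..., outcomes 0.158/0.272/0.512), injected
  *missing completely at random* — the source never states a mechanism, and
  MCAR is the minimal assumption compatible with treating missingness as a
  category.
* **Dependencies** along the expert DAG plus arcs tying in the four
  excluded variables (dose → treatment time; pathology → adjuvant
  chemotherapy; age and gender as roots), so the expert structure is
  well-specified under the generator and structure/parameter recovery are
  meaningful acceptance surfaces. Each outcome node has the six expert
  parents.
* Fourteen trial labels with invented sizes summing to 6,754 (per-trial
  sizes are unpublished); labels carry no distributional information.

Child CPTs are built as log-linear tilts of the target marginal — ordinal
scores in [-1, 1] for parent and child levels, per-arc tilt strengths fixed
in the spec — then rescaled against the *exact* parent joint (computed by
the package's variable elimination) until the node marginal matches its
target; this iterative proportional scaling converges to machine precision
in a few dozen sweeps. Effect sizes were fixed when the spec was written.

What a green test does **not** establish: the generator has no inter-trial
heterogeneity, no informative missingness, no unmeasured confounding, and
its dependence strengths are choices, not estimates. The published headline
AUCs are therefore *not* reproduction targets, and validation metrics on
synthetic cohorts say nothing about clinical performance.

A second, smaller stated world, `recovery_generator_spec()` (ten nodes on
five tiers, two-to-three categories, at most three parents, hand-fixed CPTs
far from independence, one deliberately isolated node), backs the recovery
criteria: with ~1,000+ expected observations per parent configuration at
n = 50,000, maximum-likelihood refitting recovers CPT cells within 0.02,
and at n = 10,000 tier-constrained hill climbing recovers the CPDAG within
SHD 2 in at least 90% of seeds. The clinical network cannot serve here: its
outcome CPT has 1,080 parent configurations, many of which are unobserved
even at these sample sizes.

## Preprocessing decisions

* **Unknown as a category.** Predictor missingness becomes a first-class
  `Unknown` level, appended to *every* predictor (even fully observed ones)
  so training and validation vocabularies always align. Patients missing the
  analysed outcome are excluded; no imputation anywhere.
* **Split before SMOTE.** One 80–20 split, stratified per trial label
  (`round(0.2 n)` per stratum; strata under two rows go to training with a
  warning); rebalancing is applied to the training partition only, per time
  point, to avoid leaking synthetic copies into validation.
* **Nominal SMOTE.** The classical interpolation is undefined for nominal
  features; the package uses the standard nominal adaptation: Hamming
  nearest neighbours among minority rows, each synthetic feature the
  majority vote over {seed row, k = 5 neighbours}, ties resolved to the
  seed row's value. Synthetic rows are appended until the classes are
  equal; originals are never modified and no unseen label can appear. The
  source does not state its variant or k; both are configurable.
* **Cut points.** Age <50/50–65/>65 (left-closed bins), dose ≤45/>45 Gy,
  distance ≤5/>5 cm, treatment time ≤38/>38 d, interval ≤1/>1 wk — defaults
  standing in for unpublished "literature and expert" cuts; all overridable.
  CRM is positive iff the margin is ≤ 1 mm (boundary included).

## Inference and estimation choices

* **Exact inference.** Posteriors come from variable elimination (min-degree
  order, alphabetical ties), not sampling: networks here are ≤ ~17 nodes and
  exactness keeps tests sharp (the equivalence oracle is full-joint
  enumeration at 1e-9). For cohort scoring, when every non-outcome network
  variable is observed — the standard case after Unknown encoding — the
  posterior reduces to the outcome's Markov blanket and is computed
  vectorised; the two routes are property-tested against each other.
* **alpha = 1 (Laplace) for prediction fits, alpha = 0 inside BIC.**
  Smoothing prevents zero posteriors on sparse Unknown-heavy tables while
  the structure score stays the standard ML-based BIC. Parent
  configurations never observed get a uniform row with a logged warning.
* **Search determinism.** Hill climbing starts from the empty graph,
  accepts the single best move with gain > 1e-9, breaks ties by
  lexicographic (parent, child, move-type), and runs 5 restarts of 5 random
  valid moves by default (the source reports restarts without counts); all
  randomness flows from one integer seed through named derived streams, so
  reruns are byte-identical.
* **Equivalence-aware comparison.** Learned-versus-true comparisons use the
  CPDAG (Chickering's compelled-edge labelling), since BIC cannot orient
  reversible edges; expert-versus-learned diffs report the arc partition
  (shared / reversed / unique) and the DAG-level structural Hamming
  distance.

## Evaluation choices

* **AUC** is the Mann–Whitney statistic via mid-ranks (ties count half),
  tested against brute-force pair counting. Confidence intervals and the
  paired AUC-difference test use DeLong placements (a bootstrap interval is
  available behind a flag); identical prediction vectors give p = 1 exactly.
  The source states 95% CIs and a significance claim without naming a
  method; DeLong is the field standard.
* **Threshold 0.5** for accuracy/sensitivity/specificity: after SMOTE
  balancing the natural default, and configurable; the source does not print
  its threshold. Training metrics are computed on the original
  (pre-rebalancing) training rows by default, switchable.
* **Calibration** uses up to 10 equal-count bins (ties can merge bins; a
  constant predictor collapses to one), bootstrap percentile intervals over
  200 replicates, and a bias-corrected estimate `2·apparent −
  mean(bootstrap)` — i.e. apparent minus bootstrap optimism. No model
  refitting is involved: the network is fixed at prediction time, so this
  is a plain bootstrap bias correction, not a resampling-refit optimism
  estimate.

## Degenerate inputs and edge policies

Zero-probability evidence raises an error naming the inconsistent
assignment; contradictory data under a deterministic CPT yields -Inf
log-likelihood; a single-class outcome makes SMOTE and AUC refuse rather
than degrade; values outside categorization ranges land in the terminal
bins; cyclic or backward-in-time arc sets are rejected with the offending
cycle or arcs listed.

## Known limitations

Purely discrete networks (no continuous or hybrid nodes); complete-data
parameter estimation only (missingness must be encoded first — by design);
plain hill climbing (no tabu list, no constraint-based or exact learners,
BIC only); exact inference scales exponentially in treewidth and is
intended for the ≤ 20-node clinical regime; the synthetic world is a stated
stand-in, not a surrogate license to compare against published clinical
performance.
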