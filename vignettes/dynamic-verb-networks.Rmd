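---
title: "Dynamic bipartite networks of early Hebrew verb morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic bipartite networks of early Hebrew verb morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodyn)
```

## The model

Hebrew verbs are built non-linearly from two bound morphological
constructs: a consonantal **root** (usually tri-literal, e.g. *l-m-d*) and
an **inflected binyan pattern** — one of seven prosodic conjugation
templates (Qal, Nifal, Hifil, Hufal, Piel, Pual, Hitpael), each realized in
up to five temporal categories (past, present, future, imperative,
infinitive; Hufal and Pual lack the last two, leaving 31 defined
binyan-temporal templates), further inflected for person, number and gender
agreement. Crossing the temporal categories with their admissible agreement
bundles yields 25 inflectional categories for a full-paradigm binyan
(21 for Hufal/Pual).

`morphodyn` treats one speaker's verb lexicon at one recording session as a
**bipartite network**: roots and inflected patterns are the two node
classes, and each verb wordform actually produced in the session — a
root x inflected-pattern combination — is a link. A longitudinal corpus of
dyadic recordings (child speech CS, child-directed speech CDS) then yields
two network snapshots per session, and development and adaptation become
statements about how network measures move over time and across the dyad.

Three measures are computed per snapshot:

* **degree** of a node: its number of links. By default the adjacency is
  binary, so a pattern's degree is the number of distinct roots it combines
  with in that session. The package's worked example — a present feminine
  singular Qal pattern linked to four roots — has degree 4. A token-count
  weighted mode is available (`mode = "weighted"`), because degree is also
  sometimes glossed as token frequency; the binary reading reproduces the
  worked example and is the default.
* **eigenvector centrality**: the nonnegative leading eigenvector of the
  symmetrized adjacency, scaled to unit Euclidean norm. It is computed by
  power iteration on the shifted matrix $A + I$; the shift is needed because
  bipartite spectra are symmetric ($\pm\lambda$ pairs) so the unshifted
  iteration oscillates, while eigenvectors are unchanged. Tolerance
  `1e-10` on the residual $\max_i |(Ax)_i - \lambda x_i|$, at most 10,000
  iterations; non-convergence is an error, never a silent result. On a
  disconnected snapshot the vector concentrates on the component with the
  largest eigenvalue; when two components tie the limit is a mixture
  determined by the uniform start vector, which is why oracle tests compare
  against dense eigendecompositions on connected graphs only.
* **density** $d = m / (n(n-1)/2)$ with $m$ links and $n$ nodes. The
  unipartite denominator is used deliberately — it is the printed formula —
  even though the graph is bipartite; `denominator = "bipartite"` gives
  $m / (|roots| \cdot |patterns|)$. For bipartite graphs with $n \ge 3$,
  $m \le n^2/4 < n(n-1)/2$, so the default density stays in $(0, 1]$; for a
  single link ($n = 2$) it is exactly 1. Low density is read as growth
  potential: many construct pairs not yet linked.

Empty or sub-minimal snapshots propagate missing values, never zeros: an
empty stratum is an explicit empty network object so time series keep their
index.

**Activation timelines** record, per node, in which sessions it is active,
and summarize the activity *runs* and *gaps* inside its onset-offset span.
Many short runs per node mean punctuated, intermittent usage; a single long
run means continuous usage.

## The adaptation models

For each dyad, a lagged model frame pairs every measure with its value at
the preceding recording (`prior.*`). Node-level frames keep only nodes
active in **both** CS and CDS at that session; a node inactive at the prior
session has no links there, so its prior degree and centrality are imputed
as 0 before scaling (row-dropping is available via
`impute_prior = "drop"`). First-session rows are dropped (no prior exists).
All twelve measure columns are then z-scored per dyad frame, with the
means/sds stored for back-transformation; the child's age stays in days,
which matches the magnitude of published age coefficients (~0.01 per day).

Six models are fitted per dyad:

* four **linear mixed models** (REML, `lme4`) for node degree and
  centrality in CS and CDS, with fixed effects = age plus the eleven other
  current/prior measure columns, and a random intercept per node label.
  Inference is Wald: 95% CIs as estimate ± 1.96 SE, p-values from the
  normal approximation. Reported alongside: residual variance, random
  intercept variance, ICC = tau00/(tau00+sigma2), and marginal/conditional
  R² by variance partition (variance of the fixed-effect linear predictor
  over total, and fixed-plus-random over total). The optimizer is lme4's
  default; REML is the contract, the optimizer is an implementation detail.
  Singular or non-converged fits are flagged on the object.
* two **ordinary linear models** for network density, each with exactly
  four predictors: age, the other party's density at the same recording,
  and both parties' densities at the preceding recording. Node measures are
  deliberately excluded — density is a global property.

No multiple-testing correction is applied, matching the source design.
`effect_summary()` flattens any set of fits into a machine-readable ledger
(sign and significance per predictor per model), exportable as JSON with an
edge list from affecting to affected measure.

## What the synthetic dyad generator emulates

The original recordings are not distributable, so the package ships a
generator whose defaults state a corpus world calibrated to the published
girl-dyad anchors: 47 sessions between ages 664 and 810 days, roughly 650
CDS and 100 CS verb tokens per session (corpus totals divided by sessions),
a Qal share of 80% of verb tokens, Zipfian root frequencies over a
250-root parental inventory (about 470 parent lemmas after roots take 1-3
binyanim), and a child inventory growing from 25 roots by 3 per session in
frequency-rank order.

Mechanisms, all tunable `SimParams` fields:

* **Parental continuity**: a share (default 0.8) of the parent's tokens is
  re-drawn flat from the parent's own previous-session wordforms ("routine
  reuse"). A multiplicative self-persistence boost cannot reproduce
  continuous parental usage at these token volumes — the Zipf imbalance
  inside the reused set still drops a third of it every session — whereas
  the flat mixture covers the set.
* **Child punctuated usage**: a per-session normal jitter (sd 1.5) on the
  child's log-weights; the child's effective lexicon rotates with the
  activity at hand. The parent's jitter defaults to 0.
* **Directed adaptation couplings**, as multiplicative log-weight boosts:
  child-self persistence (1.0), child-from-parent current (0.8) and prior
  (0.5), parent-from-child current (0.5) and prior (0.3).
* **Same-session transmission**: children at this age imitate heavily, so a
  share (0.45) of child tokens is echoed from the parent's current-session
  token distribution (restricted to the child's inventory), and the child's
  session token volume has elasticity 1.2 to the parent's realized volume.
  These two channels are what make the parent-to-child density coupling
  detectable at the session level; wordform-level boosts alone do not
  survive aggregation into a density summary.
* **Expansion on a limited child network**: when the child's previous
  density dips below the moving average of its recent densities, the parent
  flattens its within-binyan distribution (more varied input). The moving
  reference means the parent reacts to local dips, not to the secular
  density decline that comes with inventory growth — without it the CDS
  density trend would contradict the flat parental trajectory the analysis
  expects. Flattening is within-binyan only, and the parent's final session
  distribution is rescaled so the realized binyan token mixture equals the
  stated one.
* **Session volumes** are negative binomial, dispersion size 2 for CDS
  (naturalistic sessions vary a lot) and 50 for CS conditional on the
  parent's volume. Session-to-session variability is unreported in the
  source; these are free parameters chosen once and stated here.
* Within-session simultaneity is resolved by a two-pass parent draw: a
  provisional CDS sample (base + lagged couplings) informs the child's
  "parent current" terms; the recorded CDS keeps that provisional draw
  except for a marginal fraction (0.3) reallocated in response to the
  realized child speech.

What the generator does **not** emulate: utterance- and discourse-level
structure, imitation as a dialogue act, morpho-phonological surface forms
(the template interpolation in the package is explicitly symbolic),
over-generalization errors, and speaker-level random variation beyond one
dyad. A green simulation test therefore establishes that the pipeline's
machinery detects the couplings it was given in a world with the stated
marginal statistics — not that the published coefficient values are
reproduced, which is impossible without the original corpus.

## Numerical choices and degenerate inputs

* Romanization is ASCII-safe: glottal stop as `?`, the pharyngeal fricative
  as `H`, so node labels survive CSV round-trips. Labels are categorical
  node identities; the symbolic template interpolation is never used for
  identity.
* Imperative person is encoded as unmarked (implicitly 2nd), following the
  category labels of the inflection table; gender syncretisms (1st person,
  plural imperative, non-1st plural future, 3rd plural past) are encoded
  as unmarked gender, literally per the 25-row category table (past 2nd
  plural *is* gender-marked).
* Eigenvector centrality on snapshots with no links is an error; degree on
  an empty network returns a zero-row table flagged undefined; density
  needs two nodes, else `NA`.
* Model frames refuse to scale constant columns (error naming the column)
  and require at least two sessions; density models require five.
* The centrality recurrence is read as the standard neighbor-sum
  eigenvector definition; the printed equation's subscripts are ambiguous
  as typeset, and the standard reading is the one every network toolkit
  implements (the test suite cross-checks against igraph).

## Known limitations

* One dyad per simulated corpus; speaker-level random effects are out of
  scope, as in the source design.
* The mixed models use Wald inference only; with few sessions the density
  models are small-n OLS and their p-values should be read accordingly.
* The regular test suite runs a scaled-down Wald-coverage study (30
  replicates on moderate frames) to stay within routine test budgets; the
  simulation-oracle acceptance checks run at the stated calibration scale
  (47 sessions, 50 replicates).

## A worked run

```{r example, eval = FALSE}
sim <- simulate_dyad(default_sim_params(), seed = 1)
series <- build_network_series(sim$tokens, "dyad1")
measures <- measure_table(series)
frames <- list(
  node = assemble_model_frame(measures, "node"),
  network = assemble_model_frame(measures, "network"))
fit <- fit_density_lm(frames$network, "density.cs")
tidy(fit)
plot_density_trajectory(measures)
```
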