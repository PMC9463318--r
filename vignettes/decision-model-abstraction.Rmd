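---
title: "Building and abstracting Bayesian-network decision models for OPSCC therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and abstracting Bayesian-network decision models for OPSCC therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opsccbn)
```

## The modelling problem

Choosing the primary treatment for oropharyngeal squamous cell carcinoma
(OPSCC) — surgery, neck dissection, definitive or concurrent radiotherapy,
systemic therapy, or palliation — requires weighing tumour extent (TNM 2017
staging, infiltration of critical structures), nodal disease and extranodal
extension, p16/HPV status, the patient's performance status (Karnofsky
index), comorbidity and organ function. `opsccbn` implements a hybrid
workflow for building such decision models: the *structure* of a discrete
Bayesian network (variables, states, directed edges) is specified by hand to
match clinical knowledge, while the *parameters* (conditional probability
tables, CPTs) are learned from patient records. The model is then simplified
in recorded, replayable abstraction steps until its complexity matches the
information actually present in the data, with tenfold cross-validated
accuracy and ROC/AUC as the evaluation surface at every stage.

A Bayesian network over categorical variables factorizes the joint
distribution as $P(x_1,\dots,x_n) = \prod_i P(x_i \mid \mathrm{pa}(x_i))$.
Each node with $s$ states and parent configuration space of size $r$ carries
$(s-1)\,r$ free parameters; $r$ grows exponentially with the number and
arity of parents, which is the central tension the abstraction process
resolves: a faithful clinical inventory produces CPTs far larger than any
realistic cohort can populate.

## Inference

Posteriors are computed exactly by variable elimination
(`infer_posterior()`), with a greedy min-degree elimination order. Exactness
is the contract; the ordering affects only speed. A brute-force enumeration
oracle (`enumerate_posterior()`) is kept alongside and the two are asserted
equal (within 1e-9) on hundreds of randomized networks in the test suite.
Numerical choices:

* **MAP tie-break.** `predict_map()` resolves exact posterior ties toward
  the earlier declared state. Boolean targets declare `c("true", "false")`,
  so prediction is equivalent to thresholding the posterior of "true" at
  0.5.
* **Impossible evidence.** Evidence with probability zero raises an explicit
  error rather than returning a uniform or `NaN` posterior; a silent
  fallback would corrupt validation counts.
* **Tolerances.** CPT rows must sum to 1 within 1e-9 in memory. At model
  *load* time (`read_model_json()`), rows off by up to 1e-6 are renormalized
  (serialization noise), anything worse is an error; rows already within
  1e-9 are left bit-identical so that write–read–write round trips are byte
  stable.

## Parameter learning

`learn_cpts()` (wrapped by the fitting front end `bn_fit()`) uses
closed-form maximum likelihood with Dirichlet pseudocounts: each row is
$(\mathrm{count} + \alpha) / (\mathrm{total} + \alpha s)$. The default
$\alpha = 1$ is the usual Laplace choice; records are assumed complete, so
no EM is needed. None of the package's qualitative conclusions depend on the
exact $\alpha$. Two deliberate behaviours:

* A parent configuration never observed in the data yields, at
  $\alpha = 0$, a uniform row that is *flagged* (`fit_report()`, the
  `unseen` attribute). Unobserved configurations are the diagnosed failure
  mode of over-detailed models and must be surfaced, not hidden.
* CPTs carrying the `fixed` flag — canonical gates installed by
  `apply_noisy_or()` — are never overwritten by learning, mirroring how
  expert-specified canonical nodes behave in graphical modelling tools.

## Abstraction operators

Four operators transform a model *and its dataset* coherently, each
returning a recorded step with before/after parameter counts:

* `merge_states()` clusters a variable's states through a partition
  (e.g. eight TNM N-categories into coarser nodal patterns). Touched CPTs
  are re-learned from the remapped data by default; an analytic aggregation
  mode (probability sums over the child dimension, count-weighted row
  pooling over the parent dimension) serves dataset-free use.
* `condense_variables()` replaces several source variables by one derived
  summary via a total mapping (e.g. infiltration indicators into a single
  surgical-contraindication node). The derived node is parentless by
  default — an expert-asserted, directly observed summary. When the
  condensed node is itself a therapy *target* it must remain predictable,
  so recipes re-attach parents with explicit `add_edge` steps and re-learn;
  this is the one place the parentless convention is deliberately overridden.
* `resolve_transitivity()` enforces independence of causal influence
  between decisions: every edge from a parent of one target to a parent of
  a *different* target is removed. The operator never adds edges and is
  idempotent.
* `binarize_target()` discretizes a node to Boolean `c("true", "false")`,
  and `compile_noisy_or()` / `apply_noisy_or()` install leaky noisy-OR
  gates, $P(\mathrm{true} \mid x) = 1 - (1-\ell)\prod_{i: x_i}(1 - p_i)$,
  replacing a $2^n$-row table by $n + 1$ parameters.

Recipes (ordered step lists) serialize to YAML and replay with
`replay_recipe()`, which re-learns CPTs from the adapted dataset after
every step — the workflow in which the training data are revised alongside
each model version.

## The packaged model versions

`reference_models()` ships three reconstructed versions of the OPSCC
decision model and the two recipes connecting them:

* **v1** — the full tumour-board inventory: 37 variables with 109 states in
  total, six multi-state therapy nodes (three surgical, two radiotherapy,
  one systemic) plus a best-supportive-care summary, and deliberately
  detailed parent sets (up to ~500 parent configurations per therapy node).
* **v2** — after clinically guided clustering: Karnofsky index and
  comorbidity coarsened, nodal status clustered, infiltration detail
  condensed into a surgical-contraindication node, organ function condensed,
  the two neck-dissection nodes condensed into one; five therapy nodes.
* **v3** — after canonical-model restructuring: transitivity resolved
  between target parent sets, health summaries and nodal status discretized
  to Boolean pairs, the surgical nodes condensed into one Boolean
  feasibility node, and best supportive care recast as a leaky noisy-OR of
  the general-condition risk indicators; four Boolean therapy nodes.

Reconstruction choices worth stating explicitly, since the node inventory is
constrained but not fully determined by its documented sources:

* The best-supportive-care node exists in every version but carries the
  `intermediate` role: it is a palliation summary, never an evaluated
  therapy target.
* v1 is evaluated on five of its six therapy nodes; the contralateral neck
  dissection is treated as subordinate to the ipsilateral node and not
  scored separately, keeping the per-patient prediction count at five for
  both five-target versions.
* Nodal status is clustered in two stages: v2 keeps three clinically
  decisive patterns (none / limited / advanced), because collapsing straight
  to a binary pattern would erase the N0-versus-N+ boundary that both the
  neck-dissection and concurrent-radiotherapy decisions require — clustering
  is only admissible while it preserves decision-relevant distinctions. The
  Boolean "unresectable nodal disease" variable appears in v3, where the
  remaining targets only need the advanced-disease boundary.
* v3 binarization maps the firm recommendation to "true" for definitive
  radiotherapy, concurrent radiotherapy and chemotherapy (a "conditional"
  grade is not an eligibility assertion), while the condensed surgery node
  expresses general feasibility (recommended or conditional).
* The exact membership of the leaky-ICI grouping of
  general-state-of-health information is not documented anywhere; the
  packaged v3 recipe applies the gate to the best-supportive-care node over
  the contraindication, reduced-condition and poor-prognosis indicators,
  with expert-style link probabilities (0.40, 0.55, 0.30) and leak 0.02.
  Because that node is never evaluated, this reconstruction does not touch
  the validation surface.

## Validation protocol

`cross_validate()` implements the evaluation: shuffled round-robin fold
assignment (sizes differing by at most one, deterministic in the seed);
per fold, CPTs learned on the training folds; per held-out patient and
target, the exact posterior given evidence on *all non-target variables* —
therapy decisions are never used as evidence for one another, matching
clinical use where no decision is known in advance. Correctness is MAP
state versus recorded state; micro-averaged accuracy pools correct
predictions over all (patient, target) pairs. ROC curves sweep thresholds
over distinct posterior scores with ties grouped; AUC is the trapezoidal
area, identical to the tie-corrected concordance probability. One-class
targets yield a flagged undefined AUC rather than a number — the situation
of a therapy option with almost no positive patients, where per-fold test
sets typically contain no positives at all. Accuracies and AUCs are
reported to three decimals.

## The synthetic cohort

The real cohort behind this workflow (94 complete records from a single
centre) is not publicly deposited, so `generate_cohort()` emulates its
statistical shape rather than its joint distribution. Diagnostic and
intermediate variables are sampled from an authored generating network
(`generator_truth()`) with marginals a head-and-neck clinician would accept
as plausible: HPV-associated staging patterns, infiltration rates rising
with T-category, organ function tied to comorbidity, age and exposure.
Therapy labels derive from a deterministic guideline rule-set
(`guideline_labels()`) — resectability and performance status gate surgery,
nodal burden and extranodal extension drive radiotherapy, organ tolerance
gates systemic therapy — and are then perturbed:

* **Label noise 0.1** (default): each therapy label is flipped to another
  state with probability 0.1, standing in for tumour-board judgement
  variability and documentation inconsistency. This also sets the
  noise ceiling that keeps even the final model's accuracy realistically
  below 1.
* **Rare classes enforced exactly**: by default exactly two patients carry
  a positive definitive-radiotherapy label, enforced by patching sampled
  rows after noise (patches recorded in an attribute), reproducing the
  rare-option regime in which an AUC is essentially undetermined.

What passing tests on this cohort do and do not show: they demonstrate that
the learning, abstraction and validation machinery behaves as specified
under a cohort whose decision structure is genuinely guideline-shaped with
realistic sparsity (94 records against up to ~500-row CPTs); they do not
certify clinical fidelity of the generating distribution beyond the
documented constraints, nor performance on real hospital data, where label
noise is not independent across therapy options and records are rarely
complete.

The accuracy trajectory across versions is an emergent property of this
construction, not an assertion baked into any test value: v1's detailed
CPTs are sparsely covered (many uniform rows, noisy maximum-likelihood
rows), the v2 clustering concentrates the same information in far fewer
rows, and the v3 canonical form aligns each Boolean target with the
decision boundary of its rule. Run it yourself:

```{r demo, eval = FALSE}
demo <- run_demo(seed = 7, n = 94, k = 10)
vapply(demo$reports, function(r) r$accuracy, numeric(1))
print(demo$reports$v3)
```

## Problem sizes used by the tests

The packaged test-suite sizes are the package's own choices for a tight,
informative suite: the oracle-equivalence property uses 200 randomized
networks of at most 6 variables and 4 states (where enumeration over all
completions is exact and fast); parameter-recovery experiments use 10,000
ancestral samples; the end-to-end demonstration uses the study-scale
94-record cohort with tenfold cross-validation. Recovery rows are compared
where the recovery sample determines them well (at least 1000 observations
for the packaged fixture, whose rare parent configurations otherwise leave
per-row binomial fluctuation above any meaningful tolerance; the dedicated
five-node recovery experiment, whose configurations are all common, is
checked at the 100-observation threshold).

## Known limitations

* Complete records are required; there is no EM or imputation path.
* Inference is exact only; very dense structures with many high-arity
  parents would need approximate inference, which is out of scope.
* The XDSL export targets the common CPT subset of the dialect
  (states, parents, row-major probabilities) and is export-only.
* Condensed summaries are modelled as observed inputs; a latent treatment
  of expert-asserted summaries is not attempted.
* The guideline rule-set is a deliberately simplified, internally coherent
  stand-in for real tumour-board policy; it should not be read as clinical
  guidance.
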