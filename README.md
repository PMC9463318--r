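# opsccbn

Bayesian-network clinical decision models for primary treatment selection in
oropharyngeal squamous cell carcinoma (OPSCC), built the hybrid way: the
network **structure** (variables, states, edges) is specified from clinical
knowledge, the **parameters** are learned from patient records, and the model
is then simplified in recorded, replayable abstraction steps until its
complexity matches the information the cohort can actually support. The
package is aimed at researchers in clinical decision support and medical
informatics who want a complete, testable reference implementation of this
workflow — model data structures, exact inference, CPT learning, abstraction
operators, cross-validated evaluation, a synthetic cohort generator and
serialization, all behind a classic R modelling interface.

## The model

A discrete Bayesian network over categorical variables factorizes the joint
distribution as

    P(x_1, ..., x_n) = prod_i P(x_i | pa(x_i))

with one conditional probability table (CPT) per node. A node with `s` states
and parents of cardinalities `r_1, ..., r_k` carries `(s - 1) * prod(r_j)`
free parameters — exponential growth that quickly outstrips a small cohort.
The package therefore implements, besides exact inference (variable
elimination, verified against brute-force enumeration) and smoothed
maximum-likelihood CPT estimation, the abstraction operators used to shrink
an over-detailed model:

* **state merging** — clustering clinically equivalent states
  (e.g. eight TNM N-categories into coarse nodal-disease patterns);
* **variable condensation** — replacing several indicators by one
  expert-asserted summary (e.g. a surgical-contraindication node);
* **transitivity resolution** — removing edges between the parent sets of
  distinct therapy decisions (independence of causal influence);
* **binarization and leaky noisy-OR gates** —
  `P(true | x) = 1 - (1 - leak) * prod_{i active} (1 - p_i)`,
  `n + 1` parameters in place of a `2^n`-row table.

Evaluation is k-fold cross-validation of the full learn-and-predict cycle:
per held-out patient and therapy node, the exact posterior given evidence on
all non-target variables, MAP correctness pooled into micro-averaged
accuracy, plus per-target ROC curves and tie-corrected AUC.

## Worked example

Three packaged model versions (v1: detailed, 37 variables / 109 states / six
therapy nodes; v2: clinically clustered, five therapy nodes; v3: canonical,
four Boolean therapy nodes) are connected by YAML abstraction recipes. The
demonstration pipeline generates a 94-record synthetic cohort, learns and
cross-validates v1, replays the recipes (adapting the dataset at each step),
and re-validates:

```r
library(opsccbn)

print(opscc_v1_network())
#> Discrete Bayesian network: 37 variables, 58 edges, 109 states, 3090 free parameters
#>   roles: 28 diagnostic, 3 intermediate, 6 target

demo <- run_demo(seed = 7, n = 94, k = 10)
round(vapply(demo$reports, function(r) r$accuracy, numeric(1)), 3)
#>    v1    v2    v3
#> 0.730 0.851 0.902

print(demo$reports$v3)
#> 10-fold cross-validation, 94 records x 4 targets
#> Overall accuracy: 0.902 (339 of 376 correct)
#>                   target correct total accuracy n_positive   auc
#>                  surgery      85    94    0.904         63 0.904
#>     radiotherapy_primary      88    94    0.936          2 0.739
#>  radiotherapy_concurrent      88    94    0.936         28 0.880
#>             chemotherapy      78    94    0.830         49 0.896
```

Reading the output: accuracy climbs across versions because the detailed v1
CPTs are mostly unobserved at n = 94 (near-uniform rows), while each
abstraction concentrates the same clinical information in far fewer, well
populated rows. The definitive-radiotherapy node has exactly two positive
patients by construction — its accuracy is high only because the negative
class dominates, and its AUC is essentially undetermined (most folds contain
no positive at all), the characteristic rare-option failure mode.

Individual pieces are available directly: `bn_network()` / `bn_fit()` for
structure and fitting (with `print`, `summary`, `coef`, `predict`,
`simulate`, `logLik` methods), `infer_posterior()` / `predict_map()` for
inference, `merge_states()`, `condense_variables()`, `resolve_transitivity()`,
`binarize_target()`, `compile_noisy_or()` for abstraction,
`cross_validate()` for evaluation, `generate_cohort()` for synthetic data,
and CSV/JSON/YAML/XDSL serialization in the `read_*`/`write_*`/`export_*`
family. A thin command-line shim with `simulate`, `learn`, `validate`,
`abstract`, `inspect` and `demo` subcommands is installed at
`inst/cli/opsccbn.R`.

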