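## Reconstructed OPSCC decision-model fixtures.
##
## The first model version (v1) is a detailed tumour-board-level inventory:
## 37 variables with 109 states in total, six multi-state therapy nodes plus a
## best-supportive-care summary node. The packaged YAML recipes transform it
## into the clinically clustered second version (five therapy nodes) and the
## canonical-model third version (four Boolean therapy nodes). The node
## inventory is a documented reconstruction constrained by the textual facts
## (variable mentions, node counts per version, total state count, Boolean
## final targets); clinical fidelity beyond those constraints is not claimed.

#' Variable inventory of the first OPSCC model version
#'
#' @return Named list of [bn_variable()] objects (37 variables, 109 states).
#' @export
opscc_variables <- function() {
  v <- list(
    bn_variable("tumor_site", c("tonsil", "base_of_tongue", "soft_palate", "posterior_wall")),
    bn_variable("tumor_size", c("lt2cm", "2to4cm", "4to6cm", "gt6cm")),
    bn_variable("T_stage", c("T1", "T2", "T3", "T4a", "T4b")),
    bn_variable("p16_status", c("positive", "negative")),
    bn_variable("N_stage", c("N0", "N1", "N2a", "N2b", "N2c", "N3a", "N3b", "Nx")),
    bn_variable("M_stage", c("M0", "M1")),
    bn_variable("extranodal_extension", c("present", "absent", "unknown")),
    bn_variable("histologic_grading", c("G1", "G2", "G3")),
    bn_variable("infiltration_depth", c("superficial", "deep")),
    bn_variable("carotid_infiltration", c("present", "absent")),
    bn_variable("skull_base_infiltration", c("present", "absent")),
    bn_variable("prevertebral_infiltration", c("present", "absent")),
    bn_variable("airway_compromise", c("present", "absent")),
    bn_variable("smoking_status", c("never", "former", "current")),
    bn_variable("alcohol_abuse", c("present", "absent")),
    bn_variable("age_group", c("under60", "60to70", "over70")),
    bn_variable("comorbidity_severity", c("none", "mild", "moderate", "severe")),
    bn_variable("karnofsky_index", c("100", "90", "80", "70", "60", "50", "40", "30", "20", "10")),
    bn_variable("second_primary", c("present", "absent")),
    bn_variable("weight_loss", c("present", "absent")),
    bn_variable("dysphagia", c("present", "absent")),
    bn_variable("trismus", c("present", "absent")),
    bn_variable("pain_level", c("none_mild", "severe")),
    bn_variable("dental_status", c("rehabilitated", "poor")),
    bn_variable("renal_function", c("adequate", "impaired")),
    bn_variable("liver_function", c("adequate", "impaired")),
    bn_variable("cardiac_function", c("adequate", "impaired")),
    bn_variable("pulmonary_function", c("adequate", "impaired")),
    bn_variable("general_health", c("good", "reduced", "poor"), role = "intermediate"),
    bn_variable("prognosis", c("favorable", "intermediate", "poor"), role = "intermediate"),
    bn_variable("primary_surgery", c("recommended", "conditional", "excluded"), role = "target"),
    bn_variable("neck_dissection_ipsilateral", c("recommended", "conditional", "excluded"), role = "target"),
    bn_variable("neck_dissection_contralateral", c("recommended", "conditional", "excluded"), role = "target"),
    bn_variable("radiotherapy_primary", c("recommended", "conditional", "excluded"), role = "target"),
    bn_variable("radiotherapy_concurrent", c("recommended", "conditional", "excluded"), role = "target"),
    bn_variable("chemotherapy", c("recommended", "conditional", "excluded"), role = "target"),
    bn_variable("best_supportive_care", c("considered", "not_considered"), role = "intermediate")
  )
  stats::setNames(v, vapply(v, function(x) x$name, ""))
}

opscc_v1_edges <- function() {
  rbind(
    # diagnostic layer
    c("tumor_size", "T_stage"),
    c("smoking_status", "p16_status"),
    c("p16_status", "N_stage"),
    c("N_stage", "extranodal_extension"),
    c("T_stage", "carotid_infiltration"),
    c("T_stage", "skull_base_infiltration"),
    c("T_stage", "prevertebral_infiltration"),
    c("T_stage", "airway_compromise"),
    c("T_stage", "dysphagia"),
    c("T_stage", "trismus"),
    c("T_stage", "pain_level"),
    c("dysphagia", "weight_loss"),
    c("age_group", "comorbidity_severity"),
    c("age_group", "cardiac_function"),
    c("comorbidity_severity", "karnofsky_index"),
    c("comorbidity_severity", "renal_function"),
    c("alcohol_abuse", "liver_function"),
    c("smoking_status", "pulmonary_function"),
    c("smoking_status", "second_primary"),
    # inferred summaries
    c("karnofsky_index", "general_health"),
    c("comorbidity_severity", "general_health"),
    c("age_group", "general_health"),
    c("p16_status", "prognosis"),
    c("second_primary", "prognosis"),
    c("smoking_status", "prognosis"),
    c("general_health", "prognosis"),
    # therapy nodes; the first version deliberately carries the full
    # tumour-board detail, so the therapy CPTs are large and sparsely covered
    c("T_stage", "primary_surgery"),
    c("carotid_infiltration", "primary_surgery"),
    c("skull_base_infiltration", "primary_surgery"),
    c("prevertebral_infiltration", "primary_surgery"),
    c("infiltration_depth", "primary_surgery"),
    c("trismus", "primary_surgery"),
    c("general_health", "primary_surgery"),
    c("N_stage", "neck_dissection_ipsilateral"),
    c("extranodal_extension", "neck_dissection_ipsilateral"),
    c("airway_compromise", "neck_dissection_ipsilateral"),
    c("general_health", "neck_dissection_ipsilateral"),
    c("N_stage", "neck_dissection_contralateral"),
    c("tumor_site", "neck_dissection_contralateral"),
    c("extranodal_extension", "neck_dissection_contralateral"),
    c("prevertebral_infiltration", "neck_dissection_contralateral"),
    c("T_stage", "radiotherapy_primary"),
    c("general_health", "radiotherapy_primary"),
    c("airway_compromise", "radiotherapy_primary"),
    c("N_stage", "radiotherapy_concurrent"),
    c("extranodal_extension", "radiotherapy_concurrent"),
    c("carotid_infiltration", "radiotherapy_concurrent"),
    c("prognosis", "radiotherapy_concurrent"),
    c("M_stage", "chemotherapy"),
    c("general_health", "chemotherapy"),
    c("renal_function", "chemotherapy"),
    c("cardiac_function", "chemotherapy"),
    c("liver_function", "chemotherapy"),
    c("pulmonary_function", "chemotherapy"),
    c("age_group", "chemotherapy"),
    c("general_health", "best_supportive_care"),
    c("M_stage", "best_supportive_care"),
    c("karnofsky_index", "best_supportive_care")
  )
}

#' Structure of the first OPSCC model version
#'
#' The detailed expert model prior to any abstraction: 37 variables, 109
#' states, CPTs uniform pending learning.
#'
#' @return A `bn` object.
#' @export
opscc_v1_network <- function() {
  bn_network(opscc_variables(), opscc_v1_edges())
}

## Set a CPT from a rule: fn receives a named character vector of parent
## states and returns an (unnormalized) probability vector over child states.
set_cpt_by_rule <- function(net, var, fn) {
  parents <- net$parents[[var]]
  card <- bn_card(net, parents)
  grid <- parent_config_grid(card)
  states <- net$variables[[var]]$states
  prob <- matrix(0, nrow = nrow(grid), ncol = length(states),
                 dimnames = list(NULL, states))
  labels <- lapply(parents, function(p) net$variables[[p]]$states)
  for (i in seq_len(nrow(grid))) {
    assign <- stats::setNames(
      vapply(seq_along(parents), function(j) labels[[j]][grid[i, j]], ""), parents)
    p <- fn(assign)
    prob[i, ] <- p / sum(p)
  }
  net$cpts[[var]] <- new_cpt(var, parents, prob)
  net
}

set_prior <- function(net, var, p) {
  states <- net$variables[[var]]$states
  net$cpts[[var]] <- new_cpt(var, character(0),
                             matrix(p / sum(p), nrow = 1,
                                    dimnames = list(NULL, states)))
  net
}

## Two-state helper: probability of the FIRST state as a function of one
## parent's state, given as a named vector.
set_binary_by_parent <- function(net, var, parent, p_first) {
  set_cpt_by_rule(net, var, function(a) {
    p <- p_first[[a[[parent]]]]
    c(p, 1 - p)
  })
}

#' Generating network for the synthetic cohort
#'
#' The "truth" behind [generate_cohort()]: the v1 structure restricted to the
#' non-therapy variables, with hand-specified CPTs emulating an OPSCC
#' population (HPV-associated staging pattern, performance-status mix,
#' infiltration rates rising with T, organ function tied to comorbidity and
#' exposure). Therapy labels are not sampled from CPTs but derived from the
#' deterministic guideline rule-set ([guideline_labels()]).
#'
#' @return List with elements `network` (a `bn` over the 30 non-therapy
#'   variables) and `rules` (the label rule function).
#' @export
generator_truth <- function() {
  vars <- opscc_variables()
  roles <- vapply(vars, function(v) v$role, "")
  keep <- names(vars)[roles != "target" & names(vars) != "best_supportive_care"]
  edges <- opscc_v1_edges()
  edges <- edges[edges[, 1] %in% keep & edges[, 2] %in% keep, , drop = FALSE]
  net <- bn_network(vars[keep], edges)

  net <- set_prior(net, "tumor_site", c(.45, .35, .12, .08))
  net <- set_prior(net, "tumor_size", c(.20, .40, .25, .15))
  net <- set_prior(net, "M_stage", c(.93, .07))
  net <- set_prior(net, "histologic_grading", c(.15, .55, .30))
  net <- set_prior(net, "infiltration_depth", c(.45, .55))
  net <- set_prior(net, "smoking_status", c(.25, .35, .40))
  net <- set_prior(net, "alcohol_abuse", c(.45, .55))
  net <- set_prior(net, "age_group", c(.35, .40, .25))
  net <- set_prior(net, "dental_status", c(.55, .45))

  t_rows <- list(lt2cm  = c(.80, .18, .02, 0, 0),
                 "2to4cm" = c(.10, .60, .25, .05, 0),
                 "4to6cm" = c(0, .10, .55, .25, .10),
                 gt6cm  = c(0, 0, .25, .45, .30))
  net <- set_cpt_by_rule(net, "T_stage", function(a) t_rows[[a[["tumor_size"]]]])

  net <- set_cpt_by_rule(net, "p16_status", function(a) {
    p <- c(never = .85, former = .60, current = .35)[[a[["smoking_status"]]]]
    c(p, 1 - p)
  })
  n_rows <- list(positive = c(.12, .33, .15, .18, .10, .06, .04, .02),
                 negative = c(.30, .15, .10, .15, .12, .08, .08, .02))
  net <- set_cpt_by_rule(net, "N_stage", function(a) n_rows[[a[["p16_status"]]]])

  ece_rows <- list(N0 = c(.02, .88, .10), N1 = c(.15, .70, .15), N2a = c(.25, .60, .15),
                   N2b = c(.30, .55, .15), N2c = c(.35, .50, .15), N3a = c(.45, .40, .15),
                   N3b = c(.60, .25, .15), Nx = c(.10, .45, .45))
  net <- set_cpt_by_rule(net, "extranodal_extension", function(a) ece_rows[[a[["N_stage"]]]])

  by_t <- function(p) stats::setNames(p, c("T1", "T2", "T3", "T4a", "T4b"))
  net <- set_binary_by_parent(net, "carotid_infiltration", "T_stage",
                              by_t(c(.005, .01, .04, .12, .55)))
  net <- set_binary_by_parent(net, "skull_base_infiltration", "T_stage",
                              by_t(c(.003, .005, .02, .08, .35)))
  net <- set_binary_by_parent(net, "prevertebral_infiltration", "T_stage",
                              by_t(c(.003, .005, .02, .06, .30)))
  net <- set_binary_by_parent(net, "airway_compromise", "T_stage",
                              by_t(c(.005, .02, .06, .15, .35)))
  net <- set_binary_by_parent(net, "dysphagia", "T_stage",
                              by_t(c(.10, .20, .45, .60, .75)))
  net <- set_binary_by_parent(net, "trismus", "T_stage",
                              by_t(c(.02, .05, .15, .30, .45)))
  net <- set_cpt_by_rule(net, "pain_level", function(a) {
    p <- by_t(c(.05, .10, .25, .40, .55))[[a[["T_stage"]]]]
    c(1 - p, p)  # states: none_mild, severe
  })
  net <- set_binary_by_parent(net, "weight_loss", "dysphagia",
                              c(present = .60, absent = .15))

  net <- set_cpt_by_rule(net, "comorbidity_severity", function(a) {
    switch(a[["age_group"]],
           under60 = c(.50, .30, .15, .05),
           "60to70" = c(.28, .37, .22, .13),
           over70 = c(.12, .30, .33, .25))
  })
  ki_rows <- list(
    none     = c(.35, .35, .18, .07, .03, .010, .005, .003, .001, .001),
    mild     = c(.15, .30, .25, .15, .08, .040, .015, .010, .003, .002),
    moderate = c(.05, .12, .22, .25, .18, .100, .050, .020, .007, .003),
    severe   = c(.01, .03, .08, .15, .20, .220, .150, .100, .040, .020))
  net <- set_cpt_by_rule(net, "karnofsky_index",
                         function(a) ki_rows[[a[["comorbidity_severity"]]]])
  net <- set_cpt_by_rule(net, "second_primary", function(a) {
    p <- c(never = .03, former = .08, current = .15)[[a[["smoking_status"]]]]
    c(p, 1 - p)
  })
  net <- set_cpt_by_rule(net, "renal_function", function(a) {
    p <- c(none = .02, mild = .06, moderate = .15, severe = .35)[[a[["comorbidity_severity"]]]]
    c(1 - p, p)  # adequate, impaired
  })
  net <- set_cpt_by_rule(net, "liver_function", function(a) {
    p <- c(present = .25, absent = .04)[[a[["alcohol_abuse"]]]]
    c(1 - p, p)
  })
  net <- set_cpt_by_rule(net, "cardiac_function", function(a) {
    p <- c(under60 = .05, "60to70" = .12, over70 = .30)[[a[["age_group"]]]]
    c(1 - p, p)
  })
  net <- set_cpt_by_rule(net, "pulmonary_function", function(a) {
    p <- c(never = .03, former = .10, current = .28)[[a[["smoking_status"]]]]
    c(1 - p, p)
  })

  net <- set_cpt_by_rule(net, "general_health", function(a) {
    ki <- as.integer(a[["karnofsky_index"]])
    cm <- a[["comorbidity_severity"]]
    p <- if (ki >= 80 && cm %in% c("none", "mild")) c(.85, .13, .02)
    else if (ki >= 60 && cm != "severe") c(.25, .65, .10)
    else if (ki >= 50) c(.05, .55, .40)
    else c(.01, .20, .79)
    if (a[["age_group"]] == "over70") p <- p + c(-.10, .10, 0) * min(p[1], .10) * 10
    pmax(p, .001)
  })
  net <- set_cpt_by_rule(net, "prognosis", function(a) {
    pts <- 2 * (a[["p16_status"]] == "positive") +
      (a[["second_primary"]] == "absent") +
      (a[["smoking_status"]] != "current") +
      (a[["general_health"]] == "good") -
      2 * (a[["general_health"]] == "poor")
    if (pts >= 4) c(.80, .17, .03)
    else if (pts >= 2) c(.45, .40, .15)
    else if (pts >= 0) c(.15, .50, .35)
    else c(.03, .27, .70)
  })
  validate_network(net)
  list(network = net, rules = guideline_labels)
}

#' Canonical evaluated-target sets of the three model versions
#'
#' @return Named list of character vectors (`v1`, `v2`, `v3`). Version 1
#'   evaluates five of its six therapy nodes (the contralateral neck
#'   dissection is subordinate to the ipsilateral node and not scored);
#'   best supportive care is never evaluated.
#' @export
opscc_targets <- function() {
  list(
    v1 = c("primary_surgery", "neck_dissection_ipsilateral", "radiotherapy_primary",
           "radiotherapy_concurrent", "chemotherapy"),
    v2 = c("primary_surgery", "neck_dissection", "radiotherapy_primary",
           "radiotherapy_concurrent", "chemotherapy"),
    v3 = c("surgery", "radiotherapy_primary", "radiotherapy_concurrent", "chemotherapy")
  )
}

opscc_recipe_path <- function(which = c("v1_to_v2", "v2_to_v3")) {
  which <- match.arg(which)
  system.file("extdata", "recipes", paste0(which, ".yaml"), package = "opsccbn",
              mustWork = TRUE)
}

.fixture_cache <- new.env(parent = emptyenv())

#' The packaged v1/v2/v3 model-version fixtures
#'
#' Builds the three reference model versions: a fixed-seed synthetic cohort is
#' generated, v1 CPTs are learned from it, and the packaged YAML abstraction
#' recipes are replayed to produce v2 and v3 (datasets adapted alongside).
#' Deterministic; results are cached within the session.
#'
#' @param alpha Pseudocount used for all learning.
#' @return List with elements `v1`, `v2`, `v3` (fitted `bn` objects),
#'   `data` (named list of the version-matched datasets), `recipes` (named
#'   list of parsed recipes), `steps` (abstraction step records) and
#'   `targets` (see [opscc_targets()]).
#' @export
reference_models <- function(alpha = 1) {
  key <- sprintf("ref_%g", alpha)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cohort <- generate_cohort(cohort_config(seed = 20170301))
  v1 <- learn_cpts(opscc_v1_network(), cohort$data, alpha = alpha)
  r12 <- read_recipe_yaml(opscc_recipe_path("v1_to_v2"))
  s2 <- replay_recipe(v1, cohort$data, r12, alpha = alpha)
  r23 <- read_recipe_yaml(opscc_recipe_path("v2_to_v3"))
  s3 <- replay_recipe(s2$network, s2$data, r23, alpha = alpha)
  out <- list(v1 = v1, v2 = s2$network, v3 = s3$network,
              data = list(v1 = cohort$data, v2 = s2$data, v3 = s3$data),
              recipes = list(v1_to_v2 = r12, v2_to_v3 = r23),
              steps = list(v1_to_v2 = s2$steps, v2_to_v3 = s3$steps),
              targets = opscc_targets(),
              truth = cohort$truth)
  .fixture_cache[[key]] <- out
  out
}
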