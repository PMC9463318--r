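#' Forward (ancestral) sampling from a network
#'
#' Draws complete records in topological order: each variable is sampled from
#' its CPT row given the already-sampled parent states. Deterministic given
#' `seed`; the caller's RNG state is untouched.
#'
#' @param net A `bn` object with valid CPTs.
#' @param n Number of records.
#' @param seed Integer seed (or `NULL` to consume the current RNG stream).
#' @return Data.frame of state labels with `nrow = n`, columns in network
#'   order, attribute `provenance = "synthetic"`.
#' @export
ancestral_sample <- function(net, n, seed = NULL) {
  draw <- function() {
    ord <- topo_order(net)
    idx <- matrix(0L, nrow = n, ncol = length(ord),
                  dimnames = list(NULL, ord))
    for (v in ord) {
      cpt <- net$cpts[[v]]
      card <- bn_card(net, cpt$parents)
      row <- parent_row_index(card, idx[, cpt$parents, drop = FALSE])
      cum <- t(apply(cpt$prob, 1L, cumsum))
      u <- stats::runif(n)
      idx[, v] <- rowSums(u > cum[row, , drop = FALSE]) + 1L
    }
    idx
  }
  idx <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  out <- as.data.frame(lapply(stats::setNames(colnames(idx), colnames(idx)), function(v) {
    net$variables[[v]]$states[idx[, v]]
  }), stringsAsFactors = FALSE)
  out <- out[, bn_names(net)[bn_names(net) %in% colnames(idx)], drop = FALSE]
  attr(out, "provenance") <- "synthetic"
  out
}

#' Configuration for the synthetic OPSCC cohort generator
#'
#' Defaults emulate the study cohort this package is designed around: 94
#' complete records, a 10% chance that any therapy label deviates from its
#' guideline-rule value (tumour-board judgement and documentation variability),
#' and exactly two primary-radiotherapy patients (a clinically rare option).
#'
#' @param n_patients Cohort size.
#' @param label_noise Probability, per therapy label, of flipping the
#'   guideline-rule value to another state (uniformly chosen).
#' @param rare_class_counts Named list/vector: exact number of records whose
#'   label for that target equals the target's positive (first declared)
#'   state, enforced by patching sampled rows; patches are recorded in the
#'   `patches` attribute of the returned dataset.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return Object of class `opscc_cohort_config`.
#' @export
cohort_config <- function(n_patients = 94,
                          label_noise = 0.1,
                          rare_class_counts = list(radiotherapy_primary = 2),
                          seed = 1) {
  stopifnot(n_patients >= 1, label_noise >= 0, label_noise <= 1)
  if (length(rare_class_counts) &&
      any(unlist(rare_class_counts) > n_patients)) {
    stop("rare_class_counts cannot exceed n_patients", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients), label_noise = label_noise,
                 rare_class_counts = rare_class_counts, seed = as.integer(seed)),
            class = "opscc_cohort_config")
}

#' Generate a synthetic OPSCC patient cohort
#'
#' Samples diagnostic and intermediate variables from the generating network
#' (see [generator_truth()]), derives the six therapy labels and the
#' best-supportive-care column from a deterministic guideline rule-set
#' ([guideline_labels()]), applies independent label noise, and enforces any
#' configured rare-class counts exactly by patching (recorded). The resulting
#' table matches the v1 model schema column-for-column and state-for-state.
#'
#' @param config An [cohort_config()].
#' @return List with elements `data` (the cohort, provenance `"synthetic"`,
#'   attribute `patches`) and `truth` (list: `network` — the generating
#'   network over non-target variables, `rules` — the label rule function).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "opscc_cohort_config"))
  truth <- generator_truth()
  n <- config$n_patients
  diag <- ancestral_sample(truth$network, n, seed = config$seed)
  labels <- guideline_labels(diag)

  withr::with_seed(config$seed + 1L, {
    v1 <- opscc_v1_network()
    for (t in names(labels)) {
      if (config$label_noise > 0) {
        flip <- stats::runif(n) < config$label_noise
        if (any(flip)) {
          states <- v1$variables[[t]]$states
          labels[[t]][flip] <- vapply(labels[[t]][flip], function(cur) {
            sample(setdiff(states, cur), 1L)
          }, "")
        }
      }
    }
    data <- cbind(diag, labels, stringsAsFactors = FALSE)
    patches <- list()
    for (t in names(config$rare_class_counts)) {
      if (!t %in% names(data)) {
        stop(sprintf("rare_class_counts names unknown target '%s'", t), call. = FALSE)
      }
      pos_state <- v1$variables[[t]]$states[1L]
      target_n <- config$rare_class_counts[[t]]
      is_pos <- data[[t]] == pos_state
      excess <- sum(is_pos) - target_n
      if (excess > 0L) {
        demote <- sample(which(is_pos), excess)
        neg_states <- setdiff(v1$variables[[t]]$states, pos_state)
        data[[t]][demote] <- sample(neg_states, excess, replace = TRUE)
        patches[[t]] <- list(direction = "demote", rows = demote)
      } else if (excess < 0L) {
        promote <- sample(which(!is_pos), -excess)
        data[[t]][promote] <- pos_state
        patches[[t]] <- list(direction = "promote", rows = promote)
      }
    }
  })
  data <- data[, bn_names(opscc_v1_network()), drop = FALSE]
  attr(data, "provenance") <- "synthetic"
  attr(data, "patches") <- patches
  list(data = data, truth = truth)
}

## Deterministic guideline rule-set mapping sampled diagnostics to the six v1
## therapy labels plus best supportive care. Encodes, in simplified form, the
## decision logic a head-and-neck tumour board applies: resectability and
## performance status gate surgery; advanced nodal disease or extranodal
## extension indicate concurrent radio(chemo)therapy; unresectable or
## metastatic disease shifts to systemic therapy / definitive radiotherapy;
## poor general health shifts to palliation.
#' Guideline rule labels for a diagnostic table
#'
#' @param d Data.frame of sampled non-target columns (v1 schema).
#' @return Data.frame of the seven derived label columns.
#' @export
guideline_labels <- function(d) {
  n <- nrow(d)
  unres <- d$carotid_infiltration == "present" |
    d$skull_base_infiltration == "present" |
    d$prevertebral_infiltration == "present" |
    d$airway_compromise == "present"
  gh <- d$general_health
  nodal <- d$N_stage
  node_pos <- c("N1", "N2a", "N2b", "N2c", "N3a", "N3b")

  primary_surgery <- ifelse(unres | d$T_stage == "T4b" | gh == "poor", "excluded",
                            ifelse(gh == "good", "recommended", "conditional"))

  # ipsilateral dissection follows nodal involvement, gated by performance
  nd_ipsi <- ifelse(gh == "poor", "excluded",
                    ifelse(nodal %in% node_pos, "recommended", "conditional"))

  # contralateral dissection for bilateral/advanced disease or midline sites
  nd_contra <- rep("excluded", n)
  nd_contra[nodal %in% c("N2c", "N3a", "N3b")] <- "recommended"
  nd_contra[nodal %in% c("N1", "N2a", "N2b") &
              d$tumor_site %in% c("base_of_tongue", "soft_palate", "posterior_wall")] <-
    "conditional"

  # definitive radiotherapy: rare organ-preservation setting for fit patients
  # with an airway-compromising (hence unresectable) primary
  rt_primary <- ifelse(d$airway_compromise == "present" & gh == "good",
                       "recommended", "excluded")

  # concurrent/adjuvant radiotherapy driven by nodal burden and extranodal spread
  rt_concurrent <- rep("excluded", n)
  rt_concurrent[nodal %in% node_pos[1:4]] <- "conditional"
  rt_concurrent[nodal %in% c("N3a", "N3b") |
                  d$extranodal_extension == "present"] <- "recommended"

  # systemic therapy requires renal and cardiac tolerance; firm for metastatic
  # disease and for fit patients up to 70
  chemotherapy <- rep("conditional", n)
  chemotherapy[d$M_stage == "M1" | d$age_group != "over70"] <- "recommended"
  chemotherapy[d$renal_function == "impaired" | d$cardiac_function == "impaired" |
                 gh == "poor"] <- "excluded"

  bsc <- ifelse(gh == "poor" | (d$M_stage == "M1" & unres),
                "considered", "not_considered")

  data.frame(primary_surgery = primary_surgery,
             neck_dissection_ipsilateral = nd_ipsi,
             neck_dissection_contralateral = nd_contra,
             radiotherapy_primary = rt_primary,
             radiotherapy_concurrent = rt_concurrent,
             chemotherapy = chemotherapy,
             best_supportive_care = bsc,
             stringsAsFactors = FALSE)
}
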