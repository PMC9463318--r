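new_abstraction_step <- function(kind, details, before, after, rationale = "") {
  structure(list(kind = kind, details = details,
                 before_parameters = free_parameter_count(before),
                 after_parameters = free_parameter_count(after),
                 rationale = rationale),
            class = "bn_abstraction_step")
}

#' @export
print.bn_abstraction_step <- function(x, ...) {
  cat(sprintf("Abstraction step [%s]: %d -> %d free parameters\n",
              x$kind, x$before_parameters, x$after_parameters))
  if (nzchar(x$rationale)) cat(" ", x$rationale, "\n")
  invisible(x)
}

## Re-learn the CPTs of `vars` (and only those) from the dataset.
relearn_vars <- function(net, data, vars, alpha) {
  for (v in vars) {
    if (isTRUE(net$cpts[[v]]$fixed)) next
    counts <- count_table(net, data, v)
    s <- ncol(counts)
    prob <- (counts + alpha) / (rowSums(counts) + alpha * s)
    if (alpha == 0) {
      zero <- rowSums(counts) == 0L
      prob[zero, ] <- 1 / s
    }
    dimnames(prob) <- list(NULL, net$variables[[v]]$states)
    net$cpts[[v]] <- new_cpt(v, net$parents[[v]], prob)
  }
  net
}

check_partition <- function(net, variable, groups) {
  if (!variable %in% bn_names(net)) {
    stop(sprintf("unknown variable '%s'", variable), call. = FALSE)
  }
  states <- net$variables[[variable]]$states
  if (is.null(names(groups)) || any(!nzchar(names(groups))) || anyDuplicated(names(groups))) {
    stop("groups must carry unique non-empty new labels as names", call. = FALSE)
  }
  flat <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(flat)) {
    stop(sprintf("overlapping groups for '%s': %s", variable,
                 paste(unique(flat[duplicated(flat)]), collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(states, flat)
  extra <- setdiff(flat, states)
  if (length(extra)) {
    stop(sprintf("group member(s) not states of '%s': %s", variable,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  if (length(missing)) {
    stop(sprintf("groups do not cover state(s) of '%s': %s", variable,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Merge states of a variable (clinical state clustering)
#'
#' Replaces a variable's states by coarser groups (e.g., collapsing the eight
#' TNM N-categories into resectable vs unresectable nodal disease), remaps the
#' dataset through the partition, and rebuilds every CPT that touches the
#' variable. By default the touched CPTs are re-learned from the remapped
#' dataset, mirroring the workflow in which the training data are adapted to
#' each model version; `cpt = "aggregate"` instead aggregates the existing
#' CPT analytically (probability sums over the child dimension, count-weighted
#' row pooling over the parent dimension) for dataset-free use.
#'
#' @param net A `bn` object.
#' @param data Complete data.frame matching `net`.
#' @param variable Variable whose states are merged.
#' @param groups Named list: new label -> character vector of old states.
#'   Groups must partition the old state set.
#' @param cpt `"relearn"` (default) or `"aggregate"`.
#' @param alpha Pseudocount used when re-learning.
#' @return List with elements `network`, `data`, `step`.
#' @export
merge_states <- function(net, data, variable, groups, cpt = c("relearn", "aggregate"),
                         alpha = 1) {
  cpt <- match.arg(cpt)
  check_partition(net, variable, groups)
  validate_dataset(net, data)
  before <- net
  old_states <- net$variables[[variable]]$states
  map <- stats::setNames(rep(names(groups), lengths(groups)), unlist(groups))

  new_var <- bn_variable(variable, names(groups), net$variables[[variable]]$role)
  touched <- unique(c(variable, bn_children(net, variable)))
  old_cpts <- net$cpts[touched]
  old_card_var <- length(old_states)

  net$variables[[variable]] <- new_var
  new_data <- data
  new_data[[variable]] <- unname(map[as.character(data[[variable]])])

  if (cpt == "relearn") {
    for (v in touched) net$cpts[[v]] <- uniform_cpt(net, v)
    net <- relearn_vars(net, new_data, touched, alpha)
  } else {
    group_idx <- match(map[old_states], names(groups))  # old state -> new state index
    # child dimension: sum probabilities of member states
    own <- old_cpts[[variable]]
    newp <- matrix(0, nrow = nrow(own$prob), ncol = length(groups),
                   dimnames = list(NULL, names(groups)))
    for (s in seq_along(old_states)) {
      newp[, group_idx[s]] <- newp[, group_idx[s]] + own$prob[, s]
    }
    net$cpts[[variable]] <- new_cpt(variable, own$parents, newp)
    # parent dimension: pool rows of children, weighted by observed counts of
    # the old parent configuration (uniform weights where no record falls)
    for (v in setdiff(touched, variable)) {
      oldc <- old_cpts[[v]]
      old_pcard <- bn_card(before, oldc$parents)
      new_pcard <- bn_card(net, oldc$parents)
      old_grid <- parent_config_grid(old_pcard)
      new_rows <- old_grid
      j <- match(variable, oldc$parents)
      new_rows[, j] <- group_idx[old_grid[, j]]
      dest <- parent_row_index(new_pcard, new_rows)
      w_counts <- count_table(before, data, v)
      w <- rowSums(w_counts) + 1e-9
      num <- rowsum(oldc$prob * w, dest)
      den <- rowsum(w, dest)
      newp <- matrix(0, nrow = prod(new_pcard), ncol = ncol(oldc$prob),
                     dimnames = list(NULL, colnames(oldc$prob)))
      newp[as.integer(rownames(num)), ] <- num / as.vector(den)
      net$cpts[[v]] <- new_cpt(v, oldc$parents, newp)
    }
  }
  step <- new_abstraction_step(
    "merge",
    list(variable = variable, groups = groups),
    before, net,
    sprintf("states of '%s' clustered %d -> %d", variable, old_card_var, length(groups))
  )
  list(network = net, data = new_data, step = step)
}

#' Specify a variable-condensation rule
#'
#' A condensation rule replaces several source variables by one derived
#' summary variable (e.g., tumour-extent and infiltration indicators condensed
#' into a single resectability/contraindication node), via a total mapping
#' from source-state combinations to derived states.
#'
#' @param sources Character vector of source variable names.
#' @param derived A [bn_variable()] for the new node.
#' @param mapping Either a function taking a named character vector (one state
#'   per source) and returning a derived state label, or a declarative spec as
#'   used in YAML recipes: `list(kind = "cases", cases = list(list(when_any =
#'   list(var = c(states...)), value = "..."), ...), default = "...")` (first
#'   matching case wins), or `list(kind = "table", table = list("s1|s2" =
#'   "value", ...))` keyed by source states joined with `"|"` in source order.
#' @return Object of class `bn_condensation_rule`.
#' @export
condensation_rule <- function(sources, derived, mapping) {
  stopifnot(inherits(derived, "bn_variable"), length(sources) >= 1L)
  fn <- if (is.function(mapping)) mapping else mapping_function(sources, mapping)
  structure(list(sources = sources, derived = derived, map = fn),
            class = "bn_condensation_rule")
}

mapping_function <- function(sources, spec) {
  kind <- spec$kind
  if (identical(kind, "table")) {
    tab <- unlist(spec$table)
    function(assign) {
      key <- paste(assign[sources], collapse = "|")
      unname(tab[key])  # NA for combinations the table does not list
    }
  } else if (identical(kind, "cases")) {
    function(assign) {
      for (cs in spec$cases) {
        hit <- any(vapply(names(cs$when_any), function(v)
          assign[[v]] %in% cs$when_any[[v]], TRUE))
        if (hit) return(cs$value)
      }
      spec$default
    }
  } else {
    stop("mapping kind must be 'table' or 'cases' (or supply a function)", call. = FALSE)
  }
}

#' Condense several variables into one derived summary node
#'
#' The derived variable is added as a parentless, directly observed summary
#' (the modeling convention for expert-asserted inputs such as resectability);
#' the source variables and all their edges are removed, every dataset row
#' gains the derived column through the mapping and loses the source columns,
#' and the CPTs of former source children are re-learned. Use subsequent
#' [add_edge()] / recipe `add_edge` steps to give a condensed *target* node
#' predictive parents.
#'
#' @param net A `bn` object.
#' @param data Complete data.frame matching `net`.
#' @param rule A [condensation_rule()].
#' @param alpha Pseudocount for re-learning touched CPTs.
#' @return List with elements `network`, `data`, `step`.
#' @export
condense_variables <- function(net, data, rule, alpha = 1) {
  stopifnot(inherits(rule, "bn_condensation_rule"))
  validate_dataset(net, data)
  missing <- setdiff(rule$sources, bn_names(net))
  if (length(missing)) {
    stop(sprintf("unknown source variable(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (rule$derived$name %in% setdiff(bn_names(net), rule$sources)) {
    stop(sprintf("derived name '%s' already in use", rule$derived$name), call. = FALSE)
  }
  before <- net

  # totality check over the full source-state grid
  card <- bn_card(net, rule$sources)
  grid <- parent_config_grid(card)
  labels <- lapply(rule$sources, function(v) net$variables[[v]]$states)
  out <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    assign <- stats::setNames(
      vapply(seq_along(rule$sources), function(j) labels[[j]][grid[i, j]], ""),
      rule$sources)
    val <- rule$map(assign)
    if (is.na(val) || is.null(val) || !val %in% rule$derived$states) {
      stop(sprintf("mapping undefined or illegal for source combination (%s)",
                   paste(sprintf("%s=%s", rule$sources, assign), collapse = ", ")),
           call. = FALSE)
    }
    out[i] <- val
  }

  # dataset: derived column via the mapping, drop sources
  idx <- dataset_index(net, data, rule$sources)
  row <- parent_row_index(card, idx)
  new_data <- data[, setdiff(names(data), rule$sources), drop = FALSE]
  new_data[[rule$derived$name]] <- out[row]

  # network: drop sources and their edges, add parentless derived node
  affected_children <- setdiff(
    unique(unlist(lapply(rule$sources, bn_children, net = net))), rule$sources)
  net$variables[rule$sources] <- NULL
  net$parents[rule$sources] <- NULL
  net$cpts[rule$sources] <- NULL
  for (v in affected_children) {
    net$parents[[v]] <- setdiff(net$parents[[v]], rule$sources)
  }
  net$variables[[rule$derived$name]] <- rule$derived
  net$parents[[rule$derived$name]] <- character(0)
  net$cpts[[rule$derived$name]] <- uniform_cpt(net, rule$derived$name)
  for (v in affected_children) net$cpts[[v]] <- uniform_cpt(net, v)
  net <- relearn_vars(net, new_data, c(affected_children, rule$derived$name), alpha)

  step <- new_abstraction_step(
    "condense",
    list(sources = rule$sources, derived = rule$derived$name),
    before, net,
    sprintf("%s condensed into '%s'", paste(rule$sources, collapse = ", "),
            rule$derived$name)
  )
  list(network = net, data = new_data, step = step)
}

#' Enforce independence of causal influence between target parents
#'
#' Removes every edge running from a parent of one target node to a parent of
#' a different target node, so that the causes feeding distinct therapy
#' decisions act independently (no links between parent sets). Idempotent and
#' edge-removing only; CPTs of children that lose a parent are reset pending
#' re-learning.
#'
#' @param net A `bn` object.
#' @param targets Character vector of target node names.
#' @return List with elements `network`, `removed` (edge matrix) and `step`.
#' @export
resolve_transitivity <- function(net, targets) {
  missing <- setdiff(targets, bn_names(net))
  if (length(missing)) {
    stop(sprintf("unknown target(s): %s", paste(missing, collapse = ", ")), call. = FALSE)
  }
  before <- net
  parent_sets <- lapply(targets, function(t) net$parents[[t]])
  names(parent_sets) <- targets
  edges <- bn_edges(net)
  drop <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, "parent"]; v <- edges[i, "child"]
    from_t <- targets[vapply(parent_sets, function(p) u %in% p, TRUE)]
    to_t <- targets[vapply(parent_sets, function(p) v %in% p, TRUE)]
    # drop iff u is a parent of some target X and v of some target Y, X != Y
    if (length(from_t) && length(to_t)) {
      pairs <- expand.grid(from_t, to_t, stringsAsFactors = FALSE)
      if (any(pairs[[1L]] != pairs[[2L]])) drop[i] <- TRUE
    }
  }
  removed <- edges[drop, , drop = FALSE]
  for (i in seq_len(nrow(removed))) {
    ch <- removed[i, "child"]
    net$parents[[ch]] <- setdiff(net$parents[[ch]], removed[i, "parent"])
  }
  for (ch in unique(removed[, "child"])) net$cpts[[ch]] <- uniform_cpt(net, ch)
  step <- new_abstraction_step(
    "resolve_transitivity",
    list(targets = targets, removed = removed),
    before, net,
    sprintf("%d inter-parent edge(s) removed", nrow(removed))
  )
  list(network = net, removed = removed, step = step)
}

#' Discretize a variable into a Boolean true/false pair
#'
#' Equivalent to [merge_states()] with the two-group partition
#' `list(true = true_states, false = <rest>)`; the resulting states are
#' exactly `c("true", "false")` with "true" first, the convention used for
#' all Boolean therapy targets.
#'
#' @inheritParams merge_states
#' @param true_states Non-empty proper subset of the variable's states mapped
#'   to `"true"`.
#' @return List with elements `network`, `data`, `step` (kind `"binarize"`).
#' @export
binarize_target <- function(net, data, variable, true_states, cpt = "relearn", alpha = 1) {
  states <- net$variables[[variable]]$states
  if (length(true_states) == 0L || length(setdiff(states, true_states)) == 0L) {
    stop("true_states must be a non-empty proper subset of the variable's states",
         call. = FALSE)
  }
  res <- merge_states(net, data, variable,
                      groups = list("true" = true_states,
                                    "false" = setdiff(states, true_states)),
                      cpt = cpt, alpha = alpha)
  res$step$kind <- "binarize"
  res
}

#' Specify a leaky noisy-OR gate
#'
#' @param effect Name of the Boolean effect node (states `c("true","false")`).
#' @param causes Character vector of Boolean cause node names.
#' @param links Per-cause link probabilities in `[0, 1]`: the probability that
#'   the cause alone (all others false, no leak) produces the effect.
#' @param leak Background leak probability in `[0, 1]`.
#' @return Object of class `bn_noisy_or_spec`.
#' @export
noisy_or_spec <- function(effect, causes, links, leak = 0) {
  stopifnot(length(links) == length(causes),
            all(links >= 0 & links <= 1), leak >= 0, leak <= 1)
  structure(list(effect = effect, causes = causes,
                 links = as.numeric(links), leak = as.numeric(leak)),
            class = "bn_noisy_or_spec")
}

#' Compile a leaky noisy-OR specification into a full CPT
#'
#' Independence-of-causal-influence gate: each active cause fails to produce
#' the effect independently with probability `1 - p_i`, and a background leak
#' fails with `1 - leak`, so
#' `P(effect = true | x) = 1 - (1 - leak) * prod_{i : x_i = true} (1 - p_i)`.
#' The gate needs `n + 1` parameters where the equivalent full CPT has `2^n`
#' rows.
#'
#' @param spec A [noisy_or_spec()].
#' @return A CPT object (class `bn_cpt`) with one row per cause pattern
#'   (first cause varying fastest, "true" = state 1) and columns
#'   `true`, `false`; marked `fixed` so parameter learning preserves it.
#' @examples
#' cpt <- compile_noisy_or(noisy_or_spec("e", c("a", "b"), c(0.6, 0.5), leak = 0.1))
#' cpt$prob[1, "true"]  # both causes true: 1 - 0.9*0.4*0.5 = 0.82
#' @export
compile_noisy_or <- function(spec) {
  stopifnot(inherits(spec, "bn_noisy_or_spec"))
  k <- length(spec$causes)
  grid <- parent_config_grid(rep(2L, k))  # index 1 = "true", 2 = "false"
  fail <- rep(1 - spec$leak, nrow(grid))
  for (j in seq_len(k)) {
    fail <- fail * ifelse(grid[, j] == 1L, 1 - spec$links[j], 1)
  }
  p_true <- 1 - fail
  prob <- cbind("true" = p_true, "false" = 1 - p_true)
  new_cpt(spec$effect, spec$causes, prob, fixed = TRUE)
}

#' Install a compiled noisy-OR gate in a network
#'
#' Rewires the effect node's in-edges to the listed causes and installs the
#' compiled canonical CPT with the `fixed` flag set, so [learn_cpts()] leaves
#' it untouched (expert-specified canonical parameters).
#'
#' @param net A `bn` object.
#' @param spec A [noisy_or_spec()]; effect and causes must exist and be
#'   Boolean (`c("true","false")`).
#' @return List with elements `network` and `step` (kind `"noisy_or"`).
#' @export
apply_noisy_or <- function(net, spec) {
  stopifnot(inherits(spec, "bn_noisy_or_spec"))
  before <- net
  for (v in c(spec$effect, spec$causes)) {
    if (!v %in% bn_names(net)) stop(sprintf("unknown variable '%s'", v), call. = FALSE)
    if (!identical(net$variables[[v]]$states, c("true", "false"))) {
      stop(sprintf("'%s' must be Boolean with states [true, false] for a noisy-OR gate", v),
           call. = FALSE)
    }
  }
  net$parents[[spec$effect]] <- character(0)
  net$cpts[[spec$effect]] <- uniform_cpt(net, spec$effect)
  for (p in spec$causes) net <- add_edge(net, p, spec$effect)
  net$cpts[[spec$effect]] <- compile_noisy_or(spec)
  step <- new_abstraction_step(
    "noisy_or",
    list(effect = spec$effect, causes = spec$causes,
         links = spec$links, leak = spec$leak),
    before, net,
    sprintf("'%s' restructured as leaky noisy-OR of %d cause(s)",
            spec$effect, length(spec$causes))
  )
  list(network = net, step = step)
}

#' Compare the complexity of two model versions
#'
#' @param before,after `bn` objects.
#' @return Object of class `bn_complexity`: a data.frame with per-model and
#'   delta rows for free parameters, total states and edge count, plus a
#'   `per_variable` attribute carrying both parameter breakdowns.
#' @export
complexity_report <- function(before, after) {
  metric <- function(net) c(free_parameters = free_parameter_count(net),
                            total_states = total_state_count(net),
                            edges = nrow(bn_edges(net)))
  b <- metric(before); a <- metric(after)
  out <- data.frame(metric = names(b), before = as.integer(b), after = as.integer(a),
                    delta = as.integer(a - b), stringsAsFactors = FALSE)
  attr(out, "per_variable") <- list(
    before = free_parameter_count(before, by_variable = TRUE),
    after = free_parameter_count(after, by_variable = TRUE))
  class(out) <- c("bn_complexity", class(out))
  out
}

#' @export
print.bn_complexity <- function(x, ...) {
  cat("Model complexity comparison:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Replay an abstraction recipe
#'
#' Applies an ordered list of abstraction steps (as produced by
#' [read_recipe_yaml()] or built in code) to a model version and its dataset,
#' re-learning CPTs from the remapped data after every step, and records the
#' applied [new_abstraction_step] objects. This is how the packaged v1 -> v2
#' -> v3 model versions are produced.
#'
#' @param net A `bn` object.
#' @param data Complete data.frame matching `net`.
#' @param recipe List of step specifications; each must carry an `op` field in
#'   `merge`, `condense`, `add_edge`, `resolve_transitivity`, `binarize`,
#'   `noisy_or`.
#' @param alpha Pseudocount used for all re-learning.
#' @return List with elements `network`, `data`, `steps`.
#' @export
replay_recipe <- function(net, data, recipe, alpha = 1) {
  steps <- list()
  for (st in recipe) {
    op <- st$op
    if (is.null(op)) stop("recipe step lacks an 'op' field", call. = FALSE)
    if (op == "merge") {
      res <- merge_states(net, data, st$variable, st$groups, alpha = alpha)
      net <- res$network; data <- res$data; steps <- c(steps, list(res$step))
    } else if (op == "binarize") {
      res <- binarize_target(net, data, st$variable, st$true_states, alpha = alpha)
      net <- res$network; data <- res$data; steps <- c(steps, list(res$step))
    } else if (op == "condense") {
      derived <- bn_variable(st$derived$name, st$derived$states,
                             if (is.null(st$derived$role)) "diagnostic" else st$derived$role)
      rule <- condensation_rule(unlist(st$sources), derived, st$mapping)
      res <- condense_variables(net, data, rule, alpha = alpha)
      net <- res$network; data <- res$data; steps <- c(steps, list(res$step))
    } else if (op == "add_edge") {
      net <- add_edge(net, st$from, st$to)
      net <- relearn_vars(net, data, st$to, alpha)
    } else if (op == "resolve_transitivity") {
      res <- resolve_transitivity(net, unlist(st$targets))
      net <- res$network
      net <- relearn_vars(net, data, unique(res$removed[, "child"]), alpha)
      steps <- c(steps, list(res$step))
    } else if (op == "noisy_or") {
      spec <- noisy_or_spec(st$effect, unlist(st$causes), unlist(st$links), st$leak)
      res <- apply_noisy_or(net, spec)
      net <- res$network; steps <- c(steps, list(res$step))
    } else {
      stop(sprintf("unsupported recipe operator '%s'", op), call. = FALSE)
    }
  }
  list(network = net, data = data, steps = steps)
}
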