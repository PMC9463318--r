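#' Define a discrete clinical variable
#'
#' A variable (network node) is a named clinical concept with an ordered set of
#' categorical states and a role in the decision model. State order matters:
#' it fixes CPT column order, serialization order and the deterministic
#' tie-break used by [predict_map()] (first declared state wins).
#'
#' @param name Unique, non-empty variable name. Names double as CSV column
#'   headers and XDSL node ids, so stick to letters, digits and underscores.
#' @param states Character vector of at least two unique state labels. A
#'   Boolean target must use exactly `c("true", "false")`, in that order.
#' @param role One of `"diagnostic"` (observed patient/tumour characteristic),
#'   `"intermediate"` (inferred summary concept) or `"target"` (therapy-option
#'   node evaluated during cross-validation).
#' @return An object of class `bn_variable`.
#' @examples
#' bn_variable("p16_status", c("positive", "negative"))
#' bn_variable("surgery", c("true", "false"), role = "target")
#' @export
bn_variable <- function(name, states, role = c("diagnostic", "intermediate", "target")) {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("variable name must be a single non-empty string", call. = FALSE)
  }
  states <- as.character(states)
  if (length(states) < 2L) {
    stop(sprintf("variable '%s' needs at least 2 states", name), call. = FALSE)
  }
  if (anyDuplicated(states)) {
    stop(sprintf("variable '%s' has duplicated state labels", name), call. = FALSE)
  }
  if (any(grepl(",", states, fixed = TRUE))) {
    stop(sprintf("variable '%s': state labels must not contain commas", name), call. = FALSE)
  }
  structure(list(name = name, states = states, role = role), class = "bn_variable")
}

#' @export
print.bn_variable <- function(x, ...) {
  cat(sprintf("<%s> [%s]: %s\n", x$name, x$role, paste(x$states, collapse = ", ")))
  invisible(x)
}

## Internal CPT constructor. `prob` is a matrix with one row per configuration
## of the parents (first parent varying fastest, R column-major convention) and
## one column per child state. `fixed` marks canonical (expert-set) tables that
## parameter learning must not overwrite.
new_cpt <- function(child, parents, prob, fixed = FALSE) {
  structure(list(child = child, parents = parents, prob = prob, fixed = fixed),
            class = "bn_cpt")
}

uniform_cpt <- function(net, child) {
  parents <- net$parents[[child]]
  n_row <- prod(vapply(parents, function(p) length(net$variables[[p]]$states), 1L))
  n_col <- length(net$variables[[child]]$states)
  prob <- matrix(1 / n_col, nrow = n_row, ncol = n_col,
                 dimnames = list(NULL, net$variables[[child]]$states))
  new_cpt(child, parents, prob)
}

check_cpt <- function(net, cpt, tol = 1e-9) {
  child <- cpt$child
  card <- vapply(cpt$parents, function(p) length(net$variables[[p]]$states), 1L)
  n_row <- prod(card)
  if (nrow(cpt$prob) != n_row) {
    stop(sprintf("CPT for '%s': expected %d rows (product of parent cardinalities), got %d",
                 child, n_row, nrow(cpt$prob)), call. = FALSE)
  }
  if (ncol(cpt$prob) != length(net$variables[[child]]$states)) {
    stop(sprintf("CPT for '%s': column count does not match state count", child),
         call. = FALSE)
  }
  if (any(cpt$prob < -tol) || any(cpt$prob > 1 + tol)) {
    stop(sprintf("CPT for '%s': entries outside [0, 1]", child), call. = FALSE)
  }
  sums <- rowSums(cpt$prob)
  if (any(abs(sums - 1) > tol)) {
    stop(sprintf("CPT for '%s': row(s) %s do not sum to 1 (max deviation %.3g)",
                 child, paste(utils::head(which(abs(sums - 1) > tol), 3L), collapse = ","),
                 max(abs(sums - 1))), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a discrete Bayesian network
#'
#' Assembles variables and directed edges into a Bayesian network, the data
#' structure underlying every clinical decision model in this package. Each
#' node receives a uniform CPT pending parameter learning (see [bn_fit()] /
#' [learn_cpts()]); the graph is checked for acyclicity.
#'
#' @param variables List of [bn_variable()] objects.
#' @param edges Two-column character matrix (or data.frame) of directed
#'   `parent -> child` pairs; may be `NULL` for an edgeless network.
#' @return An object of class `bn`: a list with named elements `variables`
#'   (named list), `parents` (named list of ordered parent vectors) and
#'   `cpts` (named list of CPTs).
#' @examples
#' net <- bn_network(
#'   list(bn_variable("A", c("a1", "a2")), bn_variable("B", c("b1", "b2"))),
#'   edges = rbind(c("A", "B"))
#' )
#' net
#' @export
bn_network <- function(variables, edges = NULL) {
  if (inherits(variables, "bn_variable")) variables <- list(variables)
  names(variables) <- vapply(variables, function(v) v$name, "")
  if (anyDuplicated(names(variables))) {
    stop("duplicated variable names", call. = FALSE)
  }
  parents <- stats::setNames(vector("list", length(variables)), names(variables))
  parents[] <- list(character(0))
  net <- structure(list(variables = variables, parents = parents, cpts = list()),
                   class = "bn")
  net$cpts <- lapply(names(variables), function(v) uniform_cpt(net, v))
  names(net$cpts) <- names(variables)
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.matrix(edges)
    for (i in seq_len(nrow(edges))) {
      net <- add_edge(net, edges[i, 1L], edges[i, 2L])
    }
  }
  net
}

bn_names <- function(net) names(net$variables)

bn_card <- function(net, vars = bn_names(net)) {
  vapply(vars, function(v) length(net$variables[[v]]$states), 1L)
}

bn_children <- function(net, var) {
  names(net$parents)[vapply(net$parents, function(p) var %in% p, TRUE)]
}

#' Edge list of a network
#'
#' @param net A `bn` object.
#' @return Two-column character matrix of `parent`, `child` pairs.
#' @export
bn_edges <- function(net) {
  out <- do.call(rbind, lapply(names(net$parents), function(ch) {
    p <- net$parents[[ch]]
    if (length(p)) cbind(parent = p, child = ch) else NULL
  }))
  if (is.null(out)) out <- matrix(character(0), 0, 2, dimnames = list(NULL, c("parent", "child")))
  out
}

bn_igraph <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(bn_edges(net), stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = bn_names(net), stringsAsFactors = FALSE)
  )
}

topo_order <- function(net) {
  ord <- igraph::topo_sort(bn_igraph(net), mode = "out")
  names(ord)
}

#' Add a directed edge to a network
#'
#' Adds `parent -> child` and re-expands the child's CPT to uniform over the
#' enlarged parent configuration space (parameters are pending re-learning).
#' Cycle introduction is rejected, reporting the offending directed path.
#'
#' @param net A `bn` object.
#' @param parent,child Variable names.
#' @return The modified network.
#' @export
add_edge <- function(net, parent, child) {
  for (v in c(parent, child)) {
    if (!v %in% bn_names(net)) stop(sprintf("unknown variable '%s'", v), call. = FALSE)
  }
  if (parent == child) stop("self-loops are not allowed", call. = FALSE)
  if (parent %in% net$parents[[child]]) {
    stop(sprintf("edge %s -> %s already present", parent, child), call. = FALSE)
  }
  # adding parent -> child creates a cycle iff child already reaches parent
  g <- bn_igraph(net)
  reach <- names(igraph::subcomponent(g, child, mode = "out"))
  if (parent %in% reach) {
    path <- igraph::shortest_paths(g, from = child, to = parent, mode = "out")$vpath[[1]]
    stop(sprintf("edge %s -> %s would create a cycle via path: %s -> %s",
                 parent, child, paste(names(path), collapse = " -> "), child),
         call. = FALSE)
  }
  net$parents[[child]] <- c(net$parents[[child]], parent)
  net$cpts[[child]] <- uniform_cpt(net, child)
  net
}

#' Count free parameters of a network
#'
#' Each node with `s` states and parent configuration space of size `r`
#' contributes `(s - 1) * r` free parameters. The exponential growth of this
#' count with the number and arity of parents is the central technical
#' motivation for model abstraction.
#'
#' @param net A `bn` object.
#' @param by_variable If `TRUE`, return the named per-variable breakdown
#'   instead of the total.
#' @return Integer total, or named integer vector.
#' @examples
#' net <- bn_network(list(bn_variable("A", c("a1", "a2"))))
#' free_parameter_count(net)  # 1
#' @export
free_parameter_count <- function(net, by_variable = FALSE) {
  per <- vapply(bn_names(net), function(v) {
    r <- prod(bn_card(net, net$parents[[v]]))
    (length(net$variables[[v]]$states) - 1L) * r
  }, 1)
  if (by_variable) per else sum(per)
}

#' Total number of states in a network
#'
#' @param net A `bn` object.
#' @return Integer sum of state counts over all variables.
#' @export
total_state_count <- function(net) sum(bn_card(net))

## Row index into a CPT for given parent state indices (first parent fastest).
## `idx` may be a matrix (rows = cases, cols = parents in CPT parent order).
parent_row_index <- function(card, idx) {
  if (length(card) == 0L) return(if (is.matrix(idx)) rep(1L, nrow(idx)) else 1L)
  if (!is.matrix(idx)) idx <- matrix(idx, nrow = 1L)
  stride <- cumprod(c(1L, card[-length(card)]))
  as.integer(1L + (idx - 1L) %*% stride)
}

## Enumerate parent configurations for a CPT as a matrix of state indices,
## row i corresponding to CPT row i.
parent_config_grid <- function(card) {
  if (length(card) == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  as.matrix(do.call(expand.grid, lapply(card, seq_len)))
}

state_index <- function(net, var, labels) {
  i <- match(labels, net$variables[[var]]$states)
  if (anyNA(i)) {
    bad <- unique(labels[is.na(i)])
    stop(sprintf("illegal state(s) for '%s': %s", var, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  i
}

check_evidence <- function(net, evidence) {
  if (length(evidence) == 0L) return(invisible(TRUE))
  if (is.null(names(evidence)) || any(!nzchar(names(evidence)))) {
    stop("evidence must be a named list/vector of variable = state", call. = FALSE)
  }
  unknown <- setdiff(names(evidence), bn_names(net))
  if (length(unknown)) {
    stop(sprintf("evidence names unknown variable(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  for (v in names(evidence)) state_index(net, v, evidence[[v]])
  invisible(TRUE)
}

#' @export
print.bn <- function(x, ...) {
  e <- bn_edges(x)
  cat(sprintf("Discrete Bayesian network: %d variables, %d edges, %d states, %d free parameters\n",
              length(x$variables), nrow(e), total_state_count(x), free_parameter_count(x)))
  roles <- vapply(x$variables, function(v) v$role, "")
  cat(sprintf("  roles: %d diagnostic, %d intermediate, %d target\n",
              sum(roles == "diagnostic"), sum(roles == "intermediate"), sum(roles == "target")))
  invisible(x)
}

#' @export
summary.bn <- function(object, ...) {
  per <- free_parameter_count(object, by_variable = TRUE)
  df <- data.frame(
    variable = bn_names(object),
    role = vapply(object$variables, function(v) v$role, ""),
    states = as.integer(bn_card(object)),
    parents = vapply(object$parents, function(p) paste(p, collapse = ","), ""),
    parent_configs = vapply(bn_names(object), function(v)
      as.integer(prod(bn_card(object, object$parents[[v]]))), 1L),
    free_parameters = as.integer(per),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(df) <- c("summary.bn", class(df))
  df
}

## Validate the whole network object (used after load and in tests).
validate_network <- function(net, tol = 1e-9) {
  stopifnot(inherits(net, "bn"))
  topo_order(net)  # errors on cycles
  for (v in bn_names(net)) {
    cpt <- net$cpts[[v]]
    if (is.null(cpt)) stop(sprintf("variable '%s' has no CPT", v), call. = FALSE)
    if (!identical(cpt$parents, net$parents[[v]])) {
      stop(sprintf("CPT parent list for '%s' does not match edge set", v), call. = FALSE)
    }
    check_cpt(net, cpt, tol = tol)
  }
  invisible(TRUE)
}
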