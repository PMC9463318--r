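#' Joint probability of a complete assignment
#'
#' Chain-rule product over the DAG: the probability of one fully specified
#' patient configuration is the product, over all variables, of the CPT entry
#' for the variable's state given its parents' states.
#'
#' @param net A `bn` object with valid CPTs.
#' @param assignment Named list/vector assigning a state label to every
#'   variable in the network.
#' @return A probability in `[0, 1]`.
#' @export
joint_probability <- function(net, assignment) {
  missing <- setdiff(bn_names(net), names(assignment))
  if (length(missing)) {
    stop(sprintf("assignment is not complete; missing: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  check_evidence(net, assignment)
  idx <- vapply(bn_names(net), function(v) state_index(net, v, assignment[[v]]), 1L)
  joint_from_index(net, matrix(idx, nrow = 1L, dimnames = list(NULL, bn_names(net))))
}

## Vectorised chain-rule product. `idx` is a matrix of state indices with one
## column per network variable (named) and one row per assignment.
joint_from_index <- function(net, idx) {
  p <- rep(1, nrow(idx))
  for (v in bn_names(net)) {
    cpt <- net$cpts[[v]]
    card <- bn_card(net, cpt$parents)
    row <- parent_row_index(card, idx[, cpt$parents, drop = FALSE])
    p <- p * cpt$prob[cbind(row, idx[, v])]
  }
  p
}

#' Exact posterior by exhaustive enumeration
#'
#' Brute-force oracle: sums [joint_probability()] over all completions of the
#' unobserved variables, then renormalizes. Exponential in the number of
#' unobserved variables — intended for small networks and as the reference
#' against which [infer_posterior()] (variable elimination) is verified.
#'
#' @param net A `bn` object.
#' @param evidence Named list/vector of observed `variable = state` pairs
#'   (may be empty).
#' @param query Name of the query variable; must not appear in `evidence`.
#' @return Named numeric vector over the query's states, summing to 1.
#' @export
enumerate_posterior <- function(net, evidence = list(), query) {
  evidence <- as.list(evidence)
  check_evidence(net, evidence)
  if (query %in% names(evidence)) stop("query variable is part of the evidence", call. = FALSE)
  if (!query %in% bn_names(net)) stop(sprintf("unknown variable '%s'", query), call. = FALSE)
  vars <- bn_names(net)
  free <- setdiff(vars, names(evidence))
  grid <- as.matrix(do.call(expand.grid, lapply(bn_card(net, free), seq_len)))
  colnames(grid) <- free
  idx <- matrix(0L, nrow = nrow(grid), ncol = length(vars), dimnames = list(NULL, vars))
  idx[, free] <- grid
  for (v in names(evidence)) idx[, v] <- state_index(net, v, evidence[[v]])
  p <- joint_from_index(net, idx)
  states <- net$variables[[query]]$states
  post <- vapply(seq_along(states), function(s) sum(p[idx[, query] == s]), 1)
  total <- sum(post)
  if (total <= 0) {
    stop(sprintf("impossible evidence: P(evidence) = 0 while querying '%s'", query),
         call. = FALSE)
  }
  stats::setNames(post / total, states)
}

## ---- factor algebra for variable elimination ------------------------------

## A factor is list(vars, card, val) with val laid out column-major over vars
## (first listed variable varying fastest).
factor_assign <- function(f, var) {
  j <- match(var, f$vars)
  stride <- prod(f$card[seq_len(j - 1L)])
  (((seq_along(f$val) - 1L) %/% stride) %% f$card[j]) + 1L
}

factor_from_cpt <- function(net, v) {
  cpt <- net$cpts[[v]]
  vars <- c(cpt$parents, v)
  card <- c(bn_card(net, cpt$parents), length(net$variables[[v]]$states))
  # prob matrix is [parent configs x child states], parent configs first-fastest:
  # flattening column-major gives exactly vars = (parents..., child) layout
  list(vars = unname(vars), card = unname(card), val = as.vector(cpt$prob))
}

factor_reduce <- function(f, var, state_idx) {
  if (!var %in% f$vars) return(f)
  keep <- factor_assign(f, var) == state_idx
  j <- match(var, f$vars)
  list(vars = f$vars[-j], card = f$card[-j], val = f$val[keep])
}

factor_product <- function(f1, f2) {
  vars <- union(f1$vars, f2$vars)
  card <- integer(length(vars))
  card[match(f1$vars, vars)] <- f1$card
  card[match(f2$vars, vars)] <- f2$card
  n <- prod(card)
  pos <- seq_len(n) - 1L
  stride <- cumprod(c(1L, card[-length(card)]))
  input_index <- function(f) {
    if (length(f$vars) == 0L) return(rep(1L, n))
    idx <- rep(0L, n)
    s_in <- cumprod(c(1L, f$card[-length(f$card)]))
    for (k in seq_along(f$vars)) {
      j <- match(f$vars[k], vars)
      a <- (pos %/% stride[j]) %% card[j]
      idx <- idx + a * s_in[k]
    }
    idx + 1L
  }
  list(vars = vars, card = card, val = f1$val[input_index(f1)] * f2$val[input_index(f2)])
}

factor_marginalize <- function(f, var) {
  j <- match(var, f$vars)
  vars <- f$vars[-j]
  card <- f$card[-j]
  if (length(vars) == 0L) {
    return(list(vars = character(0), card = integer(0), val = sum(f$val)))
  }
  n_res <- prod(card)
  pos <- seq_along(f$val) - 1L
  s_in <- cumprod(c(1L, f$card[-length(f$card)]))
  res_stride <- cumprod(c(1L, card[-length(card)]))
  res_idx <- rep(0L, length(f$val))
  for (k in seq_along(vars)) {
    a <- (pos %/% s_in[match(vars[k], f$vars)]) %% card[match(vars[k], vars)]
    res_idx <- res_idx + a * res_stride[k]
  }
  sums <- rowsum(f$val, res_idx + 1L)
  val <- numeric(n_res)
  val[as.integer(rownames(sums))] <- sums[, 1L]
  list(vars = vars, card = card, val = val)
}

#' Exact posterior by variable elimination
#'
#' Production inference routine: reduces all CPT factors by the evidence, then
#' eliminates unobserved non-query variables one at a time using a greedy
#' min-degree ordering (the variable whose elimination touches the smallest
#' joint scope is removed first). Exact — the ordering affects speed only.
#' Agrees with [enumerate_posterior()] to numerical precision.
#'
#' @inheritParams enumerate_posterior
#' @return Named numeric vector over the query's states, summing to 1.
#' @export
infer_posterior <- function(net, evidence = list(), query) {
  evidence <- as.list(evidence)
  check_evidence(net, evidence)
  if (query %in% names(evidence)) stop("query variable is part of the evidence", call. = FALSE)
  if (!query %in% bn_names(net)) stop(sprintf("unknown variable '%s'", query), call. = FALSE)

  factors <- lapply(bn_names(net), function(v) factor_from_cpt(net, v))
  for (v in names(evidence)) {
    s <- state_index(net, v, evidence[[v]])
    factors <- lapply(factors, factor_reduce, var = v, state_idx = s)
  }
  hidden <- setdiff(bn_names(net), c(names(evidence), query))
  while (length(hidden)) {
    # min-degree: smallest union scope among factors mentioning the variable
    scope_size <- vapply(hidden, function(h) {
      touching <- factors[vapply(factors, function(f) h %in% f$vars, TRUE)]
      length(unique(unlist(lapply(touching, `[[`, "vars"))))
    }, 1L)
    h <- hidden[which.min(scope_size)]
    hidden <- setdiff(hidden, h)
    touch <- vapply(factors, function(f) h %in% f$vars, TRUE)
    if (!any(touch)) next
    prod_f <- Reduce(factor_product, factors[touch])
    factors <- c(factors[!touch], list(factor_marginalize(prod_f, h)))
  }
  res <- Reduce(factor_product, factors)
  states <- net$variables[[query]]$states
  if (length(res$vars) == 0L) {
    # query factor got fully absorbed: should not happen, guard anyway
    stop("internal error: query eliminated", call. = FALSE)
  }
  perm <- if (identical(res$vars, query)) res$val else {
    stop("internal error: stray variables after elimination", call. = FALSE)
  }
  total <- sum(perm)
  if (total <= 0) {
    stop(sprintf("impossible evidence: P(evidence) = 0 while querying '%s'", query),
         call. = FALSE)
  }
  stats::setNames(perm / total, states)
}

#' Maximum-a-posteriori prediction for a target node
#'
#' Returns the posterior-maximal state of `target` given the evidence. Ties
#' are broken deterministically in favour of the earlier declared state, which
#' for a Boolean target `c("true","false")` is equivalent to predicting "true"
#' at posterior threshold 0.5.
#'
#' @inheritParams enumerate_posterior
#' @param target Name of the target variable.
#' @return A single state label.
#' @export
predict_map <- function(net, evidence = list(), target) {
  post <- infer_posterior(net, evidence, target)
  names(post)[which.max(post)]
}
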