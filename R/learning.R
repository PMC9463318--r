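## Dataset validation: complete categorical records whose column names and cell
## values match node names and state labels exactly (case-sensitive).
validate_dataset <- function(net, data, require_all = TRUE) {
  if (!is.data.frame(data)) stop("dataset must be a data.frame", call. = FALSE)
  unknown <- setdiff(names(data), bn_names(net))
  if (length(unknown)) {
    stop(sprintf("dataset column(s) not in network: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (require_all) {
    missing <- setdiff(bn_names(net), names(data))
    if (length(missing)) {
      stop(sprintf("dataset lacks network variable(s): %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    }
  }
  for (v in names(data)) {
    cells <- as.character(data[[v]])
    if (anyNA(cells) || any(!nzchar(cells))) {
      rows <- which(is.na(cells) | !nzchar(cells))
      stop(sprintf("missing cell(s) in column '%s' at row(s) %s (complete records required)",
                   v, paste(utils::head(rows, 5L), collapse = ",")), call. = FALSE)
    }
    bad <- !cells %in% net$variables[[v]]$states
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("illegal value '%s' at (row %d, column '%s'); legal states: %s",
                   cells[i], i, v, paste(net$variables[[v]]$states, collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

## Dataset as matrix of state indices, columns = vars (validated beforehand).
dataset_index <- function(net, data, vars = names(data)) {
  idx <- vapply(vars, function(v) match(as.character(data[[v]]), net$variables[[v]]$states),
                integer(nrow(data)))
  if (!is.matrix(idx)) idx <- matrix(idx, nrow = nrow(data), dimnames = list(NULL, vars))
  idx
}

#' Tabulate child-state counts per parent configuration
#'
#' @param net A `bn` object (supplies state spaces).
#' @param data Complete categorical data.frame.
#' @param child Child variable name.
#' @param parents Character vector of parent names (possibly empty).
#' @return Integer matrix, one row per parent configuration (first parent
#'   varying fastest), one column per child state; `sum(counts) == nrow(data)`.
#' @export
count_table <- function(net, data, child, parents = net$parents[[child]]) {
  for (v in c(child, parents)) {
    if (!v %in% names(data)) stop(sprintf("unknown dataset column '%s'", v), call. = FALSE)
  }
  validate_dataset(net, data[, c(child, parents), drop = FALSE], require_all = FALSE)
  card <- bn_card(net, parents)
  n_row <- prod(card)
  states <- net$variables[[child]]$states
  counts <- matrix(0L, nrow = n_row, ncol = length(states),
                   dimnames = list(NULL, states))
  if (nrow(data)) {
    idx <- dataset_index(net, data, c(parents, child))
    row <- parent_row_index(card, idx[, parents, drop = FALSE])
    tab <- table(factor(row, levels = seq_len(n_row)),
                 factor(idx[, child], levels = seq_along(states)))
    counts[] <- as.integer(tab)
  }
  counts
}

#' Learn conditional probability tables from complete records
#'
#' Closed-form maximum-likelihood estimation with Dirichlet pseudocount
#' smoothing: each CPT row becomes `(count + alpha) / (row_total + alpha * s)`
#' where `s` is the child's state count. With `alpha = 0` a parent
#' configuration never observed in the data yields an undefined row; it is set
#' uniform and flagged (see the `unseen` attribute and [fit_report()]), the
#' sparse-data failure mode that motivates model abstraction.
#'
#' CPTs marked `fixed` (canonical gates installed by [apply_noisy_or()]) are
#' left untouched.
#'
#' @param net A `bn` object.
#' @param data Complete data.frame covering every network variable.
#' @param alpha Pseudocount `>= 0` added per child state per configuration.
#' @return The network with fitted CPTs; attribute `unseen` holds, per
#'   variable, the indices of parent configurations unobserved in `data`.
#' @export
learn_cpts <- function(net, data, alpha = 1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha), alpha >= 0)
  validate_dataset(net, data)
  unseen <- list()
  for (v in bn_names(net)) {
    if (isTRUE(net$cpts[[v]]$fixed)) next
    counts <- count_table(net, data, v)
    s <- ncol(counts)
    totals <- rowSums(counts)
    prob <- (counts + alpha) / (totals + alpha * s)
    zero <- which(totals == 0L)
    if (length(zero)) {
      unseen[[v]] <- zero
      if (alpha == 0) prob[zero, ] <- 1 / s
    }
    dimnames(prob) <- list(NULL, net$variables[[v]]$states)
    net$cpts[[v]] <- new_cpt(v, net$parents[[v]], prob)
  }
  attr(net, "unseen") <- unseen
  net
}

#' Coverage of parent configurations by a dataset
#'
#' For each variable, the fraction of its parent configurations observed at
#' least once — a "density of information" diagnostic. Values well below 1 on
#' high-arity nodes signal that learned CPTs will be dominated by the prior /
#' uniform fallback for the unobserved rows.
#'
#' @param net A `bn` object.
#' @param data Complete data.frame covering every network variable.
#' @return Object of class `bn_fit_report`: data.frame with columns
#'   `variable`, `parent_configs`, `observed`, `coverage`; attribute
#'   `min_coverage`.
#' @export
fit_report <- function(net, data) {
  validate_dataset(net, data)
  rows <- lapply(bn_names(net), function(v) {
    counts <- count_table(net, data, v)
    n_cfg <- nrow(counts)
    obs <- sum(rowSums(counts) > 0L)
    data.frame(variable = v, parent_configs = n_cfg, observed = obs,
               coverage = obs / n_cfg, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "min_coverage") <- min(out$coverage)
  class(out) <- c("bn_fit_report", class(out))
  out
}

#' @export
print.bn_fit_report <- function(x, ...) {
  cat(sprintf("Parent-configuration coverage (min %.3f):\n", attr(x, "min_coverage")))
  print.data.frame(x[order(x$coverage), ], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Fit a clinical decision model to patient records
#'
#' The package's central fitting function: takes an expert-specified network
#' structure and a table of complete categorical patient records and estimates
#' all conditional probability tables by smoothed maximum likelihood
#' ([learn_cpts()]). The returned object supports `print`, `summary`, `coef`,
#' `predict`, `simulate` and `logLik`.
#'
#' @param net A `bn` structure (CPT values are ignored except `fixed` ones).
#' @param data Complete data.frame; column names and cell values must match
#'   node names and state labels exactly.
#' @param alpha Pseudocount for Dirichlet smoothing (default 1).
#' @return Object of class `bn_fit` with elements `network` (fitted `bn`),
#'   `alpha`, `n`, `report` (coverage, see [fit_report()]).
#' @examples
#' net <- bn_network(
#'   list(bn_variable("A", c("a1", "a2")), bn_variable("B", c("b1", "b2"))),
#'   edges = rbind(c("A", "B"))
#' )
#' d <- data.frame(A = c("a1", "a1", "a2"), B = c("b1", "b2", "b2"))
#' fit <- bn_fit(net, d, alpha = 0)
#' coef(fit)$B$prob
#' @export
bn_fit <- function(net, data, alpha = 1) {
  fitted <- learn_cpts(net, data, alpha = alpha)
  structure(list(network = fitted, alpha = alpha, n = nrow(data),
                 report = fit_report(net, data)),
            class = "bn_fit")
}

#' @export
print.bn_fit <- function(x, ...) {
  cat(sprintf("Fitted clinical decision model (n = %d records, alpha = %g)\n", x$n, x$alpha))
  print(x$network)
  unseen <- attr(x$network, "unseen")
  if (length(unseen)) {
    cat(sprintf("  %d variable(s) with unobserved parent configurations; min coverage %.3f\n",
                length(unseen), attr(x$report, "min_coverage")))
  }
  invisible(x)
}

#' @export
summary.bn_fit <- function(object, ...) {
  s <- summary(object$network)
  s$coverage <- object$report$coverage[match(s$variable, object$report$variable)]
  s
}

#' @export
coef.bn_fit <- function(object, ...) object$network$cpts

#' Predict target states for new patients
#'
#' @param object A `bn_fit`.
#' @param newdata Data.frame of evidence columns (must not contain `target`).
#' @param target Target variable name.
#' @param type `"state"` for MAP labels, `"prob"` for the posterior matrix.
#' @param ... Unused.
#' @export
predict.bn_fit <- function(object, newdata, target,
                           type = c("state", "prob"), ...) {
  type <- match.arg(type)
  net <- object$network
  if (target %in% names(newdata)) newdata <- newdata[setdiff(names(newdata), target)]
  validate_dataset(net, newdata, require_all = FALSE)
  post <- t(vapply(seq_len(nrow(newdata)), function(i) {
    ev <- as.list(newdata[i, , drop = FALSE])
    infer_posterior(net, ev, target)
  }, numeric(length(net$variables[[target]]$states))))
  colnames(post) <- net$variables[[target]]$states
  if (type == "prob") return(post)
  colnames(post)[max.col(post, ties.method = "first")]
}

#' @export
simulate.bn_fit <- function(object, nsim = 1, seed = NULL, ...) {
  ancestral_sample(object$network, n = nsim, seed = seed)
}

#' @export
logLik.bn_fit <- function(object, data, ...) {
  validate_dataset(object$network, data)
  idx <- dataset_index(object$network, data, bn_names(object$network))
  ll <- sum(log(joint_from_index(object$network, idx)))
  structure(ll, df = free_parameter_count(object$network), nobs = nrow(data),
            class = "logLik")
}
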