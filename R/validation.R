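#' Assign records to cross-validation folds
#'
#' Shuffled round-robin assignment: records are permuted with the given seed
#' and dealt into `k` folds whose sizes differ by at most one. Deterministic
#' given `(n, k, seed)`; the caller's RNG state is left untouched.
#'
#' @param n Number of records.
#' @param k Number of folds, `1 < k <= n`.
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1..k`, one per record.
#' @export
make_folds <- function(n, k, seed) {
  if (k <= 1L || k > n) stop(sprintf("need 1 < k <= n, got k = %d, n = %d", k, n),
                             call. = FALSE)
  withr::with_seed(as.integer(seed), {
    perm <- sample.int(n)
    folds <- integer(n)
    folds[perm] <- rep_len(seq_len(k), n)
    folds
  })
}

#' Micro-averaged accuracy
#'
#' Correct predictions pooled over all (patient, target-node) pairs divided by
#' their total count — the aggregation behind the headline accuracies of the
#' three model versions (e.g. 249/470, 283/470, 332/376).
#'
#' @param correct,total Non-negative counts, `correct <= total`, `total > 0`.
#' @return The exact proportion `correct / total` (format with 3 decimals for
#'   reporting).
#' @export
micro_accuracy <- function(correct, total) {
  if (total <= 0) stop("total must be positive", call. = FALSE)
  if (correct < 0 || correct > total) stop("need 0 <= correct <= total", call. = FALSE)
  correct / total
}

#' ROC curve points from posterior scores
#'
#' Sweeps a decision threshold over the distinct score values (ties grouped),
#' yielding a curve of (false positive rate, true positive rate) points from
#' (0,0) to (1,1), monotone in both coordinates.
#'
#' @param scores Numeric vector of posterior probabilities of the positive
#'   state.
#' @param labels Logical vector (or 0/1) of true positives.
#' @return Data.frame with columns `threshold`, `fpr`, `tpr`. The leading
#'   (0,0) point carries threshold `Inf`. Attribute `degenerate` is `TRUE`
#'   when only one class is present.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  P <- sum(labels); N <- sum(!labels)
  degenerate <- P == 0L || N == 0L
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  thr <- unique(s)
  tp <- cumsum(l); fp <- cumsum(!l)
  last_of_group <- cumsum(rle(s)$lengths)
  out <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, if (N > 0) fp[last_of_group] / N else rep(0, length(thr))),
    tpr = c(0, if (P > 0) tp[last_of_group] / P else rep(0, length(thr)))
  )
  attr(out, "degenerate") <- degenerate
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_points()]; numerically identical to the
#' tie-corrected concordance probability
#' `P(score+ > score-) + 0.5 * P(score+ = score-)`. With a single observed
#' class the AUC is undefined: `NA` is returned with a `degenerate` attribute
#' reporting the class counts — the failure mode of a therapy option with
#' almost no positive patients.
#'
#' @inheritParams roc_points
#' @return AUC in `[0, 1]`, or `NA` (flagged) for one-class input.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  P <- sum(labels); N <- sum(!labels)
  if (P == 0L || N == 0L) {
    return(structure(NA_real_, degenerate = TRUE, n_positive = P, n_negative = N))
  }
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' Cross-validate a decision-model structure on patient records
#'
#' Tenfold (by default) cross-validation of the full learn-and-predict cycle:
#' for every fold, CPTs are learned on the remaining folds ([learn_cpts()]);
#' for every held-out patient and every target node, the posterior of the
#' target given evidence on *all non-target variables* is computed by exact
#' inference, the MAP state is compared with the recorded state, and the
#' posterior of the positive state is kept as the ROC score. Other target
#' nodes are never used as evidence for each other (no therapy decision is
#' known in advance in clinical use).
#'
#' @param net A `bn` structure.
#' @param data Complete data.frame covering every network variable.
#' @param targets Character vector of evaluated target node names.
#' @param k Fold count (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param alpha Pseudocount for CPT learning.
#' @param positive Named character vector mapping target name to its positive
#'   state for ROC purposes; defaults to each target's first declared state
#'   (the "true"/eligible state).
#' @return Object of class `bn_cv`: list with `targets`, `per_target`
#'   (data.frame of correct/total, AUC, degeneracy flags), `overall_correct`,
#'   `overall_total`, `accuracy`, `folds`, `scores` (long data.frame with one
#'   row per patient x target: fold, score, truth, predicted, correct),
#'   `roc` (named list of [roc_points()] frames), and the call parameters.
#' @export
cross_validate <- function(net, data, targets, k = 10, seed = 1, alpha = 1,
                           positive = NULL) {
  validate_dataset(net, data)
  missing <- setdiff(targets, bn_names(net))
  if (length(missing)) {
    stop(sprintf("target(s) not in network: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  n <- nrow(data)
  folds <- make_folds(n, k, seed)
  if (is.null(positive)) {
    positive <- vapply(targets, function(t) net$variables[[t]]$states[1L], "")
  }
  evidence_vars <- setdiff(bn_names(net), targets)

  rows <- vector("list", n * length(targets))
  ri <- 0L
  for (f in seq_len(k)) {
    train <- data[folds != f, , drop = FALSE]
    test <- data[folds == f, , drop = FALSE]
    if (nrow(train) == 0L) stop(sprintf("fold %d has an empty training set", f),
                                call. = FALSE)
    fitted <- learn_cpts(net, train, alpha = alpha)
    for (i in seq_len(nrow(test))) {
      ev <- as.list(test[i, evidence_vars, drop = FALSE])
      for (t in targets) {
        post <- infer_posterior(fitted, ev, t)
        pred <- names(post)[which.max(post)]
        truth <- as.character(test[[t]][i])
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          fold = f, target = t,
          score = unname(post[[positive[[t]]]]),
          truth = truth, predicted = pred,
          positive = truth == positive[[t]],
          correct = pred == truth,
          stringsAsFactors = FALSE)
      }
    }
  }
  scores <- do.call(rbind, rows)
  per_target <- do.call(rbind, lapply(targets, function(t) {
    s <- scores[scores$target == t, ]
    a <- auc_score(s$score, s$positive)
    data.frame(target = t, correct = sum(s$correct), total = nrow(s),
               accuracy = mean(s$correct),
               n_positive = sum(s$positive),
               auc = as.numeric(a),
               degenerate = isTRUE(attr(a, "degenerate")),
               stringsAsFactors = FALSE)
  }))
  roc <- lapply(stats::setNames(targets, targets), function(t) {
    s <- scores[scores$target == t, ]
    roc_points(s$score, s$positive)
  })
  structure(list(
    targets = targets, per_target = per_target,
    overall_correct = sum(per_target$correct),
    overall_total = n * length(targets),
    accuracy = micro_accuracy(sum(per_target$correct), n * length(targets)),
    folds = folds, scores = scores, roc = roc,
    k = k, seed = seed, alpha = alpha, positive = positive,
    n_records = n
  ), class = "bn_cv")
}

#' @export
print.bn_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %d records x %d targets\n",
              x$k, x$n_records, length(x$targets)))
  cat(sprintf("Overall accuracy: %.3f (%d of %d correct)\n",
              x$accuracy, x$overall_correct, x$overall_total))
  df <- x$per_target
  df$accuracy <- sprintf("%.3f", df$accuracy)
  df$auc <- ifelse(df$degenerate | is.na(df$auc), "undefined", sprintf("%.3f", df$auc))
  print.data.frame(df[, c("target", "correct", "total", "accuracy", "n_positive", "auc")],
                   row.names = FALSE)
  invisible(x)
}
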