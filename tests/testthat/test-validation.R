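test_that("fold assignment is balanced, reproducible and validated", {
  f <- make_folds(94, 10, seed = 1)
  sizes <- tabulate(f, 10)
  expect_equal(sort(unique(sizes)), c(9, 10))
  expect_equal(sum(sizes == 10), 4)   # 94 = 4*10 + 6*9
  expect_equal(sum(sizes == 9), 6)
  expect_identical(f, make_folds(94, 10, seed = 1))
  expect_false(identical(f, make_folds(94, 10, seed = 2)))
  expect_equal(sort(make_folds(5, 5, seed = 3)), 1:5)  # n = k: one each
  expect_error(make_folds(5, 6, seed = 1), "k <= n")
  expect_error(make_folds(5, 1, seed = 1), "k <= n")
})

test_that("micro accuracy reproduces the printed worked examples", {
  expect_lt(abs(micro_accuracy(249, 470) - 0.529), 1e-3)
  expect_lt(abs(micro_accuracy(283, 470) - 0.602), 1e-3)
  expect_lt(abs(micro_accuracy(332, 376) - 0.883), 1e-3)
  expect_equal(micro_accuracy(0, 100), 0)
  expect_error(micro_accuracy(1, 0), "positive")
  expect_error(micro_accuracy(5, 4), "correct <= total")
})

test_that("ROC points sweep thresholds with grouped ties", {
  # perfectly separated scores pass through (0, 1)
  sep <- roc_points(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(any(sep$fpr == 0 & sep$tpr == 1))
  expect_equal(sep$fpr[1], 0); expect_equal(sep$tpr[1], 0)
  expect_equal(sep$fpr[nrow(sep)], 1); expect_equal(sep$tpr[nrow(sep)], 1)

  # all scores tied: a single group, two points
  tied <- roc_points(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(nrow(tied), 2L)
  expect_equal(tied$fpr, c(0, 1)); expect_equal(tied$tpr, c(0, 1))

  # 4-record hand case: thresholds 0.9, 0.8, 0.4, 0.2
  hand <- roc_points(c(0.9, 0.8, 0.4, 0.2), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(hand$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(hand$tpr, c(0, 0.5, 0.5, 1, 1))
  expect_true(all(diff(hand$fpr) >= 0) && all(diff(hand$tpr) >= 0))
})

test_that("trapezoidal AUC equals the tie-corrected concordance statistic", {
  concordance <- function(scores, labels) {
    pos <- scores[labels]; neg <- scores[!labels]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_score(rep(0.5, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_equal(auc_score(c(0.9, 0.8, 0.4, 0.2), c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  withr::with_seed(17, {
    for (i in 1:50) {
      n <- sample(5:60, 1)
      scores <- round(stats::runif(n), sample(1:3, 1))  # force ties
      labels <- stats::runif(n) < 0.4
      if (sum(labels) == 0 || sum(labels) == n) next
      expect_lt(abs(auc_score(scores, labels) - concordance(scores, labels)), 1e-12)
    }
  })
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(23, {
    for (i in 1:10) {
      scores <- stats::runif(40)
      labels <- stats::runif(40) < 0.5
      if (sum(labels) %in% c(0, 40)) next
      ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
        response = as.integer(labels), predictor = scores,
        levels = c(0, 1), direction = "<"))))
      expect_equal(auc_score(scores, labels), ref, tolerance = 1e-12)
    }
  })
})

test_that("one-class input yields a flagged undefined AUC with counts", {
  a <- auc_score(c(0.2, 0.7), c(TRUE, TRUE))
  expect_true(is.na(a))
  expect_true(attr(a, "degenerate"))
  expect_equal(attr(a, "n_positive"), 2L)
  expect_equal(attr(a, "n_negative"), 0L)
})

test_that("cross-validation is perfect on deterministically labelled data", {
  net <- bn_network(list(bn_variable("A", c("a1", "a2")),
                         bn_variable("B", c("b1", "b2")),
                         bn_variable("T", c("true", "false"), role = "target")),
                    edges = rbind(c("A", "T"), c("B", "T")))
  withr::with_seed(31, {
    d <- data.frame(A = sample(c("a1", "a2"), 80, TRUE),
                    B = sample(c("b1", "b2"), 80, TRUE))
    d$T <- ifelse((d$A == "a1") == (d$B == "b1"), "true", "false")
  })
  # every configuration observed, labels a function of the evidence
  cv <- cross_validate(net, d, "T", k = 10, seed = 2)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$overall_total, 80)
  expect_equal(cv$per_target$auc, 1)
})

test_that("shuffled labels drive accuracy to chance", {
  net <- bn_network(list(bn_variable("A", c("a1", "a2")),
                         bn_variable("T", c("true", "false"), role = "target")),
                    edges = rbind(c("A", "T")))
  withr::with_seed(41, {
    d <- data.frame(A = sample(c("a1", "a2"), 400, TRUE),
                    T = sample(rep(c("true", "false"), 200)))
  })
  cv <- cross_validate(net, d, "T", k = 10, seed = 4)
  expect_gt(cv$accuracy, 0.4)
  expect_lt(cv$accuracy, 0.6)
})

test_that("validation reports conserve counts and reproduce bit for bit", {
  net <- bn_network(list(bn_variable("A", c("a1", "a2")),
                         bn_variable("T1", c("true", "false"), role = "target"),
                         bn_variable("T2", c("true", "false"), role = "target")),
                    edges = rbind(c("A", "T1"), c("A", "T2")))
  withr::with_seed(51, {
    d <- data.frame(A = sample(c("a1", "a2"), 37, TRUE),
                    T1 = sample(c("true", "false"), 37, TRUE),
                    T2 = sample(c("true", "false"), 37, TRUE))
  })
  cv <- cross_validate(net, d, c("T1", "T2"), k = 5, seed = 9)
  expect_equal(cv$overall_total, 37 * 2)
  expect_equal(sum(cv$per_target$total), cv$overall_total)
  expect_equal(cv$overall_correct, sum(cv$per_target$correct))
  expect_equal(nrow(cv$scores), cv$overall_total)
  cv2 <- cross_validate(net, d, c("T1", "T2"), k = 5, seed = 9)
  expect_identical(cv$scores, cv2$scores)
  expect_identical(cv$per_target, cv2$per_target)
  expect_error(cross_validate(net, d, "missing_target", k = 5, seed = 1),
               "not in network")
})

test_that("targets are never used as evidence for each other", {
  # T2 is a perfect copy of T1; if targets leaked into the evidence, T1 would
  # be predicted from T2 with certainty even though A carries no signal
  net <- bn_network(list(bn_variable("A", c("a1", "a2")),
                         bn_variable("T1", c("true", "false"), role = "target"),
                         bn_variable("T2", c("true", "false"), role = "target")),
                    edges = rbind(c("A", "T1"), c("A", "T2")))
  withr::with_seed(61, {
    d <- data.frame(A = sample(c("a1", "a2"), 200, TRUE),
                    T1 = sample(c("true", "false"), 200, TRUE))
    d$T2 <- d$T1
  })
  cv <- cross_validate(net, d, c("T1", "T2"), k = 10, seed = 3)
  acc1 <- cv$per_target$accuracy[cv$per_target$target == "T1"]
  expect_lt(acc1, 0.7)  # near chance, not near 1
})
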