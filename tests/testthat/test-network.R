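test_that("add_edge expands CPT row blocks and rejects cycles", {
  net <- bn_network(list(bn_variable("A", c("a1", "a2", "a3")),
                         bn_variable("B", c("b1", "b2"))))
  net2 <- add_edge(net, "A", "B")
  expect_equal(nrow(net2$cpts$B$prob), 3L)           # |A| row blocks
  expect_identical(net2$parents$B, "A")
  expect_error(add_edge(net2, "B", "A"), "cycle")
  expect_error(add_edge(net2, "A", "B"), "already present")
  expect_error(add_edge(net2, "A", "Z"), "unknown variable")

  net3 <- bn_network(list(bn_variable("A", c("a1", "a2", "a3")),
                          bn_variable("B", c("b1", "b2")),
                          bn_variable("C", c("c1", "c2"))),
                     edges = rbind(c("A", "C"), c("B", "C")))
  expect_equal(nrow(net3$cpts$C$prob), 3L * 2L)      # |A| * |B| rows
})

test_that("cycle errors report the offending path", {
  net <- bn_network(list(bn_variable("A", c("a1", "a2")),
                         bn_variable("B", c("b1", "b2")),
                         bn_variable("C", c("c1", "c2"))),
                    edges = rbind(c("A", "B"), c("B", "C")))
  expect_error(add_edge(net, "C", "A"), "A -> B -> C")
})

test_that("variable invariants are enforced", {
  expect_error(bn_variable("x", "only_one"), "at least 2")
  expect_error(bn_variable("x", c("a", "a")), "duplicated")
  expect_error(bn_variable("", c("a", "b")), "non-empty")
  expect_error(bn_variable("x", c("a,b", "c")), "commas")
  expect_error(bn_network(list(bn_variable("x", c("a", "b")),
                               bn_variable("x", c("a", "b")))), "duplicated")
})

test_that("free parameter count follows (s-1) * prod(parent cardinalities)", {
  one <- bn_network(list(bn_variable("A", c("t", "f"))))
  expect_equal(free_parameter_count(one), 1)

  vars <- c(lapply(1:3, function(i) bn_variable(paste0("P", i), c("t", "f"))),
            list(bn_variable("X", c("t", "f"))))
  net <- bn_network(vars, edges = cbind(paste0("P", 1:3), "X"))
  expect_equal(unname(free_parameter_count(net, by_variable = TRUE)["X"]), 8)

  vars2 <- list(bn_variable("P1", c("a", "b", "c")), bn_variable("P2", c("a", "b", "c")),
                bn_variable("X", c("s1", "s2", "s3", "s4")))
  net2 <- bn_network(vars2, edges = rbind(c("P1", "X"), c("P2", "X")))
  expect_equal(unname(free_parameter_count(net2, by_variable = TRUE)["X"]), 27)
})

test_that("joint probability is the chain-rule product", {
  one <- bn_network(list(bn_variable("A", c("a1", "a2"))))
  one$cpts$A$prob[1, ] <- c(0.3, 0.7)
  expect_equal(joint_probability(one, list(A = "a1")), 0.3)

  net <- chain_net(p_a1 = 0.5, p_b1_a1 = 0.8, p_b1_a2 = 0.3)
  expect_equal(joint_probability(net, list(A = "a1", B = "b1")), 0.4)

  zero <- chain_net(p_a1 = 0.5, p_b1_a1 = 0, p_b1_a2 = 0.3)
  expect_equal(joint_probability(zero, list(A = "a1", B = "b1")), 0)

  expect_error(joint_probability(net, list(A = "a1")), "missing: B")
  expect_error(joint_probability(net, list(A = "bad", B = "b1")), "illegal state")
})

test_that("joint probabilities over all full assignments sum to 1", {
  withr::with_seed(11, {
    for (i in 1:20) {
      net <- random_net()
      vars <- names(net$variables)
      grid <- do.call(expand.grid, lapply(vars, function(v) net$variables[[v]]$states))
      names(grid) <- vars
      total <- sum(vapply(seq_len(nrow(grid)), function(r) {
        joint_probability(net, lapply(grid[r, , drop = FALSE], as.character))
      }, 1))
      expect_lt(abs(total - 1), 1e-6)
    }
  })
})

test_that("posteriors match hand-computed Bayes results", {
  one <- bn_network(list(bn_variable("A", c("a1", "a2"))))
  one$cpts$A$prob[1, ] <- c(0.3, 0.7)
  expect_equal(enumerate_posterior(one, query = "A"),
               c(a1 = 0.3, a2 = 0.7))                  # marginal = prior

  net <- chain_net()                                   # 0.45 / 0.50
  expect_equal(enumerate_posterior(net, list(B = "b1"), "A")[["a1"]], 0.9)
  expect_equal(infer_posterior(net, list(B = "b1"), "A")[["a1"]], 0.9)
})

test_that("impossible evidence raises an explicit error, not NaN", {
  net <- chain_net(p_a1 = 1, p_b1_a1 = 1, p_b1_a2 = 0)
  expect_error(enumerate_posterior(net, list(B = "b2"), "A"), "impossible evidence")
  expect_error(infer_posterior(net, list(B = "b2"), "A"), "impossible evidence")
  expect_error(predict_map(net, list(B = "b2"), "A"), "impossible evidence")
})

test_that("variable elimination agrees with enumeration on random networks", {
  withr::with_seed(20260925, {
    for (i in 1:60) {
      net <- random_net()
      q <- sample(names(net$variables), 1)
      ev <- random_evidence(net, q, sample(0:(length(net$variables) - 1L), 1))
      pe <- tryCatch(enumerate_posterior(net, ev, q), error = function(e) e)
      pv <- tryCatch(infer_posterior(net, ev, q), error = function(e) e)
      if (inherits(pe, "error")) {
        expect_s3_class(pv, "error")
      } else {
        expect_lt(max(abs(pe - pv)), 1e-9)
        expect_lt(abs(sum(pv) - 1), 1e-9)
      }
    }
  })
})

test_that("posterior with all non-query variables observed matches enumeration", {
  withr::with_seed(99, {
    for (i in 1:10) {
      net <- random_net()
      q <- sample(names(net$variables), 1)
      ev <- random_evidence(net, q, length(net$variables) - 1L)
      pe <- tryCatch(enumerate_posterior(net, ev, q), error = function(e) e)
      if (inherits(pe, "error")) next
      expect_lt(max(abs(pe - infer_posterior(net, ev, q))), 1e-9)
    }
  })
})

test_that("MAP prediction breaks ties toward the first declared state", {
  one <- bn_network(list(bn_variable("A", c("a1", "a2"))))
  one$cpts$A$prob[1, ] <- c(0.7, 0.3)
  expect_identical(predict_map(one, list(), "A"), "a1")
  one$cpts$A$prob[1, ] <- c(0.5, 0.5)
  expect_identical(predict_map(one, list(), "A"), "a1")

  boolean <- bn_network(list(bn_variable("T", c("true", "false"), role = "target")))
  boolean$cpts$T$prob[1, ] <- c(0.49, 0.51)
  expect_identical(predict_map(boolean, list(), "T"), "false")  # 0.5 threshold
})
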