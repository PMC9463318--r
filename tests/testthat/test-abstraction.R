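abc_net <- function() {
  bn_network(list(bn_variable("A", c("a1", "a2", "a3")),
                  bn_variable("B", c("b1", "b2")),
                  bn_variable("C", c("c1", "c2"))),
             edges = rbind(c("A", "B"), c("A", "C")))
}

abc_data <- function(n = 20, seed = 6) {
  withr::with_seed(seed, {
    data.frame(A = sample(c("a1", "a2", "a3"), n, TRUE),
               B = sample(c("b1", "b2"), n, TRUE),
               C = sample(c("c1", "c2"), n, TRUE))
  })
}

test_that("identity partitions leave model and dataset unchanged", {
  net <- learn_cpts(abc_net(), abc_data(), alpha = 1)
  res <- merge_states(net, abc_data(), "A",
                      groups = list(a1 = "a1", a2 = "a2", a3 = "a3"),
                      cpt = "aggregate")
  expect_identical(res$data, abc_data())
  for (v in c("A", "B", "C")) {
    expect_equal(res$network$cpts[[v]]$prob, net$cpts[[v]]$prob)
  }
  expect_equal(res$step$before_parameters, res$step$after_parameters)
})

test_that("merging states remaps the dataset and pools counts additively", {
  net <- abc_net()
  d <- abc_data(20)
  res <- merge_states(net, d, "A", groups = list(low = c("a1", "a2"), high = "a3"))
  expect_identical(res$network$variables$A$states, c("low", "high"))
  expect_equal(nrow(res$data), nrow(d))                      # record count kept
  expect_identical(res$data$B, d$B)                          # untouched columns
  expect_identical(res$data$C, d$C)
  # merged-state marginal counts are sums of member-state counts
  expect_equal(sum(res$data$A == "low"), sum(d$A %in% c("a1", "a2")))
  expect_equal(sum(res$data$A == "high"), sum(d$A == "a3"))
  expect_error(merge_states(net, d, "A", groups = list(x = c("a1", "a2"))),
               "do not cover")
  expect_error(merge_states(net, d, "A",
                            groups = list(x = c("a1", "a2"), y = c("a2", "a3"))),
               "overlapping")
})

test_that("the eight nodal categories condense to a binary pattern", {
  cohort <- generate_cohort(cohort_config(seed = 20170301))
  net <- learn_cpts(opscc_v1_network(), cohort$data)
  res <- merge_states(net, cohort$data, "N_stage",
                      groups = list(resectable = c("N0", "N1", "N2a", "N2b", "N2c", "Nx"),
                                    unresectable = c("N3a", "N3b")))
  expect_identical(res$network$variables$N_stage$states, c("resectable", "unresectable"))
  expect_true(all(res$data$N_stage %in% c("resectable", "unresectable")))
  expect_lt(res$step$after_parameters, res$step$before_parameters)
})

test_that("merge followed by learning equals learning on the remapped data", {
  net <- abc_net()
  d <- abc_data(30, seed = 13)
  groups <- list(low = c("a1", "a2"), high = "a3")
  res <- merge_states(net, d, "A", groups, alpha = 1)
  direct <- learn_cpts(res$network, res$data, alpha = 1)
  for (v in names(res$network$variables)) {
    expect_equal(res$network$cpts[[v]]$prob, direct$cpts[[v]]$prob)
  }
})

test_that("condensation replaces sources by one observed summary", {
  # single source, identity mapping: pure rename
  net <- abc_net()
  d <- abc_data()
  rule <- condensation_rule("B", bn_variable("B2", c("b1", "b2")),
                            function(a) a[["B"]])
  res <- condense_variables(net, d, rule)
  expect_false("B" %in% names(res$network$variables))
  expect_identical(res$data$B2, d$B)

  # three binary sources mapped by OR on a 10-row toy table
  vars <- list(bn_variable("X", c("t", "f")), bn_variable("Y", c("t", "f")),
               bn_variable("Z", c("t", "f")))
  net3 <- bn_network(vars)
  withr::with_seed(3, {
    d3 <- as.data.frame(lapply(stats::setNames(nm = c("X", "Y", "Z")),
                               function(v) sample(c("t", "f"), 10, TRUE)))
  })
  rule3 <- condensation_rule(
    c("X", "Y", "Z"), bn_variable("any_t", c("t", "f")),
    list(kind = "cases",
         cases = list(list(when_any = list(X = "t", Y = "t", Z = "t"), value = "t")),
         default = "f"))
  res3 <- condense_variables(net3, d3, rule3)
  expect_identical(res3$data$any_t,
                   ifelse(d3$X == "t" | d3$Y == "t" | d3$Z == "t", "t", "f"))
  expect_identical(res3$network$parents$any_t, character(0))  # observed summary

  # mapping must be total
  bad <- condensation_rule(c("X", "Y"), bn_variable("W", c("t", "f")),
                           list(kind = "table", table = list("t|t" = "t")))
  expect_error(condense_variables(net3, d3, bad), "undefined")
})

test_that("transitivity resolution removes inter-parent edges and is idempotent", {
  # simplest resolved-transitivity shape: P_X -> X, P_Y -> Y, plus P_X -> P_Y
  vars <- list(bn_variable("P_X", c("t", "f")), bn_variable("P_Y", c("t", "f")),
               bn_variable("X", c("t", "f"), role = "target"),
               bn_variable("Y", c("t", "f"), role = "target"))
  net <- bn_network(vars, edges = rbind(c("P_X", "X"), c("P_Y", "Y"), c("P_X", "P_Y")))
  res <- resolve_transitivity(net, c("X", "Y"))
  expect_equal(nrow(res$removed), 1L)
  expect_equal(unname(res$removed[1, ]), c("P_X", "P_Y"))
  expect_identical(res$network$parents$P_Y, character(0))
  # fixed point: re-running removes nothing
  res2 <- resolve_transitivity(res$network, c("X", "Y"))
  expect_equal(nrow(res2$removed), 0L)
  # a network already satisfying the property is untouched
  clean <- bn_network(vars, edges = rbind(c("P_X", "X"), c("P_Y", "Y")))
  expect_equal(nrow(resolve_transitivity(clean, c("X", "Y"))$removed), 0L)
  # shared parents of a single target are not split
  solo <- bn_network(vars[c(1, 2, 3)],
                     edges = rbind(c("P_X", "X"), c("P_Y", "X"), c("P_X", "P_Y")))
  expect_equal(nrow(resolve_transitivity(solo, "X")$removed), 0L)
})

test_that("binarization is the two-group merge with [true, false] states", {
  net <- bn_network(list(bn_variable("T1", c("eligible", "restricted", "excluded"),
                                     role = "target")))
  withr::with_seed(5, {
    d <- data.frame(T1 = sample(c("eligible", "restricted", "excluded"), 25, TRUE))
  })
  res <- binarize_target(net, d, "T1", true_states = "eligible")
  expect_identical(res$network$variables$T1$states, c("true", "false"))
  expect_identical(res$data$T1, ifelse(d$T1 == "eligible", "true", "false"))
  expect_error(binarize_target(net, d, "T1",
                               true_states = c("eligible", "restricted", "excluded")),
               "proper subset")
  expect_error(binarize_target(net, d, "T1", true_states = character(0)),
               "proper subset")
  # operator equivalence with the explicit merge, cell for cell
  merged <- merge_states(net, d, "T1",
                         groups = list("true" = "eligible",
                                       "false" = c("restricted", "excluded")))
  expect_identical(res$data, merged$data)
  expect_equal(res$network$cpts$T1$prob, merged$network$cpts$T1$prob)
})

test_that("leaky noisy-OR compilation matches the closed form", {
  spec0 <- noisy_or_spec("E", c("C1", "C2"), links = c(0.7, 0.4), leak = 0)
  cpt0 <- compile_noisy_or(spec0)
  expect_equal(nrow(cpt0$prob), 4L)
  # all causes false, leak 0: empty product, effect impossible
  both_false <- opsccbn:::parent_row_index(c(2L, 2L), cbind(2L, 2L))
  expect_equal(unname(cpt0$prob[both_false, "true"]), 0)
  # single cause read-off
  single <- compile_noisy_or(noisy_or_spec("E", "C1", links = 0.8, leak = 0))
  expect_equal(unname(single$prob[1, "true"]), 0.8)
  # hand case: 1 - 0.9 * 0.4 * 0.5 = 0.82
  hand <- compile_noisy_or(noisy_or_spec("E", c("C1", "C2"), c(0.6, 0.5), leak = 0.1))
  expect_equal(unname(hand$prob[opsccbn:::parent_row_index(c(2L, 2L), cbind(1L, 1L)), "true"]), 0.82)
  # rows sum to 1 exactly and the gate is marked canonical
  expect_true(all(rowSums(hand$prob) == 1))
  expect_true(hand$fixed)
})

test_that("the compiled gate equals an explicitly decomposed OR-gate network", {
  links <- c(0.6, 0.5, 0.3); leak <- 0.1
  causes <- paste0("C", 1:3)
  # decomposed form: per-cause inhibited copies Zi, a leak node L, and a
  # deterministic OR; the compiled CPT must reproduce P(E | cause pattern)
  vars <- c(lapply(causes, function(c) bn_variable(c, c("true", "false"))),
            lapply(paste0("Z", 1:3), function(z) bn_variable(z, c("true", "false"))),
            list(bn_variable("L", c("true", "false")),
                 bn_variable("E", c("true", "false"))))
  edges <- rbind(cbind(causes, paste0("Z", 1:3)),
                 cbind(c(paste0("Z", 1:3), "L"), "E"))
  dec <- bn_network(vars, edges)
  for (i in 1:3) {
    dec$cpts[[paste0("Z", i)]]$prob <- matrix(c(links[i], 1 - links[i], 0, 1), 2, 2,
                                              byrow = TRUE,
                                              dimnames = list(NULL, c("true", "false")))
  }
  dec$cpts$L$prob[1, ] <- c(leak, 1 - leak)
  or_grid <- opsccbn:::parent_config_grid(rep(2L, 4))
  dec$cpts$E$prob <- cbind("true" = as.numeric(rowSums(or_grid == 1L) > 0),
                           "false" = as.numeric(rowSums(or_grid == 1L) == 0))
  for (c in causes) dec$cpts[[c]]$prob[1, ] <- c(0.5, 0.5)

  compiled <- compile_noisy_or(noisy_or_spec("E", causes, links, leak))
  grid <- opsccbn:::parent_config_grid(rep(2L, 3))
  for (r in seq_len(nrow(grid))) {
    ev <- stats::setNames(lapply(grid[r, ], function(i) c("true", "false")[i]), causes)
    post <- infer_posterior(dec, ev, "E")
    expect_lt(abs(post[["true"]] - compiled$prob[r, "true"]), 1e-9)
  }
})

test_that("abstraction steps shrink the free-parameter count", {
  cohort <- generate_cohort(cohort_config(seed = 20170301))
  net <- learn_cpts(opscc_v1_network(), cohort$data)
  d <- cohort$data
  r12 <- read_recipe_yaml(opscc_recipe_path("v1_to_v2"))
  for (st in r12) {
    if (!st$op %in% c("merge", "condense", "binarize")) next
    before <- free_parameter_count(net)
    res <- replay_recipe(net, d, list(st))
    expect_lt(free_parameter_count(res$network), before)
    expect_equal(nrow(res$data), nrow(d))
    net <- res$network; d <- res$data
  }
})

test_that("complexity reports expose the canonical-model saving", {
  net <- abc_net()
  same <- complexity_report(net, net)
  expect_true(all(same$delta == 0))

  ref <- reference_models()
  cmp <- complexity_report(ref$v1, ref$v3)
  expect_true(all(cmp$delta < 0))  # parameters, states, edges all shrink

  big <- compile_noisy_or(noisy_or_spec("E", paste0("C", 1:10),
                                        links = rep(0.5, 10), leak = 0.01))
  expect_equal(nrow(big$prob), 1024L)   # tabular form: 2^10 rows
  expect_equal(length(paste0("C", 1:10)) + 1L, 11L)  # gate: n + 1 parameters
})
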