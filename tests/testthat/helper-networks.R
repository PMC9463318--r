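# Small fixture builders shared across test files.

# A -> B chain with P(a1) = 0.5, P(b1|a1) = 0.9, P(b1|a2) = 0.1.
chain_net <- function(p_a1 = 0.5, p_b1_a1 = 0.9, p_b1_a2 = 0.1) {
  net <- bn_network(
    list(bn_variable("A", c("a1", "a2")), bn_variable("B", c("b1", "b2"))),
    edges = rbind(c("A", "B"))
  )
  net$cpts$A$prob[1, ] <- c(p_a1, 1 - p_a1)
  net$cpts$B$prob <- matrix(c(p_b1_a1, 1 - p_b1_a1, p_b1_a2, 1 - p_b1_a2),
                            2, 2, byrow = TRUE,
                            dimnames = list(NULL, c("b1", "b2")))
  net
}

# Random network with <= max_vars variables of <= max_states states each and
# random Dirichlet(1) CPT rows; edge probability 0.4 per admissible pair.
random_net <- function(max_vars = 6, max_states = 4, edge_p = 0.4) {
  nv <- sample(2:max_vars, 1)
  vars <- lapply(seq_len(nv), function(i) {
    bn_variable(paste0("V", i), paste0("s", seq_len(sample(2:max_states, 1))))
  })
  net <- bn_network(vars)
  for (j in seq_len(nv)[-1]) {
    for (i in seq_len(j - 1)) {
      if (stats::runif(1) < edge_p) net <- add_edge(net, paste0("V", i), paste0("V", j))
    }
  }
  for (v in names(net$variables)) {
    p <- net$cpts[[v]]$prob
    m <- matrix(stats::rgamma(length(p), 1), nrow(p), ncol(p))
    net$cpts[[v]]$prob <- m / rowSums(m)
    dimnames(net$cpts[[v]]$prob) <- dimnames(p)
  }
  net
}

random_evidence <- function(net, exclude, n_ev) {
  vs <- sample(setdiff(names(net$variables), exclude), n_ev)
  ev <- lapply(vs, function(v) sample(net$variables[[v]]$states, 1))
  stats::setNames(ev, vs)
}

# The seeded end-to-end demonstration pipeline is expensive; compute it once
# per test session.
demo_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_demo(seed = 7, n = 94, k = 10)
    cache
  }
})
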