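# Small graph builders used across the suite.  All draw from the current RNG
# stream; tests seed explicitly.

graph_from_upper <- function(n, edges) {
  # edges: list of c(i, j, w)
  w <- matrix(0, n, n)
  for (e in edges) {
    w[e[1], e[2]] <- e[3]
    w[e[2], e[1]] <- e[3]
  }
  weighted_graph(w)
}

path_graph <- function(weights) {
  n <- length(weights) + 1
  graph_from_upper(n, lapply(seq_along(weights), function(i) c(i, i + 1, weights[i])))
}

triangle_graph <- function(w = c(1, 1, 1)) {
  graph_from_upper(3, list(c(1, 2, w[1]), c(2, 3, w[2]), c(1, 3, w[3])))
}

random_connected_graph <- function(n = 10, density = 0.4, wmin = 0.2, wmax = 1) {
  repeat {
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w))
    k <- max(n - 1, round(density * length(ut)))
    idx <- sample(ut, k)
    w[idx] <- stats::runif(k, wmin, wmax)
    w <- w + t(w)
    g <- weighted_graph(w)
    if (is_connected(g)) return(g)
  }
}

random_tree_graph <- function(n = 8, wmin = 0.2, wmax = 2) {
  w <- matrix(0, n, n)
  for (v in 2:n) {
    u <- sample(v - 1, 1)
    w[u, v] <- w[v, u] <- stats::runif(1, wmin, wmax)
  }
  weighted_graph(w)
}

# A tiny cohort for kernel-test level checks: two populations, optionally
# mixed, at desk scale.
tiny_cohort <- function(n_per_group = 8, p = 15, mix = 1) {
  popA <- generate_population_network(p, 0.6, strength = 2)
  popB <- generate_population_network(p, 0.6, strength = 2)
  pop2 <- (1 - mix) * popA + mix * popB
  spec <- cohort_spec(p = p, n_subjects = n_per_group, sparsity = 0.6,
                      REnoise = 0.5, n_time = 80)
  gA <- sample_cohort(spec, popA, seed = NULL)
  gB <- sample_cohort(spec, pop2, seed = NULL)
  list(graphs = c(unname(gA), unname(gB)),
       y = rep(c(0, 1), each = n_per_group))
}
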