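test_that("laplacian matches D - A and annihilates constants", {
  g2 <- graph_from_upper(2, list(c(1, 2, 1)))
  expect_equal(laplacian(g2), matrix(c(1, -1, -1, 1), 2, 2))

  set.seed(11)
  g <- random_connected_graph(10, 0.4)
  L <- laplacian(g)
  expect_equal(max(abs(L %*% rep(1, 10))), 0, tolerance = 1e-12)
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(L, t(L))
})

test_that("asymmetric weight matrices are rejected", {
  w <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(weighted_graph(w), "not symmetric")
  expect_error(weighted_graph(matrix(c(1, 0, 0, 0), 2, 2)), "self-loops")
  expect_error(weighted_graph(matrix(c(0, -1, -1, 0), 2, 2)), "signed")
})

test_that("effective resistance reproduces series/parallel resistor laws", {
  # single resistor: R = 1/w
  g <- graph_from_upper(2, list(c(1, 2, 2)))
  expect_equal(effective_resistance(g)$R[1, 2], 0.5)

  # two unit resistors in series
  R <- effective_resistance(path_graph(c(1, 1)))$R
  expect_equal(R[1, 3], 2)
  expect_equal(R[1, 2], 1)
  expect_equal(R[2, 3], 1)

  # unit triangle: 1 || (1 + 1) = 2/3
  R <- effective_resistance(triangle_graph())$R
  expect_equal(R[upper.tri(R)], rep(2 / 3, 3))
})

test_that("effective resistance satisfies the Eq-definition identities", {
  set.seed(21)
  for (i in 1:5) {
    g <- random_connected_graph(10, 0.35)
    er <- effective_resistance(g)
    Lp <- er$laplacian_pinv
    d <- diag(Lp)
    expect_equal(er$R, outer(d, d, `+`) - 2 * Lp, tolerance = 1e-10)
    # rows of the pseudo-inverse sum to zero for connected graphs
    expect_lt(max(abs(rowSums(Lp))), 1e-9)
    expect_true(er$connected)
    expect_equal(diag(er$R), rep(0, 10))
    expect_true(all(er$R[upper.tri(er$R)] > 0))
    # node-level triangle inequality (resistance is a metric on vertices)
    R <- er$R
    for (i2 in 1:10) for (j in 1:10) for (k in 1:10) {
      expect_lte(R[i2, k], R[i2, j] + R[j, k] + 1e-9)
    }
  }
})

test_that("disconnected graphs error with components, or evaluate formally", {
  g <- graph_from_upper(4, list(c(1, 2, 1), c(3, 4, 1)))
  expect_false(is_connected(g))
  expect_error(effective_resistance(g), "\\{1,2\\}.*\\{3,4\\}")
  er <- effective_resistance(g, allow_disconnected = TRUE)
  expect_false(er$connected)
  expect_equal(er$R[1, 2], 1)  # within-component values are real resistances
  expect_equal(er$R, t(er$R))
})

test_that("rpd matches the hand-computed toy example and basic axioms", {
  tri <- triangle_graph()
  pth <- path_graph(c(1, 1))
  # |2/3-1| twice, |2/3-2| once, ordered pairs double everything
  expect_equal(rpd(tri, pth, p = 1), 4)
  expect_equal(rpd(tri, pth, p = 2), 2)
  expect_equal(rpd(tri, tri), 0)
  expect_equal(rpd(tri, pth), rpd(pth, tri))
  expect_error(rpd(tri, graph_from_upper(2, list(c(1, 2, 1)))), "dimension")
  expect_error(rpd(tri, pth, p = 0.5), "p")
})

test_that("pairwise_rpd agrees with one-at-a-time calls and handles strict mode", {
  set.seed(31)
  graphs <- replicate(5, random_connected_graph(10, 0.4), simplify = FALSE)
  D <- pairwise_rpd(graphs, p = 2)
  expect_equal(dim(D), c(5, 5))
  expect_equal(diag(D), rep(0, 5), ignore_attr = TRUE)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(D[i, j], rpd(graphs[[i]], graphs[[j]], p = 2), tolerance = 1e-10)
  }
  # p = 1 path goes through the generic Minkowski branch
  D1 <- pairwise_rpd(graphs, p = 1)
  expect_equal(D1[1, 2], rpd(graphs[[1]], graphs[[2]], p = 1), tolerance = 1e-10)

  expect_equal(unname(pairwise_rpd(graphs[1])), matrix(0, 1, 1))
  expect_equal(unname(pairwise_rpd(c(graphs[1], graphs[1]))), matrix(0, 2, 2))

  bad <- graph_from_upper(10, list(c(1, 2, 1)))  # isolated vertices
  expect_error(pairwise_rpd(c(graphs, list(bad = bad))), "bad")
  expect_silent(pairwise_rpd(c(graphs, list(bad = bad)), allow_disconnected = TRUE))
})

test_that("prepare_connectivity handles fisher-z and negative modes", {
  m <- matrix(c(0, -0.3, -0.3, 0), 2, 2)
  expect_equal(prepare_connectivity(m, negative_mode = "zero")$weights[1, 2], 0)
  expect_equal(prepare_connectivity(m, negative_mode = "abs")$weights[1, 2], 0.3)
  g_keep <- prepare_connectivity(m, negative_mode = "keep")
  expect_true(g_keep$signed)
  expect_equal(g_keep$weights[1, 2], -0.3)

  m2 <- matrix(c(0, -0.5, -0.5, 0), 2, 2)
  expect_equal(prepare_connectivity(m2, negative_mode = "normalize")$weights[1, 2], 0.25)

  mz <- matrix(0, 3, 3)
  expect_equal(prepare_connectivity(mz, fisher_z = TRUE)$weights, mz)  # tanh(0) = 0
  z <- matrix(c(0, 0.6, 0.6, 0), 2, 2)
  expect_equal(prepare_connectivity(z, fisher_z = TRUE)$weights[1, 2], tanh(0.6))

  # diagonal forced to zero, asymmetry averaged away
  m3 <- matrix(c(1, 0.2, 0.4, 1), 2, 2)
  g3 <- prepare_connectivity(m3)
  expect_equal(g3$weights[1, 2], 0.3)
  expect_equal(diag(g3$weights), c(0, 0))

  expect_error(prepare_connectivity(matrix(NaN, 2, 2)), "NaN")
  expect_error(prepare_connectivity(matrix(0, 2, 3)), "square")
})

test_that("global efficiency follows the inverse-shortest-path convention", {
  complete4 <- weighted_graph(matrix(1, 4, 4) - diag(4))
  expect_equal(global_efficiency(complete4), 1)

  empty <- weighted_graph(matrix(0, 4, 4))
  expect_equal(global_efficiency(empty), 0)

  # unit path 1-2-3: pair lengths 1, 1, 2 -> mean(1, 1, 1/2) = 5/6
  expect_equal(global_efficiency(path_graph(c(1, 1))), 5 / 6)

  signed <- prepare_connectivity(matrix(c(0, -0.3, -0.3, 0), 2, 2),
                                 negative_mode = "keep")
  expect_error(global_efficiency(signed), "signed")
})

test_that("rich-club coefficient matches brute-force enumeration", {
  complete5 <- weighted_graph(matrix(1, 5, 5) - diag(5))
  expect_equal(rich_club_coefficient(complete5, 2), 1)

  star <- graph_from_upper(5, lapply(2:5, function(v) c(1, v, 1)))
  rc <- rich_club_coefficient(star, 1)
  expect_true(is.na(rc))
  expect_true(attr(rc, "undefined"))

  set.seed(41)
  for (i in 1:10) {
    g <- random_connected_graph(10, 0.35)
    w <- g$weights
    k <- 3
    # independent enumeration of the definition
    deg <- colSums(w != 0)
    rich <- which(deg > k)
    expected <- if (length(rich) < 2) NA_real_ else {
      sub <- w[rich, rich]
      ww <- sub[upper.tri(sub)]
      E_k <- sum(ww != 0)
      if (E_k == 0) NA_real_ else {
        all_w <- sort(w[upper.tri(w)][w[upper.tri(w)] > 0], decreasing = TRUE)
        sum(ww) / sum(all_w[seq_len(E_k)])
      }
    }
    got <- rich_club_coefficient(g, k)
    if (is.na(expected)) expect_true(is.na(got)) else {
      expect_equal(as.numeric(got), expected, tolerance = 1e-12)
      expect_lte(got, 1 + 1e-12)
    }
  }
  # threshold above the maximum degree flags undefined rather than erroring
  expect_true(is.na(rich_club_coefficient(complete5, 10)))
})
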