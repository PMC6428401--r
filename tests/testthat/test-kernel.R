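design_iid <- function(y) phenotype_design(data.frame(outcome = y))

test_that("null logistic fit recovers closed-form intercept and projections", {
  y <- c(rep(1, 9), rep(0, 11))  # mean 0.45
  null <- fit_null_logistic(design_iid(y))
  expect_equal(unname(null$beta0), log(0.45 / 0.55), tolerance = 1e-8)

  y4 <- c(1, 1, 0, 0)
  n4 <- fit_null_logistic(design_iid(y4))
  expect_equal(n4$mu0, rep(0.5, 4), ignore_attr = TRUE)
  expect_equal(n4$d0, rep(0.25, 4), ignore_attr = TRUE)
  expect_equal(n4$P0, 0.25 * diag(4) - 0.0625 * matrix(1, 4, 4))

  # with a continuous covariate the projection still annihilates X
  set.seed(7)
  df <- data.frame(outcome = rbinom(40, 1, 0.5), age = rnorm(40))
  nfit <- fit_null_logistic(phenotype_design(df, covariates = "age"))
  expect_lt(max(abs(nfit$P0 %*% nfit$X)), 1e-8)
})

test_that("perfect separation is reported as a convergence failure", {
  df <- data.frame(outcome = rep(c(0, 1), each = 10),
                   x = c(rnorm(10, -5), rnorm(10, 5)))
  expect_error(fit_null_logistic(phenotype_design(df, covariates = "x")),
               "separation")
})

test_that("phenotype_design validates outcomes and rank", {
  expect_error(phenotype_design(data.frame(outcome = c(0, 2, 1))), "0/1")
  expect_error(phenotype_design(data.frame(outcome = rep(1, 5))), "both")
  df <- data.frame(outcome = c(0, 1, 0, 1), a = 1:4, b = 2 * (1:4))
  expect_error(phenotype_design(df, covariates = c("a", "b")), "rank")
  # two-level factors are one-hot encoded with an intercept
  df2 <- data.frame(outcome = rep(0:1, 10), sex = rep(c("F", "M"), each = 10))
  d <- phenotype_design(df2, covariates = "sex")
  expect_equal(ncol(d$X), 2)
})

test_that("rho bounds follow the 0.1 min / 100 max rule on squared distances", {
  D3 <- matrix(3, 3, 3); diag(D3) <- 0
  expect_equal(rho_bounds(D3), c(L = 0.9, U = 900))

  D12 <- matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3, 3)
  expect_equal(rho_bounds(D12), c(L = 0.1, U = 400))

  set.seed(13)
  D <- as.matrix(stats::dist(matrix(rnorm(40), 8, 5)))
  b <- rho_bounds(D)
  off <- D[upper.tri(D)]
  expect_equal(b[["L"]], 0.1 * min(off)^2)
  expect_equal(b[["U"]], 100 * max(off)^2)
  expect_lt(b[["L"]], b[["U"]])

  expect_error(rho_bounds(matrix(0, 3, 3)), "degenerate")
})

test_that("the Gaussian kernel evaluates, limits, and guards rho", {
  D <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(build_kernel(D, 4)[1, 2], exp(-1))
  expect_equal(diag(build_kernel(D, 4)), c(1, 1))
  expect_equal(build_kernel(D, 1e12), matrix(1, 2, 2), tolerance = 1e-10)
  expect_error(build_kernel(D, 0), "rho")
  expect_error(build_kernel(D, -1), "rho")
})

test_that("kernels from p = 2 distances are positive semi-definite", {
  set.seed(17)
  graphs <- replicate(8, random_connected_graph(10, 0.4), simplify = FALSE)
  D <- pairwise_rpd(graphs, p = 2)
  for (rho in rho_grid(rho_bounds(D), m = 8)) {
    K <- build_kernel(D, rho)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("non-Euclidean dissimilarities trigger the spectral guard", {
  # frozen example: this 5x5 dissimilarity gives a kernel eigenvalue ~ -0.96
  D <- matrix(0, 5, 5)
  D[upper.tri(D)] <- c(0.1498, 0.2792, 1.8457, 1.5240, 0.2432,
                       0.6969, 1.7812, 0.3474, 0.5468, 1.1361)
  D <- D + t(D)
  expect_error(build_kernel(D, 1, check_psd = TRUE), "semi-definite")
  # a genuinely PSD kernel passes through the check unchanged
  set.seed(3)
  D2 <- as.matrix(stats::dist(matrix(rnorm(30), 6, 5)))
  expect_equal(build_kernel(D2, 2, check_psd = TRUE), build_kernel(D2, 2),
               tolerance = 1e-10)
})

test_that("score statistic matches the n = 4 worked example", {
  y4 <- c(1, 1, 0, 0)
  null <- fit_null_logistic(design_iid(y4))

  ones <- matrix(1, 4, 4)
  s_ones <- score_statistic(null, ones)
  expect_equal(s_ones$Q, 0)           # balanced residuals sum to zero
  expect_true(s_ones$degenerate)      # P0 annihilates the all-ones kernel

  s_id <- score_statistic(null, diag(4))
  expect_equal(s_id$Q, 1)
  expect_equal(s_id$mu_Q, 0.75)
  # sigma_Q^2 = 2 tr(P0 P0) with P0 = 0.25 I - 0.0625 J
  P0 <- 0.25 * diag(4) - 0.0625
  expect_equal(s_id$sigma_Q, sqrt(2 * sum(P0 * P0)))
  expect_equal(s_id$S, (1 - 0.75) / s_id$sigma_Q)

  expect_error(score_statistic(null, diag(3)), "dimensions")
})

test_that("the Davies bound reduces to the normal tail when W = 0", {
  g <- c(1, 2, 4, 8)
  out <- davies_upper_bound(rep(1.6449, 4), g)
  expect_equal(out$p_upper, pnorm(-1.6449))
  expect_equal(out$p_upper, 0.05, tolerance = 1e-4)
  expect_equal(out$W, 0)

  expect_equal(davies_upper_bound(rep(0, 4), g)$p_upper, 0.5)

  # doubling the total variation at fixed maximum strictly increases the bound
  S1 <- c(1, 0.5, 1, 0.5)
  S2 <- c(1, 0, 1, 0)
  p1 <- davies_upper_bound(S1, g)
  p2 <- davies_upper_bound(S2, g)
  expect_equal(p2$W, 2 * p1$W)
  expect_gt(p2$p_raw, p1$p_raw)

  expect_error(davies_upper_bound(1, 1), "grid")
  expect_error(davies_upper_bound(c(1, 2), c(2, 1)), "increasing")
})

test_that("kernel_machine_test is deterministic and records its grid", {
  set.seed(23)
  cohort <- tiny_cohort(n_per_group = 8)
  design <- design_iid(cohort$y)
  fit1 <- kernel_machine_test(cohort$graphs, design, m = 20)
  fit2 <- kernel_machine_test(cohort$graphs, design, m = 20)
  expect_equal(fit1$p_upper, fit2$p_upper)
  expect_equal(nrow(fit1$grid), 22)
  expect_true(all(diff(fit1$grid$rho) > 0))
  expect_equal(fit1$M, max(fit1$grid$S[!fit1$grid$degenerate]))
  keep <- !fit1$grid$degenerate
  expect_equal(fit1$W, sum(abs(diff(fit1$grid$S[keep]))))
  expect_gte(fit1$p_upper, 0)
  expect_lte(fit1$p_upper, 1)
  # tidy/glance accessors
  expect_equal(nrow(glance(fit1)), 1)
  expect_equal(tidy(fit1), fit1$grid)
  # distance-matrix input path agrees with the graph path
  D <- pairwise_rpd(cohort$graphs)
  fit3 <- kernel_machine_test(D, design, m = 20)
  expect_equal(fit3$p_upper, fit1$p_upper)
  expect_error(kernel_machine_test(cohort$graphs[1:5], design), "match")
})

test_that("semiparametric fit collapses to the null as tau -> 0 and K -> 0", {
  set.seed(29)
  cohort <- tiny_cohort(n_per_group = 8)
  design <- design_iid(cohort$y)
  D <- pairwise_rpd(cohort$graphs, allow_disconnected = TRUE)
  K <- build_kernel(D, median(D[upper.tri(D)]^2))

  null <- fit_null_logistic(design)
  small_tau <- fit_semiparametric(design, K, tau = 1e-8)
  expect_true(small_tau$converged)
  expect_equal(max(abs(small_tau$h)), 0, tolerance = 1e-5)
  expect_equal(small_tau$beta, unname(null$beta0), tolerance = 1e-4,
               ignore_attr = TRUE)

  zeroK <- fit_semiparametric(design, matrix(0, 16, 16), tau = 1)
  expect_equal(zeroK$beta, unname(null$beta0), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(zeroK$h, rep(0, 16))

  expect_error(fit_semiparametric(design, K, tau = 0), "tau")
})

test_that("fitted kernel effect tracks the true group structure", {
  set.seed(31)
  cohort <- tiny_cohort(n_per_group = 10, mix = 1)
  design <- design_iid(cohort$y)
  D <- pairwise_rpd(cohort$graphs, allow_disconnected = TRUE)
  K <- build_kernel(D, stats::median(D[upper.tri(D)]^2))
  fit <- fit_semiparametric(design, K, tau = 1)
  expect_gt(stats::cor(fit$h, cohort$y), 0)
})
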