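#' @title Simulation experiments for the resistance perturbation distance and
#'   the kernel-machine score test
#' @description Scripted studies: four qualitative distance-property
#'   experiments on small connectivity matrices (edge importance, weight
#'   awareness, edge-submodularity, focus awareness), power and Type-I-error
#'   estimation for the kernel score test on full-size cohorts, and the two
#'   allocation sweeps (noise allocation under the alternative, label split
#'   under the null).
#' @name rpd_experiments
NULL

new_experiment <- function(name, records, summary, iterations, seed = NULL) {
  structure(
    list(name = name, records = records, summary = summary,
         iterations = iterations, seed = seed),
    class = "rpd_experiment"
  )
}

#' @export
print.rpd_experiment <- function(x, ...) {
  cat(sprintf("<rpd_experiment: %s, %d iterations>\n", x$name, x$iterations))
  print(x$summary)
  invisible(x)
}

#' Tidy the per-iteration records of an experiment
#' @param x an `rpd_experiment`.
#' @param ... unused.
#' @return Tibble of per-iteration records (one row per iteration and
#'   condition).
#' @method tidy rpd_experiment
#' @export
tidy.rpd_experiment <- function(x, ...) x$records

#' One-row (or per-condition) summary of an experiment
#' @param x an `rpd_experiment`.
#' @param ... unused.
#' @return The experiment's summary tibble.
#' @method glance rpd_experiment
#' @export
glance.rpd_experiment <- function(x, ...) x$summary

#' Boxplot of an experiment's distance records by condition
#' @param object an `rpd_experiment` whose records contain `condition` and
#'   `rpd` (property experiments) or `p_value` columns.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot rpd_experiment
#' @export
autoplot.rpd_experiment <- function(object, ...) {
  rec <- object$records
  if ("rpd" %in% names(rec)) {
    ggplot2::ggplot(rec, ggplot2::aes(x = .data$condition, y = log(.data$rpd))) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(x = NULL, y = "log RPD", title = object$name)
  } else {
    xvar <- intersect(c("allocation", "split"), names(rec))[1]
    ggplot2::ggplot(rec, ggplot2::aes(x = .data[[xvar]], y = .data$p_value)) +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed", colour = "red") +
      ggplot2::labs(x = xvar, y = "Davies upper-bound p-value", title = object$name)
  }
}

#' Simulate a single connectivity graph
#'
#' One pass of the cohort generator for a single subject: a fresh
#' preferential-attachment population network, one draw of Erdos-Renyi
#' subject effects, positive-definite correction, and conversion to a
#' non-negative graph (negatives zeroed).  The distance-property experiments
#' default to `method = "direct"` (the partial correlations implied by the
#' precision matrix): single network matrices then have edge weights bounded
#' away from zero, so the impact of deleting an edge reflects the network
#' change itself rather than sampling residue.  `method = "sampled"` gives
#' the empirical-correlation variant used by the cohort studies.
#'
#' @param p node count.
#' @param sparsity fraction of absent population edges; the ten-node
#'   property studies default to 0.1 (a dense population matrix) so that
#'   random edge deletions usually preserve connectivity.
#' @param REsize,REprob,REnoise,n_time,pop_strength,method see
#'   [cohort_spec()].  The property studies default to `REnoise = 1` and
#'   `pop_strength = 5`, keeping single matrices in the mixed-sign,
#'   moderate-correlation regime.
#' @return A [weighted_graph()] with non-negative weights.
#' @export
simulate_connectivity_graph <- function(p = 10, sparsity = 0.1, REsize = 10,
                                        REprob = 0.65, REnoise = 1,
                                        n_time = 150, pop_strength = 5,
                                        method = c("direct", "sampled")) {
  method <- match.arg(method)
  pop <- generate_population_network(p, sparsity, pop_strength)
  theta <- generate_subject_effects(pop, REsize, REprob, REnoise)
  subject_graph(pop + theta, n_time, "zero", method)
}

# Zero out the symmetric cells given by upper-triangle linear indices.
delete_cells <- function(w, idx) {
  if (!length(idx)) return(w)
  arr <- arrayInd(idx, dim(w))
  w[arr] <- 0
  w[arr[, c(2, 1), drop = FALSE]] <- 0
  w
}

nonzero_upper <- function(w) which(upper.tri(w) & w != 0)

rpd_after_deletion <- function(g, w_mod) {
  g_mod <- weighted_graph(w_mod)
  rpd(g, g_mod, p = 2, allow_disconnected = TRUE)
}

#' Edge-importance experiment: disconnection hurts more than random deletion
#'
#' Per iteration, a connectivity matrix is simulated; the "targeted"
#' condition zeroes every nonzero cell between the two node blocks (the
#' off-diagonal quadrants), splitting the graph into two components, and the
#' "random" condition zeroes the same number of randomly chosen nonzero
#' cells.  The distance from the original graph is recorded for both; a
#' distance respecting edge importance gives larger values to the targeted
#' disconnection on average.
#'
#' @param iterations number of simulated matrices.
#' @param p_nodes node count (must be even).
#' @param seed optional RNG seed.
#' @param ... generator settings passed to [simulate_connectivity_graph()].
#' @return An `rpd_experiment` whose records hold `iteration`, `condition`
#'   (`"targeted"`/`"random"`), `rpd` and `n_deleted`.
#' @export
edge_importance_experiment <- function(iterations = 1000, p_nodes = 10,
                                       seed = NULL, ...) {
  if (p_nodes %% 2 != 0) stop("`p_nodes` must be even for the quadrant split",
                              call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  half <- p_nodes / 2
  block <- matrix(FALSE, p_nodes, p_nodes)
  block[seq_len(half), half + seq_len(half)] <- TRUE  # upper-tri off-block
  recs <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    g <- simulate_connectivity_graph(p = p_nodes, ...)
    w <- g$weights
    cells_t <- which(block & w != 0)
    k <- length(cells_t)
    d_t <- rpd_after_deletion(g, delete_cells(w, cells_t))
    nz <- nonzero_upper(w)
    cells_r <- if (k) sample(nz, k) else integer(0)
    d_r <- rpd_after_deletion(g, delete_cells(w, cells_r))
    recs[[it]] <- tibble::tibble(
      iteration = it,
      condition = c("targeted", "random"),
      rpd = c(d_t, d_r),
      n_deleted = k
    )
  }
  records <- dplyr::bind_rows(recs)
  summarise_conditions("edge importance", records, iterations, seed)
}

summarise_conditions <- function(name, records, iterations, seed) {
  summary <- records |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      mean_rpd = mean(.data$rpd),
      mean_log_rpd = mean(log(.data$rpd[.data$rpd > 0])),
      .groups = "drop"
    )
  new_experiment(name, records, summary, iterations, seed)
}

#' Weight-awareness experiment: heavier removed edges matter more
#'
#' Per iteration, the maximum and the minimum nonzero correlation are each
#' (separately) deleted from a simulated connectivity matrix and both
#' distances from the original recorded.  Iterations are resampled when the
#' graph has fewer than two distinct nonzero weights, or when either
#' single-edge deletion would disconnect the graph: weight awareness
#' compares connectivity-preserving deletions of different strengths, while
#' disconnecting changes are the subject of the edge-importance property.
#'
#' @inheritParams edge_importance_experiment
#' @return An `rpd_experiment` with conditions `"max_weight"`/`"min_weight"`.
#' @export
weight_awareness_experiment <- function(iterations = 1000, p_nodes = 10,
                                        seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  recs <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    repeat {
      g <- simulate_connectivity_graph(p = p_nodes, ...)
      w <- g$weights
      nz <- nonzero_upper(w)
      if (length(nz) < 2 || length(unique(w[nz])) < 2) next
      cell_max <- nz[which.max(w[nz])]
      cell_min <- nz[which.min(w[nz])]
      if (is_connected(weighted_graph(delete_cells(w, cell_max))) &&
          is_connected(weighted_graph(delete_cells(w, cell_min)))) break
    }
    recs[[it]] <- tibble::tibble(
      iteration = it,
      condition = c("max_weight", "min_weight"),
      rpd = c(rpd_after_deletion(g, delete_cells(w, cell_max)),
              rpd_after_deletion(g, delete_cells(w, cell_min)))
    )
  }
  summarise_conditions("weight awareness", dplyr::bind_rows(recs), iterations, seed)
}

#' Edge-submodularity experiment: deletions matter more in sparse graphs
#'
#' Per iteration, one sparse and one dense connectivity matrix are simulated
#' and each loses its maximum nonzero correlation; the distances from the
#' respective originals are recorded.  The sparse/dense conditions correspond
#' to population edge densities of 0.45 and 0.95 (i.e. `sparsity` arguments
#' 0.55 and 0.05 in this generator's absent-edge parameterisation).
#'
#' @inheritParams edge_importance_experiment
#' @param sparse_sparsity,dense_sparsity absent-edge fractions for the two
#'   conditions.
#' @return An `rpd_experiment` with conditions `"sparse"`/`"dense"`.
#' @export
submodularity_experiment <- function(iterations = 1000, p_nodes = 10,
                                     sparse_sparsity = 0.55,
                                     dense_sparsity = 0.05,
                                     seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  one <- function(sparsity) {
    repeat {
      g <- simulate_connectivity_graph(p = p_nodes, sparsity = sparsity, ...)
      nz <- nonzero_upper(g$weights)
      if (length(nz)) break
    }
    cell <- nz[which.max(g$weights[nz])]
    rpd_after_deletion(g, delete_cells(g$weights, cell))
  }
  recs <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    recs[[it]] <- tibble::tibble(
      iteration = it,
      condition = c("sparse", "dense"),
      rpd = c(one(sparse_sparsity), one(dense_sparsity))
    )
  }
  summarise_conditions("edge submodularity", dplyr::bind_rows(recs), iterations, seed)
}

#' Focus-awareness experiment: targeted changes beat random changes
#'
#' Per iteration, the "targeted" condition deletes every edge of one randomly
#' chosen node (of nonzero degree) while the "random" condition deletes the
#' same number of randomly chosen edges anywhere in the graph.
#'
#' @inheritParams edge_importance_experiment
#' @return An `rpd_experiment` with conditions `"targeted"`/`"random"`.
#' @export
focus_awareness_experiment <- function(iterations = 1000, p_nodes = 10,
                                       seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  recs <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    repeat {
      g <- simulate_connectivity_graph(p = p_nodes, ...)
      deg <- rowSums(g$weights != 0)
      if (any(deg > 0)) break
    }
    node <- sample(which(deg > 0), 1)
    w <- g$weights
    arr <- cbind(node, which(w[node, ] != 0))
    k <- nrow(arr)
    w_t <- w
    w_t[arr] <- 0
    w_t[arr[, c(2, 1), drop = FALSE]] <- 0
    cells_r <- sample(nonzero_upper(w), min(k, length(nonzero_upper(w))))
    recs[[it]] <- tibble::tibble(
      iteration = it,
      condition = c("targeted", "random"),
      rpd = c(rpd_after_deletion(g, w_t),
              rpd_after_deletion(g, delete_cells(w, cells_r))),
      n_deleted = k
    )
  }
  summarise_conditions("focus awareness", dplyr::bind_rows(recs), iterations, seed)
}

# ---- Power / Type-I machinery ------------------------------------------------

# Davies upper-bound p-value from a precomputed distance matrix and labels.
km_pvalue_distances <- function(D, y, m = 50) {
  bounds <- rho_bounds(D)
  grid <- rho_grid(bounds, m = m)
  kernels <- lapply(grid, function(r) build_kernel(D, r, check_psd = FALSE))
  km_pvalue_kernels(kernels, grid, y)
}

km_pvalue_kernels <- function(kernels, grid, y) {
  design <- phenotype_design(data.frame(outcome = y))
  null <- fit_null_logistic(design)
  proc <- score_process(null, kernels, grid)
  davies_from_process(proc)$p_upper
}

# Simulate n subjects from a fresh population network at the given settings.
population_cohort <- function(n, p, sparsity, REsize, REprob, REnoise, n_time,
                              pop_strength) {
  spec <- cohort_spec(p = p, n_subjects = n, sparsity = sparsity,
                      REsize = REsize, REprob = REprob, REnoise = REnoise,
                      n_time = n_time, pop_strength = pop_strength)
  pop <- generate_population_network(p, sparsity, pop_strength)
  sample_cohort(spec, pop, seed = NULL)
}

#' Empirical power of the kernel score test (two-population + noise design)
#'
#' Per replicate, three cohorts are generated from three independently drawn
#' population networks: `n_control_pop` "control" subjects, `n_patient_pop`
#' "patient" subjects, and `n_noise` "noise" subjects mimicking the noisy
#' heterogeneity of fMRI cohorts.  The noise subjects are split between the
#' labelled groups (`noise_to_control` to control, the rest to patient;
#' the defaults give final group sizes 55 vs 45).  The kernel-machine score
#' test is run on the pooled cohort and the replicate counts as a rejection
#' when the Davies upper-bound p-value falls below `alpha`.
#'
#' @param reps number of replicates.
#' @param alpha rejection threshold.
#' @param n_control_pop,n_patient_pop,n_noise population sizes (10/10/80).
#' @param noise_to_control noise subjects allocated to the control label.
#' @param p,sparsity,REsize,REprob,REnoise,n_time,pop_strength generator
#'   settings (defaults are the full-scale study settings).
#' @param m interior bandwidth grid points.
#' @param seed optional RNG seed.
#' @return An `rpd_experiment`; `glance()` gives the rejection rate and its
#'   95% binomial confidence interval.
#' @export
power_experiment <- function(reps = 200, alpha = 0.05,
                             n_control_pop = 10, n_patient_pop = 10,
                             n_noise = 80, noise_to_control = 45,
                             p = 90, sparsity = 0.75, REsize = 10,
                             REprob = 0.65, REnoise = 3, n_time = 150,
                             pop_strength = 15, m = 50, seed = NULL) {
  stopifnot(reps >= 1, noise_to_control >= 0, noise_to_control <= n_noise)
  if (!is.null(seed)) set.seed(seed)
  pvals <- numeric(reps)
  for (it in seq_len(reps)) {
    ctrl <- population_cohort(n_control_pop, p, sparsity, REsize, REprob, REnoise, n_time, pop_strength)
    pat <- population_cohort(n_patient_pop, p, sparsity, REsize, REprob, REnoise, n_time, pop_strength)
    noise <- population_cohort(n_noise, p, sparsity, REsize, REprob, REnoise, n_time, pop_strength)
    to_ctrl <- seq_len(noise_to_control)
    graphs <- c(ctrl, noise[to_ctrl], pat, noise[setdiff(seq_len(n_noise), to_ctrl)])
    y <- c(rep(0, n_control_pop + noise_to_control),
           rep(1, n_patient_pop + n_noise - noise_to_control))
    D <- pairwise_rpd(unname(graphs), p = 2, allow_disconnected = TRUE)
    pvals[it] <- km_pvalue_distances(D, y, m = m)
  }
  records <- tibble::tibble(iteration = seq_len(reps), condition = "two_population",
                            p_value = pvals, reject = pvals < alpha)
  ci <- stats::binom.test(sum(records$reject), reps)$conf.int
  summary <- tibble::tibble(
    rejection_rate = mean(records$reject),
    n_reps = reps, alpha = alpha,
    ci_lower = ci[1], ci_upper = ci[2]
  )
  new_experiment("power (two-population + noise)", records, summary, reps, seed)
}

#' Empirical Type-I error of the kernel score test (one-population design)
#'
#' Per replicate, `n_subjects` graphs are generated from a single population
#' process and labelled arbitrarily (`split` controls vs the rest); the
#' rejection fraction at `alpha` estimates the Type-I error.
#'
#' @inheritParams power_experiment
#' @param n_subjects cohort size per replicate.
#' @param split number of subjects labelled as controls.
#' @return An `rpd_experiment` (same summary shape as [power_experiment()]).
#' @export
type1_experiment <- function(reps = 500, alpha = 0.05, n_subjects = 100,
                             split = 55, p = 90, sparsity = 0.75, REsize = 10,
                             REprob = 0.65, REnoise = 3, n_time = 150,
                             pop_strength = 15, m = 50, seed = NULL) {
  stopifnot(reps >= 1, split >= 1, split < n_subjects)
  if (!is.null(seed)) set.seed(seed)
  pvals <- numeric(reps)
  y <- c(rep(0, split), rep(1, n_subjects - split))
  for (it in seq_len(reps)) {
    graphs <- population_cohort(n_subjects, p, sparsity, REsize, REprob, REnoise, n_time, pop_strength)
    D <- pairwise_rpd(unname(graphs), p = 2, allow_disconnected = TRUE)
    pvals[it] <- km_pvalue_distances(D, y, m = m)
  }
  records <- tibble::tibble(iteration = seq_len(reps), condition = "one_population",
                            p_value = pvals, reject = pvals < alpha)
  ci <- stats::binom.test(sum(records$reject), reps)$conf.int
  summary <- tibble::tibble(
    rejection_rate = mean(records$reject),
    n_reps = reps, alpha = alpha,
    ci_lower = ci[1], ci_upper = ci[2]
  )
  new_experiment("Type-I error (one population)", records, summary, reps, seed)
}

#' Noise-allocation sweep under the alternative
#'
#' Two-generation design as in [power_experiment()], but the fraction of the
#' noise population allocated to the control label is varied (by default 5%
#' to 95% in steps of 5%).  Iterations with p-value at or above `alpha` are
#' false negatives, since the control and patient populations genuinely
#' differ.
#'
#' @inheritParams power_experiment
#' @param reps_per_point replicates per allocation fraction.
#' @param fractions noise-allocation fractions to sweep.
#' @return An `rpd_experiment`; records carry `allocation` and `p_value`,
#'   summary the false-negative rate per allocation.
#' @export
noise_allocation_sweep <- function(reps_per_point = 100,
                                   fractions = seq(0.05, 0.95, by = 0.05),
                                   alpha = 0.05,
                                   n_control_pop = 10, n_patient_pop = 10,
                                   n_noise = 80,
                                   p = 90, sparsity = 0.75, REsize = 10,
                                   REprob = 0.65, REnoise = 3, n_time = 150,
                                   pop_strength = 15, m = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  recs <- vector("list", length(fractions))
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    n_to_ctrl <- round(f * n_noise)
    pv <- numeric(reps_per_point)
    for (it in seq_len(reps_per_point)) {
      ctrl <- population_cohort(n_control_pop, p, sparsity, REsize, REprob, REnoise, n_time, pop_strength)
      pat <- population_cohort(n_patient_pop, p, sparsity, REsize, REprob, REnoise, n_time, pop_strength)
      noise <- population_cohort(n_noise, p, sparsity, REsize, REprob, REnoise, n_time, pop_strength)
      graphs <- c(ctrl, noise[seq_len(n_to_ctrl)], pat,
                  noise[setdiff(seq_len(n_noise), seq_len(n_to_ctrl))])
      y <- c(rep(0, n_control_pop + n_to_ctrl),
             rep(1, n_patient_pop + n_noise - n_to_ctrl))
      D <- pairwise_rpd(unname(graphs), p = 2, allow_disconnected = TRUE)
      pv[it] <- km_pvalue_distances(D, y, m = m)
    }
    recs[[fi]] <- tibble::tibble(allocation = f, iteration = seq_len(reps_per_point),
                                 p_value = pv, false_negative = pv >= alpha)
  }
  records <- dplyr::bind_rows(recs)
  summary <- records |>
    dplyr::group_by(.data$allocation) |>
    dplyr::summarise(false_negative_rate = mean(.data$false_negative),
                     .groups = "drop")
  new_experiment("noise-allocation sweep", records, summary,
                 length(fractions) * reps_per_point, seed)
}

#' Label-split sweep under the null
#'
#' One cohort of `n_subjects` graphs is generated from a single population
#' process, and the score test is run once per relabeling: the number of
#' subjects labelled as controls sweeps `splits` (default 5 to 95 by 1).
#' Because all subjects are exchangeable, any p-value below `alpha` is a
#' false positive.  The pairwise distances and bandwidth kernels are computed
#' once and shared across splits.
#'
#' @inheritParams type1_experiment
#' @param splits integer vector of control-group sizes.
#' @return An `rpd_experiment`; records carry `split` and `p_value`, summary
#'   the overall false-positive rate.
#' @export
label_split_sweep <- function(splits = 5:95, alpha = 0.05, n_subjects = 100,
                              p = 90, sparsity = 0.75, REsize = 10,
                              REprob = 0.65, REnoise = 3, n_time = 150,
                              pop_strength = 15, m = 50, seed = NULL) {
  stopifnot(all(splits >= 1), all(splits < n_subjects))
  if (!is.null(seed)) set.seed(seed)
  graphs <- population_cohort(n_subjects, p, sparsity, REsize, REprob, REnoise, n_time, pop_strength)
  D <- pairwise_rpd(unname(graphs), p = 2, allow_disconnected = TRUE)
  bounds <- rho_bounds(D)
  grid <- rho_grid(bounds, m = m)
  kernels <- lapply(grid, function(r) build_kernel(D, r, check_psd = FALSE))
  pv <- vapply(splits, function(s) {
    y <- c(rep(0, s), rep(1, n_subjects - s))
    km_pvalue_kernels(kernels, grid, y)
  }, 0)
  records <- tibble::tibble(split = splits, p_value = pv,
                            false_positive = pv < alpha)
  summary <- tibble::tibble(
    false_positive_rate = mean(records$false_positive),
    n_tests = length(splits), alpha = alpha
  )
  new_experiment("label-split sweep", records, summary, length(splits), seed)
}
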