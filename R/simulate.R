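#' Specification of a synthetic functional-connectivity cohort
#'
#' Collects the generator parameters for a cohort of correlation-derived
#' connectivity networks that share a population topology.  Each subject's
#' precision matrix is the sum of a common population component (scale-free,
#' from preferential attachment) and a subject-specific Erdos-Renyi
#' perturbation; after a positive-definite correction, `n_time` multivariate
#' normal observations are drawn and their empirical correlation matrix is
#' converted to a weighted graph.
#'
#' Defaults are the settings used throughout the simulation studies:
#' `p = 90` nodes, `sparsity = 0.75` (fraction of absent population edges),
#' `REsize = 10` (percent of population edges eligible for subject effects),
#' `REprob = 0.65` (inclusion probability of an eligible edge), and
#' `REnoise = 3` (standard deviation of a subject-effect precision entry).
#' `n_time = 150` emulates a typical resting-state acquisition length.
#' `pop_strength = 15` scales the population edge strengths relative to the
#' fixed subject-effect scale; it is calibrated once so that cohorts drawn
#' from different population networks are separable while subject-level
#' variability remains visible (see the methods vignette for the rationale
#' and sensitivity).
#'
#' @param p node count (`p >= 5`).
#' @param n_subjects cohort size.
#' @param sparsity target fraction of absent edges in the population network,
#'   in (0, 1).
#' @param REsize percentage (0-100) of vertex pairs eligible for
#'   subject-specific precision effects.
#' @param REprob inclusion probability for each eligible pair.
#' @param REnoise standard deviation of the subject-effect entries
#'   (`REnoise = 0` disables inter-subject variability).
#' @param n_time observations per subject (`n_time >= p + 5` so the sample
#'   correlation is well defined).
#' @param pop_strength multiplier on the population edge strengths (see
#'   Details).
#' @param seed optional integer seed, recorded in outputs; when `NULL` the
#'   caller's RNG stream is used unchanged.
#' @param negative_mode how negative empirical correlations are resolved; see
#'   [prepare_connectivity()].
#' @param method `"sampled"` (default) derives each subject's graph from the
#'   empirical correlation of simulated data; `"direct"` bypasses sampling
#'   and uses the partial correlations implied by the precision matrix
#'   (a noise-free variant).
#' @return Object of class `cohort_spec` (a validated named list).
#' @export
cohort_spec <- function(p = 90, n_subjects = 100, sparsity = 0.75,
                        REsize = 10, REprob = 0.65, REnoise = 3,
                        n_time = 150, seed = NULL,
                        negative_mode = c("zero", "keep", "abs", "normalize"),
                        method = c("sampled", "direct"),
                        pop_strength = 15) {
  negative_mode <- match.arg(negative_mode)
  method <- match.arg(method)
  stopifnot(
    p >= 5, n_subjects >= 1,
    sparsity > 0, sparsity < 1,
    REsize >= 0, REsize <= 100,
    REprob >= 0, REprob <= 1,
    REnoise >= 0, pop_strength > 0
  )
  if (method == "sampled" && n_time < p + 5) {
    stop("`n_time` must be at least p + 5 for a well-defined sample correlation",
         call. = FALSE)
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(p = as.integer(p), n_subjects = as.integer(n_subjects),
         sparsity = sparsity, REsize = REsize, REprob = REprob,
         REnoise = REnoise, n_time = as.integer(n_time), seed = seed,
         negative_mode = negative_mode, method = method,
         pop_strength = pop_strength),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec: p=%d, n=%d, sparsity=%.2f, REsize=%g, REprob=%.2f, REnoise=%g, n_time=%d, %s/%s%s>\n",
    x$p, x$n_subjects, x$sparsity, x$REsize, x$REprob, x$REnoise, x$n_time,
    x$method, x$negative_mode,
    if (is.null(x$seed)) "" else sprintf(", seed=%d", x$seed)
  ))
  invisible(x)
}

# Number of edges a preferential-attachment graph on p vertices reaches with
# attachment count m: vertex i (i = 2..p) attaches min(m, i - 1) edges.
pa_edge_count <- function(p, m) sum(pmin(m, seq_len(p - 1)))

#' Scale-free population precision component
#'
#' Draws a preferential-attachment (Barabasi-Albert) topology whose expected
#' edge density matches `1 - sparsity`, then assigns each edge a signed
#' strength: magnitude uniform on (0.3, 1) times `strength`, sign positive
#' with probability 1/2.  Mixed signs at the precision level produce the
#' mixed positive and negative correlations typical of
#' functional-connectivity data; they are resolved at the correlation stage
#' by `negative_mode`.  `strength` sets the scale of the shared population
#' component relative to the (absolute) subject-effect scale `REnoise`;
#' cohort-level drivers pass the spec's `pop_strength`.
#'
#' The attachment count per new vertex is chosen to minimise the gap between
#' the realised edge count and `(1 - sparsity) * choose(p, 2)`.  Uses the
#' current R RNG stream; call [set.seed()] for reproducibility.
#'
#' @param p node count (`p >= 5`).
#' @param sparsity target fraction of absent edges, in (0, 1).
#' @param strength multiplier on the edge-strength magnitudes.
#' @return Symmetric `p x p` matrix with zero diagonal (the population
#'   component of every subject's precision matrix).
#' @export
generate_population_network <- function(p, sparsity, strength = 1) {
  stopifnot(p >= 5, sparsity > 0, sparsity < 1, strength > 0)
  target <- (1 - sparsity) * choose(p, 2)
  if (target < p - 1) {
    stop("density target infeasible: (1 - sparsity) * choose(p, 2) = ",
         format(target), " is below the p - 1 edges of a minimal ",
         "preferential-attachment graph", call. = FALSE)
  }
  counts <- vapply(seq_len(p - 1), pa_edge_count, 0, p = p)
  m <- which.min(abs(counts - target))
  g <- igraph::sample_pa(p, power = 1, m = m, directed = FALSE)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A[A > 1] <- 1
  ut <- upper.tri(A)
  idx <- which(ut & A == 1)
  vals <- strength * stats::runif(length(idx), 0.3, 1) *
    sample(c(-1, 1), length(idx), replace = TRUE)
  W <- matrix(0, p, p)
  W[idx] <- vals
  W + t(W)
}

#' Subject-specific Erdos-Renyi precision effects
#'
#' Models inter-subject variability of the shared edges: selects
#' `ceiling(REsize/100 * n_edges)` candidate positions uniformly among the
#' population network's edges, includes each independently with probability
#' `REprob`, and assigns included positions a Normal(0, REnoise^2) precision
#' perturbation.  (If the supplied population matrix has no edges, candidates
#' fall back to all vertex pairs.)  Uses the current R RNG stream.
#'
#' @param pop population component matrix; its nonzero pattern defines the
#'   candidate edge set.
#' @param REsize,REprob,REnoise see [cohort_spec()].
#' @return Symmetric `p x p` matrix with zero diagonal.
#' @export
generate_subject_effects <- function(pop, REsize, REprob, REnoise) {
  stopifnot(is.matrix(pop), REsize >= 0, REsize <= 100,
            REprob >= 0, REprob <= 1, REnoise >= 0)
  p <- nrow(pop)
  W <- matrix(0, p, p)
  if (REsize == 0 || REprob == 0 || REnoise == 0) return(W)
  pool <- which(upper.tri(pop) & pop != 0)
  if (!length(pool)) pool <- which(upper.tri(W))
  n_cand <- ceiling(REsize / 100 * length(pool))
  cand <- sample(pool, n_cand)
  keep <- cand[stats::runif(n_cand) < REprob]
  W[keep] <- stats::rnorm(length(keep), 0, REnoise)
  W + t(W)
}

#' Positive-definite correction by diagonal shift
#'
#' If the smallest eigenvalue of a symmetric matrix is at most `eps`, shifts
#' the diagonal by `|lambda_min| + eps`; otherwise returns the matrix
#' unchanged.  The output's smallest eigenvalue is at least `eps`.
#'
#' @param M symmetric matrix.
#' @param eps minimum acceptable eigenvalue (default 0.1).
#' @return Positive-definite matrix.
#' @export
make_positive_definite <- function(M, eps = 0.1) {
  if (!is.matrix(M) || nrow(M) != ncol(M) ||
      max(abs(M - t(M))) > 1e-10 * max(abs(M), 1)) {
    stop("`M` must be a symmetric matrix", call. = FALSE)
  }
  lmin <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  if (lmin > eps) return(M)
  M + (abs(lmin) + eps) * diag(nrow(M))
}

# One subject's connectivity graph from a combined precision matrix.
subject_graph <- function(theta, n_time, negative_mode, method) {
  P <- make_positive_definite(theta)
  if (method == "direct") {
    s <- 1 / sqrt(diag(P))
    C <- -P * outer(s, s)
    diag(C) <- 0
    return(prepare_connectivity(C, negative_mode = negative_mode))
  }
  U <- chol(P)   # P = U'U, so solving U x = z gives x ~ N(0, P^{-1})
  p <- nrow(P)
  Z <- matrix(stats::rnorm(p * n_time), p, n_time)
  X <- t(backsolve(U, Z))
  prepare_connectivity(stats::cor(X), negative_mode = negative_mode)
}

#' Sample a cohort of connectivity graphs
#'
#' For each subject: draw Erdos-Renyi subject effects, add them to the
#' population component, apply the positive-definite correction, sample
#' `n_time` i.i.d. multivariate normal observations from the inverse of the
#' corrected precision matrix, take the empirical correlation matrix, and
#' convert it to a [weighted_graph()] with the spec's `negative_mode`
#' (`method = "direct"` replaces the sampling step with the precision
#' matrix's partial correlations).  Subjects whose zeroed-negative graph is
#' disconnected are redrawn up to `resample_max` times; any survivor is kept
#' disconnected and flagged, so downstream code can use the formal
#' pseudo-inverse path.  Resampling events are recorded in the `"resamples"`
#' attribute.
#'
#' @param spec a [cohort_spec()].
#' @param pop population component matrix, e.g. from
#'   [generate_population_network()]; must be `p x p`.
#' @param seed optional seed applied before sampling (defaults to
#'   `spec$seed`); `NULL` leaves the caller's RNG stream untouched so cohorts
#'   can be composed inside larger seeded simulations.
#' @param resample_max redraw budget per disconnected subject.
#' @return Named list of `weighted_graph`s (ids `S001`, ...) with attributes
#'   `spec` and `resamples` (tibble: subject, attempts, connected).
#' @export
sample_cohort <- function(spec, pop, seed = spec$seed, resample_max = 10) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.matrix(pop) || nrow(pop) != spec$p || ncol(pop) != spec$p) {
    stop("`pop` must be a ", spec$p, " x ", spec$p, " matrix", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  graphs <- vector("list", spec$n_subjects)
  log <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    attempts <- 0
    repeat {
      attempts <- attempts + 1
      theta_i <- generate_subject_effects(pop, spec$REsize, spec$REprob, spec$REnoise)
      g <- subject_graph(pop + theta_i, spec$n_time, spec$negative_mode, spec$method)
      connected <- if (g$signed) TRUE else is_connected(g)
      if (connected || attempts > resample_max) break
    }
    graphs[[i]] <- g
    log[[i]] <- tibble::tibble(subject = i, attempts = attempts,
                               connected = connected)
  }
  names(graphs) <- sprintf("S%03d", seq_len(spec$n_subjects))
  attr(graphs, "spec") <- spec
  attr(graphs, "resamples") <- dplyr::bind_rows(log)
  graphs
}

#' Simulate a labelled cohort and return a tidy manifest
#'
#' Convenience wrapper around [generate_population_network()] and
#' [sample_cohort()]: seeds the RNG from the spec, draws one population
#' network and the subject graphs, and returns them with a manifest tibble
#' (subject_id, group).
#'
#' @param spec a [cohort_spec()] (its `seed`, when set, makes the run fully
#'   reproducible).
#' @param group label assigned to every subject in the manifest.
#' @return List of class `rpd_cohort`: `graphs`, `manifest` (tibble), `pop`
#'   (population matrix), `spec`.
#' @export
simulate_cohort <- function(spec, group = "A") {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  pop <- generate_population_network(spec$p, spec$sparsity, spec$pop_strength)
  graphs <- sample_cohort(spec, pop, seed = NULL)
  manifest <- tibble::tibble(subject_id = names(graphs), group = group)
  structure(list(graphs = graphs, manifest = manifest, pop = pop, spec = spec),
            class = "rpd_cohort")
}

#' @export
print.rpd_cohort <- function(x, ...) {
  cat(sprintf("<rpd_cohort: %d subjects, %d nodes>\n",
              length(x$graphs), x$spec$p))
  invisible(x)
}
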