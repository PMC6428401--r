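#' Phenotype design for the kernel-machine score test
#'
#' Builds the outcome vector and parametric design matrix from a phenotype
#' table.  The design always contains an intercept; categorical covariates
#' are one-hot encoded with the first level as reference (via
#' [stats::model.matrix()]).
#'
#' @param data data frame with one row per subject.
#' @param outcome name of the binary outcome column (values 0/1 or a
#'   two-level factor; both classes must be present).
#' @param covariates character vector of covariate column names (may be
#'   empty for an intercept-only null model).
#' @param id name of the subject-id column, or `NULL` to use row order.
#' @return Object of class `phenotype_design`: list with `y` (0/1 vector),
#'   `X` (n x q design matrix, first column intercept) and `subject_ids`.
#' @export
phenotype_design <- function(data, outcome = "outcome", covariates = character(),
                             id = NULL) {
  stopifnot(is.data.frame(data))
  if (!outcome %in% names(data)) stop("outcome column not found: ", outcome, call. = FALSE)
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    stop("covariate columns not found: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  y <- data[[outcome]]
  if (is.factor(y) || is.character(y)) {
    lev <- sort(unique(as.character(y)))
    if (length(lev) != 2) stop("outcome must have exactly two levels", call. = FALSE)
    y <- as.integer(as.character(y) == lev[2])
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome values must be 0/1", call. = FALSE)
  if (length(unique(y)) != 2) stop("both outcome classes must be present", call. = FALSE)
  ids <- if (is.null(id)) {
    if (!is.null(rownames(data))) rownames(data) else as.character(seq_len(nrow(data)))
  } else {
    as.character(data[[id]])
  }
  if (length(covariates)) {
    fml <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
    X <- stats::model.matrix(fml, data = data)
  } else {
    X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  }
  q <- ncol(X)
  if (qr(X)$rank < q) stop("design matrix is rank deficient", call. = FALSE)
  if (nrow(X) < q + 2) stop("need at least q + 2 subjects", call. = FALSE)
  structure(list(y = y, X = X, subject_ids = ids), class = "phenotype_design")
}

#' Null logistic model fit
#'
#' Maximum-likelihood logistic regression of the outcome on the parametric
#' covariates only (the null model of the kernel-machine test), fit by
#' iteratively reweighted least squares.  Returns the quantities the score
#' statistic needs: fitted probabilities, the Bernoulli variance diagonal
#' `D0 = diag[mu(1-mu)]`, and the projection-weighted matrix
#' `P0 = D0 - D0 X (X' D0 X)^{-1} X' D0` (which annihilates the column space
#' of `X`: `P0 X = 0`).
#'
#' @param design a [phenotype_design()].
#' @param max_iter maximum IRLS iterations before declaring non-convergence.
#' @return Object of class `null_fit`: list with `beta0`, `mu0`, `d0`
#'   (the diagonal of `D0`), `P0`, plus `X` and `y`.
#' @export
fit_null_logistic <- function(design, max_iter = 100) {
  stopifnot(inherits(design, "phenotype_design"))
  X <- design$X
  y <- design$y
  fit <- suppressWarnings(stats::glm.fit(
    X, y,
    family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = max_iter)
  ))
  mu0 <- fit$fitted.values
  score <- drop(crossprod(X, y - mu0))
  if (any(mu0 < 1e-10) || any(mu0 > 1 - 1e-10)) {
    stop("null logistic fit did not converge (perfect or quasi-perfect separation)",
         call. = FALSE)
  }
  if (max(abs(score)) > 1e-8) {
    stop("null logistic fit did not converge: max score ",
         format(max(abs(score))), call. = FALSE)
  }
  d0 <- mu0 * (1 - mu0)
  DX <- X * d0
  P0 <- diag(d0) - DX %*% solve(crossprod(X, DX), t(DX))
  P0 <- (P0 + t(P0)) / 2
  structure(
    list(beta0 = fit$coefficients, mu0 = mu0, d0 = d0, P0 = P0, X = X, y = y),
    class = "null_fit"
  )
}

#' Bandwidth search bounds for the Gaussian distance kernel
#'
#' Following the grid-search recommendation for variance-component score
#' tests with an inestimable bandwidth, the search interval is
#' `L = 0.1 * min d^2` and `U = 100 * max d^2` over distinct subject pairs,
#' where the squared pairwise distance plays the role of the squared
#' Euclidean distance between the subjects' feature vectors (here, the
#' vectorised effective-resistance matrices).  Zero distances between
#' duplicated subjects are excluded from the minimum so that `L > 0`.
#'
#' @param distances symmetric matrix of pairwise distances.
#' @return Named numeric vector `c(L = , U = )` with `0 < L < U`.
#' @export
rho_bounds <- function(distances) {
  d <- distances[upper.tri(distances)]
  pos <- d[d > 0]
  if (!length(pos)) {
    stop("degenerate distance matrix: all pairwise distances are zero", call. = FALSE)
  }
  L <- 0.1 * min(pos)^2
  U <- 100 * max(pos)^2
  c(L = L, U = U)
}

#' Gaussian distance kernel
#'
#' `K[i, j] = exp(-d(i, j)^2 / rho)`.  When the distance is Euclidean-
#' embeddable (the `p = 2` resistance perturbation distance is: it is the
#' Euclidean distance between vectorised resistance matrices) the kernel is
#' positive semi-definite for every `rho > 0`, so no spectral check is
#' needed.  For other distances set `check_psd = TRUE`: eigenvalues in
#' `[-1e-8, 0)` are clipped to zero, anything more negative is an error.
#'
#' @param distances symmetric matrix of pairwise distances.
#' @param rho bandwidth, `rho > 0`.
#' @param check_psd logical; verify/repair positive semi-definiteness.
#' @return Symmetric kernel matrix with unit diagonal.
#' @export
build_kernel <- function(distances, rho, check_psd = FALSE) {
  if (!is.numeric(rho) || length(rho) != 1 || !is.finite(rho) || rho <= 0) {
    stop("`rho` must be a single positive number", call. = FALSE)
  }
  K <- exp(-(distances^2) / rho)
  diag(K) <- 1
  K <- (K + t(K)) / 2
  if (check_psd) {
    ed <- eigen(K, symmetric = TRUE)
    lmin <- min(ed$values)
    if (lmin < -1e-8) {
      stop("kernel is not positive semi-definite (min eigenvalue ",
           format(lmin), "); the supplied distance is not Euclidean-embeddable",
           call. = FALSE)
    }
    if (lmin < 0) {
      vals <- pmax(ed$values, 0)
      K <- ed$vectors %*% (vals * t(ed$vectors))
      K <- (K + t(K)) / 2
    }
  }
  K
}

#' Variance-component score statistic for one kernel
#'
#' For the semiparametric logistic model with subject similarity kernel `K`,
#' the score statistic for the null hypothesis that the kernel variance
#' component is zero is
#' `Q = (y - mu0)' K (y - mu0)`, with null mean `mu_Q = trace(P0 K)` and
#' variance `sigma_Q^2 = 2 trace(P0 K P0 K)`; the standardised statistic is
#' `S = (Q - mu_Q) / sigma_Q`.  No 1/2 factor is carried on `Q`; the same
#' convention is used in `mu_Q` and `sigma_Q`, so `S` is unaffected.
#'
#' @param null a [fit_null_logistic()] result.
#' @param K kernel matrix.
#' @param y outcome vector (defaults to the one stored in `null`).
#' @return List with `Q`, `mu_Q`, `sigma_Q`, `S`, and a `degenerate` flag
#'   (`TRUE` when `sigma_Q^2 <= 1e-14`, in which case `S` is `NA` and the
#'   grid point should be skipped).
#' @export
score_statistic <- function(null, K, y = null$y) {
  stopifnot(inherits(null, "null_fit"))
  n <- length(null$mu0)
  if (!is.matrix(K) || nrow(K) != n || ncol(K) != n) {
    stop("kernel dimensions do not match the null fit", call. = FALSE)
  }
  if (length(y) != n) stop("outcome length does not match the null fit", call. = FALSE)
  r <- y - null$mu0
  Q <- drop(crossprod(r, K %*% r))
  A <- null$P0 %*% K
  mu_Q <- sum(diag(A))
  sigma2 <- 2 * sum(A * t(A))
  if (sigma2 <= 1e-14) {
    return(list(Q = Q, mu_Q = mu_Q, sigma_Q = sqrt(max(sigma2, 0)),
                S = NA_real_, degenerate = TRUE))
  }
  sigma_Q <- sqrt(sigma2)
  list(Q = Q, mu_Q = mu_Q, sigma_Q = sigma_Q, S = (Q - mu_Q) / sigma_Q,
       degenerate = FALSE)
}

#' Davies-type upper bound on the p-value of a maximised score process
#'
#' The standardised score statistic indexed by the kernel bandwidth is
#' approximately a Gaussian process under the null; for its maximum `M` over
#' the searched grid, an upper bound on the p-value is
#' \deqn{\Phi(-M) + W \exp(-M^2/2)/\sqrt{8\pi},}
#' where `W` is the total variation of the process over the grid (the sum of
#' absolute increments between consecutive grid points, endpoints included).
#'
#' @param S_values numeric vector of standardised scores over the grid.
#' @param grid strictly increasing bandwidth values matching `S_values`.
#' @return List with `p_upper` (clipped to at most 1), `p_raw` (unclipped
#'   bound), `M`, and `W`.
#' @export
davies_upper_bound <- function(S_values, grid) {
  if (length(grid) < 2 || length(S_values) != length(grid)) {
    stop("need a grid of length >= 2 matching S_values", call. = FALSE)
  }
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  if (any(!is.finite(S_values))) stop("S_values must be finite", call. = FALSE)
  M <- max(S_values)
  W <- sum(abs(diff(S_values)))
  p_raw <- stats::pnorm(-M) + W * exp(-M^2 / 2) / sqrt(8 * pi)
  list(p_upper = min(p_raw, 1), p_raw = p_raw, M = M, W = W)
}

# Log-spaced bandwidth grid with endpoints: {L, m interior points, U}.
rho_grid <- function(bounds, m = 50) {
  exp(seq(log(bounds[["L"]]), log(bounds[["U"]]), length.out = m + 2))
}

# Score process over a precomputed kernel list; shared by kernel_machine_test
# and the relabeling sweeps (which reuse kernels across many outcome splits).
score_process <- function(null, kernels, grid) {
  stats_list <- lapply(kernels, score_statistic, null = null)
  tibble::tibble(
    rho = grid,
    Q = vapply(stats_list, `[[`, 0, "Q"),
    mu_Q = vapply(stats_list, `[[`, 0, "mu_Q"),
    sigma_Q = vapply(stats_list, `[[`, 0, "sigma_Q"),
    S = vapply(stats_list, `[[`, 0, "S"),
    degenerate = vapply(stats_list, `[[`, TRUE, "degenerate")
  )
}

davies_from_process <- function(proc) {
  keep <- !proc$degenerate
  if (sum(keep) < 2) {
    stop("fewer than 2 non-degenerate bandwidth grid points survive", call. = FALSE)
  }
  davies_upper_bound(proc$S[keep], proc$rho[keep])
}

#' Kernel-machine score test of association between networks and a phenotype
#'
#' End-to-end test of whether between-subject similarity of connectivity
#' graphs (measured through the resistance perturbation distance) explains a
#' binary phenotype beyond the parametric covariates.  Pipeline: pairwise
#' distances (computed here if graphs are supplied), bandwidth search bounds,
#' a log-spaced bandwidth grid with `m` interior points, the standardised
#' variance-component score statistic at every grid point, and the
#' Davies-type upper bound on the p-value of the maximised process.
#' Grid points with a degenerate score variance are dropped (at least two
#' must survive).  The result records every intermediate quantity.
#'
#' @param x either a list of [weighted_graph()]s or a precomputed symmetric
#'   distance matrix whose row order matches `design`.
#' @param design a [phenotype_design()].
#' @param p norm order of the resistance perturbation distance (only used
#'   when `x` is a list of graphs).  `p = 2` guarantees a positive
#'   semi-definite kernel; other orders trigger a spectral check.
#' @param m number of interior bandwidth grid points (grid size `m + 2`).
#' @param allow_disconnected passed to [pairwise_rpd()].
#' @return Object of class `rpd_score_test`; see [tidy.rpd_score_test()] and
#'   [glance.rpd_score_test()].
#' @examples
#' set.seed(7)
#' spec <- cohort_spec(p = 15, n_subjects = 20, sparsity = 0.6, REnoise = 1)
#' graphs <- sample_cohort(spec, generate_population_network(15, 0.6))
#' design <- phenotype_design(data.frame(outcome = rep(0:1, each = 10)))
#' fit <- kernel_machine_test(graphs, design)
#' glance(fit)
#' @export
kernel_machine_test <- function(x, design, p = 2, m = 50,
                                allow_disconnected = FALSE) {
  stopifnot(inherits(design, "phenotype_design"))
  n <- length(design$y)
  if (is.list(x) && !is.matrix(x)) {
    if (length(x) != n) {
      stop("number of graphs (", length(x), ") does not match phenotype rows (",
           n, ")", call. = FALSE)
    }
    D <- pairwise_rpd(x, p = p, allow_disconnected = allow_disconnected)
  } else {
    D <- x
    if (!is.matrix(D) || nrow(D) != n || ncol(D) != n) {
      stop("distance matrix dimensions do not match the phenotype table", call. = FALSE)
    }
  }
  bounds <- rho_bounds(D)
  grid <- rho_grid(bounds, m = m)
  check <- p != 2
  kernels <- lapply(grid, function(r) build_kernel(D, r, check_psd = check))
  null <- fit_null_logistic(design)
  proc <- score_process(null, kernels, grid)
  dav <- davies_from_process(proc)
  structure(
    list(
      p_upper = dav$p_upper, p_raw = dav$p_raw, M = dav$M, W = dav$W,
      L = bounds[["L"]], U = bounds[["U"]],
      grid = proc, p_norm_order = p, n = n,
      null_fit = null, distances = D, subject_ids = design$subject_ids
    ),
    class = "rpd_score_test"
  )
}

#' @export
print.rpd_score_test <- function(x, ...) {
  cat("Kernel-machine score test (resistance perturbation distance)\n")
  cat(sprintf("  subjects: %d   RPD norm order: %g\n", x$n, x$p_norm_order))
  cat(sprintf("  rho grid: [%g, %g], %d points (%d degenerate dropped)\n",
              x$L, x$U, nrow(x$grid), sum(x$grid$degenerate)))
  cat(sprintf("  max standardised score M = %.4f, total variation W = %.4f\n",
              x$M, x$W))
  cat(sprintf("  Davies upper bound on p-value: %.4g\n", x$p_upper))
  invisible(x)
}

#' Tidy the bandwidth grid of a kernel-machine score test
#'
#' @param x an `rpd_score_test`.
#' @param ... unused.
#' @return Tibble with one row per bandwidth grid point: `rho`, `Q`, `mu_Q`,
#'   `sigma_Q`, `S`, `degenerate`.
#' @method tidy rpd_score_test
#' @export
tidy.rpd_score_test <- function(x, ...) x$grid

#' One-row summary of a kernel-machine score test
#'
#' @param x an `rpd_score_test`.
#' @param ... unused.
#' @return One-row tibble with `p_upper`, `M`, `W`, `L`, `U`, `n`,
#'   `p_norm_order` and the surviving grid size.
#' @method glance rpd_score_test
#' @export
glance.rpd_score_test <- function(x, ...) {
  tibble::tibble(
    p_upper = x$p_upper, M = x$M, W = x$W, L = x$L, U = x$U,
    n = x$n, p_norm_order = x$p_norm_order,
    n_grid = sum(!x$grid$degenerate)
  )
}

#' Plot the standardised score process over the bandwidth grid
#'
#' @param object an `rpd_score_test`.
#' @param ... unused.
#' @return A ggplot of `S(rho)` against `rho` (log scale), with the maximum
#'   `M` marked.
#' @method autoplot rpd_score_test
#' @export
autoplot.rpd_score_test <- function(object, ...) {
  df <- dplyr::filter(object$grid, !.data$degenerate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$S)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$M, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = expression(rho), y = expression(S(rho)),
      title = "Standardised score process over the bandwidth grid",
      subtitle = sprintf("M = %.3f, W = %.3f, Davies upper bound p = %.3g",
                         object$M, object$W, object$p_upper)
    )
}

#' Semiparametric logistic fit with a kernel random effect
#'
#' Fits `logit Pr(Y = 1) = X beta + h`, `h = K alpha`, for a fixed variance
#' component `tau` (ridge penalty `1/tau` on the kernel effect), by the
#' blockwise Newton-Raphson scheme on the working response
#' `ytilde = X beta + K alpha + D^{-1}(y - mu)` with weight matrix
#' `D = diag[mu(1-mu)]`.  This estimator is for visualising the fitted
#' network effect `h`; inference uses [kernel_machine_test()], not this fit.
#'
#' @param design a [phenotype_design()].
#' @param K positive semi-definite kernel matrix.
#' @param tau variance component, `tau > 0`.  As `tau -> 0` the fit collapses
#'   to the parametric null logistic model (`h -> 0`).
#' @param max_iter,tol Newton iteration controls (max |parameter update| <
#'   `tol` declares convergence).
#' @return List with `beta`, `alpha`, `h = K alpha`, `iterations`,
#'   `converged`.
#' @export
fit_semiparametric <- function(design, K, tau, max_iter = 100, tol = 1e-8) {
  stopifnot(inherits(design, "phenotype_design"))
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) {
    stop("`tau` must be a single positive number", call. = FALSE)
  }
  X <- design$X
  y <- design$y
  n <- length(y)
  q <- ncol(X)
  if (!is.matrix(K) || nrow(K) != n || ncol(K) != n) {
    stop("kernel dimensions do not match the design", call. = FALSE)
  }
  beta <- rep(0, q)
  alpha <- rep(0, n)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta + K %*% alpha)
    mu <- stats::plogis(eta)
    d <- pmax(mu * (1 - mu), 1e-10)
    ytilde <- eta + (y - mu) / d
    dX <- X * d
    dK <- K * d   # rows scaled: D %*% K
    lhs <- rbind(
      cbind(crossprod(X, dX), crossprod(X, dK)),
      cbind(dX, diag(n) / tau + dK)
    )
    rhs <- c(drop(crossprod(X, d * ytilde)), d * ytilde)
    sol <- solve(lhs, rhs)
    delta <- max(abs(sol - c(beta, alpha)))
    beta <- sol[seq_len(q)]
    alpha <- sol[-seq_len(q)]
    trace <- c(trace, delta)
    if (delta < tol) {
      return(list(beta = beta, alpha = alpha, h = drop(K %*% alpha),
                  iterations = it, converged = TRUE))
    }
  }
  stop("semiparametric fit did not converge after ", max_iter,
       " iterations; last updates: ",
       paste(format(utils::tail(trace, 5), digits = 3), collapse = ", "),
       call. = FALSE)
}
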