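#' Construct a weighted graph from a symmetric weight matrix
#'
#' A `weighted_graph` is an undirected graph on a fixed vertex set,
#' represented by its symmetric weight (adjacency) matrix.  Weights are
#' correlation-like edge strengths: larger values mean stronger coupling
#' between the two vertices.  Self-loops are not allowed.  By default all
#' weights must be non-negative; `signed = TRUE` permits negative weights
#' (used when negative correlations are deliberately retained), at the cost
#' that the Laplacian is no longer guaranteed positive semi-definite.
#'
#' @param weights square numeric matrix of edge weights; must be symmetric to
#'   within `tol` and have a (numerically) zero diagonal.
#' @param labels optional character vector of vertex names; defaults to the
#'   row names of `weights` when present.
#' @param signed logical; allow negative edge weights.
#' @param tol numeric tolerance for the symmetry and zero-diagonal checks.
#' @return An object of class `weighted_graph`: a list with elements `n`,
#'   `weights`, `labels` and `signed`.
#' @examples
#' g <- weighted_graph(matrix(c(0, 1, 1, 0), 2, 2))
#' laplacian(g)
#' @export
weighted_graph <- function(weights, labels = NULL, signed = FALSE, tol = 1e-12) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("invalid graph: `weights` must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(weights)
  if (ncol(weights) != n) {
    stop("invalid graph: weight matrix must be square", call. = FALSE)
  }
  if (n < 2) stop("invalid graph: need at least 2 vertices", call. = FALSE)
  if (any(!is.finite(weights))) {
    stop("invalid graph: weights contain non-finite entries", call. = FALSE)
  }
  scale <- max(abs(weights), 1)
  if (max(abs(weights - t(weights))) > tol * scale) {
    stop("invalid graph: weight matrix is not symmetric", call. = FALSE)
  }
  if (max(abs(diag(weights))) > tol * scale) {
    stop("invalid graph: nonzero diagonal (self-loops are not allowed)", call. = FALSE)
  }
  if (!signed && min(weights) < -tol * scale) {
    stop("invalid graph: negative weights require signed = TRUE", call. = FALSE)
  }
  w <- (weights + t(weights)) / 2
  diag(w) <- 0
  if (!signed) w[w < 0] <- 0   # only sub-tolerance noise can be negative here
  if (is.null(labels)) labels <- rownames(weights)
  if (!is.null(labels)) {
    if (length(labels) != n) stop("invalid graph: `labels` length must equal n", call. = FALSE)
    dimnames(w) <- list(labels, labels)
  }
  structure(
    list(n = n, weights = w, labels = labels, signed = signed),
    class = "weighted_graph"
  )
}

#' @export
print.weighted_graph <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf(
    "<weighted_graph: %d vertices, %d edges%s>\n",
    x$n, ne, if (x$signed) ", signed" else ""
  ))
  invisible(x)
}

as_weight_matrix <- function(graph) {
  if (inherits(graph, "weighted_graph")) return(graph$weights)
  if (is.matrix(graph)) return(weighted_graph(graph, signed = min(graph) < 0)$weights)
  stop("expected a weighted_graph or a weight matrix", call. = FALSE)
}

#' Graph Laplacian
#'
#' Computes the (combinatorial) Laplacian `L = D - A`, where `A` is the
#' weight matrix and `D` the diagonal matrix of weighted degrees (row sums of
#' `A`).  For non-negative weights `L` is symmetric positive semi-definite
#' with row sums zero; its null space is spanned by the indicator vectors of
#' the connected components.
#'
#' @param graph a [weighted_graph()] or a symmetric weight matrix.
#' @return A symmetric `n x n` Laplacian matrix.
#' @export
laplacian <- function(graph) {
  A <- as_weight_matrix(graph)
  L <- -A
  diag(L) <- rowSums(A)
  L
}

# Spectral connectivity test: the graph is connected iff the second-smallest
# Laplacian eigenvalue exceeds a scale-free threshold relative to the largest.
connectivity_info <- function(L, rel_tol = 1e-9) {
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  n <- length(ev)
  lambda_max <- max(ev[1], .Machine$double.eps)
  list(
    connected = ev[n - 1] > rel_tol * lambda_max,
    values = ev,
    rank_tol = rel_tol * lambda_max
  )
}

#' Is a graph connected?
#'
#' Uses the algebraic connectivity (Fiedler value): the graph is declared
#' connected iff the second-smallest Laplacian eigenvalue exceeds
#' `1e-9` times the largest eigenvalue.
#'
#' @inheritParams laplacian
#' @return Logical scalar.
#' @export
is_connected <- function(graph) {
  connectivity_info(laplacian(graph))$connected
}

component_membership <- function(weights) {
  g <- igraph::graph_from_adjacency_matrix(
    (weights != 0) * 1, mode = "undirected", diag = FALSE
  )
  igraph::components(g)$membership
}

#' Effective resistance matrix of a graph
#'
#' Treats each edge as a resistor of conductance equal to its weight and
#' returns the matrix of pairwise effective resistances,
#' \deqn{R = \mathrm{diag}(L^+) 1^T + 1\, \mathrm{diag}(L^+)^T - 2 L^+,}
#' where \eqn{L^+} is the Moore--Penrose pseudo-inverse of the Laplacian.
#' For a connected graph with non-negative weights, `R[i, j]` is the
#' electrical resistance between vertices i and j; it is itself a metric on
#' the vertex set.  For a disconnected graph (`allow_disconnected = TRUE`,
#' used when a perturbation deliberately disconnects a graph) the Laplacian
#' null directions beyond the trivial constant vector are given a small
#' conductance `regularization` before inversion.  This matches the
#' continuous limit of letting a bridge weight go to zero -- the resistance
#' across a vanishing bridge grows without bound -- so disconnection is
#' penalised with a large-but-finite cross-component resistance of order
#' `1/regularization`, while within-component resistances remain exact
#' (null vectors are constant on components).  `regularization = 0` gives
#' the bare Moore-Penrose pseudo-inverse, whose small formal cross-component
#' values do not penalise disconnection.
#'
#' @inheritParams laplacian
#' @param allow_disconnected logical; if `FALSE` (default) a disconnected
#'   graph is an error naming the components.
#' @param regularization conductance assigned to the non-trivial null
#'   directions of a disconnected Laplacian (default `1e-6`).
#' @return An object of class `effective_resistance`: list with the
#'   resistance matrix `R`, the (regularised) pseudo-inverse
#'   `laplacian_pinv`, and a `connected` flag.
#' @examples
#' path <- weighted_graph(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3))
#' effective_resistance(path)$R[1, 3]  # two unit resistors in series: 2
#' @export
effective_resistance <- function(graph, allow_disconnected = FALSE,
                                 regularization = 1e-6) {
  L <- laplacian(graph)
  n <- nrow(L)
  ed <- eigen(L, symmetric = TRUE)
  lambda_max <- max(ed$values[1], .Machine$double.eps)
  rank_tol <- 1e-9 * lambda_max
  connected <- ed$values[n - 1] > rank_tol
  if (!connected && !allow_disconnected) {
    memb <- component_membership(as_weight_matrix(graph))
    comps <- split(seq_len(n), memb)
    stop(
      "graph is disconnected (components: ",
      paste(vapply(comps, function(i) paste0("{", paste(i, collapse = ","), "}"), ""),
            collapse = " "),
      "); use allow_disconnected = TRUE to evaluate regularised resistances",
      call. = FALSE
    )
  }
  null_inv <- if (connected || regularization <= 0) 0 else 1 / regularization
  inv_vals <- ifelse(abs(ed$values) > rank_tol, 1 / ed$values, null_inv)
  Lp <- ed$vectors %*% (inv_vals * t(ed$vectors))
  if (null_inv > 0) Lp <- Lp - null_inv / n  # drop the constant-vector term
  Lp <- (Lp + t(Lp)) / 2
  d <- diag(Lp)
  R <- outer(d, rep(1, n)) + outer(rep(1, n), d) - 2 * Lp
  R <- (R + t(R)) / 2
  diag(R) <- 0
  dimnames(R) <- dimnames(Lp) <- dimnames(as_weight_matrix(graph))
  structure(
    list(R = R, laplacian_pinv = Lp, connected = connected),
    class = "effective_resistance"
  )
}

#' @export
print.effective_resistance <- function(x, ...) {
  cat(sprintf(
    "<effective_resistance: %d vertices, %sconnected>\n",
    nrow(x$R), if (x$connected) "" else "NOT "
  ))
  invisible(x)
}

as_resistance_matrix <- function(x, allow_disconnected = FALSE,
                                 regularization = 1e-6) {
  if (inherits(x, "effective_resistance")) return(x$R)
  if (inherits(x, "weighted_graph")) {
    return(effective_resistance(x, allow_disconnected = allow_disconnected,
                                regularization = regularization)$R)
  }
  if (is.matrix(x)) return(x)
  stop("expected an effective_resistance, weighted_graph, or matrix", call. = FALSE)
}

#' Resistance perturbation distance between two graphs
#'
#' The element-wise p-norm of the difference between the two graphs'
#' effective-resistance matrices on a shared vertex set,
#' \deqn{d_{rp(p)} = \Big[\sum_{i,j} |R^{(1)}_{ij} - R^{(2)}_{ij}|^p\Big]^{1/p}.}
#' The sum runs over all ordered vertex pairs, so each unordered pair
#' contributes twice; the factor is uniform and harmless.  The distance is
#' zero iff the two graphs have identical resistance matrices, which for
#' connected graphs implies identical Laplacians and hence identical weights.
#'
#' @param g1,g2 [weighted_graph()]s, [effective_resistance()] results, or
#'   plain resistance matrices, on the same vertex set in the same order.
#' @param p norm order, `p >= 1`.  The default `p = 2` makes the distance the
#'   Euclidean distance between vectorised resistance matrices, which is the
#'   choice under which the Gaussian distance kernel is positive
#'   semi-definite.
#' @param allow_disconnected passed through when resistances must be computed.
#' @return Non-negative scalar distance.
#' @examples
#' tri <- weighted_graph(matrix(1, 3, 3) - diag(3))
#' path <- weighted_graph(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3))
#' rpd(tri, path, p = 1)  # 2 * (1/3 + 1/3 + 4/3) = 4
#' @export
rpd <- function(g1, g2, p = 2, allow_disconnected = FALSE) {
  if (!is.numeric(p) || length(p) != 1 || p < 1 || !is.finite(p)) {
    stop("`p` must be a single finite number >= 1", call. = FALSE)
  }
  R1 <- as_resistance_matrix(g1, allow_disconnected)
  R2 <- as_resistance_matrix(g2, allow_disconnected)
  if (!identical(dim(R1), dim(R2))) {
    stop("dimension mismatch between resistance matrices", call. = FALSE)
  }
  sum(abs(R1 - R2)^p)^(1 / p)
}

#' Pairwise resistance perturbation distances over a cohort
#'
#' Computes each subject's effective-resistance matrix once and returns the
#' symmetric matrix of pairwise distances [rpd()] between all subjects.
#'
#' @param graphs list of [weighted_graph()]s sharing the same vertex count
#'   and ordering; names (or list indices) become subject ids.
#' @param p norm order (see [rpd()]).
#' @param allow_disconnected logical; if `FALSE`, any disconnected graph is an
#'   error listing the offending subject ids.
#' @return Symmetric non-negative `n_subjects x n_subjects` matrix with zero
#'   diagonal and subject ids as dimnames.
#' @export
pairwise_rpd <- function(graphs, p = 2, allow_disconnected = FALSE) {
  stopifnot(is.list(graphs), length(graphs) >= 1)
  ids <- names(graphs)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_along(graphs))
  nv <- vapply(graphs, function(g) as.integer(nrow(as_weight_matrix(g))), 1L)
  if (length(unique(nv)) != 1) {
    stop("all graphs must share the same vertex count", call. = FALSE)
  }
  res <- lapply(graphs, effective_resistance, allow_disconnected = TRUE)
  if (!allow_disconnected) {
    bad <- ids[!vapply(res, `[[`, TRUE, "connected")]
    if (length(bad)) {
      stop("disconnected graphs for subjects: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  M <- t(vapply(res, function(r) as.vector(r$R), numeric(nv[1]^2)))
  D <- minkowski_rows(M, p)
  dimnames(D) <- list(ids, ids)
  D
}

# Pairwise Minkowski distances between the rows of M.  p = 2 uses a BLAS
# Gram-matrix path; other p fall back to stats::dist.
minkowski_rows <- function(M, p) {
  if (p == 2) {
    G <- tcrossprod(M)
    sq <- diag(G)
    D2 <- outer(sq, rep(1, length(sq))) + outer(rep(1, length(sq)), sq) - 2 * G
    D2[D2 < 0] <- 0
    D <- sqrt(D2)
  } else {
    D <- as.matrix(stats::dist(M, method = "minkowski", p = p))
  }
  diag(D) <- 0
  (D + t(D)) / 2
}

#' Prepare a raw connectivity matrix as a weighted graph
#'
#' Standardises a subject-level connectivity matrix for graph analysis:
#' optionally back-transforms Fisher-z values through the hyperbolic tangent,
#' forces the diagonal to zero, symmetrises as `(M + t(M))/2`, and resolves
#' negative correlations according to `negative_mode`:
#' \describe{
#'   \item{`"zero"`}{negatives set to 0 (the neuroimaging convention).}
#'   \item{`"keep"`}{negatives retained; returns a signed graph.}
#'   \item{`"abs"`}{absolute value.}
#'   \item{`"normalize"`}{affine map of \[-1, 1\] onto \[0, 1\], i.e. `(x+1)/2`.}
#' }
#'
#' @param m square numeric matrix (correlations, or Fisher-z values when
#'   `fisher_z = TRUE`).
#' @param fisher_z logical; apply `tanh` first.
#' @param negative_mode one of `"zero"`, `"keep"`, `"abs"`, `"normalize"`.
#' @param labels optional vertex labels.
#' @return A [weighted_graph()].
#' @export
prepare_connectivity <- function(m, fisher_z = FALSE,
                                 negative_mode = c("zero", "keep", "abs", "normalize"),
                                 labels = NULL) {
  negative_mode <- match.arg(negative_mode)
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m)) {
    stop("connectivity matrix must be square and numeric", call. = FALSE)
  }
  if (any(!is.finite(m))) {
    stop("connectivity matrix contains NaN/Inf entries", call. = FALSE)
  }
  if (fisher_z) m <- tanh(m)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  signed <- FALSE
  m <- switch(negative_mode,
    zero = pmax(m, 0),
    keep = { signed <- any(m < 0); m },
    abs = abs(m),
    normalize = { out <- (m + 1) / 2; diag(out) <- 0; out }
  )
  weighted_graph(m, labels = labels, signed = signed)
}

#' Weighted global efficiency
#'
#' Mean over ordered vertex pairs of the inverse weighted shortest-path
#' length, with edge length `1/weight` (strong connections are short).
#' Disconnected pairs contribute 0.  Only defined for non-negative weights.
#'
#' @inheritParams laplacian
#' @return Scalar in `[0, Inf)`; 1 for a complete unit-weight graph.
#' @export
global_efficiency <- function(graph) {
  if (inherits(graph, "weighted_graph") && graph$signed) {
    stop("global efficiency is not defined for signed graphs; ",
         "resolve negative weights first", call. = FALSE)
  }
  w <- as_weight_matrix(graph)
  n <- nrow(w)
  if (all(w == 0)) return(0)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / len
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Weighted rich-club coefficient
#'
#' For degree threshold `k`, let the "rich club" be the vertices with
#' (unweighted) degree greater than `k`.  The coefficient is
#' \deqn{\phi^w(k) = W_{>k} / \sum_{e=1}^{E_{>k}} w^{rank}_e,}
#' where \eqn{W_{>k}} is the total edge weight inside the rich club,
#' \eqn{E_{>k}} the number of such edges, and the denominator sums the
#' \eqn{E_{>k}} largest edge weights anywhere in the graph.  The value lies
#' in `[0, 1]`.  When no rich-club subgraph with edges exists the result is
#' flagged undefined (`NA` with attribute `undefined = TRUE`), not an error.
#'
#' @inheritParams laplacian
#' @param k integer degree threshold, `k >= 1`.
#' @return Scalar in `[0, 1]`, or flagged-`NA` when undefined.
#' @export
rich_club_coefficient <- function(graph, k) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  w <- as_weight_matrix(graph)
  if (min(w) < 0) {
    stop("rich-club coefficient requires non-negative weights", call. = FALSE)
  }
  deg <- rowSums(w != 0)
  rich <- which(deg > k)
  undefined <- structure(NA_real_, undefined = TRUE)
  if (length(rich) < 2) return(undefined)
  sub <- w[rich, rich, drop = FALSE]
  ut <- upper.tri(sub)
  W_k <- sum(sub[ut][sub[ut] != 0])
  E_k <- sum(sub[ut] != 0)
  if (E_k == 0) return(undefined)
  all_w <- sort(w[upper.tri(w)][w[upper.tri(w)] != 0], decreasing = TRUE)
  W_k / sum(all_w[seq_len(E_k)])
}
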