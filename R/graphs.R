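check_adjacency <- function(adjacency, labels = NULL, what = "adjacency") {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  if (nrow(adjacency) != ncol(adjacency))
    stop(sprintf("`%s` must be square", what))
  if (any(!is.finite(adjacency)))
    stop(sprintf("`%s` contains non-finite entries", what))
  if (!isSymmetric(unname(adjacency), tol = 1e-10))
    stop(sprintf("`%s` must be symmetric", what))
  if (any(diag(adjacency) != 0))
    stop(sprintf("`%s` must have a zero diagonal", what))
  n <- nrow(adjacency)
  if (is.null(labels)) labels <- rownames(adjacency)
  if (is.null(labels)) labels <- paste0("node_", seq_len(n))
  if (length(labels) != n) stop("`labels` length must match matrix size")
  dimnames(adjacency) <- list(labels, labels)
  list(adjacency = adjacency, labels = as.character(labels))
}

#' Weighted functional network
#'
#' A symmetric, zero-diagonal matrix of pairwise coupling strengths in
#' `[0, 1]` (typically PLF values), with channel labels as node names.
#'
#' @param adjacency N x N symmetric numeric matrix, zero diagonal, entries
#'   in `[0, 1]`.
#' @param labels node names.
#' @return An object of class `functional_network`.
#' @export
functional_network <- function(adjacency, labels = NULL) {
  x <- check_adjacency(adjacency, labels)
  if (any(x$adjacency < 0) || any(x$adjacency > 1))
    stop("functional-network weights must lie in [0, 1]")
  structure(x, class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("<functional_network> %d nodes, weighted mean degree %.3f\n",
              nrow(x$adjacency), mean(rowSums(x$adjacency))))
  invisible(x)
}

#' Binary (0/1) network
#'
#' @param adjacency N x N symmetric matrix with entries exactly 0 or 1 and
#'   zero diagonal.
#' @param labels node names.
#' @param provenance optional list recording how the network was derived
#'   (source, threshold, swaps, seed).
#' @return An object of class `binary_network`.
#' @export
binary_network <- function(adjacency, labels = NULL, provenance = list()) {
  x <- check_adjacency(adjacency, labels)
  if (!all(x$adjacency %in% c(0, 1)))
    stop("binary-network entries must be exactly 0 or 1")
  structure(c(x, list(provenance = provenance)), class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges, mean degree %.3f\n",
              nrow(x$adjacency), sum(x$adjacency) / 2,
              mean(rowSums(x$adjacency))))
  invisible(x)
}

as_igraph <- function(network) {
  igraph::graph_from_adjacency_matrix(network$adjacency, mode = "undirected",
                                      weighted = NULL, diag = FALSE)
}

is_binary_adj <- function(adjacency) all(adjacency %in% c(0, 1))

#' Graph measures: mean degree, degree variance, clustering
#'
#' The degree of a node is the sum of the weights of its incident edges
#' (the edge count, for binary networks).  Mean degree (MD) and degree
#' variance (DV, population variance) summarize the degree distribution;
#' the local clustering coefficient (CC) measures how close each node's
#' neighborhood is to complete.  For binary networks the CC is the
#' Watts-Strogatz fraction of closed triangles (0 for nodes of degree < 2);
#' for weighted networks the Onnela geometric-mean generalization is used,
#' with weights normalized by the maximum weight.
#'
#' @param network a [functional_network()] or [binary_network()] (a bare
#'   symmetric zero-diagonal matrix is also accepted and treated by its
#'   entries).
#' @return An object of class `graph_measures`: `degrees`, `mean_degree`,
#'   `degree_variance`, `local_cc`, `mean_cc`, `binary` flag.
#' @export
graph_measures <- function(network) {
  if (is.matrix(network)) {
    network <- if (is_binary_adj(network)) binary_network(network)
               else {
                 x <- check_adjacency(network)
                 structure(x, class = "functional_network")
               }
  }
  stopifnot(inherits(network, c("functional_network", "binary_network")))
  a <- network$adjacency
  degrees <- rowSums(a)
  n <- nrow(a)
  binary <- is_binary_adj(a)
  if (binary) {
    g <- as_igraph(network)
    cc <- igraph::transitivity(g, type = "local", isolates = "zero")
    k <- degrees
    cc[k < 2] <- 0
  } else {
    mx <- max(a)
    if (mx == 0) {
      cc <- rep(0, n)
    } else {
      w3 <- (a / mx)^(1 / 3)
      num <- diag(w3 %*% w3 %*% w3)
      k <- rowSums(a > 0)
      cc <- ifelse(k >= 2, num / (k * (k - 1)), 0)
    }
  }
  names(cc) <- network$labels
  structure(list(degrees = degrees, mean_degree = mean(degrees),
                 degree_variance = mean((degrees - mean(degrees))^2),
                 local_cc = cc, mean_cc = mean(cc), binary = binary),
            class = "graph_measures")
}

#' @export
print.graph_measures <- function(x, ...) {
  cat(sprintf("<graph_measures> MD=%.3f DV=%.3f mean CC=%.3f (%s)\n",
              x$mean_degree, x$degree_variance, x$mean_cc,
              if (x$binary) "binary" else "weighted"))
  invisible(x)
}

#' Binarize a weighted network preserving its mean degree
#'
#' Scans candidate thresholds (zero plus every distinct off-diagonal
#' weight), keeps edges with weight strictly above each threshold, and
#' returns the binary network whose binary mean degree is closest to the
#' weighted mean degree of the input.  Ties are broken toward the lower
#' threshold (denser network), deterministically.  Because adjacent
#' thresholds change MD by `2/N` per edge, the achievable gap is at most
#' about one edge increment.
#'
#' @param network a [functional_network()].
#' @return A [binary_network()] whose `provenance` records the chosen
#'   `threshold`, the achieved `md_gap`, and the source weighted MD.
#' @export
binarize_preserving_md <- function(network) {
  stopifnot(inherits(network, "functional_network"))
  a <- network$adjacency
  n <- nrow(a)
  w <- a[upper.tri(a)]
  if (length(unique(w)) < 2)
    stop("all weights are equal: no threshold can resolve the mean degree")
  md_w <- mean(rowSums(a))
  thresholds <- c(0, sort(unique(w)))
  best <- NULL
  for (t in thresholds) {
    md_b <- 2 * sum(w > t) / n
    gap <- abs(md_b - md_w)
    if (is.null(best) || gap < best$gap - 1e-12) {
      best <- list(t = t, gap = gap)
    }
  }
  bin <- (a > best$t) * 1
  binary_network(bin, labels = network$labels,
                 provenance = list(threshold = best$t, md_gap = best$gap,
                                   weighted_md = md_w))
}

#' Degree-preserving randomization by double-edge swaps
#'
#' Rewires a binary network by repeated double-edge swaps — pick two edges
#' `(u,v)` and `(x,y)` and rewire to `(u,y)`, `(x,v)` — rejecting any swap
#' that would create a self-loop or duplicate edge.  Every node's degree is
#' preserved exactly, so MD and DV are invariant, while higher-order
#' topology (clustering, spectrum) is scrambled.
#'
#' @param network a [binary_network()] with at least 2 edges.
#' @param n_swaps number of swap attempts; default `10 *` edge count, a
#'   standard mixing heuristic.
#' @param seed optional integer seed (swaps are reproducible given it).
#' @return A [binary_network()] with identical degree sequence and
#'   provenance recording `n_swaps` and `seed`.
#' @export
degree_preserving_randomize <- function(network, n_swaps = NULL, seed = NULL) {
  stopifnot(inherits(network, "binary_network"))
  n_edges <- sum(network$adjacency) / 2
  if (n_edges < 2) stop("at least 2 edges are required for edge swaps")
  if (is.null(n_swaps)) n_swaps <- 10 * n_edges
  g <- as_igraph(network)
  g2 <- with_seed(seed,
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                             niter = n_swaps)))
  adj <- as.matrix(igraph::as_adjacency_matrix(g2, type = "both",
                                               sparse = FALSE))
  dimnames(adj) <- list(network$labels, network$labels)
  binary_network(adj, labels = network$labels,
                 provenance = c(network$provenance,
                                list(n_swaps = n_swaps, seed = seed)))
}

#' Adjacency spectrum
#'
#' Eigenvalues of the (symmetric) adjacency matrix in descending order.
#' Two networks with different spectra necessarily differ in topology,
#' which is how randomized surrogates are checked against their source.
#'
#' @param network a network object or bare symmetric matrix.
#' @return Numeric vector of eigenvalues, descending.
#' @export
adjacency_spectrum <- function(network) {
  a <- if (is.matrix(network)) check_adjacency(network)$adjacency
       else network$adjacency
  eigen(a, symmetric = TRUE, only.values = TRUE)$values
}

#' Ensemble of MD-matched random binary surrogates
#'
#' Binarizes a weighted network once via [binarize_preserving_md()], then
#' produces `n` independent degree-preserving randomizations of the result.
#' Every member has exactly the same degree sequence (hence the same MD)
#' as the binarized source.
#'
#' @param network a [functional_network()].
#' @param n ensemble size (the reference protocol uses 30).
#' @param seed master integer seed.
#' @param n_swaps swap attempts per member (default `10 *` edges).
#' @return List of `n` [binary_network()] objects.
#' @export
make_artificial_ensemble <- function(network, n = 30, seed = 1,
                                     n_swaps = NULL) {
  stopifnot(n >= 1)
  bin <- binarize_preserving_md(network)
  seeds <- derive_seeds(seed, n)
  lapply(seq_len(n), function(k)
    degree_preserving_randomize(bin, n_swaps = n_swaps, seed = seeds[k]))
}
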