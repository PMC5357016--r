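#' Weighted social network over collared animals
#'
#' Undirected weighted graph: nodes are animal ids, at most one edge per
#' unordered pair, weights nonnegative. Metadata records the weighting
#' scheme so local (association-rate) and global (residual-weight) networks
#' stay distinguishable.
#'
#' @param edges Data frame `node_i`, `node_j`, `weight`.
#' @param nodes Optional character vector of node ids (defaults to the ids
#'   appearing in `edges`); lets isolated nodes be carried.
#' @param metadata Optional named list (study area, season, year, scheme).
#' @return An object of class `social_network`.
#' @export
social_network <- function(edges, nodes = NULL, metadata = list()) {
  if (nrow(edges) > 0) {
    if (any(edges$node_i == edges$node_j)) stop("self-loops not allowed")
    if (any(edges$weight < 0)) stop("edge weights must be nonnegative")
    key <- paste(pmin(edges$node_i, edges$node_j),
                 pmax(edges$node_i, edges$node_j))
    if (anyDuplicated(key)) stop("duplicate edges for a dyad")
  }
  if (is.null(nodes))
    nodes <- sort(unique(c(edges$node_i, edges$node_j)))
  structure(list(nodes = nodes, edges = edges, metadata = metadata),
            class = "social_network")
}

#' @export
print.social_network <- function(x, ...) {
  cat("social_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (length(x$metadata))
    cat("  ", paste(names(x$metadata), unlist(x$metadata), sep = "=",
                    collapse = ", "), "\n")
  invisible(x)
}

#' Build a local association network from filtered dyad records
#'
#' Every qualifying dyad (>= 600 simultaneous locations, overlapping home
#' ranges) becomes an edge weighted by association rate. Dyads that shared
#' space but were never within the proximity threshold at the same time get
#' the nominal weight `zero_weight` (default 1e-5, below the lowest
#' expectable nonzero rate of ~0.00062) instead of zero.
#'
#' @param dyads Filtered dyad records with `animal_i`, `animal_j`,
#'   `association_rate`.
#' @param zero_weight Replacement for zero rates (default 1e-5).
#' @param metadata Metadata list passed to [social_network()].
#' @return A `social_network`.
#' @export
build_local_network <- function(dyads, zero_weight = 1e-5,
                                metadata = list(scheme = "association_rate")) {
  w <- dyads$association_rate
  w[!is.na(w) & w == 0] <- zero_weight
  edges <- data.frame(node_i = dyads$animal_i, node_j = dyads$animal_j,
                      weight = w, stringsAsFactors = FALSE)
  edges <- edges[!is.na(edges$weight), , drop = FALSE]
  social_network(edges, metadata = metadata)
}

#' Average weighted degree of a node
#'
#' Sum of incident edge weights divided by the number of incident edges:
#' the node-level sociality index, insensitive to how many neighbours
#' happened to be monitored.
#'
#' @param net A `social_network`.
#' @param node Node id (or omit for all non-isolated nodes).
#' @return A named numeric vector (single value when `node` given). Errors
#'   for an isolated node, which carries no information.
#' @export
average_weighted_degree <- function(net, node = NULL) {
  e <- net$edges
  ids <- if (is.null(node)) net$nodes else node
  out <- vapply(ids, function(id) {
    inc <- e$weight[e$node_i == id | e$node_j == id]
    if (length(inc) == 0) {
      if (!is.null(node)) stop("node '", id, "' is isolated")
      return(NA_real_)
    }
    sum(inc) / length(inc)
  }, numeric(1))
  names(out) <- ids
  if (is.null(node)) out[!is.na(out)] else out
}

#' Residual edge weights controlling for space sharing
#'
#' Fits `log(association_rate) ~ VI` by ordinary least squares over dyads
#' pooled across networks, and returns standardized residuals (residual /
#' residual SD) shifted by `-min + eps` so all weights are strictly
#' positive, as shortest-path computation requires. Dyads above the fitted
#' line (more social than their space sharing predicts) get larger weights.
#'
#' @param dyads Data frame with `association_rate` (> 0) and `vi` (> 0).
#' @param eps Positivity margin added after shifting (default 0.01).
#' @return `dyads` with columns `residual` (standardized) and `weight`
#'   (shifted) appended; the fitted model is attached as attribute `fit`.
#' @export
residual_edge_weights <- function(dyads, eps = 0.01) {
  if (nrow(dyads) < 3) stop("need at least 3 dyads to fit the regression")
  if (any(dyads$association_rate <= 0))
    stop("association rates must be positive (zero-rate dyads are excluded ",
         "from global networks)")
  if (any(dyads$vi <= 0)) stop("VI overlap must be positive")
  fit <- stats::lm(log(association_rate) ~ vi, data = dyads)
  res <- stats::resid(fit)
  s <- stats::sd(res)
  # an (essentially) perfect fit leaves no residual structure to standardize
  degenerate <- s <= 1e-10 * (stats::sd(log(dyads$association_rate)) + 1e-300)
  std <- if (degenerate) rep(0, length(res)) else res / s
  dyads$residual <- std
  dyads$weight <- std - min(std) + eps
  attr(dyads, "fit") <- fit
  dyads
}

# Dense matrix of edge costs (1/weight) with Inf where no edge.
cost_matrix <- function(net) {
  n <- length(net$nodes)
  cm <- matrix(Inf, n, n)
  diag(cm) <- 0
  if (nrow(net$edges) > 0) {
    if (any(net$edges$weight <= 0))
      stop("all edge weights must be positive for path computation")
    i <- match(net$edges$node_i, net$nodes)
    j <- match(net$edges$node_j, net$nodes)
    cm[cbind(i, j)] <- cm[cbind(j, i)] <- 1 / net$edges$weight
  }
  dimnames(cm) <- list(net$nodes, net$nodes)
  cm
}

#' Weighted closeness centrality
#'
#' Edge cost is the reciprocal of edge weight; `d_ij` is the minimal total
#' cost over paths between i and j (Dijkstra's algorithm); closeness of i is
#' the sum over other nodes of `1 / d_ij`, with unreachable nodes
#' contributing 0. Strong ties shorten paths, so closeness grows with the
#' weight of any edge.
#'
#' @param net A `social_network` with strictly positive edge weights.
#' @param node Optional node id; default all nodes.
#' @return Named numeric vector of closeness values.
#' @export
weighted_closeness <- function(net, node = NULL) {
  if (nrow(net$edges) > 0 && any(net$edges$weight <= 0))
    stop("all edge weights must be positive")
  n <- length(net$nodes)
  if (n == 0) return(numeric(0))
  if (nrow(net$edges) == 0) {
    out <- stats::setNames(numeric(n), net$nodes)
    return(if (is.null(node)) out else out[node])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$node_i, to = net$edges$node_j),
    directed = FALSE, vertices = data.frame(name = net$nodes))
  d <- igraph::distances(g, weights = 1 / net$edges$weight,
                         algorithm = "dijkstra")
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  out <- rowSums(inv)[net$nodes]
  if (is.null(node)) out else out[node]
}

# Closeness of every node from a dense cost matrix (Floyd-Warshall);
# used for the many small induced subgraphs of subsampled_closeness.
closeness_from_costs <- function(cm) {
  n <- nrow(cm)
  for (k in seq_len(n)) {
    ck <- outer(cm[, k], cm[k, ], "+")
    cm <- pmin(cm, ck)
  }
  inv <- 1 / cm
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv)
}

#' Subset-normalised network closeness
#'
#' Network closeness depends on network size, so networks are compared via
#' exhaustive k-node subsamples: for each of the `choose(n, k)` induced
#' subgraphs, the mean node closeness is computed (a node isolated within
#' the subgraph contributes 0), and the grand mean over subsets is the
#' size-normalised network value.
#'
#' @param net A `social_network`.
#' @param k Subsample size (default 4).
#' @return A list with `mean` (grand mean), `subset_means`, `per_node`
#'   (whole-network closeness), `k` and `n_subsets`.
#' @export
subsampled_closeness <- function(net, k = 4) {
  n <- length(net$nodes)
  if (n < k) stop("network has fewer than k = ", k, " nodes")
  n_subsets <- n_combinations(n, k)
  if (n_subsets > 1e6) stop("subset enumeration too large (", n_subsets, ")")
  cm <- cost_matrix(net)
  subs <- utils::combn(n, k)
  subset_means <- vapply(seq_len(ncol(subs)), function(s) {
    mean(closeness_from_costs(cm[subs[, s], subs[, s], drop = FALSE]))
  }, numeric(1))
  list(mean = mean(subset_means), subset_means = subset_means,
       per_node = weighted_closeness(net), k = k, n_subsets = n_subsets)
}

#' Number of k-node combinations
#'
#' @param n,k Nonnegative integers with `k <= n`.
#' @return `choose(n, k)`.
#' @export
n_combinations <- function(n, k) {
  if (k > n) stop("k must not exceed n")
  if (k < 0 || n < 0) stop("n and k must be nonnegative")
  choose(n, k)
}

#' Read/write a weighted edge list CSV
#'
#' Plain `node_i,node_j,weight` interchange format for networks.
#'
#' @param net A `social_network`.
#' @param path CSV path.
#' @return `read_edgelist` returns a `social_network`; `write_edgelist`
#'   returns `path` invisibly.
#' @export
write_edgelist <- function(net, path) {
  utils::write.csv(net$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c("character", "character", "numeric"))
  names(e) <- c("node_i", "node_j", "weight")
  social_network(e)
}
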