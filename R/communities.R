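# Functional communities on the thresholded effective network. Detection
# runs Louvain modularity maximization (igraph) on the symmetrized,
# unweighted graph restricted to the largest weakly connected component; the
# community statistic Q is evaluated in-package from the Newman sum
# Q = sum_c (e_cc - a_c^2).

#' Largest weakly connected component
#'
#' @param adjacency Square binary matrix (row = source).
#' @return Sorted integer vector of node indices in the largest weakly
#'   connected component (size ties broken by the smallest lowest node id);
#'   empty for an empty graph.
#' @export
largest_component <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n == 0) return(integer(0))
  if (nrow(adjacency) != ncol(adjacency)) abort("adjacency must be square")
  g <- igraph::graph_from_adjacency_matrix(adjacency != 0, mode = "directed")
  comp <- igraph::components(g, mode = "weak")
  sizes <- comp$csize
  best_size <- max(sizes)
  cand <- which(sizes == best_size)
  # ties: pick the component containing the smallest node id
  first_node <- vapply(cand, function(cid) min(which(comp$membership == cid)),
                       integer(1))
  winner <- cand[which.min(first_node)]
  sort(which(comp$membership == winner))
}

#' Detect functional communities (Louvain)
#'
#' Runs Louvain greedy modularity maximization on the symmetrized unweighted
#' graph (an edge is present if either direction is) restricted to the
#' largest weakly connected component. Deterministic for a given seed.
#'
#' @param adjacency Square binary matrix (row = source).
#' @param seed Seed controlling Louvain tie-breaking.
#' @param resolution Resolution parameter (1 = standard modularity).
#' @return A `community_partition`: tibble (`node`, `community`) over the
#'   analyzed component (labels contiguous from 1), with attributes `q`,
#'   `n_communities` and `component`.
#' @export
detect_communities <- function(adjacency, seed = 1L, resolution = 1) {
  adjacency <- as.matrix(adjacency)
  comp <- largest_component(adjacency)
  if (length(comp) == 0) abort("empty graph: no component to analyze")
  sub <- adjacency[comp, comp, drop = FALSE]
  sym <- 1 * ((sub + t(sub)) > 0)
  diag(sym) <- 0
  if (sum(sym) == 0) {
    membership <- seq_along(comp)  # edgeless: every node its own community
  } else {
    g <- igraph::graph_from_adjacency_matrix(sym, mode = "undirected")
    cl <- with_seed(seed,
      igraph::cluster_louvain(g, resolution = resolution))
    membership <- as.integer(igraph::membership(cl))
  }
  # relabel communities contiguously in order of first appearance
  membership <- match(membership, unique(membership))
  q <- if (sum(sym) > 0) modularity_q(sym, membership) else NA_real_
  out <- tibble(node = comp, community = membership)
  structure(out, q = q, n_communities = max(membership), component = comp,
            class = c("community_partition", class(out)))
}

#' Community statistic Q (Newman modularity)
#'
#' Evaluates `Q = sum_c (e_cc - a_c^2)` on the symmetrized unweighted graph,
#' where `e_cc` is the fraction of edge ends falling inside community `c` and
#' `a_c` the fraction of edge ends attached to it. `Q = 0` for the partition
#' placing all nodes in one community (a fully integrated network);
#' partitions of many well-separated modules push Q toward 1.
#'
#' @param adjacency Square binary matrix; symmetrized internally.
#' @param membership Integer community label per node of `adjacency`.
#' @return Q in `[-0.5, 1]`.
#' @export
modularity_q <- function(adjacency, membership) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  stopifnot(length(membership) == n)
  sym <- 1 * ((adjacency + t(adjacency)) > 0)
  diag(sym) <- 0
  two_m <- sum(sym)
  if (two_m == 0)
    abort("Q undefined for a graph with no edges")
  deg <- rowSums(sym)
  labs <- unique(membership)
  q <- 0
  for (cc in labs) {
    idx <- membership == cc
    e_cc <- sum(sym[idx, idx]) / two_m
    a_c <- sum(deg[idx]) / two_m
    q <- q + e_cc - a_c^2
  }
  q
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d nodes, %d communities, Q = %.4f\n",
              nrow(x), attr(x, "n_communities"), attr(x, "q")))
  invisible(x)
}

#' @export
tidy.community_partition <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.community_partition <- function(x, ...) {
  tibble(n_nodes = nrow(x),
         n_communities = attr(x, "n_communities"),
         q = attr(x, "q"))
}

#' Node ordering grouping communities along the diagonal
#'
#' Permutation of the analyzed component's nodes that groups members of the
#' same community contiguously (communities by size, descending), for
#' block-diagonal matrix display.
#'
#' @param partition A `community_partition`.
#' @return Integer vector of node ids in display order.
#' @export
community_order <- function(partition) {
  stopifnot(inherits(partition, "community_partition"))
  sizes <- table(partition$community)
  ord <- order(-as.vector(sizes)[partition$community], partition$community,
               partition$node)
  partition$node[ord]
}
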