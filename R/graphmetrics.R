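bnet_edges <- function(net) {
  net <- as_bnet(net)
  e <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
  storage.mode(e) <- "integer"
  unname(e)
}

bnet_graph <- function(net) {
  net <- as_bnet(net)
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                      diag = FALSE)
}

distance_matrix <- function(net) {
  igraph::distances(bnet_graph(net))
}

#' Global topological metrics of a binary network
#'
#' Conventions: the clustering coefficient Cp is the mean over nodes of the
#' local clustering (triangles over possible neighbour pairs), nodes with
#' degree < 2 contributing 0. The characteristic path length Lp is the mean
#' shortest-path length over connected ordered pairs; unreachable pairs are
#' excluded from Lp but contribute 0 to the efficiencies, and the number of
#' connected components is always reported so fragmentation is visible.
#' Global efficiency is the mean inverse distance over ordered pairs; local
#' efficiency is the mean over nodes of the global efficiency of each
#' node's neighbour-induced subgraph (degree < 2 contributes 0).
#'
#' @param net a `conn_bnet` from [binarize_at_sparsity()] or a 0/1 adjacency
#'   matrix.
#' @return list with `cp`, `lp`, `eglob`, `eloc`, `n_components` (gamma,
#'   lambda, sigma are added by [small_world_normalization()]).
#' @examples
#' k5 <- matrix(1, 5, 5); diag(k5) <- 0
#' global_metrics(k5)  # cp = lp = eglob = eloc = 1
#' @export
global_metrics <- function(net) {
  net <- as_bnet(net)
  if (net$n_edges < 1) stop("empty graph: no metrics defined")
  res <- cpp_global_metrics(bnet_edges(net), nrow(net$adjacency))
  list(cp = res$cp, lp = res$lp, eglob = res$eglob, eloc = res$eloc,
       n_components = res$n_components)
}

#' Nodal centrality metrics of a binary network
#'
#' Degree (row sums of the adjacency), nodal efficiency (mean inverse
#' distance to all other nodes, unreachable contributing 0), and betweenness
#' centrality normalised by (N-1)(N-2)/2 so values are comparable across
#' sparsity levels.
#'
#' @param net a `conn_bnet` or 0/1 adjacency matrix.
#' @return list with numeric vectors `degree`, `nodal_efficiency`,
#'   `betweenness` (length N).
#' @export
nodal_metrics <- function(net) {
  net <- as_bnet(net)
  if (net$n_edges < 1) stop("empty graph: no metrics defined")
  adj <- net$adjacency
  n <- nrow(adj)
  res <- cpp_global_metrics(bnet_edges(net), n)
  btw <- igraph::betweenness(bnet_graph(net), directed = FALSE) /
    ((n - 1) * (n - 2) / 2)
  list(degree = rowSums(adj),
       nodal_efficiency = res$nodal_efficiency,
       betweenness = unname(btw))
}

#' Degree-preserving rewiring (double-edge swaps)
#'
#' Randomises a network while preserving every node's degree exactly, by
#' repeated double-edge swaps that keep the graph simple (no self-loops or
#' multi-edges). The routine targets `swaps_per_edge * n_edges` successful
#' swaps with an attempt cap of `max_attempt_factor` times the target; if no
#' legal swap exists (e.g. a complete graph) the input is returned unchanged
#' with a warning.
#'
#' @param net a `conn_bnet` or 0/1 adjacency matrix.
#' @param swaps_per_edge successful swaps per edge to aim for.
#' @param seed integer seed (own deterministic RNG; does not touch R's
#'   random stream).
#' @param max_attempt_factor attempt budget as a multiple of the target.
#' @return a `conn_bnet` with attribute `n_swaps`.
#' @export
rewire_preserving_degree <- function(net, swaps_per_edge = 10, seed = 1,
                                     max_attempt_factor = 10) {
  net <- as_bnet(net)
  if (net$n_edges < 2) stop("need at least 2 edges to rewire")
  edges <- bnet_edges(net)
  res <- cpp_rewire(edges, nrow(net$adjacency),
                    as.integer(swaps_per_edge * net$n_edges),
                    max_attempt_factor * swaps_per_edge * net$n_edges, seed)
  if (res$n_swaps == 0) {
    warning("no legal double-edge swap found; returning the input network")
    attr(net, "n_swaps") <- 0L
    return(net)
  }
  n <- nrow(net$adjacency)
  adj <- matrix(0L, n, n, dimnames = dimnames(net$adjacency))
  adj[res$edges] <- 1L
  adj <- adj + t(adj)
  out <- as_bnet(adj)
  attr(out, "n_swaps") <- res$n_swaps
  out
}

#' Small-world normalisation against degree-preserving null networks
#'
#' gamma = Cp(net) / mean Cp over rewired nulls, lambda = Lp(net) / mean Lp
#' over the same nulls (computed with the same connected-pairs convention),
#' sigma = gamma / lambda. sigma > 1 indicates small-world organisation.
#' The small-worldness is treated as estimable only when gamma and lambda
#' are finite and lambda > 0; otherwise an error is raised.
#'
#' @param net a `conn_bnet` or 0/1 adjacency matrix.
#' @param n_null number of rewired null networks.
#' @param swaps_per_edge swaps per edge for each null.
#' @param seed integer seed.
#' @return list with `gamma`, `lambda`, `sigma`, `null_cp`, `null_lp`.
#' @export
small_world_normalization <- function(net, n_null = 100, swaps_per_edge = 10,
                                      seed = 1) {
  net <- as_bnet(net)
  if (n_null < 1) stop("n_null must be at least 1")
  obs <- cpp_cp_lp(bnet_edges(net), nrow(net$adjacency))
  nulls <- cpp_null_cp_lp(bnet_edges(net), nrow(net$adjacency),
                          as.integer(n_null), as.integer(swaps_per_edge),
                          10, seed)
  mcp <- mean(nulls$cp)
  mlp <- mean(nulls$lp)
  if (!is.finite(mcp) || !is.finite(mlp) || mcp == 0 || mlp == 0) {
    stop("small-worldness not estimable: null Cp or Lp is zero or undefined")
  }
  gamma <- obs$cp / mcp
  lambda <- obs$lp / mlp
  if (!is.finite(gamma) || !is.finite(lambda) || lambda <= 0) {
    stop("small-worldness not estimable: gamma or lambda not finite")
  }
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       null_cp = mcp, null_lp = mlp)
}
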