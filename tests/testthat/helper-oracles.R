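# Brute-force graph oracles, independent of the package implementation:
# distances by Floyd-Warshall, betweenness by explicit enumeration of all
# shortest paths, clustering/efficiency straight from the definitions.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  cl <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    links <- sum(adj[nb, nb]) / 2
    cl[i] <- 2 * links / (k * (k - 1))
  }
  mean(cl)
}

oracle_lp <- function(adj) {
  d <- oracle_distances(adj)
  off <- d[row(d) != col(d)]
  if (!any(is.finite(off))) return(NA_real_)
  mean(off[is.finite(off)])
}

oracle_eglob <- function(adj) {
  d <- oracle_distances(adj)
  off <- d[row(d) != col(d)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

oracle_eloc <- function(adj) {
  n <- nrow(adj)
  e <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) next
    e[i] <- oracle_eglob(adj[nb, nb, drop = FALSE])
  }
  mean(e)
}

oracle_nodal_eff <- function(adj) {
  d <- oracle_distances(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    v <- d[i, -i]
    sum(ifelse(is.finite(v) & v > 0, 1 / v, 0)) / (n - 1)
  }, numeric(1))
}

# enumerate every path between each ordered pair (graphs are tiny) and count
# shortest ones passing through each interior node
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  btw <- numeric(n)
  all_shortest <- function(s, t) {
    # DFS enumeration of all shortest s-t paths
    paths <- list()
    walk <- function(cur, path) {
      if (cur == t) {
        paths[[length(paths) + 1]] <<- path
        return()
      }
      for (nx in which(adj[cur, ] == 1)) {
        if (!(nx %in% path) && d[s, cur] + 1 + d[nx, t] == d[s, t] &&
            d[s, nx] == d[s, cur] + 1) {
          walk(nx, c(path, nx))
        }
      }
    }
    walk(s, s)
    paths
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t]) || d[s, t] == 0) next
    paths <- all_shortest(s, t)
    if (!length(paths)) next
    inner <- table(unlist(lapply(paths, function(p) setdiff(p, c(s, t)))))
    for (nm in names(inner)) {
      btw[as.integer(nm)] <- btw[as.integer(nm)] +
        inner[[nm]] / length(paths)
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

random_adjacency <- function(n, n_edges, seed) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sel <- pairs[sample.int(nrow(pairs), n_edges), , drop = FALSE]
  adj <- matrix(0L, n, n)
  adj[sel] <- 1L
  adj + t(adj)
}

ring_lattice <- function(n, k) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) for (d in seq_len(k %/% 2)) {
    j <- ((i + d - 1) %% n) + 1
    adj[i, j] <- adj[j, i] <- 1L
  }
  adj
}
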