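# Brute-force oracles, deliberately independent of the package's algorithms:
# patristic distances by Floyd-Warshall on the tree graph, PD by explicit
# path-union enumeration (BFS), MPD/MNTD by plain double loops.

bf_adjacency <- function(tree) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  w <- matrix(Inf, n_nodes, n_nodes)
  diag(w) <- 0
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    w[a, b] <- w[b, a] <- tree$edge.length[i]
  }
  w
}

bf_patristic <- function(tree) {
  w <- bf_adjacency(tree)
  n <- nrow(w)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (w[i, k] + w[k, j] < w[i, j]) w[i, j] <- w[i, k] + w[k, j]
      }
    }
  }
  ntip <- length(tree$tip.label)
  out <- w[seq_len(ntip), seq_len(ntip)]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# Node path between two nodes via BFS on the undirected tree graph.
bf_node_path <- function(tree, from, to) {
  n_nodes <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- rep(NA_integer_, n_nodes)
  seen <- rep(FALSE, n_nodes)
  queue <- from; seen[from] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) break
    for (u in adj[[v]]) {
      if (!seen[u]) { seen[u] <- TRUE; parent[u] <- v; queue <- c(queue, u) }
    }
  }
  path <- to
  while (path[1] != from) path <- c(parent[path[1]], path)
  path
}

# Edge ids (row indices of tree$edge) along a node path.
bf_path_edges <- function(tree, from, to) {
  path <- bf_node_path(tree, from, to)
  ids <- integer(0)
  for (i in seq_len(length(path) - 1)) {
    a <- path[i]; b <- path[i + 1]
    ids <- c(ids, which((tree$edge[, 1] == a & tree$edge[, 2] == b) |
                          (tree$edge[, 1] == b & tree$edge[, 2] == a)))
  }
  ids
}

bf_pd <- function(tree, community, include_root = TRUE) {
  tips <- match(community, tree$tip.label)
  root <- length(tree$tip.label) + 1L
  ids <- integer(0)
  if (include_root) {
    for (t in tips) ids <- union(ids, bf_path_edges(tree, t, root))
  } else {
    for (a in tips) for (b in tips) {
      if (a < b) ids <- union(ids, bf_path_edges(tree, a, b))
    }
  }
  sum(tree$edge.length[ids])
}

bf_mpd <- function(tree, community) {
  d <- bf_patristic(tree)[community, community]
  k <- length(community)
  tot <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) tot <- tot + d[i, j]
  tot / (k * (k - 1) / 2)
}

bf_mntd <- function(tree, community) {
  d <- bf_patristic(tree)[community, community]
  k <- length(community)
  nn <- numeric(k)
  for (i in seq_len(k)) nn[i] <- min(d[i, -i])
  mean(nn)
}
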