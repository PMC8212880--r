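# Independent brute-force oracles used to check the package's graph and
# enrichment machinery. Deliberately written from first principles (own BFS
# and path counting, exhaustive subset enumeration) so they share no code
# path with the implementation under test.

# adjacency list from a 2-column character edge matrix over `nodes`
oracle_adjacency <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character(0)
  if (length(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  adj
}

# plain queue BFS distances from s (Inf when unreachable)
oracle_bfs <- function(adj, s) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[s] <- 0
  queue <- s
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(d[w])) {
        d[w] <- d[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}

# exact normalized betweenness/closeness/degree by shortest-path counting:
# sigma[s][v] computed by dynamic programming over BFS levels, through-counts
# sigma_sv * sigma_vt / sigma_st summed over ordered pairs (halved)
oracle_centralities <- function(nodes, edges) {
  adj <- oracle_adjacency(nodes, edges)
  n <- length(nodes)
  dmat <- t(vapply(nodes, function(s) oracle_bfs(adj, s), numeric(n)))
  rownames(dmat) <- colnames(dmat) <- nodes
  sigma <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (s in nodes) {
    sigma[s, s] <- 1
    ord <- nodes[order(dmat[s, ])]
    for (v in ord) {
      if (v == s || is.infinite(dmat[s, v])) next
      preds <- adj[[v]][dmat[s, adj[[v]]] == dmat[s, v] - 1]
      sigma[s, v] <- sum(sigma[s, preds])
    }
  }
  comp_of <- stats::setNames(rep(NA_integer_, n), nodes)
  comp_id <- 0
  for (v in nodes) {
    if (is.na(comp_of[v])) {
      comp_id <- comp_id + 1
      comp_of[names(which(is.finite(dmat[v, ])))] <- comp_id
    }
  }
  csize <- stats::setNames(as.vector(table(comp_of)[as.character(comp_of)]),
                           nodes)
  btw <- stats::setNames(numeric(n), nodes)
  for (v in nodes) {
    acc <- 0
    others <- setdiff(nodes[comp_of == comp_of[v]], v)
    if (length(others) >= 2) {
      for (s in others) for (t in others) {
        if (s >= t) next
        if (dmat[s, v] + dmat[v, t] == dmat[s, t])
          acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    denom <- (csize[v] - 1) * (csize[v] - 2) / 2
    btw[v] <- if (denom > 0) acc / denom else 0
  }
  clo <- deg <- stats::setNames(numeric(n), nodes)
  for (v in nodes) {
    same <- nodes[comp_of == comp_of[v]]
    if (length(same) > 1) {
      clo[v] <- (length(same) - 1) / sum(dmat[v, same])
      deg[v] <- length(adj[[v]]) / (length(same) - 1)
    }
  }
  data.frame(node = nodes, betweenness = unname(btw), closeness = unname(clo),
             degree = unname(deg), stringsAsFactors = FALSE)
}

# exact upper-tail hypergeometric P(X >= k) by enumerating all C(N, n) draws
oracle_hypergeom <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # first K population items are the successes
  mean(hits >= k)
}

# Erdos-Renyi-ish random small graph as a character edge matrix
random_small_graph <- function(n_nodes, p_edge) {
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  edges <- t(pairs[, keep, drop = FALSE])
  list(nodes = nodes, edges = edges)
}

igraph_from_oracle <- function(g) {
  ig <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(g$nodes)
  if (nrow(g$edges)) ig <- igraph::add_edges(ig, t(g$edges))
  ig
}
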