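# Pathway stage: hypergeometric overrepresentation of a protein set against
# a gene-set collection, the pathway-pathway shared-protein network, and
# centrality ranking of pathway nodes.

#' Hypergeometric pathway enrichment
#'
#' Upper-tail hypergeometric test per gene set: with population
#' `N = |universe|`, successes `K = |set intersect universe|`, draws
#' `n = |query|` and observed overlap `k`, the p-value is `P(X >= k)`.
#' q-values come from [bh_adjust()] across all tested sets. The universe
#' should be the measured proteome, not the collection's gene space.
#'
#' @param query character vector of protein ids (must lie in `universe`).
#' @param collection a [gene_set_collection()].
#' @param universe character vector: all quantifiable protein ids.
#' @param fdr retention threshold on q (default 0.05).
#' @return data.frame with one row per tested set: `set_id`,
#'   `overlap_count`, `set_size`, `query_size`, `universe_size`, `p`, `q`,
#'   `retained`, and a list column `overlap_members`.
#' @export
hypergeom_enrich <- function(query, collection, universe, fdr = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(toupper(query)); universe <- unique(toupper(universe))
  if (length(query) == 0 || length(universe) == 0)
    stop_param("query and universe must be non-empty")
  if (!all(query %in% universe))
    stop_param("query must be a subset of the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection$sets), function(id) {
    members <- intersect(collection$sets[[id]], universe)
    overlap <- intersect(members, query)
    k <- length(overlap); K <- length(members)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    list(set_id = id, overlap_count = k, set_size = K, query_size = n,
         universe_size = N, p = p, overlap_members = overlap)
  })
  out <- data.frame(set_id = vapply(rows, `[[`, "", "set_id"),
                    overlap_count = vapply(rows, `[[`, 0L, "overlap_count"),
                    set_size = vapply(rows, `[[`, 0L, "set_size"),
                    query_size = n, universe_size = N,
                    p = vapply(rows, `[[`, 0, "p"),
                    stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  out$retained <- out$q <= fdr
  out$overlap_members <- I(lapply(rows, `[[`, "overlap_members"))
  out
}

#' Build the pathway-pathway shared-protein network
#'
#' One node per retained enrichment record, sized by its dataset-protein
#' overlap; an edge joins two pathways iff their overlap members intersect,
#' weighted by the intersection size.
#'
#' @param records output of [hypergeom_enrich()]; rows with
#'   `retained == FALSE` are ignored when the column is present.
#' @return an igraph undirected simple graph with vertex attribute
#'   `node_size` and edge attribute `weight`. Empty (with a warning) when no
#'   record survives.
#' @export
build_pathway_graph <- function(records) {
  if (!is.data.frame(records) || !"overlap_members" %in% names(records))
    stop_param("records must carry overlap_members (see hypergeom_enrich)")
  if ("retained" %in% names(records))
    records <- records[records$retained, , drop = FALSE]
  if (nrow(records) < 1) {
    warning("no retained pathways; returning empty graph")
    return(igraph::make_empty_graph(directed = FALSE))
  }
  ids <- records$set_id
  members <- records$overlap_members
  edges <- list(); weights <- integer()
  if (nrow(records) >= 2) {
    pairs <- combn(seq_along(ids), 2)
    for (j in seq_len(ncol(pairs))) {
      shared <- length(intersect(members[[pairs[1, j]]],
                                 members[[pairs[2, j]]]))
      if (shared >= 1) {
        edges[[length(edges) + 1]] <- ids[pairs[, j]]
        weights <- c(weights, shared)
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(ids, node_size = records$overlap_count)
  if (length(edges)) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
    igraph::E(g)$weight <- weights
  }
  g
}

#' Normalized node centralities, per connected component
#'
#' Betweenness (shortest-path pair fraction, normalized by
#' `(n-1)(n-2)/2` with `n` the component size), closeness
#' (`(n-1) / sum of distances` within the component) and degree
#' (`degree / (n-1)`), all in \[0,1\]. Isolated nodes score 0 on all three;
#' components smaller than 3 have betweenness 0. Centralities are computed
#' on the unweighted topology.
#'
#' @param graph igraph undirected simple graph.
#' @return data.frame: `node`, `betweenness`, `closeness`, `degree`.
#' @export
node_centralities <- function(graph) {
  n <- igraph::vcount(graph)
  nodes <- igraph::V(graph)$name %||% as.character(seq_len(n))
  if (n == 0)
    return(data.frame(node = character(), betweenness = numeric(),
                      closeness = numeric(), degree = numeric(),
                      stringsAsFactors = FALSE))
  comp <- igraph::components(graph)
  csize <- comp$csize[comp$membership]
  btw_raw <- igraph::betweenness(graph, directed = FALSE, weights = NA)
  denom <- (csize - 1) * (csize - 2) / 2
  btw <- ifelse(denom > 0, btw_raw / denom, 0)
  deg <- ifelse(csize > 1, igraph::degree(graph) / (csize - 1), 0)
  D <- igraph::distances(graph, weights = NA)
  clo <- vapply(seq_len(n), function(i) {
    same <- comp$membership == comp$membership[i]
    if (csize[i] <= 1) return(0)
    (csize[i] - 1) / sum(D[i, same])
  }, 0)
  data.frame(node = nodes, betweenness = unname(btw),
             closeness = clo, degree = unname(deg),
             stringsAsFactors = FALSE)
}

#' Top-ranked central pathways
#'
#' Ranks pathway nodes by betweenness descending, breaking ties by
#' closeness, then degree, then lexicographic id — a fully deterministic
#' ordering.
#'
#' @param centralities data.frame from [node_centralities()].
#' @param k how many to return (default 3).
#' @return character vector of up to `k` node ids, most central first.
#' @export
top_central_pathways <- function(centralities, k = 3) {
  if (!is.numeric(k) || k < 1) stop_param("k must be >= 1")
  stopifnot(is.data.frame(centralities),
            all(c("node", "betweenness", "closeness", "degree") %in%
                  names(centralities)))
  ord <- stable_order(-centralities$betweenness, -centralities$closeness,
                      -centralities$degree, centralities$node)
  head(centralities$node[ord], k)
}
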