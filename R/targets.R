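# Within-pathway target prioritization: induced interactome subgraph on the
# pathway's dataset proteins, three centralities per protein, and a Borda
# consensus over the three centrality rankings.

#' Induced interactome subgraph on pathway member proteins
#'
#' @param interactome igraph undirected graph on protein ids.
#' @param members character vector of pathway member protein ids; members
#'   absent from the interactome are dropped with a warning.
#' @return igraph induced subgraph (contains only present members). If it is
#'   disconnected, downstream centralities are normalized per component.
#' @export
pathway_protein_subgraph <- function(interactome, members) {
  members <- unique(toupper(members))
  present <- intersect(members, igraph::V(interactome)$name)
  absent <- setdiff(members, present)
  if (length(present) < 2)
    stop_data(sprintf("fewer than 2 pathway members present in interactome (missing: %s)",
                      paste(head(absent, 10), collapse = ", ")))
  if (length(absent))
    warning(sprintf("dropped %d member(s) absent from interactome", length(absent)))
  igraph::induced_subgraph(interactome, present)
}

# dense descending rank: ties share a rank, next distinct value steps by 1
dense_rank_desc <- function(x) match(x, sort(unique(x), decreasing = TRUE))

#' Protein centrality triplets with dense ranks
#'
#' Computes the same normalized betweenness/closeness/degree as
#' [node_centralities()] on a pathway protein subgraph, plus a dense rank per
#' centrality (1 = most central; ties share a rank).
#'
#' @param graph igraph from [pathway_protein_subgraph()].
#' @return data.frame: `protein_id`, the three centralities, and
#'   `rank_betweenness`, `rank_closeness`, `rank_degree`.
#' @export
protein_centralities <- function(graph) {
  cent <- node_centralities(graph)
  data.frame(protein_id = cent$node,
             betweenness = cent$betweenness,
             closeness = cent$closeness,
             degree = cent$degree,
             rank_betweenness = dense_rank_desc(cent$betweenness),
             rank_closeness = dense_rank_desc(cent$closeness),
             rank_degree = dense_rank_desc(cent$degree),
             stringsAsFactors = FALSE)
}

#' Consensus most-central protein by Borda aggregation
#'
#' The winner minimizes the Borda score (sum of the three dense centrality
#' ranks; unanimity gives score 3). Ties break by betweenness value
#' descending, then lexicographic protein id; residual exact ties are
#' flagged.
#'
#' @param triplets data.frame from [protein_centralities()].
#' @param pathway_id optional id recorded in the call.
#' @return one-row data.frame: `pathway_id`, `protein_id`, `borda_score`,
#'   `betweenness`, `closeness`, `degree`, `tie`.
#' @export
consensus_central_protein <- function(triplets, pathway_id = NA_character_) {
  stopifnot(is.data.frame(triplets), nrow(triplets) >= 1)
  borda <- triplets$rank_betweenness + triplets$rank_closeness +
    triplets$rank_degree
  ord <- stable_order(borda, -triplets$betweenness, triplets$protein_id)
  top <- ord[1]
  contenders <- borda == borda[top]
  tie <- sum(contenders & triplets$betweenness == triplets$betweenness[top]) > 1
  data.frame(pathway_id = pathway_id,
             protein_id = triplets$protein_id[top],
             borda_score = borda[top],
             betweenness = triplets$betweenness[top],
             closeness = triplets$closeness[top],
             degree = triplets$degree[top],
             tie = tie,
             stringsAsFactors = FALSE)
}

#' Target calls for a set of pathways
#'
#' Convenience wrapper: for each pathway id, takes its dataset-protein
#' overlap, induces the interactome subgraph, computes centrality triplets
#' and emits the Borda consensus call.
#'
#' @param interactome igraph on protein ids.
#' @param records enrichment records carrying `set_id` and
#'   `overlap_members` (see [hypergeom_enrich()]).
#' @param pathway_ids which pathways to call targets for (e.g. the output of
#'   [top_central_pathways()]), in rank order.
#' @return data.frame of target calls, one row per callable pathway, with a
#'   `rank` column preserving the input pathway order.
#' @export
prioritize_targets <- function(interactome, records, pathway_ids) {
  calls <- list()
  for (i in seq_along(pathway_ids)) {
    id <- pathway_ids[i]
    row <- match(id, records$set_id)
    if (is.na(row)) stop_param(sprintf("pathway '%s' not in records", id))
    members <- records$overlap_members[[row]]
    call <- tryCatch({
      sub <- pathway_protein_subgraph(interactome, members)
      consensus_central_protein(protein_centralities(sub), pathway_id = id)
    }, graftnet_data_error = function(e) {
      warning(sprintf("pathway '%s' skipped: %s", id, conditionMessage(e)))
      NULL
    })
    if (!is.null(call)) {
      call$rank <- i
      calls[[length(calls) + 1]] <- call
    }
  }
  if (length(calls) == 0)
    return(data.frame(pathway_id = character(), protein_id = character(),
                      borda_score = integer(), betweenness = numeric(),
                      closeness = numeric(), degree = numeric(),
                      tie = logical(), rank = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, calls)
}
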