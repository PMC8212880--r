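# Module-vs-module network closeness on an interactome, judged against a
# degree-preserving randomization null: observed distance, null mean/sd,
# z-score, pseudocounted empirical p, and a BH-corrected pairwise matrix.

map_module <- function(graph, set, label) {
  set <- unique(toupper(set))
  present <- intersect(set, igraph::V(graph)$name)
  if (length(set) > 0 && length(present) == 0)
    stop_data(sprintf("module %s has no members in the interactome", label))
  dropped <- length(set) - length(present)
  if (dropped > 0) {
    if (dropped > length(set) / 2)
      stop_data(sprintf("more than half of module %s absent from interactome", label))
    warning(sprintf("dropped %d member(s) of module %s absent from interactome",
                    dropped, label))
  }
  present
}

# directional closest distance on a precomputed hop matrix; unreachable
# source nodes are silently excluded here (public wrapper warns)
closest_dir <- function(D, a_idx, b_idx) {
  m <- D[a_idx, b_idx, drop = FALSE]
  mins <- m[cbind(seq_along(a_idx), max.col(-m, ties.method = "first"))]
  fin <- is.finite(mins)
  if (!any(fin)) return(list(d = NA_real_, n_unreachable = length(mins)))
  list(d = mean(mins[fin]), n_unreachable = sum(!fin))
}

# nearest-member distance excluding self, per node of idx into set_idx
closest_excl_self <- function(D, idx, set_idx) {
  vapply(idx, function(i) {
    others <- setdiff(set_idx, i)
    if (length(others) == 0) return(NA_real_)
    min(D[i, others])
  }, 0)
}

#' Closest network distance from one protein set to another
#'
#' Mean over members of `a_set` of the shortest-path hop count to the
#' nearest member of `b_set`. Shared members contribute 0, so the distance
#' is 0 iff the mapped sets intersect. Directional: average over `a_set`
#' only (the significance and matrix stages symmetrize).
#'
#' @param graph igraph undirected interactome.
#' @param a_set,b_set character vectors of protein ids; members absent from
#'   the graph are dropped with a warning (error when more than half of a
#'   set drops out).
#' @return numeric distance (hops).
#' @export
closest_distance <- function(graph, a_set, b_set) {
  a <- map_module(graph, a_set, "A"); b <- map_module(graph, b_set, "B")
  if (length(a) == 0 && length(b) == 0)
    stop_data("both sets empty after mapping to the interactome")
  D <- igraph::distances(graph, v = a, to = b, weights = NA)
  res <- closest_dir(D, seq_along(a), seq_along(b))
  if (is.na(res$d))
    stop_data("all pairs unreachable; closest distance undefined")
  if (res$n_unreachable > 0)
    warning(sprintf("excluded %d unreachable node(s) from the mean",
                    res$n_unreachable))
  res$d
}

#' Separation score between two protein sets
#'
#' `s = <d_AB> - (<d_AA> + <d_BB>)/2`, where `<d_AB>` averages the
#' nearest-member cross distances over every node of both sets and the
#' within-set terms use each node's nearest *other* member. Positive s means
#' the sets are topologically separated; `s = 0` when the sets coincide.
#'
#' @inheritParams closest_distance
#' @return numeric separation score.
#' @export
separation_score <- function(graph, a_set, b_set) {
  a <- map_module(graph, a_set, "A"); b <- map_module(graph, b_set, "B")
  if (length(a) < 2 || length(b) < 2)
    stop_param("separation needs >= 2 mapped members per set (within-set term)")
  nodes <- union(a, b)
  D <- igraph::distances(graph, v = nodes, to = nodes, weights = NA)
  rownames(D) <- colnames(D) <- nodes
  sep_from_matrix(D, match(a, nodes), match(b, nodes))
}

sep_from_matrix <- function(D, ai, bi) {
  cross_a <- vapply(ai, function(i) min(D[i, setdiff(bi, i)]), 0)
  cross_b <- vapply(bi, function(i) min(D[i, setdiff(ai, i)]), 0)
  cross <- mean(c(cross_a, cross_b)[is.finite(c(cross_a, cross_b))])
  daa <- mean(closest_excl_self(D, ai, ai), na.rm = TRUE)
  dbb <- mean(closest_excl_self(D, bi, bi), na.rm = TRUE)
  cross - (daa + dbb) / 2
}

#' Partition interactome nodes into degree bins
#'
#' Nodes are sorted by degree (ties by name) and grouped into contiguous
#' bins grown until each holds at least `min_bin_size` nodes; an undersized
#' trailing bin merges backward. The bins drive degree-preserving module
#' randomization: sampling within a node's bin preserves hubness under the
#' null.
#'
#' @param graph igraph undirected graph.
#' @param min_bin_size minimum nodes per bin (>= 1).
#' @return object of class `degree_bins`: list with `bins` (list of node
#'   name vectors) and `bin_of` (named integer, bin index per node).
#' @export
build_degree_bins <- function(graph, min_bin_size) {
  if (!is.numeric(min_bin_size) || min_bin_size < 1)
    stop_param("min_bin_size must be >= 1")
  n <- igraph::vcount(graph)
  if (min_bin_size > n)
    stop_param("min_bin_size exceeds the node count")
  deg <- igraph::degree(graph)
  nodes <- igraph::V(graph)$name %||% as.character(seq_len(n))
  ord <- stable_order(deg, nodes)
  nodes <- nodes[ord]; deg <- deg[ord]
  bins <- list(); cur <- character()
  for (i in seq_along(nodes)) {
    cur <- c(cur, nodes[i])
    # close the bin only at a degree boundary, so equal-degree nodes are
    # never split across bins
    if (length(cur) >= min_bin_size &&
        (i == length(nodes) || deg[i + 1] != deg[i])) {
      bins[[length(bins) + 1]] <- cur
      cur <- character()
    }
  }
  if (length(cur)) {
    if (length(bins)) bins[[length(bins)]] <- c(bins[[length(bins)]], cur)
    else bins[[1]] <- cur
  }
  bin_of <- integer(n)
  names(bin_of) <- unlist(bins)
  for (i in seq_along(bins)) bin_of[bins[[i]]] <- i
  structure(list(bins = bins, bin_of = bin_of), class = "degree_bins")
}

# draw a random node set matching ref_set's degree-bin multiset exactly,
# sampling without replacement within each bin
sample_degree_matched <- function(bins, ref_set) {
  counts <- table(bins$bin_of[ref_set])
  out <- character(0)
  for (b in names(counts)) {
    pool <- bins$bins[[as.integer(b)]]
    k <- counts[[b]]
    out <- c(out, pool[sample.int(length(pool), k)])
  }
  out
}

default_min_bin_size <- function(graph) {
  if (igraph::vcount(graph) < 500) 5L else 25L
}

measure_fun <- function(measure, D) {
  if (measure == "closest") {
    function(ai, bi) {
      d_ab <- closest_dir(D, ai, bi)$d
      d_ba <- closest_dir(D, bi, ai)$d
      mean(c(d_ab, d_ba))
    }
  } else {
    function(ai, bi) sep_from_matrix(D, ai, bi)
  }
}

#' Proximity of two modules against a degree-preserving null
#'
#' Computes the observed network proximity (symmetrized closest distance by
#' default, or the separation score) and compares it with `n_rand`
#' randomizations in which *both* modules are replaced by degree-bin-matched
#' random node sets of equal size. Reports the null mean and sd, the
#' z-score, and the pseudocounted empirical p-value
#' `p = (r + 1) / (n_rand + 1)` with `r` the number of null draws at or
#' below the observed distance, so p is never exactly 0.
#'
#' @inheritParams closest_distance
#' @param n_rand number of randomizations (1000 is a typical choice).
#' @param seed integer seed; the record is a pure function of its inputs.
#' @param measure `"closest"` (default) or `"separation"`.
#' @param min_bin_size degree-bin size; default 5 for graphs under 500 nodes
#'   and 25 otherwise.
#' @param module_a,module_b labels recorded in the output.
#' @return one-row data.frame of class `proximity_record`: `module_a`,
#'   `module_b`, `d_obs`, `null_mean`, `null_sd`, `z`, `p_emp`, `n_rand`.
#' @export
proximity_significance <- function(graph, a_set, b_set, n_rand = 1000,
                                   seed = 1,
                                   measure = c("closest", "separation"),
                                   min_bin_size = NULL,
                                   module_a = "A", module_b = "B") {
  measure <- match.arg(measure)
  if (!is.numeric(n_rand) || n_rand < 1) stop_param("n_rand must be >= 1")
  a <- map_module(graph, a_set, module_a)
  b <- map_module(graph, b_set, module_b)
  min_bin_size <- min_bin_size %||% default_min_bin_size(graph)
  bins <- build_degree_bins(graph, min_bin_size)
  D <- igraph::distances(graph, weights = NA)
  nodes <- rownames(D)
  f <- measure_fun(measure, D)
  ai <- match(a, nodes); bi <- match(b, nodes)
  if (measure == "separation" && (length(ai) < 2 || length(bi) < 2))
    stop_param("separation needs >= 2 mapped members per set")
  d_obs <- f(ai, bi)
  if (is.na(d_obs)) stop_data("observed distance undefined (unreachable sets)")
  d_null <- withr::with_seed(seed, vapply(seq_len(n_rand), function(i) {
    ra <- match(sample_degree_matched(bins, a), nodes)
    rb <- match(sample_degree_matched(bins, b), nodes)
    f(ra, rb)
  }, 0))
  null_mean <- mean(d_null, na.rm = TRUE)
  null_sd <- sd(d_null, na.rm = TRUE)
  z <- if (is.na(null_sd) || null_sd == 0) {
    warning("null distances have zero spread; z undefined")
    NA_real_
  } else (d_obs - null_mean) / null_sd
  p_emp <- (sum(d_null <= d_obs, na.rm = TRUE) + 1) / (n_rand + 1)
  structure(data.frame(module_a = module_a, module_b = module_b,
                       d_obs = d_obs, null_mean = null_mean,
                       null_sd = null_sd, z = z, p_emp = p_emp,
                       n_rand = as.integer(n_rand),
                       stringsAsFactors = FALSE),
            class = c("proximity_record", "data.frame"))
}

#' Pairwise proximity matrix over a family of modules
#'
#' Runs [proximity_significance()] for every unordered module pair, then
#' BH-adjusts the empirical p-values over the whole family (self-pairs
#' excluded). Following the usual display convention for such association
#' matrices, a pair is `blank` when `p_emp > 0.05` and `significant` when
#' `q <= 0.05`. Pairs that fail (e.g. unmappable modules) are reported with
#' NA statistics rather than aborting the matrix.
#'
#' @param graph igraph undirected interactome.
#' @param modules named list of protein-id character vectors (>= 2 modules).
#' @param n_rand,seed,measure,min_bin_size see [proximity_significance()];
#'   each pair uses a seed derived from `seed` and its pair index.
#' @return data.frame with one row per unordered pair: the
#'   `proximity_record` columns plus `q`, `blank`, `significant`.
#' @export
proximity_matrix <- function(graph, modules, n_rand = 1000, seed = 1,
                             measure = c("closest", "separation"),
                             min_bin_size = NULL) {
  measure <- match.arg(measure)
  if (!is.list(modules) || length(modules) < 2 || is.null(names(modules)))
    stop_param("modules must be a named list of >= 2 protein sets")
  ids <- names(modules)
  pairs <- combn(ids, 2)
  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    rows[[j]] <- tryCatch(
      proximity_significance(graph, modules[[a]], modules[[b]],
                             n_rand = n_rand, seed = derive_seed(seed, j),
                             measure = measure, min_bin_size = min_bin_size,
                             module_a = a, module_b = b),
      graftnet_error = function(e) {
        warning(sprintf("pair %s~%s failed: %s", a, b, conditionMessage(e)))
        data.frame(module_a = a, module_b = b, d_obs = NA_real_,
                   null_mean = NA_real_, null_sd = NA_real_, z = NA_real_,
                   p_emp = NA_real_, n_rand = as.integer(n_rand),
                   stringsAsFactors = FALSE)
      })
  }
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p_emp)
  out$q <- NA_real_
  out$q[ok] <- bh_adjust(out$p_emp[ok])
  out$blank <- out$p_emp > 0.05
  out$significant <- !is.na(out$q) & out$q <= 0.05
  rownames(out) <- NULL
  out
}
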