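# Seeded generators for every input the pipeline consumes, each with planted
# ground truth sufficient to score the downstream stage that consumes it.
# Every generator is a pure function of its parameters and seed.

#' Default kinetic trend templates
#'
#' Ten fractional 4-timepoint templates: four early-peaking, four
#' late-peaking and two flat (range below the 0.10 phase threshold). Each
#' row sums to 1. Non-flat templates are mutually well separated so planted
#' labels remain recoverable at realistic noise.
#'
#' @return 10 x 4 numeric matrix.
#' @export
default_kinetic_templates <- function() {
  m <- rbind(
    c(0.55, 0.25, 0.12, 0.08),  # sharp day-1 peak
    c(0.40, 0.40, 0.10, 0.10),  # sustained early
    c(0.25, 0.55, 0.12, 0.08),  # day-3 peak
    c(0.15, 0.45, 0.25, 0.15),  # broad early shoulder
    c(0.08, 0.12, 0.25, 0.55),  # week-4 peak
    c(0.10, 0.10, 0.40, 0.40),  # sustained late
    c(0.08, 0.12, 0.55, 0.25),  # week-2 peak
    c(0.15, 0.25, 0.45, 0.15),  # broad late shoulder
    c(0.21, 0.29, 0.29, 0.21),  # flat, mid-weighted
    c(0.29, 0.21, 0.21, 0.29))  # flat, edge-weighted
  colnames(m) <- c("D1", "D3", "W2", "W4")
  m
}

default_timepoint_labels <- function(T_) {
  if (T_ == 4) c("D1", "D3", "W2", "W4") else paste0("T", seq_len(T_))
}

protein_id_pool <- function(n) sprintf("P%04d", seq_len(n))

#' Synthesize a two-condition kinetic proteome with planted trend clusters
#'
#' Emulates a vein-graft time-course design: for each protein and condition
#' (graft `VG` vs control vein `IVC`), a trend template is drawn uniformly
#' (independent draws per condition), and replicate abundances are emitted
#' as `scale * max(0, template + N(0, noise_sd))` per timepoint, with a
#' lognormal per-profile scale mimicking label-free AUC magnitudes. At
#' `noise_sd = 0` each profile's fractional normalization equals its
#' template exactly.
#'
#' @param n_proteins number of proteins (default 1357, a typical quantified
#'   label-free vein-graft proteome).
#' @param timepoints number of timepoints (default 4: D1, D3, W2, W4).
#' @param replicates biological replicates per timepoint (default 3).
#' @param templates matrix of fractional templates (rows sum to 1, ncol =
#'   timepoints); default [default_kinetic_templates()].
#' @param noise_sd Gaussian noise sd on the fractional scale (default 0.03).
#' @param seed integer seed.
#' @param protein_ids optional explicit protein ids (length `n_proteins`).
#' @return list: `table` (an [abundance_table()] with
#'   `2 * timepoints * replicates` samples) and `truth` (list with
#'   `assignments` data.frame `protein_id, condition, template_id` and the
#'   `templates` matrix).
#' @export
synth_kinetic_proteome <- function(n_proteins = 1357, timepoints = 4,
                                   replicates = 3,
                                   templates = default_kinetic_templates(),
                                   noise_sd = 0.03, seed = 1,
                                   protein_ids = NULL) {
  templates <- as.matrix(templates)
  if (ncol(templates) != timepoints)
    stop_param("templates must have one column per timepoint")
  if (any(abs(rowSums(templates) - 1) > 1e-9))
    stop_param("each template must sum to 1 (+-1e-9)")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_param("noise_sd must be >= 0")
  if (n_proteins < 1 || replicates < 1) stop_param("need >=1 protein and replicate")
  ids <- toupper(protein_ids %||% protein_id_pool(n_proteins))
  if (length(ids) != n_proteins) stop_param("protein_ids length mismatch")
  tps <- if (!is.null(colnames(templates))) colnames(templates)
         else default_timepoint_labels(timepoints)
  conds <- c("VG", "IVC")
  K_true <- nrow(templates)
  withr::with_seed(seed, {
    assign_tab <- expand.grid(protein_id = ids, condition = conds,
                              KEEP.OUT.ATTRS = FALSE,
                              stringsAsFactors = FALSE)
    assign_tab$template_id <- sample.int(K_true, nrow(assign_tab),
                                         replace = TRUE)
    scale <- exp(rnorm(nrow(assign_tab), mean = log(1e6), sd = 0.5))
    cols <- list(); ann <- list()
    for (ci in seq_along(conds)) {
      rows <- assign_tab$condition == conds[ci]
      tmpl <- templates[assign_tab$template_id[rows], , drop = FALSE]
      sc <- scale[rows]
      for (t in seq_len(timepoints)) {
        for (r in seq_len(replicates)) {
          noise <- if (noise_sd > 0) rnorm(n_proteins, 0, noise_sd) else 0
          sid <- sprintf("%s_%s_R%d", conds[ci], tps[t], r)
          cols[[sid]] <- sc * pmax(0, tmpl[, t] + noise)
          ann[[sid]] <- data.frame(sample_id = sid, condition = conds[ci],
                                   timepoint = tps[t], replicate = r,
                                   stringsAsFactors = FALSE)
        }
      }
    }
  })
  values <- do.call(cbind, cols)
  rownames(values) <- ids
  table <- abundance_table(values, do.call(rbind, ann))
  list(table = table,
       truth = list(assignments = assign_tab, templates = templates))
}

#' Synthesize a multigroup static proteome with planted differentials
#'
#' Log-normal abundances per protein; a planted fraction of proteins is
#' shifted by `effect_log2` (log2 units) in the lesion groups
#' (`up_lesion` direction) or the control groups (`up_control`). With
#' `effect_log2 = 0` no protein is flagged differential.
#'
#' @param groups named integer vector: samples per condition (default
#'   `c(IVC = 3, NEO = 3, ADV = 3, WT = 3)`); at least 2 groups of >= 2.
#' @param n_proteins number of proteins.
#' @param frac_differential fraction of proteins planted differential,
#'   split evenly between the two directions.
#' @param effect_log2 planted shift in log2 units (default 2).
#' @param noise_sd residual sd in log2 units (default 0.25).
#' @param seed integer seed.
#' @param lesion_conditions conditions carrying the lesion shift (default
#'   `c("NEO", "ADV")`); the rest are controls.
#' @param protein_ids optional explicit ids.
#' @param up_lesion,up_control optional explicit planted sets (overriding
#'   `frac_differential`); must be disjoint subsets of the protein ids.
#' @return list: `table` ([abundance_table()]) and `truth` (data.frame:
#'   `protein_id`, `differential`, `direction`, `effect_log2`).
#' @export
synth_static_proteome <- function(groups = c(IVC = 3, NEO = 3, ADV = 3, WT = 3),
                                  n_proteins = 1357,
                                  frac_differential = 0.2,
                                  effect_log2 = 2, noise_sd = 0.25, seed = 1,
                                  lesion_conditions = c("NEO", "ADV"),
                                  protein_ids = NULL,
                                  up_lesion = NULL, up_control = NULL) {
  if (length(groups) < 2 || any(groups < 2))
    stop_param("need >= 2 groups with >= 2 samples each")
  if (!is.numeric(frac_differential) ||
      frac_differential < 0 || frac_differential > 1)
    stop_param("frac_differential must lie in [0, 1]")
  if (!all(lesion_conditions %in% names(groups)))
    stop_param("lesion_conditions must name groups")
  ids <- toupper(protein_ids %||% protein_id_pool(n_proteins))
  if (length(ids) != n_proteins) stop_param("protein_ids length mismatch")
  direction <- rep(NA_character_, n_proteins)
  names(direction) <- ids
  withr::with_seed(seed, {
    if (!is.null(up_lesion) || !is.null(up_control)) {
      up_lesion <- intersect(toupper(up_lesion %||% character()), ids)
      up_control <- setdiff(intersect(toupper(up_control %||% character()), ids),
                            up_lesion)
      direction[up_lesion] <- "up_lesion"
      direction[up_control] <- "up_control"
    } else if (effect_log2 != 0 && frac_differential > 0) {
      n_diff <- round(frac_differential * n_proteins)
      flagged <- sample(ids, n_diff)
      half <- ceiling(n_diff / 2)
      direction[flagged[seq_len(half)]] <- "up_lesion"
      if (n_diff > half) direction[flagged[(half + 1):n_diff]] <- "up_control"
    }
    if (effect_log2 == 0) direction[] <- NA_character_
    base_log2 <- rnorm(n_proteins, mean = 20, sd = 2)
    cols <- list(); ann <- list()
    for (g in names(groups)) {
      shift <- numeric(n_proteins)
      if (g %in% lesion_conditions)
        shift[!is.na(direction) & direction == "up_lesion"] <- effect_log2
      else
        shift[!is.na(direction) & direction == "up_control"] <- effect_log2
      for (r in seq_len(groups[[g]])) {
        sid <- sprintf("%s_%d", g, r)
        cols[[sid]] <- 2^(base_log2 + shift + rnorm(n_proteins, 0, noise_sd))
        ann[[sid]] <- data.frame(sample_id = sid, condition = g,
                                 timepoint = "static", replicate = r,
                                 stringsAsFactors = FALSE)
      }
    }
  })
  values <- do.call(cbind, cols)
  rownames(values) <- ids
  truth <- data.frame(protein_id = ids,
                      differential = !is.na(direction),
                      direction = unname(direction),
                      effect_log2 = ifelse(is.na(direction), 0, effect_log2),
                      stringsAsFactors = FALSE)
  list(table = abundance_table(values, do.call(rbind, ann)), truth = truth)
}

#' Synthesize a connected scale-free interactome
#'
#' Preferential attachment: starting from `attachment` unconnected seed
#' nodes, the first added node links to all of them and every later node
#' links to `attachment` distinct existing nodes with probability
#' proportional to degree + 1. The result is a connected simple graph with
#' exactly `attachment * (n_nodes - attachment)` edges and a heavy-tailed
#' degree distribution.
#'
#' @param n_nodes number of nodes (> attachment).
#' @param attachment edges added per incoming node (>= 1).
#' @param seed integer seed.
#' @return igraph undirected simple graph with nodes named `P0001`, ...
#' @export
synth_interactome <- function(n_nodes, attachment = 2, seed = 1) {
  if (!is.numeric(n_nodes) || !is.numeric(attachment) ||
      attachment < 1 || n_nodes <= attachment)
    stop_param("need n_nodes > attachment >= 1")
  n_nodes <- as.integer(n_nodes); attachment <- as.integer(attachment)
  deg <- integer(n_nodes)
  from <- integer(0); to <- integer(0)
  withr::with_seed(seed, {
    first <- attachment + 1L
    from <- c(from, rep(first, attachment)); to <- c(to, seq_len(attachment))
    deg[first] <- attachment; deg[seq_len(attachment)] <- 1L
    if (first < n_nodes) {
      for (v in (first + 1L):n_nodes) {
        existing <- seq_len(v - 1L)
        targets <- existing[sample.int(v - 1L, attachment,
                                       prob = deg[existing] + 1)]
        from <- c(from, rep(v, attachment)); to <- c(to, targets)
        deg[v] <- attachment
        deg[targets] <- deg[targets] + 1L
      }
    }
  })
  ids <- protein_id_pool(n_nodes)
  igraph::graph_from_data_frame(
    data.frame(from = ids[from], to = ids[to], stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = ids))
}

# nodes ordered by hop distance from a seed node, randomized within each
# distance shell (caller provides RNG state)
ball_order <- function(graph, seed_node) {
  d <- igraph::distances(graph, v = seed_node, weights = NA)[1, ]
  nodes <- names(d)[is.finite(d)]
  d <- d[nodes]
  nodes[order(d, sample.int(length(nodes)))]
}

#' Synthesize a module pair at a controlled proximity class
#'
#' `overlapping`: both modules grow by breadth-first expansion from one seed
#' node and share at least 30\% of their members. `neighboring`: disjoint
#' modules grown from two adjacent seed nodes. `random`: two independent
#' uniform node samples (the degree-matched null's reference class).
#'
#' @param graph igraph undirected connected graph.
#' @param module_size nodes per module (>= 5).
#' @param proximity_class one of `"overlapping"`, `"neighboring"`,
#'   `"random"`.
#' @param seed integer seed.
#' @return list with character vectors `a` and `b`.
#' @export
synth_modules <- function(graph, module_size, proximity_class, seed = 1) {
  if (!is.numeric(module_size) || module_size < 5)
    stop_param("module_size must be >= 5")
  n <- igraph::vcount(graph)
  if (module_size > n) stop_param("module_size exceeds the node count")
  proximity_class <- match.arg(proximity_class,
                               c("overlapping", "neighboring", "random"))
  nodes <- igraph::V(graph)$name
  withr::with_seed(seed, {
    if (proximity_class == "overlapping") {
      s <- sample(nodes, 1)
      ord <- ball_order(graph, s)
      core_n <- ceiling(0.4 * module_size)
      if (length(ord) < 2 * module_size - core_n)
        stop_param("graph too small for an overlapping pair of this size")
      a <- ord[seq_len(module_size)]
      b <- c(a[seq_len(core_n)],
             ord[(module_size + 1):(2 * module_size - core_n)])
    } else if (proximity_class == "neighboring") {
      s <- sample(nodes, 1)
      t <- sample(names(igraph::neighbors(graph, s)), 1)
      a <- ball_order(graph, s)
      a <- a[!a %in% t][seq_len(module_size)]
      b <- ball_order(graph, t)
      b <- b[!b %in% a][seq_len(module_size)]
    } else {
      a <- sample(nodes, module_size)
      b <- sample(nodes, module_size)
    }
  })
  list(a = a, b = b)
}

#' Synthesize a pathway collection around a planted hub target
#'
#' Generates `n_sets` gene sets as graph neighborhoods: the first
#' `n_hub_sets` (>= 3) are star-like neighborhoods of `hub_target` (the hub
#' plus random direct neighbors, extended outward only when its
#' neighborhood is too small), so the hub sits on many inter-pathway
#' shared-protein edges and dominates its pathways' induced subgraphs; the
#' rest are breadth-first neighborhoods of random seed nodes.
#'
#' @param graph igraph undirected connected graph.
#' @param n_sets total sets (>= n_hub_sets).
#' @param size_range integer pair `(min, max)` of set sizes.
#' @param hub_target node id of the planted hub (must be in `graph`).
#' @param seed integer seed.
#' @param n_hub_sets how many sets contain the hub (default 3).
#' @return a [gene_set_collection()] with ids `PW01`, `PW02`, ...
#' @export
synth_pathways <- function(graph, n_sets = 15, size_range = c(10, 25),
                           hub_target, seed = 1, n_hub_sets = 3) {
  hub_target <- toupper(hub_target)
  if (!hub_target %in% igraph::V(graph)$name)
    stop_param("hub_target is not a node of the graph")
  if (length(size_range) != 2 || size_range[1] < 2 ||
      size_range[2] < size_range[1] ||
      size_range[2] > igraph::vcount(graph))
    stop_param("infeasible size_range")
  if (n_sets < n_hub_sets) stop_param("n_sets must be >= n_hub_sets")
  nodes <- igraph::V(graph)$name
  sets <- list()
  withr::with_seed(seed, {
    sizes <- sample(seq(size_range[1], size_range[2]), n_sets, replace = TRUE)
    hub_ord <- ball_order(graph, hub_target)  # hub first, then by shell
    for (i in seq_len(n_sets)) {
      id <- sprintf("PW%02d", i)
      if (i <= n_hub_sets) {
        nbrs <- names(igraph::neighbors(graph, hub_target))
        want <- sizes[i] - 1
        picked <- if (length(nbrs) >= want) sample(nbrs, want)
                  else c(nbrs, setdiff(hub_ord, c(hub_target, nbrs))[
                           seq_len(want - length(nbrs))])
        sets[[id]] <- c(hub_target, picked)
      } else {
        s <- sample(nodes, 1)
        sets[[id]] <- ball_order(graph, s)[seq_len(sizes[i])]
      }
    }
  })
  gene_set_collection(sets,
                      descriptions = sprintf("synthetic neighborhood pathway %d",
                                             seq_len(n_sets)))
}

#' Generate the full synthetic study bundle
#'
#' One call that wires every generator together with a shared protein
#' namespace and planted, mutually consistent ground truth: a scale-free
#' interactome whose top-degree node is the planted hub target; a pathway
#' collection in which the hub anchors three pathways; a four-group static
#' proteome whose lesion-elevated proteins are exactly the members of the
#' hub pathways plus two more planted pathways (so enrichment, the pathway
#' network and target prioritization can all be scored); a two-condition
#' kinetic proteome with planted trend templates; and two synthetic disease
#' modules (one grown around the hub, one random).
#'
#' @param dir optional directory: when given, all inputs are written there
#'   as TSV/GMT files together with a pipeline `config.txt`, and the paths
#'   are recorded in the return value.
#' @param n_nodes interactome/proteome size (default 1357).
#' @param seed integer global seed; all component seeds derive from it.
#' @param noise_sd_kinetic,noise_sd_static,effect_log2 generator noise and
#'   effect settings (defaults 0.03, 0.25, 2).
#' @return list: `interactome`, `pathways`, `static` (table + truth),
#'   `kinetic` (table + truth), `disease_modules` (named list),
#'   `hub_target`, `planted` (lesion/control planted sets) and, when `dir`
#'   is given, `paths` and `config_path`.
#' @export
synth_bundle <- function(dir = NULL, n_nodes = 1357, seed = 1,
                         noise_sd_kinetic = 0.03, noise_sd_static = 0.25,
                         effect_log2 = 2) {
  g <- synth_interactome(n_nodes, attachment = 2, seed = derive_seed(seed, 11))
  deg <- igraph::degree(g)
  hub <- names(deg)[stable_order(-deg, names(deg))][1]
  pathways <- synth_pathways(g, n_sets = 15, size_range = c(10, 25),
                             hub_target = hub, seed = derive_seed(seed, 12))
  # the planted lesion signature is the hub's pathway family (its
  # first-neighbor subnetwork), so the hub is the bridging protein of every
  # lesion-enriched pathway; a disjoint pathway family is planted as the
  # control-predominant signature
  up_lesion <- unique(unlist(pathways$sets[1:3]))
  up_control <- setdiff(unique(unlist(pathways$sets[6:8])), up_lesion)
  ids <- igraph::V(g)$name
  static <- synth_static_proteome(n_proteins = n_nodes, protein_ids = ids,
                                  effect_log2 = effect_log2,
                                  noise_sd = noise_sd_static,
                                  seed = derive_seed(seed, 13),
                                  up_lesion = up_lesion,
                                  up_control = up_control)
  kinetic <- synth_kinetic_proteome(n_proteins = n_nodes, protein_ids = ids,
                                    noise_sd = noise_sd_kinetic,
                                    seed = derive_seed(seed, 14))
  disease <- withr::with_seed(derive_seed(seed, 15), {
    list(AVF_SYNTH = ball_order(g, hub)[seq_len(20)],
         RANDOM_SYNTH = sample(ids, 20))
  })
  bundle <- list(interactome = g, pathways = pathways, static = static,
                 kinetic = kinetic, disease_modules = disease,
                 hub_target = hub,
                 planted = list(up_lesion = up_lesion,
                                up_control = up_control))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    write_abundance_table(static$table, p("abundance_static.tsv"),
                          p("annotations_static.tsv"))
    write_abundance_table(kinetic$table, p("abundance_kinetic.tsv"),
                          p("annotations_kinetic.tsv"))
    write_gmt(pathways, p("pathways.gmt"))
    write_gmt(gene_set_collection(disease,
                                  descriptions = c("synthetic disease module near hub",
                                                   "synthetic random disease module")),
              p("disease_modules.gmt"))
    write_edge_list(g, p("interactome.tsv"))
    write_results(static$truth, p("truth_static.tsv"))
    write_results(kinetic$truth$assignments, p("truth_kinetic.tsv"))
    cfg <- c(sprintf("abundance_static = %s", p("abundance_static.tsv")),
             sprintf("annotations_static = %s", p("annotations_static.tsv")),
             sprintf("abundance_kinetic = %s", p("abundance_kinetic.tsv")),
             sprintf("annotations_kinetic = %s", p("annotations_kinetic.tsv")),
             sprintf("pathways = %s", p("pathways.gmt")),
             sprintf("interactome = %s", p("interactome.tsv")),
             sprintf("disease_modules = %s", p("disease_modules.gmt")),
             sprintf("seed = %d", seed))
    writeLines(cfg, p("config.txt"))
    bundle$paths <- list(dir = dir)
    bundle$config_path <- p("config.txt")
  }
  bundle
}
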