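# Configuration-driven end-to-end runner: static filtering -> kinetic
# clustering -> pathway networks -> target prioritization -> module
# proximity, with a reproducibility manifest written last.

#' Default pipeline configuration
#'
#' Stage parameters with their conventional defaults: static-filter FDR
#' 0.05, network-stage FDR 0.001, K = 30 trend clusters, flat range 0.10,
#' top 3 central pathways, 1000 proximity randomizations.
#'
#' @return named list of defaults (input paths unset).
#' @export
default_config <- function() {
  list(abundance_static = NULL, annotations_static = NULL,
       abundance_kinetic = NULL, annotations_kinetic = NULL,
       pathways = NULL, interactome = NULL, disease_modules = NULL,
       fdr_static = 0.05, fdr_network = 0.001,
       K = 30, restarts = 3, flat_range = 0.10,
       early_timepoints = NULL, late_timepoints = NULL,
       keep_condition = "VG", control_condition = "IVC",
       top_k = 3, n_rand = 1000, min_bin_size = NULL,
       measure = "closest", seed = 1, out_dir = NULL)
}

#' Read a flat key-value pipeline configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Numeric-looking
#' values are coerced; comma-separated values become character vectors.
#'
#' @param path configuration file.
#' @return named list (unvalidated; see [validate_config()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such config file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop_config(sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (grepl(",", val, fixed = TRUE)) val <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    if (length(val) == 1 && !is.na(num)) val <- num
    cfg[[key]] <- val
  }
  cfg
}

#' Validate and complete a pipeline configuration
#'
#' Fills unset keys from [default_config()], checks every parameter range
#' and verifies that all referenced input paths exist. Unknown keys are a
#' config error, as is any out-of-range value (the error names the key).
#'
#' @param config named list (e.g. from [read_config()]).
#' @return the completed configuration, invisibly classed
#'   `pipeline_config`.
#' @export
validate_config <- function(config) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_config(sprintf("unknown config key(s): %s",
                        paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config)
  for (key in c("fdr_static", "fdr_network")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || v <= 0 || v > 1)
      stop_config(sprintf("%s must lie in (0, 1]", key))
  }
  if (!is.numeric(cfg$K) || cfg$K < 2) stop_config("K must be >= 2")
  if (!is.numeric(cfg$n_rand) || cfg$n_rand < 1) stop_config("n_rand must be >= 1")
  if (!is.numeric(cfg$top_k) || cfg$top_k < 1) stop_config("top_k must be >= 1")
  if (!is.numeric(cfg$flat_range) || cfg$flat_range < 0 || cfg$flat_range > 1)
    stop_config("flat_range must lie in [0, 1]")
  if (!cfg$measure %in% c("closest", "separation"))
    stop_config("measure must be 'closest' or 'separation'")
  if (!is.numeric(cfg$seed)) stop_config("seed must be an integer")
  for (key in c("abundance_static", "annotations_static", "abundance_kinetic",
                "annotations_kinetic", "pathways", "interactome",
                "disease_modules")) {
    p <- cfg[[key]]
    if (is.null(p)) stop_config(sprintf("missing required input path: %s", key))
    if (!file.exists(p)) stop_config(sprintf("%s does not exist: %s", key, p))
  }
  class(cfg) <- c("pipeline_config", "list")
  invisible(cfg)
}

#' Run the full target-discovery pipeline
#'
#' Executes, in order: median normalization, ANOVA/FDR filtering and
#' predominance bipartition of the static proteome; fractional
#' normalization, trend clustering, phase labelling and condition filtering
#' of the kinetic proteome; hypergeometric enrichment, shared-protein
#' pathway network, centrality ranking and Borda target calls for each of
#' the four protein-set networks (lesion, control, early, late); and the
#' BH-corrected proximity matrix over the proteomic modules plus the
#' user-supplied disease modules. All outputs are written to
#' `config$out_dir` as deterministic TSVs, followed by a JSON manifest
#' capturing the config, package version, per-file checksums and every
#' warning raised along the way. A stage failure aborts with the stage name
#' after persisting the partial outputs and manifest.
#'
#' @param config a validated [validate_config()] list (or a raw list /
#'   config path, validated on the fly).
#' @return invisibly, a list with the stage results (`differential`,
#'   `clusters`, `kinetic_model`, `phase_sets`, `networks`, `targets`,
#'   `proximity`, `primary_target`) and the `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- config$out_dir %||% stop_config("out_dir must be set")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  warnings_log <- character(0)
  outputs <- character(0)
  results <- list()
  stage <- "setup"
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_results(df, path)
    outputs <<- c(outputs, path)
  }
  run_stage <- function(name, expr) {
    stage <<- name
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log,
                         sprintf("[%s] %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  }
  finish_manifest <- function(error = NULL) {
    manifest <- list(
      package_version = as.character(utils::packageVersion("graftnet")),
      config = config[!vapply(config, is.null, TRUE)],
      outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                        basename(outputs))),
      warnings = warnings_log,
      error = if (is.null(error)) NULL
              else sprintf("stage '%s': %s", stage, conditionMessage(error)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    manifest
  }
  res <- tryCatch({
    # ---- inputs ------------------------------------------------------
    run_stage("read_inputs", {
      static <- read_abundance_table(config$abundance_static,
                                     config$annotations_static)
      kinetic <- read_abundance_table(config$abundance_kinetic,
                                      config$annotations_kinetic)
      pathways <- read_gmt(config$pathways)
      interactome <- read_edge_list(config$interactome)
      disease <- read_gmt(config$disease_modules)
    })
    # ---- static stage ------------------------------------------------
    run_stage("differential_filtering", {
      norm <- normalize_median(static)
      diff <- anova_filter(norm, fdr = config$fdr_static)
      clusters <- bipartition_proteins(norm, diff$retained,
                                       control_condition = config$control_condition)
      emit(diff$records, "differential_records.tsv")
      emit(data.frame(protein_id = c(clusters$cluster1, clusters$cluster2),
                      cluster = rep(c("cluster1", "cluster2"),
                                    c(length(clusters$cluster1),
                                      length(clusters$cluster2))),
                      stringsAsFactors = FALSE),
           "predominance_clusters.tsv")
      results$differential <- diff
      results$clusters <- clusters
    })
    # ---- kinetic stage -----------------------------------------------
    run_stage("kinetic_clustering", {
      profiles <- kinetic_profiles(kinetic)
      model <- fit_kinetic_clusters(profiles, K = config$K,
                                    seed = derive_seed(config$seed, 101),
                                    restarts = config$restarts)
      model <- classify_phase(model,
                              early_timepoints = config$early_timepoints,
                              late_timepoints = config$late_timepoints,
                              flat_range = config$flat_range)
      phase_sets <- condition_filter(model,
                                     keep_condition = config$keep_condition)
      emit(data.frame(protein_id = model$protein,
                      condition = model$condition,
                      cluster = model$assignment,
                      phase = model$phase[model$assignment],
                      stringsAsFactors = FALSE),
           "kinetic_clusters.tsv")
      cent <- as.data.frame(model$centroids)
      names(cent) <- model$timepoints
      emit(cbind(data.frame(cluster = seq_len(model$K),
                            phase = model$phase), cent),
           "kinetic_centroids.tsv")
      results$kinetic_model <- model
      results$phase_sets <- phase_sets
    })
    # ---- pathway networks + target calls -----------------------------
    run_stage("pathway_network", {
      queries <- list(lesion = results$clusters$cluster2,
                      control = results$clusters$cluster1,
                      early = results$phase_sets$early,
                      late = results$phase_sets$late)
      networks <- list(); targets <- list()
      for (nm in names(queries)) {
        query <- queries[[nm]]
        if (length(query) == 0) { warning(sprintf("empty query for network '%s'", nm)); next }
        universe <- if (nm %in% c("lesion", "control"))
          rownames(static$values) else rownames(kinetic$values)
        enr <- hypergeom_enrich(query, pathways, universe,
                                fdr = config$fdr_network)
        graph <- build_pathway_graph(enr)
        if (igraph::vcount(graph) == 0) next
        cent <- node_centralities(graph)
        top <- top_central_pathways(cent, k = config$top_k)
        calls <- prioritize_targets(interactome, enr, top)
        if (nrow(calls)) calls$network <- nm
        networks[[nm]] <- list(enrichment = enr, graph = graph,
                               centralities = cent, top = top)
        targets[[nm]] <- calls
        emit(enr[, setdiff(names(enr), "overlap_members")],
             sprintf("enrichment_%s.tsv", nm))
        emit(cent, sprintf("pathway_centralities_%s.tsv", nm))
      }
      target_tab <- if (length(targets)) do.call(rbind, targets)
                    else data.frame()
      rownames(target_tab) <- NULL
      emit(target_tab, "targets.tsv")
      results$networks <- networks
      results$targets <- target_tab
      lesion_calls <- targets[["lesion"]]
      results$primary_target <-
        if (!is.null(lesion_calls) && nrow(lesion_calls))
          lesion_calls$protein_id[lesion_calls$rank == 1][1]
        else NA_character_
    })
    # ---- proximity ---------------------------------------------------
    run_stage("disease_proximity", {
      modules <- c(list(cluster1 = results$clusters$cluster1,
                        cluster2 = results$clusters$cluster2,
                        early = results$phase_sets$early,
                        late = results$phase_sets$late),
                   disease$sets)
      modules <- modules[lengths(modules) > 0]
      prox <- proximity_matrix(interactome, modules,
                               n_rand = config$n_rand,
                               seed = derive_seed(config$seed, 301),
                               measure = config$measure,
                               min_bin_size = config$min_bin_size)
      emit(prox, "proximity.tsv")
      results$proximity <- prox
    })
    stage <- "manifest"
    results$manifest <- finish_manifest()
    results
  }, error = function(e) {
    finish_manifest(error = e)
    graftnet_stop(sprintf("pipeline failed in stage '%s': %s",
                          stage, conditionMessage(e)),
                  "graftnet_pipeline_error")
  })
  invisible(res)
}
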