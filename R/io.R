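# Readers/writers for every external format the pipeline touches.
# Canonical table dialect is unquoted UTF-8 TSV so outputs diff byte-exactly.
# Protein/gene identifiers are normalized to uppercase at every boundary
# (mouse and human symbols are routinely mixed in vascular proteomics).

#' Construct a validated abundance table
#'
#' An abundance table is a non-negative proteins x samples matrix plus a
#' sample annotation frame (`sample_id`, `condition`, `timepoint`,
#' `replicate`) aligned to its columns. Missing abundances are `NA`, which is
#' a distinct state from an observed zero.
#'
#' @param values numeric matrix, proteins in rows (rownames = protein ids),
#'   samples in columns (colnames = sample ids). `NA` marks missing.
#' @param annotations data.frame with columns `sample_id`, `condition`,
#'   `timepoint`, `replicate`; one row per sample.
#' @return an object of class `abundance_table`: a list with elements
#'   `values` and `annotations`.
#' @export
abundance_table <- function(values, annotations) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_format("abundance values must be a numeric matrix")
  if (is.null(rownames(values)))
    stop_format("abundance matrix must carry protein ids as rownames")
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop_format("duplicate protein ids in abundance table")
  if (any(values[!is.na(values)] < 0))
    stop_format("abundances must be non-negative")
  if (any(is.infinite(values)))
    stop_format("abundances must be finite or missing")
  required <- c("sample_id", "condition", "timepoint", "replicate")
  if (!is.data.frame(annotations) || !all(required %in% names(annotations)))
    stop_format("annotations need columns sample_id, condition, timepoint, replicate")
  annotations <- as.data.frame(annotations)[, required]
  annotations$sample_id <- as.character(annotations$sample_id)
  annotations$condition <- as.character(annotations$condition)
  annotations$timepoint <- as.character(annotations$timepoint)
  annotations$replicate <- as.integer(annotations$replicate)
  if (anyDuplicated(annotations$sample_id))
    stop_format("duplicate sample_id in annotations")
  if (any(is.na(annotations$replicate)) || any(annotations$replicate < 1))
    stop_format("replicate must be a positive integer")
  if (is.null(colnames(values)))
    colnames(values) <- annotations$sample_id
  if (ncol(values) != nrow(annotations) ||
      !setequal(colnames(values), annotations$sample_id))
    stop_format("annotation rows must match abundance columns one-to-one")
  annotations <- annotations[match(colnames(values), annotations$sample_id), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  structure(list(values = values, annotations = annotations),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d proteins x %d samples (%d missing cells)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  cat("conditions:", paste(unique(x$annotations$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Read an abundance TSV plus its sample-annotation sidecar
#'
#' The abundance file has a header row of sample ids and protein ids in the
#' first column. Empty cells and `NA` are read as missing (never as zero).
#'
#' @param path abundance TSV.
#' @param annotation_path annotation TSV with columns `sample_id`,
#'   `condition`, `timepoint`, `replicate`.
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path, annotation_path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  if (!file.exists(annotation_path)) stop_io(sprintf("no such file: %s", annotation_path))
  raw <- read.delim(path, check.names = FALSE, na.strings = c("NA", ""),
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop_format("abundance table needs a protein column and >=1 sample")
  ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  ann <- read.delim(annotation_path, check.names = FALSE, stringsAsFactors = FALSE)
  abundance_table(mat, ann)
}

#' Write an abundance table and its annotations as TSV
#'
#' @param table an [abundance_table()].
#' @param path abundance TSV destination.
#' @param annotation_path annotation TSV destination.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path, annotation_path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(protein_id = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_exact(df, path)
  write_tsv_exact(table$annotations, annotation_path)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (member identifiers).
#' @param descriptions optional character vector aligned to `sets`.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop_format("set ids must be unique and non-empty")
  sets <- lapply(sets, function(m) unique(toupper(as.character(m))))
  if (any(lengths(sets) == 0)) stop_format("empty gene sets are not allowed")
  descriptions <- descriptions %||% rep("", length(sets))
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `set_id<TAB>description<TAB>member...`. Members are uppercased and
#' deduplicated; a line with fewer than three fields is a format error.
#'
#' @param path GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_format("empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop_format(sprintf("GMT line %d has fewer than 3 fields", bad[1]))
  ids <- vapply(fields, `[[`, "", 1)
  desc <- vapply(fields, `[[`, "", 2)
  members <- lapply(fields, function(f) f[-(1:2)])
  names(members) <- ids
  gene_set_collection(members, desc)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an interactome from a 2-column edge list or 3-column SIF
#'
#' Produces an undirected simple graph on uppercased protein identifiers.
#' Self-loops are dropped (node retained) with a warning; duplicate and
#' reversed edges collapse to one.
#'
#' @param path whitespace/tab-separated edge file. A 3-column file is read as
#'   SIF (`source interaction target`; the middle token is ignored).
#' @return an `igraph` undirected simple graph.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_format("empty edge list")
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2 | nf > 3))
    stop_format("edge lines must have 2 (edge list) or 3 (SIF) fields")
  from <- toupper(vapply(fields, `[[`, "", 1))
  to <- toupper(vapply(fields, function(f) f[[length(f)]], ""))
  nodes <- unique(c(from, to))
  loops <- from == to
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    from <- from[!loops]; to <- to[!loops]
  }
  g <- igraph::graph_from_data_frame(data.frame(from = from, to = to,
                                                stringsAsFactors = FALSE),
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write an interactome as a 2-column TSV edge list
#'
#' Edges are written once each with endpoints in lexicographic order, rows
#' sorted, so identical graphs always serialize byte-identically.
#'
#' @param graph igraph undirected graph.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  if (nrow(el)) {
    swap <- el[, 1] > el[, 2]
    el[swap, ] <- el[swap, 2:1]
    el <- el[stable_order(el[, 1], el[, 2]), , drop = FALSE]
  }
  # headerless, like every interactome edge-list distribution
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), path)
  invisible(path)
}

# deterministic TSV emitter shared by every writer: no quoting, "\n" EOLs,
# NA rendered as the literal token NA
write_tsv_exact <- function(df, path) {
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, eol = "\n", na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_io(sprintf("cannot write %s: %s", path, conditionMessage(ok)))
  invisible(path)
}

#' Write a flat result table deterministically
#'
#' Rows are sorted by the first column (then the second, when present) with a
#' locale-independent byte order, so the same records always yield
#' byte-identical files. An empty record list yields a header-only file.
#'
#' @param records data.frame of results.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path) {
  if (!is.data.frame(records)) stop_param("records must be a data.frame")
  if (nrow(records) > 0) {
    keys <- records[, seq_len(min(2L, ncol(records))), drop = FALSE]
    records <- records[do.call(stable_order, unname(as.list(keys))), ,
                       drop = FALSE]
  }
  write_tsv_exact(records, path)
  invisible(path)
}
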