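# Small in-code fixtures shared across test files.

# minimal abundance table: values matrix built from a vector, one condition
# label per sample
make_table <- function(values, conditions, timepoints = NULL,
                       proteins = NULL) {
  values <- as.matrix(values)
  proteins <- proteins %||% sprintf("PR%02d", seq_len(nrow(values)))
  rownames(values) <- proteins
  n <- ncol(values)
  timepoints <- timepoints %||% rep("static", n)
  reps <- stats::ave(seq_len(n), paste(conditions, timepoints),
                     FUN = seq_along)
  ann <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                    condition = conditions, timepoint = timepoints,
                    replicate = reps, stringsAsFactors = FALSE)
  colnames(values) <- ann$sample_id
  abundance_table(values, ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# path graph 1-2-3-4-5 used by the proximity worked examples
path5 <- function() {
  igraph::make_graph(~ N1 - N2 - N3 - N4 - N5)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
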