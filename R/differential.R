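# Static-proteome stage: median normalization, multigroup ANOVA filtering at
# a chosen FDR, two-group Welch tests, and the two-way predominance
# bipartition of the filtered proteins.

#' Median-center samples of an abundance table
#'
#' Each sample is rescaled so that its median non-missing abundance equals
#' the global median of the per-sample medians. This removes per-run loading
#' differences while preserving within-sample rank order. Missing cells stay
#' missing.
#'
#' @param table an [abundance_table()].
#' @return a normalized [abundance_table()].
#' @export
normalize_median <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  med <- apply(table$values, 2, median, na.rm = TRUE)
  if (any(is.na(med)))
    stop_data(sprintf("sample(s) with no observed values: %s",
                      paste(colnames(table$values)[is.na(med)], collapse = ", ")))
  if (any(med == 0))
    stop_data("sample with zero median abundance cannot be median-scaled")
  target <- median(med)
  scaled <- sweep(table$values, 2, target / med, `*`)
  abundance_table(scaled, table$annotations)
}

# Row-wise one-way fixed-effects ANOVA on a numeric matrix with NA handling.
# Returns per-row F, dfs and p. Rows violating the design preconditions get
# NA statistics (callers decide whether to warn/skip).
row_anova <- function(mat, groups) {
  groups <- as.factor(groups)
  lev <- levels(groups)
  n_g <- s_g <- ss_g <- matrix(0, nrow(mat), length(lev),
                               dimnames = list(NULL, lev))
  for (g in lev) {
    sub <- mat[, groups == g, drop = FALSE]
    obs <- !is.na(sub)
    sub0 <- ifelse(obs, sub, 0)
    n_g[, g] <- rowSums(obs)
    s_g[, g] <- rowSums(sub0)
    ss_g[, g] <- rowSums(sub0^2)
  }
  usable <- n_g >= 2
  k <- rowSums(usable)
  n_tot <- rowSums(n_g * usable)
  s_tot <- rowSums(s_g * usable)
  grand <- s_tot / n_tot
  mean_g <- ifelse(usable, s_g / n_g, NA)
  ssb <- rowSums(ifelse(usable, n_g * (mean_g - grand)^2, 0))
  ssw <- rowSums(ifelse(usable, ss_g - s_g^2 / pmax(n_g, 1), 0))
  df1 <- k - 1
  df2 <- n_tot - k
  ok <- k >= 2 & df2 >= 1
  f <- ifelse(ok, (ssb / df1) / (ssw / df2), NA_real_)
  p <- ifelse(ok, pf(f, df1, df2, lower.tail = FALSE), NA_real_)
  # zero within-group variance with real between-group signal: F = Inf, p = 0
  inf_f <- ok & ssw == 0 & ssb > 0
  f[inf_f] <- Inf; p[inf_f] <- 0
  list(statistic = f, p = p, df1 = df1, df2 = df2,
       group_means = mean_g, tested = ok, ssb = ssb, ssw = ssw)
}

#' Multigroup ANOVA filter with Benjamini-Hochberg FDR
#'
#' One-way fixed-effects F test per protein on (by default) log2-transformed
#' abundances, BH-adjusted across all tested proteins; retains proteins with
#' `q <= fdr`. Proteins constant across all samples are dropped before
#' testing with a warning, as are proteins without two groups holding at
#' least two observed values each.
#'
#' @param table an [abundance_table()].
#' @param group_of optional named character vector mapping sample id to
#'   condition; defaults to the table's `condition` annotation.
#' @param fdr FDR threshold, default 0.05.
#' @param log2 transform abundances with `log2()` before testing (set FALSE
#'   when the table already holds log-scale values).
#' @return list with `records` (data.frame: protein_id, statistic, df1, df2,
#'   p, q, and one `mean_<condition>` column per group) and `retained`
#'   (character vector of protein ids with q <= fdr).
#' @export
anova_filter <- function(table, group_of = NULL, fdr = 0.05, log2 = TRUE) {
  stopifnot(inherits(table, "abundance_table"))
  if (!is.numeric(fdr) || fdr <= 0 || fdr > 1)
    stop_param("fdr must be in (0, 1]")
  groups <- resolve_groups(table, group_of)
  mat <- prepare_log2(table$values, log2)
  constant <- apply(mat, 1, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && max(x) == min(x)
  })
  if (any(constant)) {
    warning(sprintf("dropped %d protein(s) constant across all samples",
                    sum(constant)))
    mat <- mat[!constant, , drop = FALSE]
  }
  if (nrow(mat) == 0) stop_data("no testable proteins")
  res <- row_anova(mat, groups)
  if (any(!res$tested))
    warning(sprintf("skipped %d protein(s) lacking 2 groups with >=2 values",
                    sum(!res$tested)))
  keep <- res$tested
  q <- rep(NA_real_, nrow(mat))
  q[keep] <- bh_adjust(res$p[keep])
  records <- data.frame(protein_id = rownames(mat),
                        statistic = res$statistic,
                        df1 = res$df1, df2 = res$df2,
                        p = res$p, q = q,
                        stringsAsFactors = FALSE)
  gm <- res$group_means
  colnames(gm) <- paste0("mean_", colnames(gm))
  records <- cbind(records, as.data.frame(gm))
  rownames(records) <- NULL
  retained <- records$protein_id[!is.na(records$q) & records$q <= fdr]
  list(records = records, retained = retained)
}

resolve_groups <- function(table, group_of) {
  if (is.null(group_of))
    return(table$annotations$condition[match(colnames(table$values),
                                             table$annotations$sample_id)])
  miss <- setdiff(colnames(table$values), names(group_of))
  if (length(miss))
    stop_param(sprintf("group_of misses sample(s): %s",
                       paste(miss, collapse = ", ")))
  as.character(group_of[colnames(table$values)])
}

prepare_log2 <- function(values, log2) {
  if (!log2) return(values)
  mat <- base::log2(values)
  zero <- is.finite(values) & values == 0
  if (any(zero)) {
    warning(sprintf("%d zero abundance(s) treated as missing on the log2 scale",
                    sum(zero)))
    mat[zero] <- NA
  }
  mat
}

#' Two-group Welch t test per protein
#'
#' Two-sided Welch (unequal-variance) t statistics on log2 abundances,
#' `test` minus `control`. Proteins with zero variance in both groups are
#' dropped with a warning; identical group means with shared variance give
#' t = 0, p = 1.
#'
#' @param table an [abundance_table()].
#' @param labels named character vector mapping sample id to `"test"` or
#'   `"control"`.
#' @param log2 transform before testing (see [anova_filter()]).
#' @return data.frame: protein_id, statistic, df, p, q, mean_test,
#'   mean_control.
#' @export
ttest_two_group <- function(table, labels, log2 = TRUE) {
  stopifnot(inherits(table, "abundance_table"))
  if (!all(sort(unique(labels)) %in% c("control", "test")))
    stop_param("labels must map samples to 'test' or 'control'")
  lab <- resolve_groups(table, labels)
  if (!all(c("test", "control") %in% lab))
    stop_param("need both a test and a control group")
  mat <- prepare_log2(table$values, log2)
  stat_of <- function(side) {
    sub <- mat[, lab == side, drop = FALSE]
    obs <- !is.na(sub)
    n <- rowSums(obs)
    m <- rowSums(ifelse(obs, sub, 0)) / n
    v <- (rowSums(ifelse(obs, sub, 0)^2) - n * m^2) / pmax(n - 1, 1)
    list(n = n, m = m, v = pmax(v, 0))
  }
  a <- stat_of("test"); b <- stat_of("control")
  testable <- a$n >= 2 & b$n >= 2
  se2 <- a$v / a$n + b$v / b$n
  zerovar <- testable & se2 == 0
  if (any(zerovar))
    warning(sprintf("dropped %d protein(s) with zero variance in both groups",
                    sum(zerovar)))
  keep <- testable & !zerovar
  if (any(!testable))
    warning(sprintf("skipped %d protein(s) lacking >=2 values per group",
                    sum(!testable)))
  t_stat <- (a$m - b$m) / sqrt(se2)
  df <- se2^2 / (a$v^2 / (a$n^2 * (a$n - 1)) + b$v^2 / (b$n^2 * (b$n - 1)))
  p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  out <- data.frame(protein_id = rownames(mat), statistic = t_stat, df = df,
                    p = p, mean_test = a$m, mean_control = b$m,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out[, c("protein_id", "statistic", "df", "p", "q",
          "mean_test", "mean_control")]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic BH q-values: `q_(i) = min_{j >= i} m * p_(j) / j`, clipped at 1,
#' returned in the input order. Thin validated front-end to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1))
    stop_param("p-values must be numeric in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Bipartition filtered proteins into predominance clusters
#'
#' Rows are z-scored on the log2 scale and cut into two groups by
#' agglomerative hierarchical clustering (Ward linkage on Euclidean
#' distances). `cluster1` is oriented as the control-predominant group: the
#' cluster whose mean z-score over control-condition samples is higher;
#' `cluster2` is the lesion-predominant complement.
#'
#' @param table an [abundance_table()].
#' @param retained protein ids to cluster (subset of the table's proteins).
#' @param control_condition condition token marking control samples
#'   (default `"IVC"`).
#' @param log2 transform before z-scoring.
#' @return list of class `predominance_clusters` with character vectors
#'   `cluster1` (control-predominant) and `cluster2` (lesion-predominant).
#' @export
bipartition_proteins <- function(table, retained, control_condition = "IVC",
                                 log2 = TRUE) {
  stopifnot(inherits(table, "abundance_table"))
  retained <- toupper(retained)
  missing <- setdiff(retained, rownames(table$values))
  if (length(missing))
    stop_param(sprintf("retained proteins absent from table: %s",
                       paste(head(missing, 5), collapse = ", ")))
  if (length(retained) < 2)
    stop_data("need at least 2 retained proteins to bipartition")
  if (!control_condition %in% table$annotations$condition)
    stop_param(sprintf("no samples with condition '%s'", control_condition))
  mat <- prepare_log2(table$values[retained, , drop = FALSE], log2)
  z <- t(apply(mat, 1, function(x) {
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x, na.rm = TRUE)) / s
  }))
  colnames(z) <- colnames(mat)
  cl <- cutree(hclust(dist(z), method = "ward.D2"), k = 2)
  ctrl_cols <- table$annotations$sample_id[table$annotations$condition ==
                                             control_condition]
  mean_ctrl <- vapply(1:2, function(k) {
    mean(z[cl == k, ctrl_cols, drop = FALSE], na.rm = TRUE)
  }, 0)
  first <- which.max(mean_ctrl)
  structure(list(cluster1 = sort(retained[cl == first]),
                 cluster2 = sort(retained[cl != first])),
            class = "predominance_clusters")
}
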