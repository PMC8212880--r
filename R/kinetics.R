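# Coabundance trend clustering of time-course proteomes. Diseased and
# control profiles are pooled and clustered once; clusters are then labelled
# early/late/flat by centroid shape and the disease-condition proteins are
# extracted per phase.

#' Fractional normalization of a raw kinetic profile
#'
#' Divides each timepoint value by the profile sum, so profiles describe the
#' *shape* of a protein's trajectory on a common scale (entries in \[0,1\]
#' summing to 1), invariant to absolute abundance.
#'
#' @param x non-negative numeric vector (one replicate-averaged value per
#'   timepoint).
#' @return numeric vector of fractions, or `NULL` (with a warning) for an
#'   all-zero profile, which carries no shape information.
#' @export
fractional_normalize <- function(x) {
  if (any(is.na(x)) || any(x < 0))
    stop_param("profile values must be non-negative and observed")
  s <- sum(x)
  if (s == 0) {
    warning("all-zero profile excluded from fractional normalization")
    return(NULL)
  }
  x / s
}

#' Build fractional kinetic profiles from an abundance table
#'
#' Replicates are averaged per condition and timepoint, then each
#' (protein, condition) trajectory is fractionally normalized. All-zero
#' trajectories are excluded with a warning.
#'
#' @param table an [abundance_table()] whose annotations carry `condition`,
#'   `timepoint` and `replicate`.
#' @param timepoint_order optional character vector fixing the timepoint
#'   order; defaults to order of first appearance in the annotations.
#' @return object of class `kinetic_profiles`: list with `fractions`
#'   (profiles x timepoints matrix), `protein`, `condition`, `timepoints`.
#' @export
kinetic_profiles <- function(table, timepoint_order = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  ann <- table$annotations
  tps <- timepoint_order %||% unique(ann$timepoint)
  if (!all(ann$timepoint %in% tps))
    stop_param("timepoint_order does not cover all annotated timepoints")
  if (length(tps) < 2) stop_param("need at least 2 timepoints")
  conds <- unique(ann$condition)
  vals <- table$values
  rows <- list(); protein <- character(); condition <- character()
  dropped <- 0L
  for (cond in conds) {
    avg <- do.call(cbind, lapply(tps, function(tp) {
      cols <- ann$sample_id[ann$condition == cond & ann$timepoint == tp]
      if (length(cols) == 0) return(rep(NA_real_, nrow(vals)))
      rowMeans(vals[, cols, drop = FALSE], na.rm = TRUE)
    }))
    avg[is.nan(avg)] <- 0
    sums <- rowSums(avg)
    zero <- sums == 0
    dropped <- dropped + sum(zero)
    keep <- which(!zero)
    if (length(keep)) {
      rows[[cond]] <- avg[keep, , drop = FALSE] / sums[keep]
      protein <- c(protein, rownames(vals)[keep])
      condition <- c(condition, rep(cond, length(keep)))
    }
  }
  if (dropped > 0)
    warning(sprintf("excluded %d all-zero profile(s)", dropped))
  fractions <- do.call(rbind, rows)
  colnames(fractions) <- tps
  rownames(fractions) <- paste(protein, condition, sep = "|")
  structure(list(fractions = fractions, protein = protein,
                 condition = condition, timepoints = tps),
            class = "kinetic_profiles")
}

# k-means++ seeding: first center uniform, then points weighted by squared
# distance to the nearest chosen center
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (k in seq_len(K - 1)) {
    if (all(d2 == 0)) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = d2)
    centers[k + 1, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[k + 1, ])^2))
  }
  centers
}

em_diag_gmm <- function(X, K, max_iter, tol, var_floor) {
  n <- nrow(X); T_ <- ncol(X)
  centers <- kmeanspp_centers(X, K)
  # hard-assign to the nearest seed to initialize moments
  d2 <- vapply(seq_len(K), function(k) rowSums(sweep(X, 2, centers[k, ])^2),
               numeric(n))
  assign0 <- max.col(-d2, ties.method = "first")
  w <- pmax(tabulate(assign0, K), 1) / n
  w <- w / sum(w)
  mu <- centers
  global_var <- pmax(apply(X, 2, var), var_floor)
  sig2 <- matrix(rep(global_var, each = K), K, T_)
  for (k in seq_len(K)) {
    pts <- X[assign0 == k, , drop = FALSE]
    if (nrow(pts) >= 2) sig2[k, ] <- pmax(apply(pts, 2, var), var_floor)
  }
  ll_prev <- -Inf
  ll_trace <- numeric(0)
  monotone <- TRUE
  reseeded <- FALSE
  logdens <- matrix(0, n, K)
  for (iter in seq_len(max_iter)) {
    for (k in seq_len(K)) {
      logdens[, k] <- log(w[k]) -
        0.5 * rowSums(sweep(sweep(X, 2, mu[k, ])^2, 2, sig2[k, ], `/`)) -
        0.5 * sum(log(2 * pi * sig2[k, ]))
    }
    lse <- row_logsumexp(logdens)
    ll <- sum(lse)
    if (!reseeded && ll < ll_prev - 1e-8 * (1 + abs(ll))) monotone <- FALSE
    ll_trace <- c(ll_trace, ll)
    converged <- is.finite(ll_prev) && abs(ll - ll_prev) < tol * (1 + abs(ll))
    ll_prev <- ll
    resp <- exp(logdens - lse)
    Nk <- colSums(resp)
    empty <- which(Nk < 1e-8)
    if (length(empty)) {
      worst <- which.min(lse)
      for (k in empty) {
        mu[k, ] <- X[worst, ]
        sig2[k, ] <- global_var
        Nk[k] <- 1
      }
      w <- Nk / sum(Nk)
      reseeded <- TRUE
      next
    }
    reseeded <- FALSE
    w <- Nk / n
    mu <- (t(resp) %*% X) / Nk
    sig2 <- pmax((t(resp) %*% X^2) / Nk - mu^2, var_floor)
    if (converged) break
  }
  list(loglik = ll_prev, weights = w, mu = mu, sig2 = sig2,
       assignment = max.col(logdens, ties.method = "first"),
       converged = converged, ll_trace = ll_trace, monotone = monotone)
}

#' Fit coabundance trend clusters by Gaussian mixture EM
#'
#' Fits a K-component mixture of diagonal-covariance Gaussians to the pooled
#' fractional profiles (disease and control conditions together, so matched
#' profiles land in a shared cluster space) by expectation-maximization.
#' Initialization is seeded k-means++; the best of `restarts` runs by
#' log-likelihood wins. Clusters that empty out during EM are re-seeded from
#' the worst-fit profile. Hard assignments take the maximum responsibility.
#'
#' @param profiles a [kinetic_profiles()] object.
#' @param K number of clusters (default 30, matching a 30-cluster trend
#'   layout typical for 4-timepoint vein-graft time courses).
#' @param seed integer seed; the fit is a pure function of profiles, K and
#'   seed.
#' @param restarts independent initializations (default 5).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param var_floor lower bound on per-dimension variances; keeps noiseless
#'   (zero-variance) clusters proper.
#' @return object of class `cluster_model`: `K`, `centroids` (K x T),
#'   `assignment` (integer per profile), `protein`, `condition`,
#'   `timepoints`, `loglik`, `converged`, `phase` (NULL until
#'   [classify_phase()]), plus the log-likelihood trace of the winning run.
#' @export
fit_kinetic_clusters <- function(profiles, K = 30, seed = 1, restarts = 5,
                                 max_iter = 300, tol = 1e-8,
                                 var_floor = 1e-6) {
  stopifnot(inherits(profiles, "kinetic_profiles"))
  X <- profiles$fractions
  if (!is.numeric(K) || K < 2) stop_param("K must be >= 2")
  if (nrow(X) < K) stop_param("need at least K profiles")
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- withr::with_seed(derive_seed(seed, r),
                            em_diag_gmm(X, K, max_iter, tol, var_floor))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged)
    warning("EM did not converge within max_iter; returning best iterate")
  structure(list(K = as.integer(K),
                 centroids = unname(best$mu),
                 assignment = best$assignment,
                 protein = profiles$protein,
                 condition = profiles$condition,
                 timepoints = profiles$timepoints,
                 loglik = best$loglik,
                 ll_trace = best$ll_trace,
                 monotone = best$monotone,
                 converged = best$converged,
                 phase = NULL),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: K=%d over %d profiles (%d timepoints), loglik=%.2f\n",
              x$K, length(x$assignment), length(x$timepoints), x$loglik))
  if (!is.null(x$phase))
    cat("phases:", paste(sprintf("%s=%d", names(table(x$phase)),
                                 table(x$phase)), collapse = ", "), "\n")
  invisible(x)
}

#' Label clusters as early, late or flat
#'
#' A cluster is `flat` when its centroid's range (max minus min fraction)
#' falls below `flat_range`; otherwise it is `early` when the centroid peaks
#' at an early timepoint and `late` when it peaks late.
#'
#' @param model a [fit_kinetic_clusters()] model.
#' @param early_timepoints,late_timepoints timepoint names (or indices)
#'   forming a disjoint partition of all timepoints. Defaults: first half
#'   early, second half late.
#' @param flat_range centroid range below which a cluster is flat, on the
#'   fractional scale (default 0.10; a perfectly uniform 4-point profile sits
#'   at 0.25 per timepoint).
#' @return the model with a `phase` character vector (one of
#'   `"early"`, `"late"`, `"flat"` per cluster).
#' @export
classify_phase <- function(model,
                           early_timepoints = NULL,
                           late_timepoints = NULL,
                           flat_range = 0.10) {
  stopifnot(inherits(model, "cluster_model"))
  tps <- model$timepoints
  half <- length(tps) %/% 2
  early_timepoints <- early_timepoints %||% tps[seq_len(half)]
  late_timepoints <- late_timepoints %||% tps[-seq_len(half)]
  as_idx <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    m <- match(x, tps)
    if (anyNA(m)) stop_param("unknown timepoint in phase index sets")
    m
  }
  e <- as_idx(early_timepoints); l <- as_idx(late_timepoints)
  if (length(e) == 0 || length(l) == 0)
    stop_param("early and late timepoint sets must be non-empty")
  if (length(intersect(e, l)) || !setequal(c(e, l), seq_along(tps)))
    stop_param("early and late sets must partition the timepoints")
  model$phase <- apply(model$centroids, 1, function(cen) {
    if (max(cen) - min(cen) < flat_range) return("flat")
    if (which.max(cen) %in% e) "early" else "late"
  })
  model
}

#' Extract per-phase protein sets for one condition
#'
#' For each non-flat phase, returns the proteins whose profile *in the kept
#' condition* sits in a cluster of that phase. Control-condition profiles
#' never contribute, and flat clusters are omitted entirely (minimally
#' changing trends carry no kinetic signal).
#'
#' @param model a phase-labelled [classify_phase()] model.
#' @param keep_condition condition token to keep (default `"VG"`).
#' @return list with character vectors `early` and `late`.
#' @export
condition_filter <- function(model, keep_condition = "VG") {
  stopifnot(inherits(model, "cluster_model"))
  if (is.null(model$phase))
    stop_param("model has no phases; run classify_phase() first")
  if (!keep_condition %in% model$condition)
    stop_param(sprintf("unknown condition '%s'", keep_condition))
  keep <- model$condition == keep_condition
  phase_of <- model$phase[model$assignment[keep]]
  prot <- model$protein[keep]
  list(early = sort(unique(prot[phase_of == "early"])),
       late = sort(unique(prot[phase_of == "late"])))
}

#' Set concordance between two protein sets
#'
#' @param set_a,set_b character vectors.
#' @return list: `n_common`, `n_only_a`, `n_only_b`, `jaccard` (NA when both
#'   sets are empty).
#' @export
set_concordance <- function(set_a, set_b) {
  a <- unique(toupper(set_a)); b <- unique(toupper(set_b))
  common <- length(intersect(a, b))
  uni <- length(union(a, b))
  list(n_common = common,
       n_only_a = length(setdiff(a, b)),
       n_only_b = length(setdiff(b, a)),
       jaccard = if (uni == 0) NA_real_ else common / uni)
}
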