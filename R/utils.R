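#' @keywords internal
"_PACKAGE"

#' @importFrom stats dist hclust cutree median p.adjust pf pt phyper rnorm
#'   runif sd var dnorm ks.test
#' @importFrom utils head read.delim write.table combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a global seed
#'
#' Stage seeds are a fixed affine function of the global seed so that changing
#' one stage's parameters never shifts another stage's random stream. The
#' result always fits a 32-bit integer.
#'
#' @param seed integer global seed.
#' @param offset integer stage offset (each pipeline stage uses its own).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483629 + 9973 * (as.numeric(offset) %% 100000)) %% 2147483629)
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-model-corrected agreement between two partitions of the same
#' items; 1 means identical partitions, 0 is the chance level. Used to score
#' recovery of planted cluster labels.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_param("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# log(sum(exp(x))) by rows of a matrix, stably
row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# locale-independent order for character keys (byte-wise radix)
stable_order <- function(...) order(..., method = "radix")
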