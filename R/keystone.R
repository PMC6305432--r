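#' Stable genera by occurrence frequency
#'
#' A genus is "stable" when it is present (relative abundance at or
#' above `floor`) in strictly more than `min_freq` of the samples.
#'
#' @param genus_profile Genus x samples relative [abundance_matrix()].
#' @param min_freq Occurrence-frequency threshold (default 0.70).
#' @param floor Presence floor (default `1e-8`).
#' @return Character vector of stable genus names.
#' @export
occurrence_filter <- function(genus_profile, min_freq = 0.70,
                              floor = 1e-8) {
  m <- unclass(genus_profile)
  freq <- rowMeans(m >= floor)
  rownames(m)[freq > min_freq]
}

#' Significance-pruned Spearman correlation network of genera
#'
#' Pairwise Spearman correlations between genus profiles (average ranks
#' for ties), assessed with the t statistic
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom, two-sided. Edges with `p > alpha` are removed. A perfectly
#' monotone pair (`|rho| = 1`) gets the enumeration bound `p = 2 / n!`,
#' flagged exact. Constant genus vectors are excluded and recorded.
#'
#' @param stable_profile Genus x samples matrix restricted to stable
#'   genera; at least 4 samples.
#' @param alpha Edge significance level (default 0.05).
#' @return Data frame of retained undirected edges (`source < target`):
#'   `source`, `target`, `rho`, `p`, `sign`, `exact`; attribute
#'   `nodes` holds all tested genera and `excluded` the constant ones.
#' @export
correlation_network <- function(stable_profile, alpha = 0.05) {
  m <- unclass(stable_profile)
  n <- ncol(m)
  if (n < 4) stop("correlation network needs at least 4 samples")
  sds <- apply(m, 1L, stats::sd)
  excluded <- rownames(m)[sds == 0]
  m <- m[sds > 0, , drop = FALSE]
  g <- rownames(m)
  rho_mat <- stats::cor(t(m), method = "spearman")
  pair <- which(upper.tri(rho_mat), arr.ind = TRUE)
  rho <- rho_mat[pair]
  ok <- !is.na(rho)
  pair <- pair[ok, , drop = FALSE]
  rho <- rho[ok]
  monotone <- abs(rho) >= 1 - 1e-12
  t_stat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  p[monotone] <- 2 / factorial(min(n, 170))
  keep <- p <= alpha
  out <- data.frame(source = g[pair[keep, 1]],
                    target = g[pair[keep, 2]],
                    rho = rho[keep], p = p[keep],
                    sign = sign(rho[keep]),
                    exact = monotone[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nodes") <- g
  attr(out, "excluded") <- excluded
  out
}

#' Hub genera of a correlation network
#'
#' Hubs have strictly more than `min_degree - 1` significant connections
#' (default: over 30, i.e. degree at least 31), evaluated on the pruned
#' network only.
#'
#' @param network Edge data frame from [correlation_network()].
#' @param min_degree Minimum degree (default 31).
#' @return Character vector of hub genus names.
#' @export
hub_genera <- function(network, min_degree = 31L) {
  deg <- table(c(network$source, network$target))
  names(deg)[deg >= min_degree]
}

#' Random-forest classification of age groups from genus profiles
#'
#' Fits a classification forest ([randomForest::randomForest()]) of
#' `n_trees` trees on genus abundances with group labels, reporting the
#' out-of-bag (OOB) error rate, the confusion matrix, and per-genus
#' importance as the mean decrease in the Gini index.
#'
#' @param genus_profile Genus x samples matrix.
#' @param groups Group label per sample; at least 2 groups of at least
#'   2 samples.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed; fixed seed gives identical importances.
#' @param top_k Genera reported in `top` (default 20).
#' @return A list with `oob_error`, `confusion`, `importances` (named,
#'   decreasing), `top` (top-k genus names), `n_trees`, `seed`.
#' @export
rf_importance <- function(genus_profile, groups, n_trees = 500L,
                          seed = 1L, top_k = 20L) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stop("random forest needs at least 2 groups")
  if (any(table(groups) < 2))
    stop("every group needs at least 2 samples")
  x <- t(unclass(genus_profile))
  colnames(x) <- make.names(colnames(x))
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = groups, ntree = n_trees,
                                    importance = FALSE)
  conf <- fit$confusion[, levels(groups), drop = FALSE]
  oob <- 1 - sum(diag(conf)) / sum(conf)
  imp <- fit$importance[, "MeanDecreaseGini"]
  names(imp) <- rownames(genus_profile)
  imp <- sort(imp, decreasing = TRUE)
  list(oob_error = unname(oob),
       confusion = conf,
       importances = imp,
       top = names(imp)[seq_len(min(top_k, length(imp)))],
       n_trees = as.integer(n_trees),
       seed = as.integer(seed))
}

#' Intersect hub genera with top random-forest genera
#'
#' The shared set — genera that are both network hubs and among the most
#' discriminative by Gini importance — is the structurally important
#' ("keystone") call of the two-method approach. Random-forest rank
#' order is preserved.
#'
#' @param hubs Hub genus names ([hub_genera()]).
#' @param rf_top Ordered top genera ([rf_importance()]`$top`).
#' @return A list with `hub_genera`, `rf_top`, `shared`.
#' @export
intersect_important <- function(hubs, rf_top) {
  list(hub_genera = hubs,
       rf_top = rf_top,
       shared = rf_top[rf_top %in% hubs])
}
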