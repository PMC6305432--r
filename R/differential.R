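#' Aggregate gene abundances to functional features
#'
#' Feature abundance is the sum of the abundances of all genes annotated
#' to it. A gene with several annotations in the namespace contributes
#' fully to every assigned feature; unannotated genes are ignored.
#'
#' @param gene_matrix Genes x samples [abundance_matrix()].
#' @param catalog A [gene_catalog()].
#' @param namespace One of `KO`, `pathway`, `COG_category`, `EC`, `CAZy`.
#' @return A features x samples [abundance_matrix()] (class
#'   `feature_profile`) with a `namespace` attribute. Units are carried
#'   over but note that multi-annotation means feature columns may sum to
#'   more than the annotated gene mass.
#' @export
aggregate_features <- function(gene_matrix, catalog, namespace) {
  ann <- catalog_annotations(catalog, namespace)
  ann <- ann[intersect(rownames(gene_matrix), names(ann))]
  n_per_gene <- lengths(ann)
  keep <- n_per_gene > 0
  if (!any(keep))
    stop("no gene in the matrix carries a ", namespace, " annotation")
  gene_rep <- rep(names(ann)[keep], n_per_gene[keep])
  feat <- unlist(ann[keep], use.names = FALSE)
  agg <- rowsum(unclass(gene_matrix)[gene_rep, , drop = FALSE],
                group = feat)
  # relative flag is not preserved: sums can exceed 1 via multi-annotation
  prof <- abundance_matrix(agg, "counts")
  attr(prof, "units") <- abundance_units(gene_matrix)
  attr(prof, "namespace") <- namespace
  class(prof) <- c("feature_profile", "abundance_matrix", "matrix",
                   "array")
  prof
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the pooled size is at most `exact_threshold`
#' and there are no ties; otherwise the normal approximation with tie
#' and continuity correction. Backed by [stats::wilcox.test()].
#'
#' @param a,b Numeric samples, each non-empty.
#' @param exact_threshold Pooled-size bound for the exact test
#'   (default 12).
#' @return The two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_threshold = 12L) {
  if (length(a) < 1 || length(b) < 1) stop("empty group")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && (length(a) + length(b)) <= exact_threshold
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
}

#' Holm step-down adjustment of p-values
#'
#' `adj_(i) = max_{j <= i} min(1, (m - j + 1) * p_(j))` over the
#' ascending order, restored to input order. Delegates to
#' [stats::p.adjust()].
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, `>=` the raw ones.
#' @export
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1) || anyNA(p_values))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "holm")
}

#' Pairwise Wilcoxon screening of a feature profile
#'
#' Tests every feature between two sample classes and applies Holm
#' adjustment within the namespace x contrast family.
#'
#' @param profile A features x samples matrix ([aggregate_features()]
#'   output or any [abundance_matrix()]).
#' @param groups Two-level factor over samples.
#' @param exact_threshold Pooled-size bound for the exact Wilcoxon
#'   p-value (default 50, the [stats::wilcox.test()] convention).
#' @return Data frame `feature_id`, `raw_p`, `adjusted_p`, `direction`
#'   (sign of the median difference, first level minus second).
#' @export
test_features <- function(profile, groups, exact_threshold = 50L) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("test_features contrasts two classes")
  m <- unclass(profile)
  a_idx <- groups == levels(groups)[1]
  raw <- apply(m, 1L, function(v)
    wilcoxon_rank_sum(v[a_idx], v[!a_idx], exact_threshold))
  data.frame(feature_id = rownames(m),
             raw_p = unname(raw),
             adjusted_p = unname(holm_adjust(raw)),
             direction = sign(apply(m, 1L, function(v)
               stats::median(v[a_idx]) - stats::median(v[!a_idx]))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Linear-discriminant effect size of features between two classes
#'
#' A reimplementation of the LDA-effect-size biomarker score for a flat
#' (subclass-free) design. Features first pass a Kruskal-Wallis filter
#' at `alpha`; surviving features are placed on the `[1, 1e6]` relative
#' scale (fractional abundances are multiplied by 1e6; matrices already
#' on an absolute scale are used as-is), and over `n_boot` stratified bootstrap
#' resamples a one-dimensional linear discriminant between the classes
#' is fitted per feature (for a single feature the discriminant axis is
#' the feature itself, so the discriminant class difference is the
#' scaled between-class mean difference). The reported score is the
#' median over resamples of `log10(1 + |difference|)`, signed by the
#' direction of enrichment (positive = enriched in the first class).
#'
#' @param feature_matrix Features x samples matrix.
#' @param classes Two-level factor over samples, each level with at
#'   least 3 samples.
#' @param cutoff Effect-size cutoff on the log10 scale (default 2.0).
#' @param seed Integer seed for the bootstrap.
#' @param alpha Kruskal-Wallis filter level (default 0.05).
#' @param n_boot Bootstrap resamples (default 30).
#' @param prefilter Apply the Kruskal-Wallis filter (default `TRUE`);
#'   when `FALSE` every feature is scored.
#' @return Data frame `feature_id`, `kw_p`, `lda_score` (`NA` for
#'   features failing the filter), `passes`.
#' @export
lda_effect_size <- function(feature_matrix, classes, cutoff = 2.0,
                            seed = 1L, alpha = 0.05, n_boot = 30L,
                            prefilter = TRUE) {
  classes <- as.factor(classes)
  if (nlevels(classes) != 2) stop("lda_effect_size needs two classes")
  if (any(table(classes) < 3))
    stop("each class needs at least 3 samples")
  m <- unclass(feature_matrix)
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))

  kw_p <- apply(m, 1L, function(v) {
    if (stats::sd(v) == 0) return(1)
    suppressWarnings(stats::kruskal.test(v, classes)$p.value)
  })
  score_idx <- if (prefilter) which(kw_p < alpha) else seq_len(nrow(m))

  # the [1, 1e6] relative-abundance convention: fractional inputs
  # (column sums <= 1) are mapped onto a per-million scale; inputs
  # already on an absolute scale are scored as-is
  scaled <- if (all(colSums(m) <= 1 + 1e-9)) m * 1e6 else m

  scores <- rep(NA_real_, nrow(m))
  if (length(score_idx)) {
    set.seed(seed)
    idx_by_class <- split(seq_along(classes), classes)
    boot <- matrix(NA_real_, length(score_idx), n_boot)
    for (b in seq_len(n_boot)) {
      take <- unlist(lapply(idx_by_class, function(ix)
        sample(ix, length(ix), replace = TRUE)))
      cl <- classes[take]
      mm <- scaled[score_idx, take, drop = FALSE]
      d <- rowMeans(mm[, cl == levels(classes)[1], drop = FALSE]) -
        rowMeans(mm[, cl == levels(classes)[2], drop = FALSE])
      boot[, b] <- sign(d) * log10(1 + abs(d))
    }
    scores[score_idx] <- apply(boot, 1L, stats::median)
  }
  data.frame(feature_id = rownames(m),
             kw_p = unname(kw_p),
             lda_score = scores,
             passes = !is.na(scores) & abs(scores) >= cutoff,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Host genus attribution of pathway abundance
#'
#' For each pathway and group, the abundance contributed by each genus
#' is the summed abundance (over the group's samples) of the pathway's
#' member genes carried by that genus; the host is the genus with the
#' largest share. Ties resolve lexicographically with a warning; a
#' pathway with zero abundance in a group is flagged undefined
#' (`NA` host).
#'
#' @param gene_matrix Genes x samples [abundance_matrix()].
#' @param catalog A [gene_catalog()] (pathway annotations and genus
#'   lineage).
#' @param groups Group label per matrix sample.
#' @param pathways Pathways to attribute (default: all annotated).
#' @return Data frame `pathway_id`, `group`, `host_genus`, `host_share`.
#' @export
host_attribution <- function(gene_matrix, catalog, groups,
                             pathways = NULL) {
  ann <- catalog_annotations(catalog, "pathway")
  ann <- ann[intersect(rownames(gene_matrix), names(ann))]
  n_per <- lengths(ann)
  gene_rep <- rep(names(ann)[n_per > 0], n_per[n_per > 0])
  pw <- unlist(ann[n_per > 0], use.names = FALSE)
  if (is.null(pathways)) pathways <- sort(unique(pw))
  genus <- catalog$genus[match(gene_rep, catalog$gene_id)]
  m <- unclass(gene_matrix)
  groups <- as.character(groups)

  out <- list()
  for (g in unique(groups)) {
    tot_per_gene <- rowSums(m[gene_rep, groups == g, drop = FALSE])
    for (p in pathways) {
      sel <- pw == p
      shares <- tapply(tot_per_gene[sel], genus[sel], sum)
      total <- sum(shares)
      if (length(shares) == 0 || total == 0) {
        out[[length(out) + 1L]] <- data.frame(
          pathway_id = p, group = g, host_genus = NA_character_,
          host_share = NA_real_, stringsAsFactors = FALSE)
        next
      }
      shares <- shares / total
      winners <- sort(names(shares)[shares == max(shares)])
      if (length(winners) > 1)
        warning(sprintf("host tie for %s in group %s: taking '%s'",
                        p, g, winners[1]))
      out[[length(out) + 1L]] <- data.frame(
        pathway_id = p, group = g, host_genus = winners[1],
        host_share = unname(max(shares)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
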