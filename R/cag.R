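#' Pearson correlation between two gene abundance profiles
#'
#' The complement of the Pearson correlation coefficient (PCC) is the
#' "distance" that drives canopy clustering of co-abundance genes.
#' Returns `NA` with a warning for a zero-variance vector; such genes are
#' excluded from clustering.
#'
#' @param x,y Numeric abundance vectors over the same samples.
#' @return PCC in `[-1, 1]`, or `NA` when either vector has zero
#'   variance.
#' @export
gene_pcc <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance vector: PCC undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

# correlation of one profile against each row of m, NA for constant rows
row_pcc <- function(m, profile) {
  sds <- apply(m, 1L, stats::sd)
  out <- rep(NA_real_, nrow(m))
  ok <- sds > 0 & stats::sd(profile) > 0
  if (any(ok))
    out[ok] <- as.vector(stats::cor(t(m[ok, , drop = FALSE]), profile))
  out
}

#' Canopy clustering of genes by co-abundance
#'
#' Iterates genes in a seeded-random order. Each still-unassigned gene
#' becomes the seed of a new canopy; all unassigned genes whose PCC with
#' the seed profile is at least `capture_pcc` join it. The canopy profile
#' is then recomputed as the per-sample median over members and
#' membership re-gathered against the refined profile, until a fixed
#' point or at most `max_iter` refinements. Assigned genes are never
#' re-seeded, so canopies partition the clustered genes.
#'
#' Genes with zero variance or absent (zero) in more than
#' `max_zero_fraction` of samples are excluded (PCC is unstable on
#' near-constant vectors) and listed in the `excluded` attribute.
#'
#' @param gene_matrix An [abundance_matrix()] of genes x samples.
#' @param capture_pcc Capture threshold (default 0.90).
#' @param seed_order_seed Integer seed for the gene iteration order;
#'   identical seeds give identical partitions.
#' @param max_zero_fraction Sparsity cutoff for exclusion (default 0.90).
#' @param max_iter Maximum profile refinements per canopy (default 5).
#' @return A list of canopies (each with `seed_gene`, `members`,
#'   `profile`), with attribute `excluded` naming the genes left out.
#' @export
canopy_cluster <- function(gene_matrix, capture_pcc = 0.90,
                           seed_order_seed = 1L,
                           max_zero_fraction = 0.90, max_iter = 5L) {
  m <- unclass(gene_matrix)
  sds <- apply(m, 1L, stats::sd)
  zero_frac <- rowMeans(m == 0)
  usable <- sds > 0 & zero_frac <= max_zero_fraction
  excluded <- rownames(m)[!usable]
  m <- m[usable, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 genes with positive variance")

  set.seed(seed_order_seed)
  order_idx <- sample.int(nrow(m))
  assigned <- logical(nrow(m))
  canopies <- list()
  for (i in order_idx) {
    if (assigned[i]) next
    pool <- which(!assigned)
    profile <- m[i, ]
    members <- i
    for (iter in seq_len(max_iter)) {
      pcc <- row_pcc(m[pool, , drop = FALSE], profile)
      new_members <- pool[!is.na(pcc) & pcc >= capture_pcc]
      new_members <- union(i, new_members)  # seed always stays
      if (setequal(new_members, members) && iter > 1L) break
      members <- new_members
      profile <- apply(m[members, , drop = FALSE], 2L, stats::median)
      if (length(members) == 1L) break
    }
    assigned[members] <- TRUE
    canopies[[length(canopies) + 1L]] <-
      list(seed_gene = rownames(m)[i],
           members = rownames(m)[members],
           profile = profile)
  }
  attr(canopies, "excluded") <- excluded
  canopies
}

#' Merge correlated canopies into co-abundance gene groups (CAGs)
#'
#' Canopies whose median profiles correlate at PCC `>= merge_pcc` are
#' merged by single linkage (connected components of the
#' above-threshold correlation graph). Each CAG's profile is the
#' per-sample median over all of its member genes.
#'
#' @param canopies Output of [canopy_cluster()].
#' @param gene_matrix The gene matrix the canopies were built from.
#' @param merge_pcc Merge threshold on profile PCC (default 0.97,
#'   i.e. a PCC distance below 0.03).
#' @return A list of CAGs (`cag_id`, `members`, `profile`,
#'   `label = NA`, `is_mgs = NA`), ordered by decreasing size.
#' @export
merge_canopies <- function(canopies, gene_matrix, merge_pcc = 0.97) {
  k <- length(canopies)
  if (k == 0) return(list())
  profiles <- do.call(rbind, lapply(canopies, `[[`, "profile"))
  comp <- seq_len(k)
  if (k > 1) {
    sds <- apply(profiles, 1L, stats::sd)
    cc <- suppressWarnings(stats::cor(t(profiles)))
    cc[is.na(cc)] <- 0
    adj <- cc >= merge_pcc & outer(sds > 0, sds > 0)
    diag(adj) <- TRUE
    # union-find over the adjacency graph (single linkage)
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k))
      if (adj[i, j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    comp <- vapply(seq_len(k), find, integer(1))
  }
  m <- unclass(gene_matrix)
  groups <- split(seq_len(k), comp)
  cags <- lapply(groups, function(idx) {
    members <- unlist(lapply(canopies[idx], `[[`, "members"),
                      use.names = FALSE)
    prof <- apply(m[members, , drop = FALSE], 2L, stats::median)
    list(cag_id = NA_character_, members = members, profile = prof,
         label = NA_character_, is_mgs = NA)
  })
  cags <- unname(cags[order(-vapply(cags, function(c) length(c$members),
                                    integer(1)))])
  for (i in seq_along(cags))
    cags[[i]]$cag_id <- sprintf("CAG_%04d", i)
  cags
}

#' Flag metagenomic species (MGS) among CAGs
#'
#' An MGS is a CAG with strictly more than 20 member genes (at least
#' `min_genes = 21`), large enough to be treated as a species-level
#' entity.
#'
#' @param cags CAG list from [merge_canopies()].
#' @param min_genes Minimum member count (default 21).
#' @return The CAG list with `is_mgs` set.
#' @export
call_mgs <- function(cags, min_genes = 21L) {
  lapply(cags, function(cag) {
    cag$is_mgs <- length(cag$members) >= min_genes
    cag
  })
}

#' Assign a taxonomy label to a CAG
#'
#' A CAG is labelled with its modal member species when at least
#' `majority` (default 50%) of its genes are annotated to that species;
#' otherwise it is marked `'group'`. Genes unclassified at species level
#' count toward the denominator but cannot provide the label. A tie at
#' exactly the majority between two species resolves to the
#' lexicographically first, with a warning.
#'
#' @param cag A single CAG.
#' @param catalog A [gene_catalog()].
#' @param majority Modal-species fraction required (default 0.5).
#' @return The CAG with `label` set.
#' @export
label_cag <- function(cag, catalog, majority = 0.5) {
  sp <- catalog$species[match(cag$members, catalog$gene_id)]
  sp <- sp[!is.na(sp) & sp != "Unclassified"]
  if (length(sp) == 0) {
    cag$label <- "group"
    return(cag)
  }
  tab <- sort(table(sp), decreasing = TRUE)
  frac <- as.numeric(tab) / length(cag$members)
  if (frac[1] < majority) {
    cag$label <- "group"
  } else {
    winners <- names(tab)[frac == frac[1]]
    if (length(winners) > 1) {
      winners <- sort(winners)
      warning(sprintf("species tie at %.0f%% in %s: taking '%s'",
                      100 * frac[1], cag$cag_id, winners[1]))
    }
    cag$label <- winners[1]
  }
  cag
}

#' Summary table of a CAG list
#' @param cags CAG list.
#' @return Data frame with `cag_id`, `n_genes`, `is_mgs`, `label`, and a
#'   semicolon-joined `members` column.
#' @export
cag_table <- function(cags) {
  data.frame(
    cag_id = vapply(cags, `[[`, character(1), "cag_id"),
    n_genes = vapply(cags, function(c) length(c$members), integer(1)),
    is_mgs = vapply(cags, `[[`, logical(1), "is_mgs"),
    label = vapply(cags, `[[`, character(1), "label"),
    members = vapply(cags, function(c)
      paste(c$members, collapse = ";"), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Full CAG construction pipeline
#'
#' Canopy clustering, merging, MGS calling and labelling in one call.
#'
#' @param gene_matrix Genes x samples [abundance_matrix()].
#' @param catalog A [gene_catalog()].
#' @param config An [analysis_config()].
#' @param seed Seed for the canopy iteration order.
#' @return Labelled CAG list with MGS flags; `excluded` attribute names
#'   genes left out of clustering.
#' @export
build_cags <- function(gene_matrix, catalog, config = analysis_config(),
                       seed = 1L) {
  canopies <- canopy_cluster(gene_matrix,
                             capture_pcc = config$canopy_capture_pcc,
                             seed_order_seed = seed,
                             max_zero_fraction = config$max_zero_fraction)
  cags <- merge_canopies(canopies, gene_matrix,
                         merge_pcc = config$canopy_merge_pcc)
  cags <- call_mgs(cags, min_genes = config$mgs_min_genes)
  cags <- lapply(cags, label_cag, catalog = catalog,
                 majority = config$group_label_majority)
  attr(cags, "excluded") <- attr(canopies, "excluded")
  cags
}

#' Screen CAGs for significant change between two sample classes
#'
#' Per member gene, a two-sided Wilcoxon rank-sum test between the
#' contrasted classes with Holm adjustment across all tested genes. Each
#' CAG is then collapsed to only its significantly changed genes
#' (adjusted p < `alpha`); the collapsed abundance is the per-sample
#' median of the retained genes. Collapsed CAGs are scored with the LDA
#' effect size and reported when `|score| >= lda_cutoff`; the CAG-level
#' `q_value` is the Holm-adjusted Wilcoxon p on the collapsed profile.
#'
#' @param cags Labelled CAG list.
#' @param gene_matrix Genes x samples [abundance_matrix()].
#' @param groups Factor (or coercible) with exactly two levels over the
#'   matrix samples, e.g. pooled age-group contrasts; at least 3 samples
#'   per level.
#' @param alpha Gene-level significance (default 0.05).
#' @param lda_cutoff LDA effect-size cutoff (default 2.0).
#' @param seed Seed for the LDA bootstrap.
#' @param exact_threshold Pooled-size bound below which the Wilcoxon
#'   p-value is computed by exact enumeration (default 50, the
#'   [stats::wilcox.test()] convention; at microbiome sample sizes the
#'   exact tail is what lets any gene clear a Holm family of thousands).
#' @return Data frame `cag_id`, `label`, `n_retained`, `lda_score`,
#'   `q_value`, `retained_genes` (semicolon-joined), with the collapsed
#'   abundance matrix as attribute `abundance`.
#' @export
significant_cags <- function(cags, gene_matrix, groups, alpha = 0.05,
                             lda_cutoff = 2.0, seed = 1L,
                             exact_threshold = 50L) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2)
    stop("significant_cags contrasts exactly two classes")
  if (any(table(groups) < 3))
    stop("each contrasted class needs at least 3 samples")
  m <- unclass(gene_matrix)
  genes <- unique(unlist(lapply(cags, `[[`, "members")))
  a_idx <- groups == levels(groups)[1]
  raw_p <- vapply(genes, function(g)
    wilcoxon_rank_sum(m[g, a_idx], m[g, !a_idx], exact_threshold),
    numeric(1))
  adj_p <- holm_adjust(raw_p)
  sig_genes <- genes[adj_p < alpha]

  kept <- list()
  for (cag in cags) {
    retained <- intersect(cag$members, sig_genes)
    if (length(retained) == 0) next
    collapsed <- apply(m[retained, , drop = FALSE], 2L, stats::median)
    kept[[cag$cag_id]] <- list(cag = cag, retained = retained,
                               profile = collapsed)
  }
  empty <- data.frame(cag_id = character(0), label = character(0),
                      n_retained = integer(0), lda_score = numeric(0),
                      q_value = numeric(0), retained_genes = character(0),
                      stringsAsFactors = FALSE)
  if (length(kept) == 0) return(empty)

  coll <- do.call(rbind, lapply(kept, `[[`, "profile"))
  rownames(coll) <- names(kept)
  lda <- lda_effect_size(coll, groups, cutoff = lda_cutoff, seed = seed,
                         prefilter = FALSE)
  q <- holm_adjust(vapply(names(kept), function(id)
    wilcoxon_rank_sum(coll[id, a_idx], coll[id, !a_idx], exact_threshold),
    numeric(1)))

  res <- data.frame(
    cag_id = names(kept),
    label = vapply(kept, function(k) k$cag$label, character(1)),
    n_retained = vapply(kept, function(k) length(k$retained), integer(1)),
    lda_score = lda$lda_score[match(names(kept), lda$feature_id)],
    q_value = unname(q),
    retained_genes = vapply(kept, function(k)
      paste(k$retained, collapse = ";"), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  pass <- !is.na(res$lda_score) & abs(res$lda_score) >= lda_cutoff
  out <- res[pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "abundance") <- coll[out$cag_id, , drop = FALSE]
  out
}
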