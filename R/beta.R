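#' Whittaker dissimilarity matrix between samples
#'
#' The Whittaker index compares total to mean per-sample richness:
#' `beta_w - 1 = S_union / mean(alpha) - 1`, computed on presence/absence
#' where presence means relative abundance at or above `floor`. It is 0
#' for identical and 1 for disjoint communities. The abundance-weighted
#' variant (`weighted = TRUE`) is `sum|x - y| / sum(x + y)` on
#' proportions (Bray-Curtis form). Pairwise values come from
#' [vegan::betadiver()] / [vegan::vegdist()].
#'
#' @param profile A relative-abundance `taxon_profile` (taxa x samples).
#' @param floor Presence floor on relative abundance (default `1e-8`).
#' @param weighted Use the abundance-weighted variant (default `FALSE`).
#' @return A symmetric `dist`-convertible matrix with zero diagonal and
#'   entries in `[0, 1]`, samples in input order.
#' @export
whittaker_distance <- function(profile, floor = 1e-8, weighted = FALSE) {
  if (abundance_units(profile) != "relative")
    stop("whittaker_distance requires relative abundances")
  m <- t(unclass(profile))  # samples x taxa for vegan
  if (weighted) {
    d <- vegan::vegdist(m, method = "bray")
  } else {
    pa <- m >= floor
    if (any(rowSums(pa) == 0))
      stop("sample(s) with no taxon present at the floor: ",
           paste(rownames(pa)[rowSums(pa) == 0], collapse = ", "))
    d <- vegan::betadiver(pa, method = "w")
  }
  out <- as.matrix(d)
  diag(out) <- 0
  out
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers `-D^2/2` and eigendecomposes it. Negative eigenvalues
#' (possible for non-metric dissimilarities such as the Whittaker index)
#' are reported but excluded from the variance-explained denominator; no
#' Lingoes/Cailliez correction is applied.
#'
#' @param dist A symmetric dissimilarity matrix with zero diagonal.
#' @return A list with `coordinates` (samples x axes, one axis per
#'   positive eigenvalue), `eigenvalues` (all, descending), and
#'   `proportion_explained` (over positive eigenvalues only).
#' @export
pcoa <- function(dist) {
  d <- as.matrix(dist)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  n <- nrow(d)
  # cmdscale warns when fewer than k eigenvalues are positive; negative
  # eigenvalues are expected for non-metric input and reported below
  sc <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = n - 1L, eig = TRUE))
  eig <- sc$eig
  pos <- eig > max(eig) * 1e-9
  # cmdscale may return fewer axes than there are positive eigenvalues
  coords <- sc$points[, seq_len(min(sum(pos), ncol(sc$points))),
                      drop = FALSE]
  rownames(coords) <- rownames(d)
  if (ncol(coords) > 0)
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords,
       eigenvalues = eig,
       proportion_explained = if (any(pos)) eig[pos] / sum(eig[pos])
                              else numeric(0))
}

#' PERMANOVA (Adonis) on a dissimilarity matrix
#'
#' Partitions the total sum of squared dissimilarities by a grouping
#' factor (Anderson's pseudo-F) and assesses it by label permutation:
#' `p = (1 + #permuted F >= observed) / (1 + n_permutations)`. Computed
#' by [vegan::adonis2()].
#'
#' A degenerate all-zero dissimilarity matrix returns `R2 = 0`, `p = 1`
#' with a warning rather than an error.
#'
#' @param dist Symmetric dissimilarity matrix, samples in `groups` order.
#' @param groups Group label per sample; at least 2 groups with at least
#'   2 samples each.
#' @param n_permutations Number of permutations (default 999; the
#'   attainable p floor is `1/(n_permutations + 1)`).
#' @param seed Integer seed for the permutation stream.
#' @return A list with `R2`, `pseudo_F`, `p_value`, `n_permutations`.
#' @export
permanova <- function(dist, groups, n_permutations = 999L, seed = 1L) {
  d <- as.matrix(dist)
  groups <- as.factor(groups)
  if (length(groups) != nrow(d))
    stop("groups length must match distance matrix")
  tab <- table(groups)
  if (length(tab) < 2) stop("PERMANOVA needs at least 2 groups")
  if (any(tab < 2)) stop("every group needs at least 2 samples")
  if (all(d == 0)) {
    warning("all-zero dissimilarity matrix: returning R2 = 0, p = 1")
    return(list(R2 = 0, pseudo_F = 0, p_value = 1,
                n_permutations = as.integer(n_permutations)))
  }
  set.seed(seed)
  fit <- vegan::adonis2(stats::as.dist(d) ~ groups,
                        data = data.frame(groups = groups),
                        permutations = n_permutations)
  list(R2 = fit$R2[1],
       pseudo_F = fit$F[1],
       p_value = fit$`Pr(>F)`[1],
       n_permutations = as.integer(n_permutations))
}
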