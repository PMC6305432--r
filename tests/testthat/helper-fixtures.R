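# Fixture builders and independent oracles shared across test files.
# Oracles are deliberately naive (enumeration, brute-force group-by,
# direct formulas) and never call the code paths they check.

rand_abundance <- function(n_genes, n_samples, seed = 1, relative = TRUE) {
  set.seed(seed)
  m <- matrix(rexp(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  if (relative) m <- sweep(m, 2, colSums(m), "/")
  abundance_matrix(m, if (relative) "relative" else "counts")
}

tiny_catalog <- function(gene_ids, species = NULL, genus = NULL,
                         pathway = NULL) {
  n <- length(gene_ids)
  if (is.null(species)) species <- rep("Genus_A species_A", n)
  if (is.null(genus))
    genus <- ifelse(species == "Unclassified", "Unclassified",
                    sub(" .*", "", species))
  gene_catalog(data.frame(
    gene_id = gene_ids, length_bp = 500L,
    phylum = ifelse(genus == "Unclassified", "Unclassified", "Proteobacteria"),
    family = ifelse(genus == "Unclassified", "Unclassified", "Family_A"),
    genus = genus, species = species,
    KO = "", pathway = if (is.null(pathway)) "" else pathway,
    COG_category = "", EC = "", CAZy = "",
    stringsAsFactors = FALSE))
}

# exhaustive two-sided Wilcoxon rank-sum p-value by enumerating every
# assignment of pooled ranks to group A
enum_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(a)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_w <- apply(utils::combn(length(pooled), n1), 2, function(idx)
    sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  min(1, mean(abs(all_w - mu) >= abs(w_obs - mu) - 1e-9))
}

# hand-executed Holm step-down recursion
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- running
  }
  adj
}

# brute-force PERMANOVA pseudo-F and R2 from squared dissimilarities
brute_permanova <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.factor(groups)
  ss_total <- sum(d[lower.tri(d)]^2) / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    dg <- d[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(dg[lower.tri(dg)]^2) / length(idx)
  }
  a <- nlevels(groups)
  f <- ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
  list(F = f, R2 = (ss_total - ss_within) / ss_total)
}

# independent CAG partition on small inputs: full PCC matrix plus the
# same capture/merge rules applied in the same seeded order
brute_cag_partition <- function(m, capture, merge, seed) {
  cc <- suppressWarnings(cor(t(m)))
  set.seed(seed)
  ord <- sample.int(nrow(m))
  assigned <- rep(NA_integer_, nrow(m))
  canopies <- list()
  for (i in ord) {
    if (!is.na(assigned[i])) next
    pool <- which(is.na(assigned))
    profile <- m[i, ]
    members <- i
    for (iter in 1:5) {
      pcc <- suppressWarnings(apply(m[pool, , drop = FALSE], 1,
                                    function(r) cor(r, profile)))
      new_members <- union(i, pool[!is.na(pcc) & pcc >= capture])
      if (setequal(new_members, members) && iter > 1) break
      members <- new_members
      profile <- apply(m[members, , drop = FALSE], 2, median)
      if (length(members) == 1) break
    }
    canopies[[length(canopies) + 1]] <-
      list(members = members,
           profile = apply(m[members, , drop = FALSE], 2, median))
    assigned[members] <- length(canopies)
  }
  k <- length(canopies)
  comp <- seq_len(k)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  if (k > 1)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      r <- suppressWarnings(cor(canopies[[i]]$profile,
                                canopies[[j]]$profile))
      if (!is.na(r) && r >= merge) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  comp <- vapply(seq_len(k), find, integer(1))
  part <- comp[assigned]
  names(part) <- rownames(m)
  part
}

# map a CAG list to a gene -> cluster-id vector
cag_partition <- function(cags) {
  out <- unlist(lapply(cags, function(c)
    stats::setNames(rep(c$cag_id, length(c$members)), c$members)))
  out
}

# small simulated dataset for fast pipeline-level tests
small_sim <- function(seed = 1, ...) {
  p <- simulation_params(n_species = 12L, genes_per_species = c(5L, 8L),
                         n_keystone = 2L, ...)
  sim <- simulate_catalog(p, seed = seed)
  ab <- simulate_abundance(sim$catalog, sim$truth, p, seed = seed)
  c(sim, ab, list(params = p))
}
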