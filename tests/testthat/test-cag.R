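named_matrix <- function(vals, prefix = "g") {
  dimnames(vals) <- list(sprintf("%s%02d", prefix, seq_len(nrow(vals))),
                         sprintf("s%02d", seq_len(ncol(vals))))
  vals
}

test_that("gene_pcc is the Pearson correlation with a zero-variance flag", {
  x <- c(1, 2, 3, 4)
  expect_equal(gene_pcc(x, 2 * x), 1)
  expect_equal(gene_pcc(x, -x + 10), -1)
  # hand computation: cov = 14, sds = sqrt(5), sqrt(50) -> 14/sqrt(250)
  expect_equal(gene_pcc(x, c(1, 2, 3, 10)), 14 / sqrt(250),
               tolerance = 1e-12)
  expect_warning(r <- gene_pcc(x, rep(2, 4)), "zero-variance")
  expect_true(is.na(r))
})

test_that("canopy clustering handles degenerate geometries", {
  base <- c(1, 3, 2, 5, 4, 6)
  m <- named_matrix(rbind(base, base * 2, base * 0.5))
  can <- canopy_cluster(abundance_matrix(m, "counts"), capture_pcc = 0.9)
  expect_length(can, 1)
  expect_setequal(can[[1]]$members, rownames(m))

  m2 <- named_matrix(rbind(base, max(base) + 1 - base))
  can2 <- canopy_cluster(abundance_matrix(m2, "counts"),
                         capture_pcc = 0.9)
  expect_length(can2, 2)
  expect_true(all(lengths(lapply(can2, `[[`, "members")) == 1))
})

test_that("sparse and constant genes are excluded and reported", {
  base <- c(1, 3, 2, 5, 4, 6, 8, 7, 9, 10, 12, 11, 14, 13, 15, 16, 18,
            17, 19, 20)
  m <- named_matrix(rbind(base, base * 1.1, rep(4, 20),
                          c(2, rep(0, 19))))  # zero in 95% > 90% cut
  can <- canopy_cluster(abundance_matrix(m, "counts"))
  expect_setequal(attr(can, "excluded"), c("g03", "g04"))
  expect_setequal(unlist(lapply(can, `[[`, "members")),
                  c("g01", "g02"))
})

test_that("identical seeds give identical partitions; genes partition", {
  sim <- small_sim(seed = 31)
  c1 <- build_cags(sim$relative, sim$catalog, seed = 77)
  c2 <- build_cags(sim$relative, sim$catalog, seed = 77)
  expect_identical(cag_table(c1), cag_table(c2))
  members <- unlist(lapply(c1, `[[`, "members"))
  expect_identical(anyDuplicated(members), 0L)
  expect_setequal(c(members, attr(c1, "excluded")),
                  rownames(sim$relative))
})

test_that("canopy merging is single linkage over profile correlation", {
  t_axis <- seq(0, 1, length.out = 12)
  a <- sin(2 * pi * t_axis) + 2
  b <- a + 0.12 * t_axis          # highly correlated with a
  c_ <- b + 0.12 * t_axis         # highly correlated with b, less with a
  stopifnot(cor(a, b) > 0.97, cor(b, c_) > 0.97)
  canopies <- list(list(seed_gene = "A", members = "A", profile = a),
                   list(seed_gene = "B", members = "B", profile = b),
                   list(seed_gene = "C", members = "C", profile = c_))
  gm <- abundance_matrix(named_matrix(rbind(a, b, c_)), "counts")
  rownames(gm) <- c("A", "B", "C")
  cags <- merge_canopies(canopies, gm, merge_pcc = 0.97)
  expect_length(cags, 1)
  expect_setequal(cags[[1]]$members, c("A", "B", "C"))
  # profile is the per-sample median over member genes
  expect_equal(cags[[1]]$profile,
               apply(rbind(a, b, c_), 2, median), ignore_attr = TRUE)

  # far-apart canopies stay apart
  d <- rev(a)
  stopifnot(cor(a, d) < 0.5)
  gm2 <- named_matrix(rbind(a, d))
  rownames(gm2) <- c("A", "D")
  cags2 <- merge_canopies(
    list(canopies[[1]], list(seed_gene = "D", members = "D", profile = d)),
    abundance_matrix(gm2, "counts"), 0.97)
  expect_length(cags2, 2)
})

test_that("MGS and 'group' labels match brute-force rules on random CAGs", {
  set.seed(41)
  species_pool <- c(sprintf("Sp_%02d", 1:6), "Unclassified")
  n_cags <- 200
  sizes <- sample(1:40, n_cags, replace = TRUE)
  gene_ids <- sprintf("g%05d", seq_len(sum(sizes)))
  sp <- sample(species_pool, sum(sizes), replace = TRUE,
               prob = c(rep(0.9 / 6, 6), 0.1))
  catalog <- tiny_catalog(gene_ids,
                          species = sp,
                          genus = ifelse(sp == "Unclassified",
                                         "Unclassified",
                                         paste0("G_", sp)))
  idx <- split(seq_len(sum(sizes)), rep(seq_len(n_cags), sizes))
  cags <- lapply(seq_len(n_cags), function(i)
    list(cag_id = sprintf("CAG_%04d", i), members = gene_ids[idx[[i]]],
         profile = NULL, label = NA_character_, is_mgs = NA))
  cags <- call_mgs(cags)
  cags <- suppressWarnings(lapply(cags, label_cag, catalog = catalog))
  for (i in seq_len(n_cags)) {
    mem_sp <- sp[idx[[i]]]
    expect_identical(cags[[i]]$is_mgs, length(mem_sp) > 20)
    tab <- table(mem_sp[mem_sp != "Unclassified"])
    expected <- if (length(tab) == 0 ||
                    max(tab) / length(mem_sp) < 0.5) "group"
                else sort(names(tab)[tab == max(tab)])[1]
    expect_identical(cags[[i]]$label, expected)
  }
})

test_that("MGS boundary: 21 genes in, 20 genes out", {
  mk <- function(n) list(cag_id = "c", members = sprintf("g%d", 1:n),
                         profile = NULL, label = NA, is_mgs = NA)
  expect_true(call_mgs(list(mk(21)))[[1]]$is_mgs)
  expect_false(call_mgs(list(mk(20)))[[1]]$is_mgs)
})

test_that("label ties at exactly 50% resolve lexicographically with a
           warning", {
  genes <- sprintf("g%d", 1:10)
  catalog <- tiny_catalog(genes, species = rep(c("Zeta sp", "Alpha sp"),
                                               each = 5))
  cag <- list(cag_id = "CAG_0001", members = genes, profile = NULL,
              label = NA, is_mgs = FALSE)
  expect_warning(out <- label_cag(cag, catalog), "tie")
  expect_identical(out$label, "Alpha sp")
})

test_that("the CAG partition equals brute force on small inputs", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed + 100)
    n <- 24
    latent <- matrix(rexp(4 * 10), 4, 10)
    m <- named_matrix(
      latent[sample(1:4, n, replace = TRUE), ] *
        matrix(exp(rnorm(n * 10, 0, 0.05)), n, 10))
    part <- cag_partition(
      merge_canopies(canopy_cluster(abundance_matrix(m, "counts"),
                                    capture_pcc = 0.9,
                                    seed_order_seed = seed),
                     abundance_matrix(m, "counts"), 0.97))
    oracle <- brute_cag_partition(m, 0.9, 0.97, seed)
    # same partition up to cluster relabelling
    expect_equal(mclust::adjustedRandIndex(part[rownames(m)],
                                           oracle[rownames(m)]), 1)
  }
})

test_that("significant-CAG screening collapses to retained-gene medians", {
  set.seed(55)
  n_a <- 5; n_b <- 8
  groups <- factor(rep(c("A", "B"), c(n_a, n_b)))
  # one planted CAG with a strong effect + background genes
  eff <- c(rep(1, n_a), rep(8, n_b))
  m <- rbind(
    t(vapply(1:10, function(i) eff * exp(rnorm(13, 0, 0.1)), numeric(13))),
    matrix(rexp(15 * 13), 15, 13))
  m <- named_matrix(m)
  gm <- abundance_matrix(m, "counts")
  cags <- list(list(cag_id = "CAG_0001", members = rownames(m)[1:10],
                    profile = NULL, label = "Sp", is_mgs = FALSE),
               list(cag_id = "CAG_0002", members = rownames(m)[11:25],
                    profile = NULL, label = "group", is_mgs = FALSE))
  res <- significant_cags(cags, gm, groups, alpha = 0.05,
                          lda_cutoff = 0, seed = 1)
  expect_true("CAG_0001" %in% res$cag_id)
  retained <- strsplit(res$retained_genes[res$cag_id == "CAG_0001"],
                       ";")[[1]]
  expect_true(all(retained %in% rownames(m)[1:10]))
  coll <- attr(res, "abundance")["CAG_0001", ]
  oracle <- apply(m[retained, , drop = FALSE], 2, median)
  expect_equal(coll, oracle)

  # identically distributed data yield an empty result
  m0 <- named_matrix(matrix(rexp(20 * 13), 20, 13))
  cags0 <- list(list(cag_id = "CAG_0001", members = rownames(m0)[1:10],
                     profile = NULL, label = "Sp", is_mgs = FALSE))
  res0 <- significant_cags(cags0, abundance_matrix(m0, "counts"), groups)
  expect_identical(nrow(res0), 0L)
  expect_error(significant_cags(cags0, abundance_matrix(m0, "counts"),
                                factor(rep(c("A", "B"), c(2, 11)))),
               "at least 3")
})

test_that("a planted 8-fold CAG is recovered significant with power", {
  hits <- 0L
  n_rep <- 30L
  for (s in seq_len(n_rep)) {
    set.seed(900 + s)
    groups <- factor(rep(c("A", "B"), c(5, 8)))
    eff <- c(rep(1, 5), rep(8, 8))
    m <- rbind(
      t(vapply(1:12, function(i) eff * exp(rnorm(13, 0, 0.3)),
               numeric(13))),
      # heavy uncorrelated background so the planted CAG stays a small
      # fraction of the community and TSS barely damps its fold change
      matrix(20 * rexp(10 * 13), 10, 13))
    m <- sweep(m, 2, colSums(m), "/")  # community relative abundances
    m <- named_matrix(m)
    cags <- list(list(cag_id = "CAG_0001", members = rownames(m)[1:12],
                      profile = NULL, label = "Sp", is_mgs = FALSE),
                 list(cag_id = "CAG_0002", members = rownames(m)[13:22],
                      profile = NULL, label = "group", is_mgs = FALSE))
    res <- significant_cags(cags, abundance_matrix(m, "relative"),
                            groups, alpha = 0.05, lda_cutoff = 2,
                            seed = s)
    if ("CAG_0001" %in% res$cag_id &&
        res$q_value[res$cag_id == "CAG_0001"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("cluster recovery degrades monotonically with gene noise", {
  ari_at <- function(cv) {
    p <- simulation_params(n_species = 8L, genes_per_species = c(10L, 10L),
                           gene_noise_cv = cv, occupancy = 1,
                           n_keystone = 2L)
    mean(vapply(1:3, function(s) {
      sim <- simulate_catalog(p, seed = s)
      ab <- simulate_abundance(sim$catalog, sim$truth, p, seed = s)
      cags <- merge_canopies(
        canopy_cluster(ab$relative, capture_pcc = 0.9,
                       seed_order_seed = s),
        ab$relative, 0.97)
      cl <- sim$truth$cluster_membership
      planted <- names(cl)[!is.na(cl)]
      part <- cag_partition(cags)
      mclust::adjustedRandIndex(cl[planted], part[planted])
    }, numeric(1)))
  }
  a05 <- ari_at(0.05); a2 <- ari_at(0.2); a5 <- ari_at(0.5)
  expect_gte(a05, 0.9)
  expect_gte(a05, a2 - 0.05)
  expect_gte(a2, a5 - 0.05)
})
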