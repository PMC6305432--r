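test_that("feature aggregation sums genes with full multiplicity", {
  m <- abundance_matrix(
    matrix(c(0.4, 0.3, 0.2, 0.1), 2, 2,
           dimnames = list(c("g1", "g2"), c("s1", "s2"))), "relative")
  catalog <- gene_catalog(data.frame(
    gene_id = c("g1", "g2"), length_bp = 400L, phylum = "P",
    family = "F", genus = "G", species = "G s",
    KO = c("K00001", ""), pathway = "",
    COG_category = "", EC = c("EC:1.1.1.1;EC:2.2.2.2", "EC:1.1.1.1"),
    CAZy = "", stringsAsFactors = FALSE))
  ko <- aggregate_features(m, catalog, "KO")
  expect_equal(unclass(ko)["K00001", ], c(s1 = 0.4, s2 = 0.2))
  ec <- aggregate_features(m, catalog, "EC")
  # g1 carries two ECs and contributes fully to both
  expect_equal(unclass(ec)["EC:2.2.2.2", ], c(s1 = 0.4, s2 = 0.2))
  expect_equal(unclass(ec)["EC:1.1.1.1", ], c(s1 = 0.7, s2 = 0.3))
  expect_error(aggregate_features(m, catalog, "opera"),
               "unknown annotation namespace")
})

test_that("feature sums equal a brute-force join on synthetic data", {
  sim <- small_sim(seed = 19)
  feat <- aggregate_features(sim$relative, sim$catalog, "pathway")
  ann <- strsplit(sim$catalog$pathway, ";")
  names(ann) <- sim$catalog$gene_id
  m <- unclass(sim$relative)
  for (f in rownames(feat)) {
    carriers <- names(ann)[vapply(ann, function(a) f %in% a, logical(1))]
    expect_equal(unclass(feat)[f, ],
                 colSums(m[carriers, , drop = FALSE]), tolerance = 1e-12)
  }
  # annotated mass conservation: sum over features = sum of gene
  # abundance times annotation multiplicity
  mult <- lengths(lapply(ann, function(a) a[nzchar(a)]))
  expect_equal(sum(unclass(feat)),
               sum(m * mult[rownames(m)]), tolerance = 1e-9)
})

test_that("Wilcoxon p-values match exhaustive enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  set.seed(23)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    repeat {
      v <- round(rnorm(n1 + n2), 4)
      if (!anyDuplicated(v)) break
    }
    a <- v[1:n1]; b <- v[-(1:n1)]
    expect_equal(wilcoxon_rank_sum(a, b, exact_threshold = 12),
                 enum_wilcox_p(a, b), tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty")
})

test_that("the large-sample Wilcoxon approximation tracks the exact p", {
  set.seed(29)
  for (i in 1:20) {
    repeat {
      v <- round(rnorm(12), 4)
      if (!anyDuplicated(v)) break
    }
    a <- v[1:6]; b <- v[7:12]
    p_exact <- enum_wilcox_p(a, b)
    p_approx <- wilcoxon_rank_sum(a, b, exact_threshold = 0)
    expect_lt(abs(p_approx - p_exact), 0.02)
  }
})

test_that("Holm adjustment equals the hand step-down recursion", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    adj <- holm_adjust(p)
    expect_equal(adj, holm_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
  }
  expect_error(holm_adjust(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("test_features screens a profile per contrast family", {
  set.seed(37)
  groups <- factor(rep(c("A", "B"), c(6, 7)))
  m <- rbind(shifted = c(rnorm(6, 0, 0.1), rnorm(7, 5, 0.1)),
             flat = rnorm(13))
  colnames(m) <- sprintf("s%02d", 1:13)
  res <- test_features(abundance_matrix(abs(m), "counts"), groups)
  expect_identical(res$feature_id, c("shifted", "flat"))
  expect_lt(res$adjusted_p[1], 0.05)
  expect_identical(res$direction[1], -1)
  expect_true(all(res$adjusted_p >= res$raw_p))
})

test_that("LDA effect size separates scale-split features and is
           insensitive to identical classes", {
  set.seed(41)
  classes <- factor(rep(c("A", "B"), each = 8))
  m <- rbind(marker = c(runif(8, 90, 110), runif(8, 9e5, 1.1e6)),
             noise1 = runif(16, 100, 200),
             noise2 = runif(16, 100, 200))
  colnames(m) <- sprintf("s%02d", 1:16)
  res <- lda_effect_size(m, classes, cutoff = 2, seed = 1)
  expect_true(res$passes[res$feature_id == "marker"])
  expect_lt(res$kw_p[1], 0.05)

  # identical class distributions fail the Kruskal-Wallis filter
  m0 <- matrix(rep(runif(16, 10, 20), 3), 3, 16, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), colnames(m)))
  res0 <- lda_effect_size(m0, classes, cutoff = 2, seed = 1)
  expect_true(all(is.na(res0$lda_score)))
  expect_true(all(!res0$passes))
  expect_error(lda_effect_size(m, factor(rep(c("A", "B"), c(2, 14)))),
               "at least 3")
})

test_that("doubling a feature shifts its LDA score by at most log10(2)", {
  set.seed(43)
  classes <- factor(rep(c("A", "B"), each = 8))
  m <- rbind(f1 = c(runif(8, 1, 2), runif(8, 10, 20)),
             f2 = runif(16, 5, 6))
  colnames(m) <- sprintf("s%02d", 1:16)
  s1 <- lda_effect_size(m, classes, seed = 7)$lda_score[1]
  m2 <- m; m2["f1", ] <- 2 * m["f1", ]
  s2 <- lda_effect_size(m2, classes, seed = 7)$lda_score[1]
  expect_lte(abs(s2) - abs(s1), log10(2) + 1e-9)
})

test_that("pathway hosts follow the dominant contributing genus", {
  m <- abundance_matrix(
    matrix(c(0.7, 0.6, 0.3, 0.2, 0.0, 0.1), 3, 2, byrow = TRUE,
           dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))),
    "relative")
  catalog <- tiny_catalog(c("g1", "g2", "g3"),
                          species = c("Escherichia coli",
                                      "Klebsiella pneumoniae",
                                      "Klebsiella pneumoniae"),
                          pathway = c("map00010", "map00010", "map00020"))
  res <- host_attribution(m, catalog, groups = c("C0", "C0"))
  row1 <- res[res$pathway_id == "map00010", ]
  expect_identical(row1$host_genus, "Escherichia")
  expect_equal(row1$host_share, 1.3 / 1.8, tolerance = 1e-12)
  row2 <- res[res$pathway_id == "map00020", ]
  expect_identical(row2$host_genus, "Klebsiella")
  expect_equal(row2$host_share, 1.0)
})

test_that("host attribution equals a brute-force join-group-argmax", {
  sim <- small_sim(seed = 23)
  groups <- sim$metadata$group[match(colnames(sim$relative),
                                     sim$metadata$sample_id)]
  res <- suppressWarnings(
    host_attribution(sim$relative, sim$catalog, groups))
  ann <- strsplit(sim$catalog$pathway, ";")
  names(ann) <- sim$catalog$gene_id
  m <- unclass(sim$relative)
  for (r in sample(nrow(res), 12)) {
    p <- res$pathway_id[r]; g <- res$group[r]
    carriers <- names(ann)[vapply(ann, function(a) p %in% a, logical(1))]
    genus <- sim$catalog$genus[match(carriers, sim$catalog$gene_id)]
    tot <- tapply(rowSums(m[carriers, groups == g, drop = FALSE]),
                  genus, sum)
    if (is.na(res$host_genus[r])) {
      expect_equal(sum(tot), 0)
    } else {
      expect_identical(res$host_genus[r],
                       sort(names(tot)[tot == max(tot)])[1])
      expect_equal(res$host_share[r], max(tot) / sum(tot),
                   tolerance = 1e-12)
    }
  }
})

test_that("the Wilcoxon test is calibrated and Holm controls the FWER", {
  set.seed(71)
  n_sim <- 1000
  rej <- vapply(seq_len(n_sim), function(i)
    wilcoxon_rank_sum(rnorm(5), rnorm(8)) < 0.05, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)

  n_fam <- 300
  fwer <- vapply(seq_len(n_fam), function(i) {
    p <- vapply(1:100, function(j)
      wilcoxon_rank_sum(rnorm(5), rnorm(8)), numeric(1))
    any(holm_adjust(p) < 0.05)
  }, logical(1))
  expect_lte(mean(fwer), 0.07)
})
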