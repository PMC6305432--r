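#' Parameters of the synthetic-data generator
#'
#' The generator emulates the statistical structure the downstream
#' analysis assumes: a gene catalog in which blocks of genes from one
#' species share a latent per-sample abundance trajectory (the
#' co-abundance signal that canopy clustering exploits), group-dependent
#' shifts of taxon abundance along a cub-to-adult succession gradient,
#' sparse structural zeros, and functional annotations drawn from a small
#' fixed vocabulary.
#'
#' @param n_samples_per_group Named integer vector of samples per age
#'   group; the default mirrors the modelled sampling design: 22 cub
#'   samples split into C0/C1/C2 age windows plus 5 father and 6 mother
#'   samples (33 in total).
#' @param n_species Number of planted species (default 60); each species
#'   is one co-abundance cluster and, by construction, one genus. The
#'   default keeps the genus universe large enough for the over-30-
#'   connections hub rule to be attainable.
#' @param genes_per_species Integer range (length-2) of genes per planted
#'   species (default 15 to 40, so that most clusters exceed the 20-gene
#'   MGS threshold).
#' @param gene_noise_cv Coefficient of variation of the per-gene,
#'   per-sample multiplicative lognormal noise around the species
#'   trajectory (default 0.1). At 0 the genes of one species are exactly
#'   proportional across samples.
#' @param trajectory_cv Coefficient of variation of the per-species,
#'   per-sample lognormal noise on the latent trajectory (default 0.3).
#' @param occupancy Baseline per-taxon, per-sample presence probability
#'   (default 0.95); see Details.
#' @param depth Per-sample total count scale used when rendering counts
#'   (default 5e6).
#' @param background_fraction Fraction of catalog genes that carry
#'   uncorrelated noise profiles instead of belonging to a planted
#'   cluster (default 0.2).
#' @param annotation_fraction Fraction of genes carrying functional
#'   annotations (default 0.6).
#' @param n_keystone Number of planted keystone genera (default 5): block
#'   species given the strongest succession loading, a fold change of at
#'   least 4 between the extreme age groups.
#' @param block_fraction Fraction of species belonging to the correlated
#'   succession block (default 0.7); block species load on a shared
#'   group-level gradient and are therefore mutually correlated, which is
#'   what makes hub genera detectable.
#' @param base_abundance_sdlog Lognormal spread of species base
#'   abundances (default 1).
#' @return A list of class `simulation_params`.
#' @details Structural zeros are drawn once per taxon and sample via a
#'   detection-limit model: a species is absent from a sample when its
#'   latent trajectory falls below a fixed censoring threshold,
#'   calibrated so that a species with no group effect is present with
#'   probability `occupancy`. Taxa shifted down in a group therefore
#'   drop out more often there, so presence/absence carries the same
#'   succession signal as abundance. With `occupancy = 1` no zeros are
#'   generated.
#' @export
simulation_params <- function(n_samples_per_group = c(C0 = 5L, C1 = 9L,
                                                      C2 = 8L, F = 5L,
                                                      M = 6L),
                              n_species = 60L,
                              genes_per_species = c(15L, 40L),
                              gene_noise_cv = 0.1,
                              trajectory_cv = 0.3,
                              occupancy = 0.95,
                              depth = 5e6,
                              background_fraction = 0.2,
                              annotation_fraction = 0.6,
                              n_keystone = 5L,
                              block_fraction = 0.7,
                              base_abundance_sdlog = 1) {
  stopifnot(all(n_samples_per_group > 0),
            setequal(names(n_samples_per_group), GROUP_LEVELS),
            n_species >= 1, length(genes_per_species) == 2,
            gene_noise_cv >= 0, trajectory_cv >= 0,
            occupancy > 0, occupancy <= 1,
            background_fraction >= 0, background_fraction < 1,
            annotation_fraction >= 0, annotation_fraction <= 1,
            n_keystone <= n_species * block_fraction)
  p <- as.list(environment())
  p$n_samples_per_group <-
    as.integer(n_samples_per_group[GROUP_LEVELS])
  names(p$n_samples_per_group) <- GROUP_LEVELS
  class(p) <- "simulation_params"
  p
}

# Succession gradient: group-level scores of the latent cub-to-adult
# trajectory that block species load on. C2 (oldest cubs) and C0
# (youngest) are the extremes; parents sit between.
GROUP_SCORES <- c(C0 = -1, C1 = -0.4, C2 = 1, F = 0, M = 0)

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Simulate a gene catalog with planted co-abundance structure
#'
#' Each planted species contributes a contiguous block of genes sharing
#' its lineage; the remaining (background) genes are unclassified.
#' Species are split into a correlated succession block — whose members
#' load on the shared cub-to-adult gradient with species-specific
#' strength, the `n_keystone` strongest being the planted keystones — and
#' independent species with no group effect.
#'
#' @param params A [simulation_params()] list.
#' @param seed Integer seed; fixed seed gives a byte-identical catalog.
#' @return A list with elements `catalog` (a [gene_catalog()]) and
#'   `truth` (a `synthetic_truth` list holding `cluster_membership`,
#'   `cluster_species`, `group_effects` (species x group fold-change
#'   matrix), `keystone_genera`, and `seed`).
#' @export
simulate_catalog <- function(params = simulation_params(), seed = 1L) {
  set.seed(seed)
  ns <- params$n_species
  sp_idx <- seq_len(ns)
  genus <- sprintf("Genus_%02d", sp_idx)
  species <- sprintf("Genus_%02d species_%02d", sp_idx, sp_idx)
  family <- sprintf("Family_%02d", ((sp_idx - 1) %/% 4) + 1)
  phyla <- c("Proteobacteria", "Firmicutes", "Bacteroidetes",
             "Actinobacteria")
  phylum <- phyla[((sp_idx - 1) %% 4) + 1]

  # succession loadings: keystones strongest, then block, then zero
  n_block <- max(round(params$block_fraction * ns), params$n_keystone)
  block <- sort(sample.int(ns, n_block))
  keystone <- sort(sample(block, params$n_keystone))
  lambda <- numeric(ns)
  lambda[block] <- runif(n_block, 0.3, 0.5) *
    sample(c(-1, 1), n_block, replace = TRUE)
  lambda[keystone] <- 0.8
  group_effects <- exp(outer(lambda, GROUP_SCORES))
  dimnames(group_effects) <- list(genus, GROUP_LEVELS)

  rng <- params$genes_per_species
  n_genes_sp <- if (rng[1] == rng[2]) rep(as.integer(rng[1]), ns)
                else sample(rng[1]:rng[2], ns, replace = TRUE)
  n_planted <- sum(n_genes_sp)
  n_bg <- round(n_planted * params$background_fraction /
                  (1 - params$background_fraction))

  sp_of_gene <- rep(sp_idx, n_genes_sp)
  gene_id <- c(sprintf("gene_%05d", seq_len(n_planted + n_bg)))
  df <- data.frame(
    gene_id = gene_id,
    length_bp = sample(200:3000, n_planted + n_bg, replace = TRUE),
    phylum = c(phylum[sp_of_gene], rep("Unclassified", n_bg)),
    family = c(family[sp_of_gene], rep("Unclassified", n_bg)),
    genus = c(genus[sp_of_gene], rep("Unclassified", n_bg)),
    species = c(species[sp_of_gene], rep("Unclassified", n_bg)),
    stringsAsFactors = FALSE)

  # functional annotations from a small fixed vocabulary; each species
  # favours a 3-pathway repertoire so host attribution has signal
  vocab <- list(KO = sprintf("K%05d", 1:40),
                pathway = sprintf("map%05d", c(10, 20, 30, 40, 51, 61,
                                               71, 190, 230, 240)),
                COG_category = strsplit("CEGJKLMOPT", "")[[1]],
                EC = sprintf("EC:%d.%d.%d.%d", sample(1:6, 30, TRUE),
                             sample(1:9, 30, TRUE), sample(1:9, 30, TRUE),
                             sample(1:99, 30, TRUE)),
                CAZy = c("GH5", "GH9", "GH10", "GH43", "GT2", "GT4",
                         "CE1", "PL1"))
  pw_repertoire <- lapply(sp_idx, function(i)
    sample(vocab$pathway, 3))
  annotated <- runif(nrow(df)) < params$annotation_fraction
  pick <- function(v, n) sample(v, n, replace = TRUE)
  n_all <- nrow(df)
  df$KO <- ifelse(annotated, pick(vocab$KO, n_all), "")
  df$pathway <- vapply(seq_len(n_all), function(j) {
    if (!annotated[j]) return("")
    if (j <= n_planted) sample(pw_repertoire[[sp_of_gene[j]]], 1)
    else sample(vocab$pathway, 1)
  }, character(1))
  df$COG_category <- ifelse(annotated, pick(vocab$COG_category, n_all), "")
  df$EC <- ifelse(annotated & runif(n_all) < 0.5, pick(vocab$EC, n_all), "")
  df$CAZy <- ifelse(annotated & runif(n_all) < 0.3, pick(vocab$CAZy, n_all),
                    "")

  cluster_id <- c(sprintf("PC%02d", sp_of_gene), rep(NA_character_, n_bg))
  names(cluster_id) <- gene_id
  cluster_species <- species
  names(cluster_species) <- sprintf("PC%02d", sp_idx)

  truth <- structure(list(cluster_membership = cluster_id,
                          cluster_species = cluster_species,
                          group_effects = group_effects,
                          keystone_genera = genus[keystone],
                          block_genera = genus[block],
                          seed = seed),
                     class = "synthetic_truth")
  list(catalog = gene_catalog(df), truth = truth)
}

#' Simulate gene abundances and sample metadata
#'
#' Renders the planted structure into a genes x samples matrix: each
#' cluster gene equals the species' latent per-sample trajectory times a
#' fixed per-gene size factor times per-gene lognormal noise with
#' coefficient of variation `gene_noise_cv`; latent trajectories encode
#' the group fold changes; background genes are independent lognormal
#' noise; zeros are structural, drawn once per taxon and sample.
#'
#' @param catalog,truth Output of [simulate_catalog()].
#' @param params The same [simulation_params()].
#' @param seed Integer seed.
#' @return A list with `relative` (an [abundance_matrix()], columns sum
#'   to 1), `counts` (rounded to `depth` reads per sample), and
#'   `metadata` (a [sample_metadata()]).
#' @export
simulate_abundance <- function(catalog, truth,
                               params = simulation_params(), seed = 1L) {
  set.seed(seed + 1000L)
  npg <- params$n_samples_per_group
  groups <- rep(GROUP_LEVELS, npg)
  sample_id <- unlist(lapply(GROUP_LEVELS, function(g)
    sprintf("%s_%02d", g, seq_len(npg[[g]]))))
  individual <- c(rep(c("P3", "P4"), length.out = sum(npg[1:3])),
                  rep("P1", npg[["F"]]), rep("P2", npg[["M"]]))
  meta <- sample_metadata(data.frame(
    sample_id = sample_id, individual = individual, group = groups,
    collection_index = seq_along(sample_id), stringsAsFactors = FALSE))

  n_samp <- length(sample_id)
  cl <- truth$cluster_membership[catalog$gene_id]
  planted <- !is.na(cl)
  sp_names <- rownames(truth$group_effects)
  sp_of_gene <- match(catalog$genus[planted], sp_names)
  ns <- length(sp_names)

  log_base <- rnorm(ns, 0, params$base_abundance_sdlog)
  # keystones are planted as abundant core members (upper half of the
  # base-abundance distribution), as dominant succession genera are in
  # real gut communities; their 4-fold swings stay above detection
  ks <- sp_names %in% truth$keystone_genera
  log_base[ks] <- abs(log_base[ks]) + 0.3
  base <- exp(log_base)
  fold <- truth$group_effects[, groups, drop = FALSE]  # species x samples
  sd_traj <- cv_to_sdlog(params$trajectory_cv)
  traj_z <- matrix(rnorm(ns * n_samp, 0, sd_traj), ns, n_samp)
  latent <- base * fold * exp(traj_z)
  # structural zeros by left-censoring the latent log abundance at a
  # global detection limit calibrated so the community-wide presence
  # probability equals `occupancy`; rare taxa blink out, dominant taxa
  # never do, and group fold changes shift taxa across the limit
  if (params$occupancy < 1) {
    sd_tot <- sqrt(params$base_abundance_sdlog^2 + sd_traj^2)
    present <- if (sd_tot > 0) {
      detection <- sd_tot * stats::qnorm(1 - params$occupancy)
      log_base + log(fold) + traj_z >= detection
    } else {
      matrix(runif(ns * n_samp) < params$occupancy, ns, n_samp)
    }
    latent <- latent * present
  }

  n_genes <- nrow(catalog)
  vals <- matrix(0, n_genes, n_samp,
                 dimnames = list(catalog$gene_id, sample_id))
  size <- exp(rnorm(n_genes, 0, 0.5))
  sd_gene <- cv_to_sdlog(params$gene_noise_cv)
  gnoise <- if (sd_gene > 0)
    matrix(exp(rnorm(sum(planted) * n_samp, 0, sd_gene)),
           sum(planted), n_samp)
  else 1
  vals[planted, ] <- latent[sp_of_gene, , drop = FALSE] *
    size[planted] * gnoise

  n_bg <- sum(!planted)
  if (n_bg > 0) {
    bg_present <- matrix(runif(n_bg * n_samp) < params$occupancy,
                         n_bg, n_samp)
    vals[!planted, ] <- size[!planted] *
      matrix(exp(rnorm(n_bg * n_samp, 0, 1)), n_bg, n_samp) * bg_present
  }

  cs <- colSums(vals)
  if (any(cs == 0)) cs[cs == 0] <- 1
  rel <- sweep(vals, 2, cs, "/")
  counts <- round(rel * params$depth)
  list(relative = abundance_matrix(rel, "relative"),
       counts = abundance_matrix(counts, "counts"),
       metadata = meta)
}

#' Write ground-truth tables for a synthetic dataset
#'
#' Dumps the planted truth losslessly as three TSVs under `outdir`:
#' `membership.tsv` (one row per planted gene), `effects.tsv` (one row
#' per species x group fold change), `keystones.tsv`.
#'
#' @param truth A `synthetic_truth` from [simulate_catalog()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
truth_report <- function(truth, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cl <- truth$cluster_membership
  mem <- data.frame(gene_id = names(cl)[!is.na(cl)],
                    cluster_id = cl[!is.na(cl)],
                    species = truth$cluster_species[cl[!is.na(cl)]],
                    stringsAsFactors = FALSE)
  write.table(mem, file.path(outdir, "membership.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ge <- truth$group_effects
  eff <- data.frame(genus = rep(rownames(ge), ncol(ge)),
                    group = rep(colnames(ge), each = nrow(ge)),
                    fold = as.vector(ge), stringsAsFactors = FALSE)
  write.table(eff, file.path(outdir, "effects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ks <- data.frame(genus = truth$keystone_genera, stringsAsFactors = FALSE)
  write.table(ks, file.path(outdir, "keystones.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Read ground-truth tables back
#' @param outdir Directory written by [truth_report()].
#' @return A list with `membership`, `effects`, `keystones` data frames.
#' @export
read_truth <- function(outdir) {
  list(membership = read.delim(file.path(outdir, "membership.tsv"),
                               colClasses = "character"),
       effects = read.delim(file.path(outdir, "effects.tsv")),
       keystones = read.delim(file.path(outdir, "keystones.tsv"),
                              colClasses = "character"))
}
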