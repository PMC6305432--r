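#' Build a two-class contrast factor from metadata
#'
#' @param meta A [sample_metadata()].
#' @param a,b Character vectors of group labels pooled into the first
#'   and second class (e.g. `a = c("C0", "C1")`, `b = "C2"`).
#' @param sample_ids Samples to label, in matrix column order (default:
#'   all metadata samples).
#' @return Named factor with levels `A` and `B`; samples outside the
#'   contrast are `NA`.
#' @export
contrast_factor <- function(meta, a, b, sample_ids = meta$sample_id) {
  grp <- meta$group[match(sample_ids, meta$sample_id)]
  f <- ifelse(grp %in% a, "A", ifelse(grp %in% b, "B", NA))
  factor(f, levels = c("A", "B"), labels = c(paste(a, collapse = "+"),
                                             paste(b, collapse = "+")))
}

# the pairwise contrasts narrated by the study design
default_contrasts <- function() {
  list(C0_vs_C1 = list(a = "C0", b = "C1"),
       C1_vs_C2 = list(a = "C1", b = "C2"),
       C2_vs_FM = list(a = "C2", b = c("F", "M")),
       C0_vs_FM = list(a = "C0", b = c("F", "M")),
       F_vs_M = list(a = "F", b = "M"))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on a synthetic dataset
#'
#' Generates a synthetic dataset, then executes every downstream stage
#' — taxonomic profiling, alpha diversity, Whittaker ordination with
#' PERMANOVA, CAG/MGS construction with significance screening,
#' functional differential testing with host attribution, and keystone
#' discovery — writing each stage's tables under `outdir` together with
#' the effective configuration.
#'
#' @param outdir Output directory (created if needed).
#' @param params A [simulation_params()].
#' @param config An [analysis_config()].
#' @param seed Integer master seed for every stochastic stage.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_all <- function(outdir, params = simulation_params(),
                    config = analysis_config(), seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(outdir, "config.json"))

  sim <- simulate_catalog(params, seed = seed)
  ab <- simulate_abundance(sim$catalog, sim$truth, params, seed = seed)
  write_catalog(sim$catalog, file.path(outdir, "catalog.tsv"))
  write_abundance_matrix(ab$relative, file.path(outdir, "abundance.tsv"))
  write_metadata(ab$metadata, file.path(outdir, "metadata.tsv"))
  truth_report(sim$truth, file.path(outdir, "truth"))

  chk <- validate_inputs(ab$relative, sim$catalog, ab$metadata)
  if (!chk$ok)
    stop("inconsistent inputs: ", length(chk$orphan_genes),
         " orphan genes, ", length(chk$orphan_samples),
         " orphan samples")

  # taxonomic profiles + alpha diversity
  profiles <- list()
  for (rk in c("species", "genus", "family", "phylum")) {
    prof <- aggregate_taxa(ab$relative, sim$catalog, rk)
    prof <- filter_low_abundance(prof, config$abundance_floor)
    profiles[[rk]] <- prof
    write_abundance_matrix(prof, file.path(outdir,
                                           paste0("profile_", rk, ".tsv")))
  }
  counts_species <- aggregate_taxa(ab$counts, sim$catalog, "species")
  div <- diversity_table(counts_species)
  write_tsv(div, file.path(outdir, "diversity.tsv"))

  # ordination + PERMANOVA on the Whittaker matrix
  dmat <- whittaker_distance(profiles$species,
                             floor = config$abundance_floor,
                             weighted = config$whittaker_weighted)
  ord <- pcoa(dmat)
  groups <- ab$metadata$group[match(colnames(ab$relative),
                                    ab$metadata$sample_id)]
  perm <- permanova(dmat, groups,
                    n_permutations = config$n_permutations,
                    seed = seed)
  write_tsv(data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates[, seq_len(min(4,
                         ncol(ord$coordinates))), drop = FALSE]),
            file.path(outdir, "pcoa.tsv"))
  jsonlite::write_json(perm, file.path(outdir, "permanova.json"),
                       auto_unbox = TRUE, digits = NA)

  # CAG construction and significance screening (C0+C1 vs C2)
  cags <- build_cags(ab$relative, sim$catalog, config, seed = seed)
  write_tsv(cag_table(cags), file.path(outdir, "cags.tsv"))
  contrast <- contrast_factor(ab$metadata, c("C0", "C1"), "C2",
                              colnames(ab$relative))
  in_contrast <- !is.na(contrast)
  sig <- significant_cags(cags,
                          abundance_matrix(
                            unclass(ab$relative)[, in_contrast,
                                                 drop = FALSE],
                            "relative"),
                          droplevels(contrast[in_contrast]),
                          alpha = config$alpha,
                          lda_cutoff = config$lda_cutoff_species,
                          seed = seed)
  write_tsv(sig, file.path(outdir, "significant_cags.tsv"))

  # functional differential testing + host attribution
  tests <- list()
  for (ns in c("pathway", "COG_category")) {
    feat <- aggregate_features(ab$relative, sim$catalog, ns)
    for (cn in names(default_contrasts())) {
      ct <- default_contrasts()[[cn]]
      f <- contrast_factor(ab$metadata, ct$a, ct$b, colnames(feat))
      ok <- !is.na(f)
      res <- test_features(
        abundance_matrix(unclass(feat)[, ok, drop = FALSE], "counts"),
        droplevels(f[ok]))
      res$namespace <- ns
      res$contrast <- cn
      tests[[paste(ns, cn)]] <- res
    }
  }
  write_tsv(do.call(rbind, tests), file.path(outdir, "tests.tsv"))

  feat_pw <- aggregate_features(ab$relative, sim$catalog, "pathway")
  f <- contrast_factor(ab$metadata, c("C0", "C1"), "C2",
                       colnames(feat_pw))
  ok <- !is.na(f)
  lda <- lda_effect_size(unclass(feat_pw)[, ok, drop = FALSE],
                         droplevels(f[ok]),
                         cutoff = config$lda_cutoff_species,
                         seed = seed, n_boot = config$lda_n_boot)
  write_tsv(lda, file.path(outdir, "lda.tsv"))
  hosts <- host_attribution(ab$relative, sim$catalog, groups)
  write_tsv(hosts, file.path(outdir, "hosts.tsv"))

  # keystone discovery
  stable <- occurrence_filter(profiles$genus,
                              min_freq = config$occurrence_min_freq,
                              floor = config$abundance_floor)
  stable_prof <- unclass(profiles$genus)[stable, , drop = FALSE]
  net <- correlation_network(stable_prof, alpha = config$alpha)
  write_tsv(net, file.path(outdir, "network_edges.tsv"))
  hubs <- hub_genera(net, min_degree = config$hub_min_degree)
  rf <- rf_importance(stable_prof, groups,
                      n_trees = config$rf_n_trees, seed = seed)
  jsonlite::write_json(list(oob_error = rf$oob_error,
                            n_trees = rf$n_trees, seed = rf$seed),
                       file.path(outdir, "rf_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  important <- intersect_important(hubs, rf$top)
  write_tsv(data.frame(
    genus = unique(c(important$shared,
                     setdiff(important$hub_genera, important$shared),
                     setdiff(important$rf_top, important$shared))),
    stringsAsFactors = FALSE) |> (\(d) {
      d$is_hub <- d$genus %in% important$hub_genera
      d$is_rf_top <- d$genus %in% important$rf_top
      d$shared <- d$genus %in% important$shared
      d
    })(), file.path(outdir, "important_genera.tsv"))

  invisible(list(catalog = sim$catalog, truth = sim$truth,
                 abundance = ab, profiles = profiles, diversity = div,
                 distance = dmat, ordination = ord, permanova = perm,
                 cags = cags, significant_cags = sig,
                 lda = lda, hosts = hosts, network = net,
                 stable_genera = stable, important = important,
                 rf = rf))
}
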