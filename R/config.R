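#' Analysis configuration
#'
#' Collects every tunable constant of the pipeline in one place. Defaults
#' follow the study design this pipeline models: a 1e-8 relative-abundance
#' floor for taxon filtering and presence calls, canopy capture at
#' PCC 0.90 and canopy merging at PCC 0.97, metagenomic species (MGS)
#' called for CAGs with more than 20 genes, the 'group' label when fewer
#' than 50% of a CAG's genes share a modal species, LDA effect-size
#' cutoffs of 2.0 (species-level CAGs) and 4.0 (family level), a 70%
#' occurrence frequency defining stable genera, hub genera at over 30
#' significant network connections, and a 500-tree random forest.
#'
#' @param abundance_floor Relative abundances strictly below this are
#'   treated as absent (default `1e-8`).
#' @param canopy_capture_pcc Pearson correlation for a gene to join a
#'   canopy (default 0.90).
#' @param canopy_merge_pcc Pearson correlation of canopy median profiles
#'   above which canopies merge into one CAG (default 0.97).
#' @param mgs_min_genes Minimum gene count for a CAG to be called an MGS
#'   (default 21, i.e. strictly more than 20 genes).
#' @param group_label_majority Modal-species fraction below which a CAG is
#'   labelled `'group'` (default 0.50).
#' @param lda_cutoff_species,lda_cutoff_family LDA effect-size cutoffs on
#'   the log10 scale (defaults 2.0 and 4.0).
#' @param occurrence_min_freq Occurrence frequency above which a genus is
#'   "stable" (default 0.70).
#' @param hub_min_degree Minimum network degree for a hub genus
#'   (default 31, i.e. over 30 connections).
#' @param rf_n_trees Trees in the random forest (default 500).
#' @param rf_seed Seed for the random forest.
#' @param alpha Significance level (default 0.05).
#' @param n_permutations Permutations for PERMANOVA (default 999).
#' @param max_zero_fraction Genes absent in more than this fraction of
#'   samples are excluded from canopy clustering (default 0.90).
#' @param whittaker_weighted If `TRUE`, [whittaker_distance()] uses the
#'   abundance-weighted variant instead of presence/absence.
#' @param lda_n_boot Bootstrap resamples for the LDA effect size
#'   (default 30).
#' @param rarefaction_resamples Resamples per rarefaction depth
#'   (default 10).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(abundance_floor = 1e-8,
                            canopy_capture_pcc = 0.90,
                            canopy_merge_pcc = 0.97,
                            mgs_min_genes = 21L,
                            group_label_majority = 0.50,
                            lda_cutoff_species = 2.0,
                            lda_cutoff_family = 4.0,
                            occurrence_min_freq = 0.70,
                            hub_min_degree = 31L,
                            rf_n_trees = 500L,
                            rf_seed = 1L,
                            alpha = 0.05,
                            n_permutations = 999L,
                            max_zero_fraction = 0.90,
                            whittaker_weighted = FALSE,
                            lda_n_boot = 30L,
                            rarefaction_resamples = 10L) {
  cfg <- list(abundance_floor = abundance_floor,
              canopy_capture_pcc = canopy_capture_pcc,
              canopy_merge_pcc = canopy_merge_pcc,
              mgs_min_genes = as.integer(mgs_min_genes),
              group_label_majority = group_label_majority,
              lda_cutoff_species = lda_cutoff_species,
              lda_cutoff_family = lda_cutoff_family,
              occurrence_min_freq = occurrence_min_freq,
              hub_min_degree = as.integer(hub_min_degree),
              rf_n_trees = as.integer(rf_n_trees),
              rf_seed = as.integer(rf_seed),
              alpha = alpha,
              n_permutations = as.integer(n_permutations),
              max_zero_fraction = max_zero_fraction,
              whittaker_weighted = isTRUE(whittaker_weighted),
              lda_n_boot = as.integer(lda_n_boot),
              rarefaction_resamples = as.integer(rarefaction_resamples))
  stopifnot(cfg$canopy_capture_pcc > 0, cfg$canopy_capture_pcc < 1,
            cfg$canopy_merge_pcc > 0, cfg$canopy_merge_pcc < 1,
            cfg$occurrence_min_freq > 0, cfg$occurrence_min_freq <= 1,
            cfg$alpha > 0, cfg$alpha < 1)
  class(cfg) <- "analysis_config"
  cfg
}

#' Write an analysis configuration as JSON
#' @param config An [analysis_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an analysis configuration from JSON
#' @param path JSON file written by [write_config()].
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  do.call(analysis_config, jsonlite::read_json(path, simplifyVector = TRUE))
}
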