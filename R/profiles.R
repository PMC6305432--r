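#' Aggregate a gene matrix to a taxonomic rank
#'
#' Taxon abundance is the sum of assigned gene abundances per sample;
#' genes unclassified at the requested rank are pooled into a single
#' `"Unclassified"` row, so aggregation conserves column mass.
#'
#' @param gene_matrix An [abundance_matrix()] of genes x samples.
#' @param catalog A [gene_catalog()] covering every matrix gene.
#' @param rank One of `"species"`, `"genus"`, `"family"`, `"phylum"`.
#' @return A `taxon_profile`: an [abundance_matrix()] of taxa x samples
#'   with a `rank` attribute, same units as the input.
#' @export
aggregate_taxa <- function(gene_matrix, catalog,
                           rank = c("species", "genus", "family",
                                    "phylum")) {
  rank <- match.arg(rank)
  idx <- match(rownames(gene_matrix), catalog$gene_id)
  if (anyNA(idx))
    stop("genes absent from catalog: ",
         paste(utils::head(rownames(gene_matrix)[is.na(idx)], 5),
               collapse = ", "))
  taxon <- catalog[[rank]][idx]
  agg <- rowsum(unclass(gene_matrix), group = taxon)
  prof <- abundance_matrix(agg, abundance_units(gene_matrix))
  attr(prof, "rank") <- rank
  class(prof) <- c("taxon_profile", class(prof))
  prof
}

#' Remove taxa of uniformly negligible relative abundance
#'
#' A taxon is dropped only when its relative abundance is strictly below
#' `floor` in every sample; a taxon at or above the floor in at least one
#' sample is kept in all samples.
#'
#' @param profile A relative-abundance `taxon_profile`.
#' @param floor Relative-abundance floor (default `1e-8`).
#' @return The filtered profile.
#' @export
filter_low_abundance <- function(profile, floor = 1e-8) {
  if (abundance_units(profile) != "relative")
    stop("filter_low_abundance requires relative abundances")
  keep <- apply(unclass(profile) >= floor, 1L, any)
  out <- unclass(profile)[keep, , drop = FALSE]
  prof <- abundance_matrix(out, "relative")
  attr(prof, "rank") <- attr(profile, "rank")
  class(prof) <- c("taxon_profile", class(prof))
  prof
}
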