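#' @importFrom utils read.delim write.table
NULL

CATALOG_RANKS <- c("phylum", "family", "genus", "species")
ANNOTATION_NAMESPACES <- c("KO", "pathway", "COG_category", "EC", "CAZy")

#' Construct a gene catalog
#'
#' A gene catalog is the non-redundant set of predicted genes that all
#' downstream stages share. Each gene carries a taxonomic lineage
#' (phylum, family, genus, species; any rank may be `"Unclassified"`) and
#' functional annotations in up to five namespaces (KO, pathway,
#' COG_category, EC, CAZy; multiple features separated by `;`).
#'
#' @param df A data frame with columns `gene_id`, `length_bp`, the four
#'   lineage ranks, and one character column per annotation namespace.
#' @return The validated data frame with class `gene_catalog`.
#' @details Lineages must be prefix-consistent: a gene classified at
#'   species level must also be classified at genus level.
#' @export
gene_catalog <- function(df) {
  needed <- c("gene_id", "length_bp", CATALOG_RANKS)
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("catalog missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  for (ns in ANNOTATION_NAMESPACES)
    if (!ns %in% names(df)) df[[ns]] <- ""
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in catalog: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  if (any(df$length_bp < 1) || any(df$length_bp != round(df$length_bp)))
    stop("length_bp must be a positive integer")
  for (rk in CATALOG_RANKS)
    df[[rk]][is.na(df[[rk]]) | df[[rk]] == ""] <- "Unclassified"
  bad <- df$species != "Unclassified" & df$genus == "Unclassified"
  if (any(bad))
    stop("lineage not prefix-consistent (species without genus) for: ",
         paste(df$gene_id[bad], collapse = ", "))
  df <- df[c(needed, ANNOTATION_NAMESPACES)]
  rownames(df) <- NULL
  class(df) <- c("gene_catalog", "data.frame")
  df
}

#' Read a gene catalog from TSV
#'
#' @param path TSV with columns `gene_id`, `length_bp`, `phylum`,
#'   `family`, `genus`, `species`, plus one column per annotation
#'   namespace (semicolon-separated multi-values, empty = unannotated).
#' @return A [gene_catalog()].
#' @export
read_catalog <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   colClasses = "character", check.names = FALSE)
  if ("length_bp" %in% names(df)) df$length_bp <- as.numeric(df$length_bp)
  gene_catalog(df)
}

#' Write a gene catalog to TSV
#' @param catalog A [gene_catalog()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_catalog"))
  write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotation features of catalog genes in one namespace
#'
#' @param catalog A [gene_catalog()].
#' @param namespace One of `KO`, `pathway`, `COG_category`, `EC`, `CAZy`.
#' @return Named list mapping gene_id to a character vector of feature ids
#'   (length 0 for unannotated genes).
#' @export
catalog_annotations <- function(catalog, namespace) {
  if (!namespace %in% ANNOTATION_NAMESPACES)
    stop("unknown annotation namespace: ", namespace)
  ann <- strsplit(catalog[[namespace]], ";", fixed = TRUE)
  ann <- lapply(ann, function(a) a[nzchar(a)])
  names(ann) <- catalog$gene_id
  ann
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id`, `individual`, `group`
#'   (one of C0, C1, C2, F, M), `collection_index`.
#' @return Data frame of class `sample_metadata`.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   colClasses = "character", check.names = FALSE)
  df$collection_index <- as.integer(df$collection_index)
  sample_metadata(df)
}

#' Construct sample metadata
#'
#' @param df Data frame with columns `sample_id`, `individual`, `group`,
#'   `collection_index`. Groups follow the study design: C0 (0-1.5 mo
#'   cubs), C1 (1.5-6 mo), C2 (6-9 mo), F (father), M (mother).
#' @return The validated data frame with class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  needed <- c("sample_id", "individual", "group", "collection_index")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  bad <- !df$group %in% GROUP_LEVELS
  if (any(bad))
    stop("unknown group label(s): ", paste(unique(df$group[bad]),
                                           collapse = ", "))
  df <- df[needed]
  rownames(df) <- NULL
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Write sample metadata to TSV
#' @param meta A [sample_metadata()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Age-group levels of the study design
#' @export
GROUP_LEVELS <- c("C0", "C1", "C2", "F", "M")

#' Cross-check a gene matrix, catalog and metadata for consistency
#'
#' Reports genes present in the matrix but absent from the catalog, and
#' samples present in the matrix but absent from the metadata. The
#' pipeline refuses to run on a non-empty error list.
#'
#' @param matrix An [abundance_matrix()] of genes x samples.
#' @param catalog A [gene_catalog()].
#' @param meta A [sample_metadata()].
#' @return A list with elements `orphan_genes`, `orphan_samples`, `ok`.
#' @export
validate_inputs <- function(matrix, catalog, meta) {
  orphan_genes <- setdiff(rownames(matrix), catalog$gene_id)
  orphan_samples <- setdiff(colnames(matrix), meta$sample_id)
  list(orphan_genes = orphan_genes,
       orphan_samples = orphan_samples,
       ok = length(orphan_genes) == 0L && length(orphan_samples) == 0L)
}
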