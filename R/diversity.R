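#' Shannon-Wiener diversity of one sample
#'
#' `H = -sum(p_i * ln(p_i))` over the positive proportions `p_i`
#' (natural log; zeros contribute nothing). Raw counts are converted to
#' proportions first, so either units are accepted.
#'
#' @param column Non-negative abundance vector with at least one positive
#'   entry.
#' @return `H >= 0`.
#' @export
shannon_index <- function(column) {
  if (any(column < 0) || anyNA(column)) stop("abundances must be >= 0")
  if (all(column == 0)) stop("all-zero sample: Shannon undefined")
  p <- column[column > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Pielou evenness of one sample
#'
#' `J = H / ln(S)` with `S` the number of taxa present. `J` is 1 for a
#' perfectly even community and undefined (`NA`) when only one taxon is
#' present.
#'
#' @inheritParams shannon_index
#' @return `J` in `[0, 1]`, or `NA` when `S = 1`.
#' @export
pielou_evenness <- function(column) {
  s <- sum(column > 0)
  h <- shannon_index(column)
  if (s < 2) return(NA_real_)
  h / log(s)
}

#' Bias-corrected Chao1 richness of one sample
#'
#' `S_obs + F1*(F1-1) / (2*(F2+1))`, with `F1`/`F2` the singleton and
#' doubleton counts. Equals observed richness when there are no
#' singletons. This is the bias-corrected form, the one
#' [vegan::estimateR()] reports as `S.chao1`.
#'
#' @param counts Non-negative integer count vector.
#' @return Chao1 estimate, `>=` observed richness.
#' @export
chao1 <- function(counts) {
  if (any(counts != round(counts)) || any(counts < 0))
    stop("chao1 requires non-negative integer counts")
  if (all(counts == 0)) stop("all-zero sample")
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  sum(counts > 0) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Rarefaction of richness and Chao1 by read subsampling
#'
#' Subsamples reads without replacement (hypergeometric) `n_resamples`
#' times at each depth and reports the mean and standard deviation of
#' observed richness and Chao1.
#'
#' @param counts Integer count vector for one sample.
#' @param depths Integer subsampling depths, each `<=` the total count.
#' @param n_resamples Resamples per depth (default 10).
#' @param seed Integer seed.
#' @return Data frame with columns `depth`, `richness_mean`,
#'   `richness_sd`, `chao1_mean`, `chao1_sd`.
#' @export
rarefaction_curve <- function(counts, depths, n_resamples = 10L,
                              seed = 1L) {
  if (any(counts != round(counts)) || any(counts < 0))
    stop("rarefaction requires non-negative integer counts")
  total <- sum(counts)
  if (any(depths > total))
    stop("depth exceeds total count (", total, ")")
  set.seed(seed)
  reads <- rep.int(seq_along(counts), counts)
  res <- lapply(depths, function(d) {
    stats <- vapply(seq_len(n_resamples), function(i) {
      sub <- tabulate(sample(reads, d), nbins = length(counts))
      c(sum(sub > 0), chao1(sub))
    }, numeric(2))
    data.frame(depth = d,
               richness_mean = mean(stats[1, ]),
               richness_sd = stats::sd(stats[1, ]),
               chao1_mean = mean(stats[2, ]),
               chao1_sd = stats::sd(stats[2, ]))
  })
  do.call(rbind, res)
}

#' Per-sample alpha-diversity table
#'
#' @param profile A `taxon_profile` (relative or counts). Chao1 is only
#'   computed for counts.
#' @return Data frame with one row per sample: `sample_id`, `shannon_H`,
#'   `pielou_J`, `observed_richness`, and `chao1` (NA for relative
#'   units).
#' @export
diversity_table <- function(profile) {
  m <- unclass(profile)
  is_counts <- abundance_units(profile) == "counts"
  data.frame(
    sample_id = colnames(m),
    shannon_H = apply(m, 2L, shannon_index),
    pielou_J = apply(m, 2L, pielou_evenness),
    observed_richness = colSums(m > 0),
    chao1 = if (is_counts) apply(m, 2L, chao1) else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
}
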