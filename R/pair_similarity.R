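#' Shared relative-abundance fraction between two cecal pouches
#'
#' Let `S` be the features with positive counts in both pouches. The default
#' statistic is the mean over the two pouches of the fraction of each pouch's
#' reads carried by `S`. `"pooled"` computes the shared mass of the pooled
#' pair; `"min"` takes the smaller of the two per-pouch fractions. Invariant
#' to per-pouch sequencing depth.
#'
#' @param pouch_a,pouch_b Non-negative count vectors over the same features.
#' @param method `"mean"` (default), `"pooled"` or `"min"`.
#' @return Fraction in \[0, 1\].
#' @export
shared_abundance_fraction <- function(pouch_a, pouch_b,
                                      method = c("mean", "pooled", "min")) {
  method <- match.arg(method)
  if (length(pouch_a) != length(pouch_b))
    stop("pouch vectors must align on the same features", call. = FALSE)
  if (sum(pouch_a) == 0 || sum(pouch_b) == 0)
    stop("empty pouch", call. = FALSE)
  shared <- pouch_a > 0 & pouch_b > 0
  fa <- sum(pouch_a[shared]) / sum(pouch_a)
  fb <- sum(pouch_b[shared]) / sum(pouch_b)
  switch(method,
         mean = (fa + fb) / 2,
         pooled = sum(pouch_a[shared] + pouch_b[shared]) /
           sum(pouch_a + pouch_b),
         min = min(fa, fb))
}

#' Shared-ASV fraction between two cecal pouches
#'
#' Jaccard index of the presence sets, `|A intersect B| / |A union B|`
#' (default); `"mean"` instead averages the per-pouch fractions of member
#' ASVs also found in the mate.
#'
#' @inheritParams shared_abundance_fraction
#' @param method `"jaccard"` (default) or `"mean"`.
#' @return Fraction in \[0, 1\].
#' @export
shared_asv_fraction <- function(pouch_a, pouch_b,
                                method = c("jaccard", "mean")) {
  method <- match.arg(method)
  if (length(pouch_a) != length(pouch_b))
    stop("pouch vectors must align on the same features", call. = FALSE)
  a <- pouch_a > 0
  b <- pouch_b > 0
  if (!any(a) || !any(b)) stop("empty pouch", call. = FALSE)
  n_shared <- sum(a & b)
  if (method == "jaccard") n_shared / sum(a | b)
  else (n_shared / sum(a) + n_shared / sum(b)) / 2
}

#' Cecal pair similarity report for a flock
#'
#' One record per bird: shared relative-abundance fraction, shared-ASV
#' (Jaccard) fraction, and whether each pouch's nearest neighbour among all
#' cecum samples is its pair mate. The summary gives the flock mean and range
#' per statistic and the fraction of pouches whose nearest neighbour is the
#' mate.
#'
#' @param table An [asv_table()] containing the cecum samples.
#' @param meta A `sample_metadata` data frame; every bird must have exactly
#'   two cecum samples.
#' @param dm Distance matrix covering the cecum samples (nearest-neighbour
#'   concordance is computed on its restriction to cecum samples).
#' @param abundance_method,asv_method Variants passed to the two statistics.
#' @return A `pair_report`: `birds` (data frame), `summary` (list).
#' @export
pair_report <- function(table, meta, dm,
                        abundance_method = "mean", asv_method = "jaccard") {
  meta <- align_metadata(table, meta)
  cec <- meta[meta$site == "cecum", , drop = FALSE]
  counts_per_bird <- split(cec$sample_id, cec$bird_id)
  bad <- names(counts_per_bird)[lengths(counts_per_bird) != 2]
  if (length(bad))
    stop("bird(s) without exactly 2 cecum samples: ",
         paste(bad, collapse = ", "), call. = FALSE)
  cec_ids <- cec$sample_id
  dmc <- dm[cec_ids, cec_ids, drop = FALSE]
  counts <- unclass(table)
  rows <- lapply(names(counts_per_bird), function(bird) {
    pair <- counts_per_bird[[bird]]
    a <- counts[, pair[1]]
    b <- counts[, pair[2]]
    shared <- a > 0 & b > 0
    nn1 <- nearest_neighbor(dmc, pair[1])
    nn2 <- nearest_neighbor(dmc, pair[2])
    n_nn_mate <- sum(nn1 == pair[2], nn2 == pair[1])
    data.frame(
      bird_id = bird,
      shared_abundance_fraction =
        shared_abundance_fraction(a, b, method = abundance_method),
      shared_asv_fraction = shared_asv_fraction(a, b, method = asv_method),
      n_shared = sum(shared),
      n_union = sum(a > 0 | b > 0),
      nn_is_mate = n_nn_mate == 2,
      n_nn_mate = n_nn_mate,
      stringsAsFactors = FALSE
    )
  })
  birds <- do.call(rbind, rows)
  summary <- list(
    mean_shared_abundance = mean(birds$shared_abundance_fraction),
    range_shared_abundance = range(birds$shared_abundance_fraction),
    mean_shared_asv = mean(birds$shared_asv_fraction),
    range_shared_asv = range(birds$shared_asv_fraction),
    ## fraction of pouches whose nearest cecum sample is the pair mate
    fraction_nn_is_mate = sum(birds$n_nn_mate) / (2 * nrow(birds))
  )
  structure(list(birds = birds, summary = summary), class = "pair_report")
}

#' @export
print.pair_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Cecal pair similarity over %d birds:\n", nrow(x$birds)))
  cat(sprintf("  shared abundance: mean %.4f (range %.4f-%.4f)\n",
              s$mean_shared_abundance, s$range_shared_abundance[1],
              s$range_shared_abundance[2]))
  cat(sprintf("  shared ASVs (Jaccard): mean %.4f (range %.4f-%.4f)\n",
              s$mean_shared_asv, s$range_shared_asv[1], s$range_shared_asv[2]))
  cat(sprintf("  nearest neighbour is pair mate: %.0f%% of birds\n",
              100 * s$fraction_nn_is_mate))
  invisible(x)
}
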