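## Per-bird, per-site values with the two cecal pouches averaged within bird.
## Returns a birds x sites matrix (NA where a bird lacks the site).
bird_site_values <- function(values, meta) {
  birds <- sort(unique(meta$bird_id[!meta$is_negative]))
  sites <- intersect(names(SITE_ORDINALS), unique(meta$site))
  out <- matrix(NA_real_, length(birds), length(sites),
                dimnames = list(birds, sites))
  for (b in birds) for (s in sites) {
    ids <- meta$sample_id[meta$bird_id == b & meta$site == s]
    if (length(ids)) out[b, s] <- mean(values[ids])
  }
  out
}

#' Mean distance from each alimentary-tract site to the bird's own swab
#'
#' For each bird, the distance from every non-swab sample to that bird's
#' cloacal swab (cecal pouches averaged within the bird first); the profile
#' reports the mean and standard deviation across birds per site.
#'
#' @param dm Distance matrix covering the flock's samples.
#' @param meta A `sample_metadata` data frame; each bird needs exactly one
#'   cloacal swab.
#' @param metric Optional metric label carried into the result.
#' @return Data frame (`swab_proxy_profile`): `site`, `ordinal`,
#'   `mean_distance_to_swab`, `sd`, `n_birds`, `metric`.
#' @export
distance_to_swab <- function(dm, meta, metric = NA_character_) {
  validate_distance_matrix(dm)
  meta <- meta[match(rownames(dm), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata does not cover all samples in the distance matrix",
         call. = FALSE)
  birds <- sort(unique(meta$bird_id[!meta$is_negative]))
  swab_of <- vapply(birds, function(b) {
    ids <- meta$sample_id[meta$bird_id == b & meta$site == "cloacal_swab"]
    if (length(ids) != 1)
      stop(sprintf("bird '%s' must have exactly one cloacal swab", b),
           call. = FALSE)
    ids
  }, character(1))
  sites <- setdiff(intersect(names(SITE_ORDINALS), unique(meta$site)),
                   "cloacal_swab")
  rows <- lapply(sites, function(s) {
    per_bird <- vapply(birds, function(b) {
      ids <- meta$sample_id[meta$bird_id == b & meta$site == s]
      if (!length(ids)) return(NA_real_)
      mean(dm[ids, swab_of[b]])          # pouches averaged within bird
    }, numeric(1))
    per_bird <- per_bird[!is.na(per_bird)]
    data.frame(site = s, ordinal = unname(SITE_ORDINALS[s]),
               mean_distance_to_swab = mean(per_bird),
               sd = stats::sd(per_bird), n_birds = length(per_bird),
               metric = metric, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$ordinal), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("swab_proxy_profile", "data.frame")
  out
}

#' Family-level correlation between each site and the cloacal swab
#'
#' Aggregates the (normalized) table at the family rank, extracts one
#' family's per-bird values at each site (cecal pouches averaged within
#' bird), and correlates them with the same birds' swab values.
#'
#' @param table A normalized [asv_table()].
#' @param taxonomy A `taxonomy_table`.
#' @param meta A `sample_metadata` data frame (>= 3 birds).
#' @param family Family label, e.g. `"Enterobacteriaceae"`.
#' @param method `"pearson"` (default; two-sided p from the t distribution
#'   with n - 2 df) or `"spearman"`.
#' @return Data frame: `site`, `r`, `p`, `n_birds` (r is `NA` where either
#'   vector has zero variance).
#' @export
family_correlation <- function(table, taxonomy, meta,
                               family = "Enterobacteriaceae",
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  meta <- align_metadata(table, meta)
  fam_table <- aggregate_by_rank(table, taxonomy, "family")
  if (!family %in% rownames(fam_table))
    stop(sprintf("family '%s' absent from the taxonomy/table", family),
         call. = FALSE)
  vals <- unclass(fam_table)[family, ]
  bs <- bird_site_values(vals, meta)
  if (nrow(bs) < 3) stop("need >= 3 birds", call. = FALSE)
  if (!"cloacal_swab" %in% colnames(bs))
    stop("no cloacal swab samples present", call. = FALSE)
  swab <- bs[, "cloacal_swab"]
  sites <- setdiff(colnames(bs), "cloacal_swab")
  rows <- lapply(sites, function(s) {
    keep <- !is.na(bs[, s]) & !is.na(swab)
    x <- bs[keep, s]; y <- swab[keep]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(site = s, r = NA_real_, p = NA_real_,
                        n_birds = length(x), stringsAsFactors = FALSE))
    ct <- stats::cor.test(x, y, method = method, exact = FALSE)
    data.frame(site = s, r = unname(ct$estimate), p = ct$p.value,
               n_birds = length(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## least squares of y on x: slope, intercept, pearson r
ls_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  r <- sxy / sqrt(sxx * sum((y - my)^2))
  list(slope = slope, intercept = my - slope * mx, r = r)
}

#' Distance-decay analysis within one bird
#'
#' Community similarity (`1 - distance`) for every within-bird sample pair is
#' regressed on the physical separation of the sites (difference of
#' anatomical ordinals; both cecal pouches share one ordinal). Significance
#' of the negative association is assessed by a one-sided Mantel-style
#' permutation test that permutes the site ordinals among the bird's samples;
#' all `n!` relabelings are enumerated exactly when they fit the permutation
#' budget.
#'
#' @param dm Distance matrix covering the bird's samples.
#' @param meta A `sample_metadata` data frame.
#' @param bird Bird id (needs >= 4 sampled sites).
#' @param n_permutations Permutation budget (default 999).
#' @param seed Optional integer seed.
#' @return A `distance_decay_fit`: `bird_id`, `slope`, `intercept`, `r`,
#'   `p`, `n_pairs`, `n_permutations`, `exhaustive`.
#' @export
distance_decay <- function(dm, meta, bird, n_permutations = 999, seed = NULL) {
  validate_distance_matrix(dm)
  ids <- meta$sample_id[meta$bird_id == bird & !meta$is_negative]
  ids <- intersect(rownames(dm), ids)
  ords <- meta$ordinal[match(ids, meta$sample_id)]
  n <- length(ids)
  if (length(unique(ords)) < 4)
    stop(sprintf("bird '%s' has fewer than 4 sampled sites", bird),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sub <- dm[ids, ids, drop = FALSE]
  ut <- upper.tri(sub)
  pr <- which(ut, arr.ind = TRUE)
  sim <- 1 - sub[ut]
  gap_for <- function(o) abs(o[pr[, 1]] - o[pr[, 2]])
  gap <- gap_for(ords)
  fit <- ls_fit(gap, sim)
  ## permutation statistic: negative association of similarity with distance
  stat_for <- function(o) {
    g <- gap_for(o)
    suppressWarnings(stats::cor(g, sim))
  }
  r_obs <- stat_for(ords)
  total <- if (n <= 9) factorial(n) else Inf
  exhaustive <- is.finite(total) && total <= n_permutations
  if (exhaustive) {
    perms <- all_orderings(n)
    rp <- apply(perms, 1, function(ix) stat_for(ords[ix]))
    p <- mean(rp <= r_obs + 1e-12, na.rm = TRUE)
    n_used <- nrow(perms)
  } else {
    rp <- vapply(seq_len(n_permutations),
                 function(i) stat_for(sample(ords)), numeric(1))
    p <- (1 + sum(rp <= r_obs + 1e-12, na.rm = TRUE)) / (n_permutations + 1)
    n_used <- n_permutations
  }
  structure(list(bird_id = bird, slope = fit$slope, intercept = fit$intercept,
                 r = fit$r, p = p, n_pairs = length(sim),
                 n_permutations = n_used, exhaustive = exhaustive),
            class = "distance_decay_fit")
}

#' @export
print.distance_decay_fit <- function(x, ...) {
  cat(sprintf(
    "Distance decay [%s]: slope = %.4f, r = %.4f, p = %.4g (%d pairs)\n",
    x$bird_id, x$slope, x$r, x$p, x$n_pairs))
  invisible(x)
}

#' Cecal vs non-cecal enrichment contrast (permutation test)
#'
#' Per feature, the log2 fold change of cecal over non-cecal mean normalized
#' counts (pseudocount 1), with a two-sided permutation test on the
#' difference of group means of `log2(count + 1)`; sample labels are permuted
#' at the whole-sample level so all features share one permutation null.
#' Benjamini-Hochberg adjustment yields q-values; features are called
#' enriched/depleted when `q < alpha`, with the call's sign taken from the
#' fold change. The test is reported as `method = "permutation-LFC"` in the
#' result: it is a deliberate permutation-based replacement for a parametric
#' negative-binomial Wald contrast.
#'
#' @param table A normalized [asv_table()] (negative controls removed).
#' @param meta A `sample_metadata` data frame.
#' @param alpha Significance level on q (default 0.01).
#' @param n_permutations Permutation budget (default 999).
#' @param seed Optional integer seed.
#' @return Data frame (`enrichment_result`): `feature_id`,
#'   `log2_fold_change`, `p`, `q`, `status`; attribute `method`.
#' @export
cecal_enrichment <- function(table, meta, alpha = 0.01,
                             n_permutations = 999, seed = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  meta <- align_metadata(table, meta)
  keep <- !meta$is_negative
  counts <- unclass(table)[, keep, drop = FALSE]
  grp <- meta$site[keep] == "cecum"
  if (!any(grp) || all(grp))
    stop("both cecal and non-cecal samples are required", call. = FALSE)
  absent <- rowSums(counts) == 0
  if (any(absent)) {
    warning("skipping feature(s) absent everywhere: ",
            paste(rownames(counts)[absent], collapse = ", "), call. = FALSE)
    counts <- counts[!absent, , drop = FALSE]
  }
  if (!is.null(seed)) set.seed(seed)
  eps <- 1
  lfc <- log2((rowMeans(counts[, grp, drop = FALSE]) + eps) /
                (rowMeans(counts[, !grp, drop = FALSE]) + eps))
  lx <- log2(counts + 1)
  n <- ncol(lx)
  n_cec <- sum(grp)
  obs <- rowMeans(lx[, grp, drop = FALSE]) - rowMeans(lx[, !grp, drop = FALSE])
  ## whole-sample label permutations shared across features
  perm_idx <- vapply(seq_len(n_permutations),
                     function(i) sample.int(n, n_cec), integer(n_cec))
  ind <- matrix(0, n, n_permutations)
  ind[cbind(as.vector(perm_idx), rep(seq_len(n_permutations), each = n_cec))] <- 1
  row_tot <- rowSums(lx)
  cec_sums <- lx %*% ind
  perm_stat <- cec_sums / n_cec - (row_tot - cec_sums) / (n - n_cec)
  exceed <- rowSums(abs(perm_stat) >= abs(obs) - 1e-12)
  p <- (1 + exceed) / (n_permutations + 1)
  q <- stats::p.adjust(p, method = "BH")
  status <- ifelse(q < alpha, ifelse(lfc > 0, "enriched", "depleted"), "ns")
  out <- data.frame(feature_id = rownames(counts), log2_fold_change = lfc,
                    p = p, q = q, status = status, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "method") <- "permutation-LFC"
  attr(out, "alpha") <- alpha
  class(out) <- c("enrichment_result", "data.frame")
  out
}
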