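#' Remove organelle and kingdom-unassigned features
#'
#' Drops features whose lineage mentions chloroplasts or mitochondria at any
#' rank (case-insensitive) and features without a kingdom assignment.
#' Features missing from the taxonomy are treated as kingdom-unassigned.
#'
#' @param table An [asv_table()].
#' @param taxonomy A `taxonomy_table`.
#' @return A possibly smaller [asv_table()]; retained rows are untouched.
#' @export
filter_nonbacterial <- function(table, taxonomy) {
  idx <- match(rownames(table), taxonomy$feature_id)
  drop <- logical(nrow(table))
  for (i in seq_len(nrow(table))) {
    ti <- idx[i]
    if (is.na(ti)) { drop[i] <- TRUE; next }
    lineage <- unlist(taxonomy[ti, TAXONOMY_RANKS], use.names = FALSE)
    if (is.na(lineage[1])) { drop[i] <- TRUE; next }   # no kingdom
    hit <- grepl("chloroplast|mitochondri", lineage, ignore.case = TRUE)
    drop[i] <- any(hit, na.rm = TRUE)
  }
  if (any(drop))
    message(sprintf("filter_nonbacterial: removing %d of %d features",
                    sum(drop), nrow(table)))
  as_asv(unclass(table)[!drop, , drop = FALSE],
         normalized = is_normalized(table))
}

#' Remove features by rank-qualified taxon name
#'
#' Exact label match at the stated rank removes the feature; names matching
#' nothing raise a warning, not an error.
#'
#' @param table An [asv_table()].
#' @param taxonomy A `taxonomy_table`.
#' @param taxa Data frame with columns `rank` and `label`, one row per taxon
#'   to remove (e.g. species-level Lactobacillus contaminants).
#' @return A possibly smaller [asv_table()].
#' @export
remove_named_taxa <- function(table, taxonomy, taxa) {
  if (is.null(taxa) || nrow(taxa) == 0) return(table)
  if (!all(c("rank", "label") %in% colnames(taxa)))
    stop("`taxa` needs columns 'rank' and 'label'", call. = FALSE)
  bad <- setdiff(unique(taxa$rank), TAXONOMY_RANKS)
  if (length(bad))
    stop("unknown rank(s) in taxa list: ", paste(bad, collapse = ", "),
         call. = FALSE)
  idx <- match(rownames(table), taxonomy$feature_id)
  drop <- logical(nrow(table))
  for (k in seq_len(nrow(taxa))) {
    labs <- taxonomy[[taxa$rank[k]]][idx]
    hit <- !is.na(labs) & labs == taxa$label[k]
    if (!any(hit))
      warning(sprintf("no feature matches %s '%s'", taxa$rank[k], taxa$label[k]),
              call. = FALSE)
    drop <- drop | hit
  }
  message(sprintf("remove_named_taxa: removing %d feature(s)", sum(drop)))
  as_asv(unclass(table)[!drop, , drop = FALSE],
         normalized = is_normalized(table))
}

## Fisher's method for two p-values (chi-square with 4 df); NA p2 -> p1 etc.
fisher_combine <- function(p_freq, p_prev) {
  if (is.na(p_freq)) return(p_prev)
  if (is.na(p_prev)) return(p_freq)
  x2 <- -2 * (log(p_freq) + log(p_prev))
  stats::pchisq(x2, df = 4, lower.tail = FALSE)
}

#' Score features as contaminants from frequency and prevalence evidence
#'
#' Combines two per-feature tests in the manner of the "combo" contaminant
#' classifier. The frequency test asks whether a feature's relative abundance
#' scales inversely with sample DNA concentration (the physical signature of a
#' reagent contaminant): in log10 space over true samples where the feature is
#' present, the residual sum of squares of the contaminant model
#' (slope fixed at -1 against log10 concentration) is compared with the
#' constant model, and the ratio's significance is assessed by permuting
#' concentration labels. The prevalence test is a one-sided Fisher exact test
#' for enrichment of presence in negative controls. The two p-values are
#' combined by Fisher's method (chi-square, 4 df).
#'
#' Features present in fewer than 3 concentration-bearing true samples have no
#' frequency p-value; their combined score falls back to the prevalence
#' p-value.
#'
#' @param table A raw [asv_table()] including negative-control samples.
#' @param meta A `sample_metadata` data frame covering the table's samples;
#'   true samples need `dna_conc`.
#' @param threshold Flagging threshold on the combined score (default 0.1).
#' @param n_permutations Permutations for the frequency test (>= 1000
#'   recommended).
#' @param seed Optional integer seed for the permutation draws.
#' @return Data frame (`contaminant_report`): `feature_id`, `p_freq`,
#'   `p_prev`, `p_combined`, `flagged`.
#' @export
decontam_combo <- function(table, meta, threshold = 0.1,
                           n_permutations = 1000, seed = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  meta <- align_metadata(table, meta)
  if (!is.null(seed)) set.seed(seed)
  is_neg <- meta$is_negative
  if (sum(is_neg) < 1)
    stop("at least one negative control is required", call. = FALSE)
  true_conc_idx <- which(!is_neg & !is.na(meta$dna_conc))
  if (length(true_conc_idx) < 2)
    stop("need >= 2 true samples with dna_conc", call. = FALSE)
  counts <- unclass(table)
  freq <- sweep(counts, 2, colSums(counts), "/")
  present <- counts >= 1
  logC <- log10(meta$dna_conc)

  ## permutation index cache, keyed by number of present samples
  perm_cache <- new.env(parent = emptyenv())
  get_perms <- function(n) {
    key <- as.character(n)
    if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
    m <- vapply(seq_len(n_permutations), function(i) sample.int(n),
                integer(n))
    perm_cache[[key]] <- m
    m
  }

  n_feat <- nrow(counts)
  p_freq <- rep(NA_real_, n_feat)
  p_prev <- rep(NA_real_, n_feat)
  n_true <- sum(!is_neg)
  n_neg <- sum(is_neg)
  for (i in seq_len(n_feat)) {
    ## prevalence: presence in negatives vs true samples
    a <- sum(present[i, is_neg]); b <- n_neg - a
    c_ <- sum(present[i, !is_neg]); d <- n_true - c_
    p_prev[i] <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2),
                                    alternative = "greater")$p.value
    ## frequency: inverse-concentration signature among present true samples
    idx <- true_conc_idx[present[i, true_conc_idx]]
    n <- length(idx)
    if (n < 3) next
    y <- log10(freq[i, idx])
    x <- logC[idx]
    cy <- y - mean(y)
    ssr_non <- sum(cy^2)
    cx <- x - mean(x)
    ssx <- sum(cx^2)
    ssr_con <- ssr_non + ssx + 2 * sum(cy * cx)
    if (ssr_non < 1e-12) { p_freq[i] <- 1; next }
    perms <- get_perms(n)
    cross_perm <- as.vector(crossprod(cy, matrix(cx[perms], nrow = n)))
    ssr_perm <- ssr_non + ssx + 2 * cross_perm
    p_freq[i] <- (1 + sum(ssr_perm <= ssr_con + 1e-12)) / (n_permutations + 1)
  }
  if (anyNA(p_freq))
    message(sprintf(
      "decontam_combo: %d feature(s) present in < 3 concentration-bearing samples; using prevalence p only",
      sum(is.na(p_freq))))
  p_combined <- mapply(fisher_combine, p_freq, p_prev)
  out <- data.frame(
    feature_id = rownames(counts),
    p_freq = p_freq, p_prev = p_prev, p_combined = p_combined,
    flagged = p_combined < threshold,
    stringsAsFactors = FALSE
  )
  class(out) <- c("contaminant_report", "data.frame")
  out
}

#' Cumulative sum scaling normalization
#'
#' For each sample, `q` is the `quantile_l`-th quantile of the sample's
#' positive counts under the nearest-rank-lower convention; the scaling
#' factor `s_j` is the cumulative sum of counts no larger than `q`; normalized
#' counts are `c_ij / s_j * scale`. Robust to variable sequencing depth
#' because the cumulative sum up to a mid-quantile ignores the high-abundance
#' tail that dominates total library size.
#'
#' @param table A raw [asv_table()] (every sample needs a positive count).
#' @param quantile_l Quantile in (0, 1), default 0.5.
#' @param scale Multiplicative rescale, default 1000.
#' @return List with `table` (normalized [asv_table()]) and `factors`
#'   (data frame: `sample_id`, `quantile_l`, `s_j`, `scale`).
#' @export
css_normalize <- function(table, quantile_l = 0.5, scale = 1000) {
  stopifnot(quantile_l > 0, quantile_l < 1, scale > 0)
  counts <- unclass(table)
  s <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    pos <- sort(counts[counts[, j] > 0, j])
    if (length(pos) == 0)
      stop(sprintf("sample '%s' has no positive counts (s_j = 0)",
                   colnames(counts)[j]), call. = FALSE)
    k <- max(1L, floor(quantile_l * length(pos)))
    q <- pos[k]
    s[j] <- sum(counts[counts[, j] <= q, j])
    if (s[j] <= 0)
      stop(sprintf("sample '%s' has s_j = 0", colnames(counts)[j]),
           call. = FALSE)
  }
  normalized <- sweep(counts, 2, s, "/") * scale
  list(
    table = as_asv(normalized, normalized = TRUE),
    factors = data.frame(sample_id = colnames(counts),
                         quantile_l = quantile_l, s_j = s, scale = scale,
                         stringsAsFactors = FALSE)
  )
}
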