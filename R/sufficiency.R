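## presence input -> logical features x units matrix
as_presence_matrix <- function(presence) {
  if (is.list(presence) && !is.data.frame(presence)) {
    feats <- sort(unique(unlist(presence)))
    m <- vapply(presence, function(s) feats %in% s, logical(length(feats)))
    rownames(m) <- feats
    if (is.null(colnames(m))) colnames(m) <- paste0("unit", seq_len(ncol(m)))
    return(m)
  }
  if (!is.matrix(presence)) stop("presence must be a matrix or list of sets",
                                 call. = FALSE)
  presence > 0
}

all_orderings <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_orderings(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    block <- cbind(first, matrix(rest[sub], nrow = nrow(sub)))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Bird-accumulation curve of new, cumulative and unique ASVs
#'
#' For an ordering of the flock's birds (or cecal pouches) at one site and
#' each step `k`: `new(k)` is the number of ASVs of bird `k` not seen in the
#' first `k - 1` birds, `cumulative(k)` the union size after `k` birds, and
#' `unique(k)` the number of ASVs present in exactly one of the first `k`
#' birds. The curve reports means over random orderings (all orderings
#' enumerated exactly when `n_orderings` covers them).
#'
#' @param presence Per-bird presence for one site: a logical/numeric
#'   features x birds matrix, or a named list of per-bird ASV id sets.
#' @param n_orderings Number of random orderings to average over (default
#'   100); `Inf` or any value `>= n!` enumerates all orderings.
#' @param seed Optional integer seed for the ordering draws.
#' @param site Optional site label carried into the result.
#' @param orderings Optional explicit list of integer orderings (overrides
#'   sampling; used for fixed-order analyses).
#' @param keep_per_ordering Keep the per-ordering matrix of new-ASV counts.
#' @return An `accumulation_curve`: `site`, `steps` (data frame `k`,
#'   `mean_new`, `mean_cumulative`, `mean_unique`), `n_orderings`,
#'   `per_ordering_new` (optional).
#' @export
accumulate <- function(presence, n_orderings = 100, seed = NULL,
                       site = NA_character_, orderings = NULL,
                       keep_per_ordering = FALSE) {
  m <- as_presence_matrix(presence)
  n <- ncol(m)
  if (n < 2) stop("need >= 2 birds", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(orderings)) {
    total <- if (n <= 12) factorial(n) else Inf
    if (n_orderings >= total) {
      if (n > 9) stop("exhaustive enumeration limited to <= 9 birds",
                      call. = FALSE)
      ord_mat <- all_orderings(n)
      orderings <- lapply(seq_len(nrow(ord_mat)), function(i) ord_mat[i, ])
    } else {
      orderings <- lapply(seq_len(n_orderings), function(i) sample.int(n))
    }
  }
  n_ord <- length(orderings)
  UT <- upper.tri(matrix(0, n, n), diag = TRUE) * 1   # column k sums birds 1..k
  mp <- m * 1
  sum_new <- sum_cum <- sum_uni <- numeric(n)
  per_new <- if (keep_per_ordering) matrix(0, n_ord, n) else NULL
  for (o in seq_len(n_ord)) {
    ord <- orderings[[o]]
    rc <- mp[, ord, drop = FALSE] %*% UT
    cumulative <- colSums(rc >= 1)
    uni <- colSums(rc == 1)
    new <- diff(c(0, cumulative))
    sum_new <- sum_new + new
    sum_cum <- sum_cum + cumulative
    sum_uni <- sum_uni + uni
    if (keep_per_ordering) per_new[o, ] <- new
  }
  steps <- data.frame(
    k = seq_len(n),
    mean_new = sum_new / n_ord,
    mean_cumulative = sum_cum / n_ord,
    mean_unique = sum_uni / n_ord
  )
  structure(list(site = site, steps = steps, n_orderings = n_ord,
                 per_ordering_new = per_new),
            class = "accumulation_curve")
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat(sprintf("Accumulation curve%s over %d ordering(s):\n",
              if (is.na(x$site)) "" else paste0(" [", x$site, "]"),
              x$n_orderings))
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Smallest sufficient sample size at a new-ASV threshold
#'
#' `new_fraction(k) = mean_new(k) / mean_cumulative(k - 1)` for `k >= 2`
#' (running-union denominator; `denominator = "final"` uses the full-flock
#' union instead). The sufficient size is the smallest `n` such that the
#' next bird adds a fraction below `t` of what has been seen so far;
#' "not reached" if no such `n` exists within the flock.
#'
#' @param curve An [accumulate()] result.
#' @param t Threshold fraction in (0, 1), e.g. 0.10 or 0.01.
#' @param denominator `"running"` (default) or `"final"` union.
#' @return A `sample_size_result`: `site`, `threshold`, `n_sufficient`
#'   (`NA` when not reached), `reached`, `new_fraction_series`.
#' @export
sample_size_at_threshold <- function(curve, t,
                                     denominator = c("running", "final")) {
  denominator <- match.arg(denominator)
  if (!is.numeric(t) || t <= 0 || t >= 1)
    stop("threshold t must lie in (0, 1)", call. = FALSE)
  steps <- curve$steps
  n <- nrow(steps)
  if (n < 2) stop("curve needs >= 2 steps", call. = FALSE)
  ks <- 2:n
  denom <- if (denominator == "running")
    steps$mean_cumulative[ks - 1] else rep(steps$mean_cumulative[n], length(ks))
  nf <- steps$mean_new[ks] / denom
  hit <- which(nf < t)
  n_sufficient <- if (length(hit)) ks[hit[1]] - 1L else NA_integer_
  structure(list(site = curve$site, threshold = t,
                 n_sufficient = n_sufficient, reached = !is.na(n_sufficient),
                 new_fraction_series = nf),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf("Sample size at threshold %.3g%s: %s\n", x$threshold,
              if (is.na(x$site)) "" else paste0(" [", x$site, "]"),
              if (x$reached) x$n_sufficient else "not reached"))
  invisible(x)
}

#' Summarize per-site sufficient sample sizes
#'
#' Arithmetic mean and range over sites that reached each threshold;
#' unreached sites are listed separately.
#'
#' @param results List of [sample_size_at_threshold()] results.
#' @return Data frame with one row per threshold: `threshold`,
#'   `n_sites_reached`, `mean`, `min`, `max`, `unreached_sites`.
#' @export
summarize_sites <- function(results) {
  thr <- vapply(results, function(r) r$threshold, numeric(1))
  out <- lapply(unique(thr), function(t) {
    rs <- results[thr == t]
    ns <- vapply(rs, function(r) as.integer(r$n_sufficient), integer(1))
    sites <- vapply(rs, function(r) as.character(r$site), character(1))
    ok <- !is.na(ns)
    if (!any(ok))
      warning(sprintf("no site reached threshold %.3g", t), call. = FALSE)
    data.frame(
      threshold = t,
      n_sites_reached = sum(ok),
      mean = if (any(ok)) mean(ns[ok]) else NA_real_,
      min = if (any(ok)) min(ns[ok]) else NA_integer_,
      max = if (any(ok)) max(ns[ok]) else NA_integer_,
      unreached_sites = paste(sites[!ok], collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

## Per-site, per-unit presence matrices. Non-cecum sites: one unit per bird;
## cecum: each pouch is its own unit.
site_presence <- function(table, meta, site) {
  meta <- align_metadata(table, meta)
  sel <- meta$site == site
  if (!any(sel)) stop(sprintf("no samples at site '%s'", site), call. = FALSE)
  ids <- meta$sample_id[sel]
  units <- if (site == "cecum")
    paste0(meta$bird_id[sel], "_", meta$pouch[sel]) else meta$bird_id[sel]
  if (anyDuplicated(units))
    stop(sprintf("multiple samples per unit at site '%s'", site), call. = FALSE)
  m <- unclass(table)[, ids, drop = FALSE] >= 1
  colnames(m) <- units
  m
}

#' Accumulation analysis for every site of a flock
#'
#' Runs [accumulate()] and [sample_size_at_threshold()] per sampling site.
#' At the cecum each pouch counts as its own sampling unit.
#'
#' @param table A preprocessed [asv_table()] (negative controls removed).
#' @param meta A `sample_metadata` data frame.
#' @param thresholds New-ASV fractions to evaluate (default `c(0.10, 0.01)`).
#' @param n_orderings Orderings per curve (default 100).
#' @param seed Optional integer seed.
#' @param denominator Passed to [sample_size_at_threshold()].
#' @return List with `curves` (named by site), `results` (per site x
#'   threshold) and `summary` (from [summarize_sites()]).
#' @export
flock_sufficiency <- function(table, meta, thresholds = c(0.10, 0.01),
                              n_orderings = 100, seed = NULL,
                              denominator = "running") {
  meta <- align_metadata(table, meta)
  sites <- intersect(names(SITE_ORDINALS), unique(meta$site))
  curves <- list()
  results <- list()
  for (s in seq_along(sites)) {
    site <- sites[s]
    pres <- site_presence(table, meta, site)
    curves[[site]] <- accumulate(pres, n_orderings = n_orderings,
                                 seed = if (is.null(seed)) NULL else seed + s,
                                 site = site)
    for (t in thresholds)
      results[[length(results) + 1]] <-
        sample_size_at_threshold(curves[[site]], t, denominator = denominator)
  }
  list(curves = curves, results = results, summary = summarize_sites(results))
}
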