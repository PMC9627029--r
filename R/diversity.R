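#' Shannon diversity of a count vector
#'
#' `H = -sum p_i log(p_i)` over positive entries, with `p_i = c_i / sum(c)`.
#' Natural log by default; the base is a parameter.
#'
#' @param x Non-negative numeric vector with at least one positive entry.
#' @param base Logarithm base (default `exp(1)`, i.e. nats).
#' @return Shannon diversity (scalar).
#' @export
shannon <- function(x, base = exp(1)) {
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(x)
  if (total == 0) stop("all-zero vector has no diversity", call. = FALSE)
  p <- x[x > 0] / total
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` between all sample pairs.
#'
#' @param table An [asv_table()] with at least 2 samples.
#' @return Symmetric distance matrix with zero diagonal, sample ids on both
#'   axes.
#' @export
bray_curtis <- function(table) {
  counts <- unclass(table)
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  zero <- colSums(counts) == 0
  if (sum(zero) >= 2)
    stop("Bray-Curtis undefined for a pair of all-zero samples: ",
         paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  d <- as.matrix(vegan::vegdist(t(counts), method = "bray"))
  dimnames(d) <- list(colnames(counts), colnames(counts))
  diag(d) <- 0
  validate_distance_matrix(d)
  d
}

#' Weighted UniFrac distance matrix
#'
#' Phylogeny-aware community distance. For each branch `b` with length `l_b`,
#' let `p_X(b)` be the proportion of sample X's reads on leaves descending
#' from `b`. The raw variant is `d = sum_b l_b |p_A(b) - p_B(b)|`; the
#' normalized variant divides by `sum_b l_b (p_A(b) + p_B(b))`, bounding the
#' distance in \[0, 1\].
#'
#' @param table An [asv_table()]; every feature with a positive count must be
#'   a leaf of `tree`.
#' @param tree A rooted `ape::phylo` tree with branch lengths.
#' @param normalized Use the normalized variant (default `FALSE`, the raw
#'   variant).
#' @return Symmetric distance matrix with sample ids on both axes.
#' @export
weighted_unifrac <- function(table, tree, normalized = FALSE) {
  validate_tree(tree)
  counts <- unclass(table)
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("all-zero sample(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "), call. = FALSE)
  used <- rownames(counts)[rowSums(counts) > 0]
  missing <- setdiff(used, tree$tip.label)
  if (length(missing))
    stop("feature(s) missing from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  props <- sweep(counts, 2, totals, "/")
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- tr$Nnode
  S <- ncol(props)
  node_p <- matrix(0, nrow = n_tip + n_node, ncol = S)
  hit <- match(tr$tip.label, rownames(props))
  ok <- !is.na(hit)
  node_p[which(ok), ] <- props[hit[ok], , drop = FALSE]
  for (e in seq_len(nrow(tr$edge)))
    node_p[tr$edge[e, 1], ] <- node_p[tr$edge[e, 1], ] + node_p[tr$edge[e, 2], ]
  branch_p <- node_p[tr$edge[, 2], , drop = FALSE]      # clade below each edge
  el <- tr$edge.length
  d <- as.matrix(stats::dist(t(branch_p * el), method = "manhattan"))
  if (normalized) {
    s <- colSums(branch_p * el)
    denom <- outer(s, s, "+")
    d <- ifelse(denom > 0, d / denom, 0)
  }
  dimnames(d) <- list(colnames(counts), colnames(counts))
  diag(d) <- 0
  validate_distance_matrix(d)
  d
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: double-centred `-D^2/2`, eigendecomposition,
#' coordinates scaled by the square root of the eigenvalues. Negative
#' eigenvalues are reported, not silently dropped.
#'
#' @param dm A validated square distance matrix.
#' @param axes Number of axes to return (truncated with a warning when the
#'   configuration has lower rank).
#' @return A `pcoa_result`: `coordinates` (samples x axes), `eigenvalues`
#'   (all, descending), `proportion_explained` (over retained axes, from the
#'   positive eigenvalue mass).
#' @export
pcoa <- function(dm, axes = 2) {
  validate_distance_matrix(dm)
  n <- nrow(dm)
  k <- min(axes, n - 1)
  if (k < axes)
    warning(sprintf("axes truncated to %d (n - 1)", k), call. = FALSE)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = k, eig = TRUE))
  coords <- fit$points
  if (ncol(coords) < axes && k == axes)
    warning(sprintf("axes truncated to %d (rank of configuration)", ncol(coords)),
            call. = FALSE)
  eig <- fit$eig
  pos_mass <- sum(pmax(eig, 0))
  prop <- pmax(eig[seq_len(ncol(coords))], 0) / pos_mass
  rownames(coords) <- rownames(dm)
  structure(list(coordinates = coords, eigenvalues = eig,
                 proportion_explained = prop),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d retained axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("  proportion explained:",
      paste(sprintf("%.3f", x$proportion_explained), collapse = ", "), "\n")
  invisible(x)
}

## All distinct arrangements of a label multiset, one arrangement per column.
multiset_permutations <- function(x) {
  n <- length(x)
  if (n == 1) return(matrix(x, nrow = 1))
  ux <- unique(x)
  cols <- list()
  for (u in ux) {
    rest <- x[-match(u, x)]
    sub <- multiset_permutations(rest)
    cols[[length(cols) + 1]] <- rbind(matrix(u, 1, ncol(sub)), sub)
  }
  do.call(cbind, cols)
}

n_distinct_arrangements <- function(groups) {
  tab <- table(groups)
  exp(lfactorial(length(groups)) - sum(lfactorial(tab)))
}

## R statistic and permutation Rs from a rank vector and label matrix.
anosim_stats <- function(r, ii, jj, G) {
  M <- length(r)
  W <- G[ii, , drop = FALSE] == G[jj, , drop = FALSE]
  cw <- colSums(W)
  mean_w <- colSums(r * W) / cw
  mean_b <- colSums(r * (1 - W)) / (M - cw)
  (mean_b - mean_w) / (M / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group separation in a distance matrix.
#' `R = (mean between-group rank - mean within-group rank) / (M/2)` with
#' `M = n(n-1)/2` pairwise distances (mid-ranks for ties). Significance by
#' permuting group labels; when the number of distinct label arrangements does
#' not exceed `n_permutations` the null distribution is enumerated exactly.
#'
#' @param dm A validated square distance matrix.
#' @param groups Group labels, one per sample (>= 2 groups of >= 2).
#' @param n_permutations Permutation budget (default 999).
#' @param seed Optional integer seed for sampled permutations.
#' @return An `anosim_result`: `R`, `p`, `n_permutations` (permutations
#'   actually used), `exhaustive`.
#' @export
anosim <- function(dm, groups, n_permutations = 999, seed = NULL) {
  validate_distance_matrix(dm)
  n <- nrow(dm)
  groups <- as.character(groups)
  if (length(groups) != n)
    stop("one group label per sample required", call. = FALSE)
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(tab < 2))
    stop("group(s) of size 1: ", paste(names(tab)[tab < 2], collapse = ", "),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pr <- which(upper.tri(dm), arr.ind = TRUE)
  ii <- pr[, 1]; jj <- pr[, 2]
  r <- rank(dm[upper.tri(dm)])
  R_obs <- anosim_stats(r, ii, jj, matrix(groups, ncol = 1))
  A <- n_distinct_arrangements(groups)
  exhaustive <- is.finite(A) && A <= n_permutations
  if (exhaustive) {
    G <- multiset_permutations(groups)
    Rp <- anosim_stats(r, ii, jj, G)
    p <- mean(Rp >= R_obs - 1e-12)
    n_used <- ncol(G)
  } else {
    G <- vapply(seq_len(n_permutations), function(i) sample(groups),
                character(n))
    Rp <- anosim_stats(r, ii, jj, G)
    p <- (1 + sum(Rp >= R_obs - 1e-12)) / (n_permutations + 1)
    n_used <- n_permutations
  }
  structure(list(R = R_obs, p = p, n_permutations = n_used,
                 exhaustive = exhaustive),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s, %d permutations)\n",
              x$R, x$p, if (x$exhaustive) "exhaustive" else "sampled",
              x$n_permutations))
  invisible(x)
}

#' Nearest neighbour of a sample in a distance matrix
#'
#' Returns the distinct sample at minimal distance; ties are broken by the
#' lexicographically smallest id, with a warning.
#'
#' @param dm A validated square distance matrix.
#' @param query Sample id present in `dm`.
#' @return Sample id of the nearest neighbour.
#' @export
nearest_neighbor <- function(dm, query) {
  validate_distance_matrix(dm)
  ids <- rownames(dm)
  if (!query %in% ids)
    stop(sprintf("query sample '%s' absent from the matrix", query),
         call. = FALSE)
  if (length(ids) < 2) stop("need >= 2 samples", call. = FALSE)
  d <- dm[query, ids != query]
  hits <- names(d)[d <= min(d) + 1e-12]
  if (length(hits) > 1)
    warning(sprintf("nearest-neighbour tie for '%s'; returning '%s'",
                    query, sort(hits)[1]), call. = FALSE)
  sort(hits)[1]
}
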