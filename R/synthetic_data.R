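## Fixed lineage pool used to label synthetic features; includes the families
## and genera the family-level operations and named-taxon removal exercise.
LINEAGE_POOL <- data.frame(
  kingdom = "Bacteria",
  phylum = c("Firmicutes", "Firmicutes", "Firmicutes", "Proteobacteria",
             "Bacteroidetes", "Firmicutes", "Firmicutes", "Actinobacteria"),
  class = c("Bacilli", "Clostridia", "Clostridia", "Gammaproteobacteria",
            "Bacteroidia", "Clostridia", "Bacilli", "Actinobacteria"),
  order = c("Lactobacillales", "Clostridiales", "Clostridiales",
            "Enterobacteriales", "Bacteroidales", "Clostridiales",
            "Lactobacillales", "Bifidobacteriales"),
  family = c("Lactobacillaceae", "Lachnospiraceae", "Ruminococcaceae",
             "Enterobacteriaceae", "Bacteroidaceae", "Clostridiaceae",
             "Streptococcaceae", "Bifidobacteriaceae"),
  genus = c("Lactobacillus", "Blautia", "Faecalibacterium", "Escherichia",
            "Bacteroides", "Clostridium", "Streptococcus", "Bifidobacterium"),
  stringsAsFactors = FALSE
)

#' Parameters of a synthetic broiler flock
#'
#' The generative model behind [generate_flock()]: site base compositions
#' drift along the alimentary tract as a log-scale random walk
#' (`gradient_step_sd` per ordinal step), each bird perturbs them by a
#' lognormal bird effect (`bird_effect_sd`; 0 = clonal flock), cecal pouches
#' are Dirichlet-multinomial draws from a shared bird-cecum composition with
#' the concentration calibrated so the expected shared-abundance fraction is
#' `pair_overlap`, each bird carries `rare_pool_per_bird` private
#' low-abundance ASVs, and negative controls carry planted contaminants whose
#' expected frequency in true samples is proportional to
#' `contaminant_strength / dna_conc`.
#'
#' Defaults describe a single market-age broiler flock: 9 birds sampled at 10
#' alimentary-tract locations (both cecal pouches sampled), a target depth of
#' 30,000 reads per sample, two negative controls, 95% expected cecal pair
#' shared abundance, and ten 8-fold cecum-enriched features.
#'
#' @param n_birds Number of birds (default 9).
#' @param n_features Size of the shared (flock-wide) ASV pool.
#' @param gradient_step_sd Log-scale white-noise drift of site base
#'   composition per anatomical ordinal step.
#' @param gradient_trend_sd Log-scale sd of the per-feature directional trend
#'   applied at every ordinal step; the trend accumulates linearly along the
#'   tract, so between-site divergence grows with anatomical separation
#'   instead of plateauing.
#' @param bird_effect_sd Within-flock clonality control; log-scale sd of the
#'   per-bird, per-feature effect (0 = clonal).
#' @param pair_overlap Target expected cecal shared-abundance fraction
#'   (rho_mass) in (0, 1]; 1 means zero pouch noise.
#' @param rare_pool_per_bird Number of bird-private low-abundance ASVs.
#' @param private_rel_abundance Expected relative abundance of each private
#'   ASV.
#' @param depth_mean Target sequencing depth per true sample.
#' @param depth_dispersion Lognormal sd of realized depths.
#' @param n_contaminants Number of planted reagent contaminants.
#' @param contaminant_strength Scale of the inverse-concentration contaminant
#'   frequency (expected frequency = strength / dna_conc, per contaminant
#'   base weight).
#' @param n_planted_enriched Number of planted cecum-enriched features.
#' @param enrichment_fold Fold change (> 1) of planted features in cecal
#'   samples.
#' @param n_negatives Number of negative-control samples.
#' @param base_abundance_sd Log-scale sd of the baseline feature abundance
#'   distribution (controls the rare tail that drives accumulation curves).
#' @param seed Integer seed; required (the manifest must reproduce the flock).
#' @return A validated `flock_model` list.
#' @export
flock_model <- function(n_birds = 9,
                        n_features = 600,
                        gradient_step_sd = 0.30,
                        gradient_trend_sd = 0.35,
                        bird_effect_sd = 1.0,
                        pair_overlap = 0.95,
                        rare_pool_per_bird = 2,
                        private_rel_abundance = 4e-4,
                        depth_mean = 30000,
                        depth_dispersion = 0.2,
                        n_contaminants = 8,
                        contaminant_strength = 0.3,
                        n_planted_enriched = 10,
                        enrichment_fold = 8,
                        n_negatives = 2,
                        base_abundance_sd = 2.0,
                        seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("seed is required", call. = FALSE)
  stopifnot(
    n_birds >= 1, n_features >= 10,
    gradient_step_sd > 0, gradient_trend_sd >= 0, bird_effect_sd >= 0,
    pair_overlap > 0, pair_overlap <= 1,
    rare_pool_per_bird >= 0, private_rel_abundance > 0,
    depth_mean >= 100, depth_dispersion > 0,
    n_contaminants >= 0, contaminant_strength > 0,
    n_planted_enriched >= 0, enrichment_fold > 1,
    n_negatives >= 0, base_abundance_sd > 0
  )
  model <- list(
    n_birds = as.integer(n_birds), n_features = as.integer(n_features),
    gradient_step_sd = gradient_step_sd, gradient_trend_sd = gradient_trend_sd,
    bird_effect_sd = bird_effect_sd,
    pair_overlap = pair_overlap,
    rare_pool_per_bird = as.integer(rare_pool_per_bird),
    private_rel_abundance = private_rel_abundance,
    depth_mean = as.integer(depth_mean), depth_dispersion = depth_dispersion,
    n_contaminants = as.integer(n_contaminants),
    contaminant_strength = contaminant_strength,
    n_planted_enriched = as.integer(n_planted_enriched),
    enrichment_fold = enrichment_fold, n_negatives = as.integer(n_negatives),
    base_abundance_sd = base_abundance_sd, seed = as.integer(seed)
  )
  class(model) <- "flock_model"
  model
}

## P(X = 0) for a beta-binomial DM marginal with concentration theta,
## proportion p, depth N.
dm_zero_prob <- function(theta, p, N) {
  b <- theta * (1 - p)
  exp(lgamma(b + N) + lgamma(theta) - lgamma(b) - lgamma(theta + N))
}

## Expected per-pouch shared-abundance fraction for two independent
## DM(N, theta * p) pouch draws: sum_i p_i * (1 - P0_i).
expected_shared_mass <- function(theta, p, N) {
  sum(p * (1 - dm_zero_prob(theta, p, N)))
}

## Multinomial limit (theta -> Inf) of the expected shared mass.
shared_mass_limit <- function(p, N) sum(p * (1 - (1 - p)^N))

## Bisection for the Dirichlet concentration hitting the target shared mass.
calibrate_concentration <- function(p, N, target) {
  limit <- shared_mass_limit(p, N)
  if (target > limit)
    stop(sprintf(
      "pair_overlap %.4f infeasible: detection-limited maximum is %.4f (increase depth or reduce the rare pool)",
      target, limit), call. = FALSE)
  lo <- 1; hi <- 1e9
  if (expected_shared_mass(lo, p, N) >= target) return(lo)
  for (i in 1:80) {
    mid <- sqrt(lo * hi)
    if (expected_shared_mass(mid, p, N) < target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

softmax <- function(eta) {
  w <- exp(eta - max(eta))
  w / sum(w)
}

#' Generate a synthetic broiler flock with known ground truth
#'
#' Produces an ASV count table, sample metadata, taxonomy, a random
#' phylogenetic tree and a ground-truth manifest for a flock drawn from a
#' [flock_model()]. The construction guarantees the properties the pipeline
#' is meant to detect: adjacent alimentary-tract sites are most similar
#' (distance decay), cecal pouch pairs share `pair_overlap` of their reads in
#' expectation, planted contaminants follow the inverse-concentration
#' signature, and planted cecum-enriched features carry a known fold change.
#'
#' @param model A [flock_model()].
#' @return A `flock`: list with `table` ([asv_table()]), `metadata`,
#'   `taxonomy`, `tree` (`ape::phylo`), `truth` (ground-truth list) and
#'   `model`.
#' @export
generate_flock <- function(model) {
  stopifnot(inherits(model, "flock_model"))
  set.seed(model$seed)
  nb <- model$n_birds
  nf <- model$n_features
  n_priv <- nb * model$rare_pool_per_bird
  n_cont <- model$n_contaminants
  n_total <- nf + n_priv + n_cont
  ids <- sprintf("ASV_%04d", seq_len(n_total))
  shared_ids <- ids[seq_len(nf)]
  priv_ids <- if (n_priv) ids[nf + seq_len(n_priv)] else character(0)
  cont_ids <- if (n_cont) ids[nf + n_priv + seq_len(n_cont)] else character(0)
  priv_of <- if (n_priv)
    split(priv_ids, rep(seq_len(nb), each = model$rare_pool_per_bird)) else
    rep(list(character(0)), nb)

  ## --- latent compositions -------------------------------------------------
  n_ord <- max(SITE_ORDINALS)              # 9 anatomical positions
  eta <- matrix(0, nf, n_ord)
  eta[, 1] <- stats::rnorm(nf, 0, model$base_abundance_sd)
  trend <- stats::rnorm(nf, 0, model$gradient_trend_sd)
  for (o in 2:n_ord)
    eta[, o] <- eta[, o - 1] + trend +
      stats::rnorm(nf, 0, model$gradient_step_sd)
  ## planted cecum-enriched features: mid-abundance shared features, so the
  ## fold change is detectable without letting the planted set dominate the
  ## cecal composition
  ## planted cecum-enriched features hold an explicit relative-abundance
  ## slice outside the softmax, flat across sites except for the cecal fold:
  ## this keeps "enriched by `enrichment_fold` in the ceca" true against
  ## every other site instead of being confounded with the tract gradient
  ## (a flat log-abundance row would still drift in relative abundance
  ## because the softmax denominator changes along the tract)
  enriched_ids <- character(0)
  planted_idx <- integer(0)
  planted_base <- numeric(0)
  if (model$n_planted_enriched > 0) {
    planted_idx <- sample.int(nf, model$n_planted_enriched)
    planted_base <- stats::rlnorm(model$n_planted_enriched,
                                  meanlog = log(1.5e-3), sdlog = 0.3)
    enriched_ids <- shared_ids[planted_idx]
  }
  bird_effect <- matrix(stats::rnorm(nf * nb, 0, model$bird_effect_sd), nf, nb)
  priv_mass <- model$rare_pool_per_bird * model$private_rel_abundance
  if (priv_mass >= 0.5)
    stop("rare pool mass too large; reduce rare_pool_per_bird", call. = FALSE)

  ## composition of bird b at ordinal o over all n_total features
  bird_comp <- function(b, o) {
    p <- numeric(n_total)
    planted_mass <- numeric(0)
    if (length(planted_idx)) {
      fold <- if (o == SITE_ORDINALS[["cecum"]]) model$enrichment_fold else 1
      ## the planted slice is bird-independent: the fold change is the whole
      ## of its cecal signal, so recovery tests measure the test, not the
      ## bird-to-bird noise layered on top of it
      planted_mass <- planted_base * fold
      if (sum(planted_mass) > 0.5)      # keep the slice a minority of reads
        planted_mass <- planted_mass * 0.5 / sum(planted_mass)
    }
    other <- setdiff(seq_len(nf), planted_idx)
    p[other] <- softmax(eta[other, o] + bird_effect[other, b]) *
      (1 - priv_mass - sum(planted_mass))
    p[planted_idx] <- planted_mass
    if (model$rare_pool_per_bird > 0)
      p[match(priv_of[[b]], ids)] <- model$private_rel_abundance
    p / sum(p)
  }

  ## feasibility of the pair-overlap target, checked before any count is drawn
  cecum_comp <- lapply(seq_len(nb), function(b) bird_comp(b, SITE_ORDINALS["cecum"]))
  theta <- if (model$pair_overlap < 1)
    vapply(cecum_comp, calibrate_concentration, numeric(1),
           N = model$depth_mean, target = model$pair_overlap) else
    rep(Inf, nb)

  ## --- samples -------------------------------------------------------------
  site_list <- names(SITE_ORDINALS)
  sample_rows <- list()
  count_cols <- list()
  draw_depth <- function() {
    dd <- model$depth_dispersion
    max(100L, as.integer(round(stats::rlnorm(
      1, meanlog = log(model$depth_mean) - dd^2 / 2, sdlog = dd))))
  }
  true_conc <- stats::rlnorm(nb * (length(site_list) + 1), log(20), 0.5)
  conc_i <- 0L
  cont_base <- if (n_cont) rdirichlet1(rep(2, n_cont)) else numeric(0)
  cont_noise_sd <- 0.3

  add_sample <- function(sid, bird, site, pouch, comp, is_neg, conc) {
    depth <- if (is_neg) max(50L, as.integer(round(draw_depth() / 6))) else
      draw_depth()
    x <- as.vector(stats::rmultinom(1, depth, comp))
    if (!is_neg && n_cont > 0) {
      f <- cont_base * model$contaminant_strength / conc *
        exp(stats::rnorm(n_cont, 0, cont_noise_sd))
      f <- pmin(f, 0.05)
      x[nf + n_priv + seq_len(n_cont)] <-
        x[nf + n_priv + seq_len(n_cont)] + stats::rpois(n_cont, depth * f)
    }
    count_cols[[sid]] <<- x
    sample_rows[[sid]] <<- data.frame(
      sample_id = sid, bird_id = bird, site = site,
      pouch = if (is.na(pouch)) NA_character_ else pouch,
      dna_conc = conc, is_negative = is_neg, stringsAsFactors = FALSE)
  }

  realized_overlap <- numeric(0)
  for (b in seq_len(nb)) {
    bird <- sprintf("B%d", b)
    for (site in site_list) {
      o <- SITE_ORDINALS[[site]]
      if (site == "cecum") {
        p <- cecum_comp[[b]]
        if (model$pair_overlap >= 1) {
          conc_i <- conc_i + 1L
          depth <- draw_depth()
          x <- as.vector(stats::rmultinom(1, depth, p))
          for (pch in c("left", "right")) {
            sid <- sprintf("%s_cecum_%s", bird, substr(pch, 1, 1))
            count_cols[[sid]] <- x
            sample_rows[[sid]] <- data.frame(
              sample_id = sid, bird_id = bird, site = site, pouch = pch,
              dna_conc = true_conc[conc_i], is_negative = FALSE,
              stringsAsFactors = FALSE)
          }
        } else {
          for (pch in c("left", "right")) {
            conc_i <- conc_i + 1L
            comp <- rdirichlet1(theta[b] * p)
            add_sample(sprintf("%s_cecum_%s", bird, substr(pch, 1, 1)),
                       bird, site, pch, comp, FALSE, true_conc[conc_i])
          }
        }
      } else {
        conc_i <- conc_i + 1L
        add_sample(sprintf("%s_%s", bird, site), bird, site, NA,
                   bird_comp(b, o), FALSE, true_conc[conc_i])
      }
    }
    a <- count_cols[[sprintf("%s_cecum_l", bird)]]
    bb <- count_cols[[sprintf("%s_cecum_r", bird)]]
    realized_overlap <- c(realized_overlap,
                          shared_abundance_fraction(a, bb))
  }

  ## negative controls: contaminant-dominated, low DNA concentration
  if (model$n_negatives > 0) {
    neg_conc_ceiling <- stats::quantile(true_conc[seq_len(conc_i)], 0.1)
    spill <- softmax(eta[, 1])                 # faint carry-over of real ASVs
    for (k in seq_len(model$n_negatives)) {
      comp <- numeric(n_total)
      if (n_cont) {
        comp[nf + n_priv + seq_len(n_cont)] <- 0.8 * cont_base
        comp[seq_len(nf)] <- 0.2 * spill
      } else comp[seq_len(nf)] <- spill
      comp <- comp / sum(comp)
      add_sample(sprintf("NEG%d", k), sprintf("NEG%d", k),
                 "negative_control", NA, comp, TRUE,
                 unname(neg_conc_ceiling) * stats::runif(1, 0.3, 0.9))
    }
  }

  counts <- do.call(cbind, count_cols)
  rownames(counts) <- ids
  ## drop features never observed (keeps the table honest about richness)
  observed <- rowSums(counts) > 0
  counts <- counts[observed, , drop = FALSE]
  kept <- rownames(counts)

  meta <- as_sample_metadata(do.call(rbind, sample_rows))

  ## taxonomy: fixed lineage pool; two contaminants get the named
  ## Lactobacillus species so named-taxon removal is exercised
  pool_idx <- sample.int(nrow(LINEAGE_POOL), n_total, replace = TRUE)
  tax <- LINEAGE_POOL[pool_idx, , drop = FALSE]
  tax$species <- NA_character_
  rownames(tax) <- NULL
  if (n_cont >= 1) {
    ci <- nf + n_priv + 1L
    lacto <- which(LINEAGE_POOL$genus == "Lactobacillus")[1]
    for (k in seq_len(min(2, n_cont))) {
      tax[ci + k - 1L, c("kingdom", "phylum", "class", "order",
                         "family", "genus")] <-
        LINEAGE_POOL[lacto, c("kingdom", "phylum", "class", "order",
                              "family", "genus")]
      tax$species[ci + k - 1L] <- c("L. acidipiscis", "L. helveticus")[k]
    }
  }
  taxonomy <- data.frame(feature_id = ids, tax, stringsAsFactors = FALSE)
  taxonomy <- taxonomy[taxonomy$feature_id %in% kept, , drop = FALSE]
  rownames(taxonomy) <- NULL
  class(taxonomy) <- c("taxonomy_table", "data.frame")

  tree <- ape::rtree(length(kept), tip.label = sample(kept),
                     br = stats::rexp)

  truth <- list(
    contaminant_ids = intersect(cont_ids, kept),
    enriched_ids = intersect(enriched_ids, kept),
    depleted_ids = character(0),
    private_ids = lapply(priv_of, intersect, y = kept),
    realized_pair_overlap = realized_overlap,
    site_base_eta = eta,
    concentration = theta
  )
  structure(list(table = asv_table(counts), metadata = meta,
                 taxonomy = taxonomy, tree = tree, truth = truth,
                 model = model),
            class = "flock")
}

#' @export
print.flock <- function(x, ...) {
  cat(sprintf(
    "Synthetic flock: %d birds, %d samples, %d observed features (seed %d)\n",
    x$model$n_birds, ncol(x$table), nrow(x$table), x$model$seed))
  cat(sprintf("  planted: %d contaminants, %d cecum-enriched (fold %.1f)\n",
              length(x$truth$contaminant_ids), length(x$truth$enriched_ids),
              x$model$enrichment_fold))
  invisible(x)
}

#' Write a flock to plain-text files
#'
#' Writes the count table, metadata and taxonomy as TSV, the tree as newick
#' and the ground-truth manifest (model parameters plus planted feature ids)
#' as JSON.
#'
#' @param flock A [generate_flock()] result.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_flock <- function(flock, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    table = file.path(dir, "asv_table.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    tree = file.path(dir, "tree.nwk"),
    manifest = file.path(dir, "manifest.json")
  )
  write_asv_table(flock$table, paths["table"])
  write_metadata(flock$metadata, paths["metadata"])
  write_taxonomy(flock$taxonomy, paths["taxonomy"])
  ape::write.tree(flock$tree, paths["tree"])
  manifest <- list(
    model = unclass(flock$model),
    truth = list(
      contaminant_ids = flock$truth$contaminant_ids,
      enriched_ids = flock$truth$enriched_ids,
      depleted_ids = flock$truth$depleted_ids,
      realized_pair_overlap = flock$truth$realized_pair_overlap
    )
  )
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Regenerate a flock from its manifest
#'
#' The manifest records every generative parameter including the seed, so the
#' same code version reproduces bit-identical tables.
#'
#' @param manifest A manifest list (`$model` element), a path to a manifest
#'   JSON, or a `flock`.
#' @return A `flock`, identical to the original for the same seed.
#' @export
regenerate_from_manifest <- function(manifest) {
  if (inherits(manifest, "flock")) manifest <- list(model = unclass(manifest$model))
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest,
                                                              simplifyVector = TRUE)
  params <- manifest$model
  if (is.null(params)) params <- manifest
  if (is.null(params$seed)) stop("manifest lacks a seed", call. = FALSE)
  generate_flock(do.call(flock_model, params))
}
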