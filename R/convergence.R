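# Wheatsheaf-style convergence index on a phylogeny, with permutation
# significance and a per-trait "signature trait" scan.

#' Phylogenetically penalized phenotypic distance matrix
#'
#' Euclidean distances between species trait means, inflated for close
#' relatives: `d'_ij = d_ij / sqrt(t_ij / t_max)` where `t_ij` is the
#' patristic distance and `t_max` its maximum over the tree. Phenotypic
#' similarity between close relatives is thereby discounted, so that only
#' similarity *despite* phylogenetic distance counts as convergence. The
#' penalty may differ in constants from other published implementations;
#' its ratio-of-means use below is what the index relies on.
#'
#' @param means numeric matrix of species trait means (rows named by
#'   species) — a single column for a per-trait index.
#' @param tree a `phylo` object containing all row-name species as tips.
#' @return A symmetric species x species matrix of class
#'   `penalized_dist` with zero diagonal.
#' @export
penalized_distance_matrix <- function(means, tree) {
  means <- as.matrix(means)
  sp <- rownames(means)
  if (is.null(sp)) .stopf("species means must have species row names")
  missing_sp <- setdiff(sp, tree$tip.label)
  if (length(missing_sp))
    .stopf("species missing from tree: %s", paste(missing_sp, collapse = ", "))
  d <- as.matrix(stats::dist(means))
  t_mat <- ape::cophenetic.phylo(tree)[sp, sp]
  penalty <- sqrt(t_mat / max(t_mat))
  diag(penalty) <- 1   # diagonal distances are zero anyway
  out <- d / penalty
  diag(out) <- 0
  class(out) <- c("penalized_dist", class(out))
  out
}

.upper_mean <- function(m, idx = seq_len(nrow(m))) {
  sub <- m[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Wheatsheaf convergence index for a focal species group
#'
#' Ratio of the mean phylogenetically penalized phenotypic distance over
#' all species pairs to the mean over pairs within the focal (putatively
#' convergent) group: `w > 1` indicates the focal species are more similar
#' to each other than the radiation at large, after discounting similarity
#' due to shared ancestry. Significance comes from permuting focal-set
#' membership: `n_perm` random focal sets of the same size yield a null
#' distribution of `w`, and `p = (#\{w_null >= w_obs\} + 1) / (n_perm + 1)`.
#'
#' @param means species x traits matrix of trait means computed from
#'   standardized traits (see [species_means()]); rows named by species.
#' @param tree a `phylo` object with all species as tips.
#' @param focal character vector of focal species (>= 2), e.g. the members
#'   of one ecomorph.
#' @param n_perm permutations for the significance level.
#' @param seed integer seed.
#' @return A list of class `convergence_result`: `focal_n`, `w`, `p`,
#'   `n_perm`, `per_trait` (NULL here; see [signature_scan()]).
#' @export
wheatsheaf <- function(means, tree, focal, n_perm = 999L, seed = NULL) {
  means <- as.matrix(means)
  if (length(focal) < 2L) .stopf("focal group needs at least 2 species")
  missing_sp <- setdiff(focal, rownames(means))
  if (length(missing_sp))
    .stopf("focal species missing from trait means: %s",
           paste(missing_sp, collapse = ", "))
  pd <- penalized_distance_matrix(means, tree)
  idx <- match(focal, rownames(pd))
  all_mean <- .upper_mean(pd)
  w_obs <- all_mean / .upper_mean(pd, idx)
  n <- nrow(pd)
  k <- length(idx)
  w_null <- with_seed(seed, vapply(seq_len(n_perm), function(r)
    all_mean / .upper_mean(pd, sample.int(n, k)), numeric(1L)))
  structure(list(focal_n = k, w = w_obs,
                 p = (sum(w_null >= w_obs) + 1) / (n_perm + 1),
                 n_perm = n_perm, per_trait = NULL),
            class = "convergence_result")
}

#' @export
print.convergence_result <- function(x, ...) {
  cat(sprintf("convergence_result: w = %.3f, p = %.3f (focal n = %d, %d permutations)",
              x$w, x$p, x$focal_n, x$n_perm))
  if (!is.null(x$per_trait))
    cat(sprintf("; %d signature trait(s)", sum(x$per_trait$signature)))
  cat("\n")
  invisible(x)
}

#' Per-trait convergence scan ("signature traits")
#'
#' Applies the Wheatsheaf index to every trait column separately; traits
#' whose per-trait permutation p-value falls below `alpha` are the focal
#' group's signature traits — the features convergent beyond chance. The
#' same random focal sets are reused across traits so the scan costs one
#' permutation pass.
#'
#' @inheritParams wheatsheaf
#' @param alpha signature flagging level (default 0.05).
#' @return A `convergence_result` whose `per_trait` is a data.frame
#'   (`trait`, `w_trait`, `p_trait`, `signature`).
#' @export
signature_scan <- function(means, tree, focal, n_perm = 999L, seed = NULL,
                           alpha = 0.05) {
  res <- wheatsheaf(means, tree, focal, n_perm = n_perm, seed = seed)
  means <- as.matrix(means)
  n <- nrow(means)
  k <- length(focal)
  idx <- match(focal, rownames(means))
  sp <- rownames(means)
  t_mat <- ape::cophenetic.phylo(tree)[sp, sp]
  penalty <- sqrt(t_mat / max(t_mat))
  diag(penalty) <- 1
  ut <- upper.tri(penalty)
  null_sets <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, "scan"),
                         replicate(n_perm, sample.int(n, k), simplify = FALSE))
  p_tr <- w_tr <- numeric(ncol(means))
  for (j in seq_len(ncol(means))) {
    d <- abs(outer(means[, j], means[, j], `-`)) / penalty
    diag(d) <- 0
    all_mean <- mean(d[ut])
    w_tr[j] <- all_mean / .upper_mean(d, idx)
    w_null <- vapply(null_sets, function(s) all_mean / .upper_mean(d, s),
                     numeric(1L))
    p_tr[j] <- (sum(w_null >= w_tr[j]) + 1) / (n_perm + 1)
  }
  res$per_trait <- data.frame(trait = colnames(means), w_trait = w_tr,
                              p_trait = p_tr, signature = p_tr < alpha,
                              stringsAsFactors = FALSE)
  res
}

#' Species trait means from a standardized trait matrix
#'
#' Row means per species (individuals pooled with equal weight), computed
#' after standardization so shape and linear traits contribute on the same
#' scale; no standard-error weighting is applied.
#'
#' @param traits a [trait_matrix()] or matrix with specimen rows.
#' @param species species label per row.
#' @return species x traits matrix with species row names.
#' @export
species_means <- function(traits, species) {
  x <- if (inherits(traits, "trait_matrix")) traits$values else as.matrix(traits)
  if (length(species) != nrow(x))
    .stopf("species has length %d for %d rows", length(species), nrow(x))
  rowsum(x, species) / as.vector(table(species)[sort(unique(species))])
}
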