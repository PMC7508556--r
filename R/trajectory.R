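# Phenotypic trajectory analysis: t-value vectors between ecomorph groups,
# the angle (theta) and length difference (delta L) between island
# trajectories, permutation and bootstrap significance, quartet
# enumeration, cross-method validation and outlier-based trait ranking.

# Vectorized two-sample t statistics per column. Zero-variance columns get
# t = 0 (count returned so callers can warn outside hot loops).
.tstats <- function(a, b, var_equal = FALSE) {
  na <- nrow(a)
  nb <- nrow(b)
  ma <- colMeans(a)
  mb <- colMeans(b)
  va <- colSums((a - rep(ma, each = na))^2) / (na - 1L)
  vb <- colSums((b - rep(mb, each = nb))^2) / (nb - 1L)
  se <- if (var_equal) {
    sqrt(((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L) * (1 / na + 1 / nb))
  } else {
    sqrt(va / na + vb / nb)
  }
  t <- (ma - mb) / se
  zero <- !is.finite(t)
  t[zero] <- 0
  attr(t, "n_zero_variance") <- sum(zero)
  t
}

.new_trajectory_vector <- function(values, contrast, n_a, n_b, method) {
  structure(list(t_values = values, contrast = contrast,
                 n_A = n_a, n_B = n_b, method = method,
                 L = sqrt(sum(values^2))),
            class = "trajectory_vector")
}

#' t-value trajectory vector between two groups
#'
#' For every trait, the independent two-sample t statistic contrasting
#' group A against group B (sign convention mean(A) - mean(B)): the
#' difference in trait means expressed in units of its standard error. The
#' resulting vector describes the direction and magnitude (length `L`) of
#' divergence between the groups in the standardized multivariate trait
#' space.
#'
#' @param a,b numeric matrices (specimens x traits) for groups A and B,
#'   with identical columns; both need at least 2 rows.
#' @param method `"welch"` (default, unequal variances) or `"pooled"`
#'   (classical equal-variance t).
#' @param contrast length-2 character vector of group labels.
#' @return An object of class `trajectory_vector` with fields `t_values`,
#'   `contrast`, `n_A`, `n_B`, `method` and `L` (Euclidean length).
#' @export
t_vector <- function(a, b, method = c("welch", "pooled"),
                     contrast = c("A", "B")) {
  method <- match.arg(method)
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (ncol(a) != ncol(b)) .stopf("groups have different trait sets")
  if (nrow(a) < 2L || nrow(b) < 2L)
    .stopf("both groups need at least 2 specimens (got %d, %d)",
           nrow(a), nrow(b))
  t <- .tstats(a, b, var_equal = method == "pooled")
  if (attr(t, "n_zero_variance") > 0L)
    .warnf("%d trait(s) with zero variance in contrast %s vs %s; t set to 0",
           attr(t, "n_zero_variance"), contrast[1L], contrast[2L])
  attr(t, "n_zero_variance") <- NULL
  .new_trajectory_vector(t, contrast, nrow(a), nrow(b),
                         paste0("t_statistic_", method))
}

#' Mean-difference trajectory vector between two groups
#'
#' Per-trait difference in group means, mean(A) - mean(B); the alternative
#' phenotypic-change-vector parameterisation used to cross-validate the
#' t-value trajectories.
#'
#' @inheritParams t_vector
#' @return A `trajectory_vector` with `method = "mean_difference"`.
#' @export
mean_difference_vector <- function(a, b, contrast = c("A", "B")) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (ncol(a) != ncol(b)) .stopf("groups have different trait sets")
  .new_trajectory_vector(colMeans(a) - colMeans(b), contrast,
                         nrow(a), nrow(b), "mean_difference")
}

#' @export
print.trajectory_vector <- function(x, ...) {
  cat(sprintf("trajectory_vector (%s): %s vs %s (n = %d, %d), %d traits, L = %.3f\n",
              x$method, x$contrast[1L], x$contrast[2L], x$n_A, x$n_B,
              length(x$t_values), x$L))
  invisible(x)
}

.vec <- function(v) {
  if (inherits(v, "trajectory_vector")) return(v$t_values)
  stopifnot(is.numeric(v))
  v   # keep names
}

# angle between two bare numeric vectors, degrees; NA if either is zero
# (can happen for degenerate resamples inside the permutation/bootstrap
# loops, where such replicates are simply not counted)
.angle_deg <- function(a, b) {
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NA_real_)
  r <- sum(a * b) / den
  acos(min(1, max(-1, r))) * 180 / pi
}

#' Angle between two trajectory vectors
#'
#' Arc cosine of the cosine similarity, in degrees; 0 means the two
#' divergences are parallel, 90 that they are unrelated in direction. The
#' dot/norm ratio is clipped to [-1, 1] before the arc cosine so the result
#' lies in [0, 180] even under rounding.
#'
#' @param a,b `trajectory_vector`s or bare numeric vectors of equal length.
#' @return Angle in degrees, in [0, 180].
#' @export
vector_angle <- function(a, b) {
  a <- .vec(a)
  b <- .vec(b)
  if (length(a) != length(b)) .stopf("vectors differ in length")
  if (sum(a^2) == 0 || sum(b^2) == 0)
    .stopf("angle undefined for a zero-length vector")
  .angle_deg(a, b)
}

#' Difference in length between two trajectory vectors
#'
#' `L(a) - L(b)`: the difference in the magnitude of divergence.
#' Antisymmetric under swapping the arguments.
#'
#' @inheritParams vector_angle
#' @return A single number (positive when `a` is the longer vector).
#' @export
delta_length <- function(a, b) {
  a <- .vec(a)
  b <- .vec(b)
  sqrt(sum(a^2)) - sqrt(sum(b^2))
}

#' Enumerate ecomorph-pair x island-pair quartets
#'
#' All combinations of an ecomorph pair and an island pair in which both
#' ecomorphs have at least `min_n` specimens on both islands — the
#' comparisons for which trajectory vectors can be computed on each island
#' and compared between islands. Ordering is deterministic: ecomorph pairs
#' lexicographic, then island pairs lexicographic.
#'
#' @param records data.frame with columns `ecomorph` and `island` (one row
#'   per specimen), e.g. the `records` of a [morph_dataset()].
#' @param min_n minimum specimens per ecomorph x island cell (default 2,
#'   the smallest group a t statistic allows).
#' @return data.frame of class `quartet_list` with columns `e1`, `e2`,
#'   `i1`, `i2`.
#' @export
enumerate_quartets <- function(records, min_n = 2L) {
  records <- records[!is.na(records$ecomorph) & !is.na(records$island), ]
  counts <- table(records$ecomorph, records$island)
  ecos <- sort(rownames(counts))
  isls <- sort(colnames(counts))
  out <- list()
  for (a in seq_along(ecos)) for (b in seq_along(ecos)) {
    if (a >= b) next
    for (i in seq_along(isls)) for (j in seq_along(isls)) {
      if (i >= j) next
      cells <- counts[c(ecos[a], ecos[b]), c(isls[i], isls[j])]
      if (all(cells >= min_n))
        out[[length(out) + 1L]] <- data.frame(
          e1 = ecos[a], e2 = ecos[b], i1 = isls[i], i2 = isls[j],
          stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(e1 = character(0), e2 = character(0),
                         i1 = character(0), i2 = character(0))
  class(res) <- c("quartet_list", "data.frame")
  res
}

# Extract the four cell matrices of a quartet; traits may be a trait_matrix
# or a plain matrix with specimen row names matching records$specimen_id.
.quartet_cells <- function(quartet, traits, records) {
  x <- if (inherits(traits, "trait_matrix")) traits$values else as.matrix(traits)
  pick <- function(e, i) {
    ids <- records$specimen_id[records$ecomorph %in% e & records$island %in% i]
    x[ids[ids %in% rownames(x)], , drop = FALSE]
  }
  list(a1 = pick(quartet$e1, quartet$i1), b1 = pick(quartet$e2, quartet$i1),
       a2 = pick(quartet$e1, quartet$i2), b2 = pick(quartet$e2, quartet$i2))
}

#' Observed trajectory vectors of a quartet
#'
#' One t-value (or mean-difference) vector per island for the quartet's
#' ecomorph contrast, sign convention e1 - e2.
#'
#' @param quartet one row of [enumerate_quartets()] (or a list with `e1`,
#'   `e2`, `i1`, `i2`).
#' @param traits a standardized [trait_matrix()] (or matrix with specimen
#'   row names).
#' @param records specimen metadata data.frame (`specimen_id`, `ecomorph`,
#'   `island`).
#' @param method trajectory parameterisation: `"welch"`, `"pooled"` or
#'   `"mean_difference"`.
#' @return List with trajectory vectors `v1` (island i1) and `v2` (i2).
#' @export
quartet_vectors <- function(quartet, traits, records, method = "welch") {
  cells <- .quartet_cells(quartet, traits, records)
  mk <- function(a, b, island) {
    lab <- c(paste(quartet$e1, island, sep = "@"),
             paste(quartet$e2, island, sep = "@"))
    if (method == "mean_difference") mean_difference_vector(a, b, lab)
    else t_vector(a, b, method = method, contrast = lab)
  }
  list(v1 = mk(cells$a1, cells$b1, quartet$i1),
       v2 = mk(cells$a2, cells$b2, quartet$i2))
}

#' Permutation test of parallelism for one quartet
#'
#' Simulates the parallel null by shuffling island labels among the
#' specimens of each ecomorph (within-ecomorph, preserving the per-island
#' cell sizes), recomputing both island trajectory vectors and their angle
#' theta and length difference delta L for each permutation. The observed
#' angle is significantly non-parallel when few permuted angles reach it:
#' `p_parallel = (#\{theta_null >= theta_obs\} + 1) / (n_perm + 1)`, and
#' `p_length` analogously on `|delta L|`.
#'
#' @inheritParams quartet_vectors
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for reproducibility.
#' @param shuffle `"within-ecomorph"` (default reading of the permutation
#'   scheme) or `"across"` (island labels shuffled over all four cells
#'   jointly).
#' @return List with `theta`, `delta_L`, `p_parallel`, `p_length`,
#'   `n_perm`, `seed`.
#' @export
permutation_parallel_test <- function(quartet, traits, records,
                                      n_perm = 999L, seed = NULL,
                                      method = "welch",
                                      shuffle = c("within-ecomorph", "across")) {
  shuffle <- match.arg(shuffle)
  if (n_perm < 99L) .stopf("n_perm must be at least 99")
  cells <- .quartet_cells(quartet, traits, records)
  ns <- vapply(cells, nrow, integer(1L))
  if (any(ns < 2L))
    .stopf("cell(s) with fewer than 2 specimens in quartet %s/%s x %s/%s",
           quartet$e1, quartet$e2, quartet$i1, quartet$i2)
  var_equal <- method == "pooled"
  xa <- rbind(cells$a1, cells$a2)
  xb <- rbind(cells$b1, cells$b2)
  na1 <- ns[["a1"]]
  nb1 <- ns[["b1"]]
  v1 <- .tstats(cells$a1, cells$b1, var_equal)
  v2 <- .tstats(cells$a2, cells$b2, var_equal)
  theta_obs <- .angle_deg(v1, v2)
  dl_obs <- sqrt(sum(v1^2)) - sqrt(sum(v2^2))
  theta_null <- numeric(n_perm)
  dl_null <- numeric(n_perm)
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      if (shuffle == "within-ecomorph") {
        ia <- sample.int(nrow(xa))
        ib <- sample.int(nrow(xb))
        a1 <- xa[ia[seq_len(na1)], , drop = FALSE]
        a2 <- xa[ia[-seq_len(na1)], , drop = FALSE]
        b1 <- xb[ib[seq_len(nb1)], , drop = FALSE]
        b2 <- xb[ib[-seq_len(nb1)], , drop = FALSE]
      } else {
        # shuffle island labels across the whole quartet: permute specimens
        # within each ecomorph column jointly with a single island relabelling
        ix <- sample.int(nrow(xa) + nrow(xb))
        pooled <- rbind(xa, xb)
        isl1 <- ix[seq_len(na1 + nb1)]
        isl2 <- ix[-seq_len(na1 + nb1)]
        a1 <- pooled[isl1[seq_len(na1)], , drop = FALSE]
        b1 <- pooled[isl1[-seq_len(na1)], , drop = FALSE]
        a2 <- pooled[isl2[seq_len(ns[["a2"]])], , drop = FALSE]
        b2 <- pooled[isl2[-seq_len(ns[["a2"]])], , drop = FALSE]
      }
      p1 <- .tstats(a1, b1, var_equal)
      p2 <- .tstats(a2, b2, var_equal)
      theta_null[r] <- .angle_deg(p1, p2)
      dl_null[r] <- sqrt(sum(p1^2)) - sqrt(sum(p2^2))
    }
  })
  list(theta = theta_obs, delta_L = dl_obs,
       p_parallel = (sum(theta_null >= theta_obs, na.rm = TRUE) + 1) /
         (n_perm + 1),
       p_length = (sum(abs(dl_null) >= abs(dl_obs), na.rm = TRUE) + 1) /
         (n_perm + 1),
       n_perm = n_perm, seed = seed)
}

#' Bootstrap test of the angle against orthogonality (90 degrees)
#'
#' Resamples specimens with replacement within each ecomorph x island cell
#' (cell sizes preserved), recomputes the angle theta per replicate, and
#' rejects orthogonality when almost no bootstrap angle reaches 90:
#' `p_orthogonal = (#\{theta_boot >= 90\} + 1) / (n_boot + 1)`.
#'
#' @inheritParams permutation_parallel_test
#' @param n_boot number of bootstrap replicates (>= 99).
#' @return List with `theta`, `p_orthogonal`, `theta_boot` (the replicate
#'   angles), `n_boot`, `seed`.
#' @export
bootstrap_orthogonality_test <- function(quartet, traits, records,
                                         n_boot = 999L, seed = NULL,
                                         method = "welch") {
  if (n_boot < 99L) .stopf("n_boot must be at least 99")
  cells <- .quartet_cells(quartet, traits, records)
  ns <- vapply(cells, nrow, integer(1L))
  if (any(ns < 1L)) .stopf("empty cell in quartet")
  if (any(ns < 2L))
    .warnf("cell(s) of size 1: bootstrap resampling is degenerate")
  var_equal <- method == "pooled"
  v1 <- .tstats(cells$a1, cells$b1, var_equal)
  v2 <- .tstats(cells$a2, cells$b2, var_equal)
  theta_obs <- .angle_deg(v1, v2)
  theta_boot <- numeric(n_boot)
  with_seed(seed, {
    for (r in seq_len(n_boot)) {
      res <- lapply(cells, function(m)
        m[sample.int(nrow(m), replace = TRUE), , drop = FALSE])
      b1 <- .tstats(res$a1, res$b1, var_equal)
      b2 <- .tstats(res$a2, res$b2, var_equal)
      theta_boot[r] <- .angle_deg(b1, b2)
    }
  })
  list(theta = theta_obs,
       p_orthogonal = (sum(theta_boot >= 90, na.rm = TRUE) + 1) / (n_boot + 1),
       theta_boot = theta_boot, n_boot = n_boot, seed = seed)
}

#' Classify a quartet's alignment from its two tests
#'
#' Combines the parallelism permutation test and the orthogonality
#' bootstrap at level `alpha`: failure to reject the parallel null means
#' the angle is indistinguishable from 0 degrees; failure to reject
#' orthogonality means indistinguishable from 90; rejecting both places
#' the angle between 0 and 90. When neither test rejects, the quartet is
#' flagged `"ambiguous"` with a warning.
#'
#' @param p_parallel p-value of [permutation_parallel_test()].
#' @param p_orthogonal p-value of [bootstrap_orthogonality_test()].
#' @param alpha significance level (default 0.05).
#' @return One of `"indistinguishable_from_0"`, `"between_0_and_90"`,
#'   `"indistinguishable_from_90"`, `"ambiguous"`.
#' @export
classify_quartet <- function(p_parallel, p_orthogonal, alpha = 0.05) {
  par_ok <- p_parallel >= alpha     # parallel null not rejected
  orth_ok <- p_orthogonal >= alpha  # orthogonality not rejected
  if (par_ok && orth_ok) {
    .warnf("neither parallelism nor orthogonality rejected; quartet ambiguous")
    return("ambiguous")
  }
  if (par_ok) return("indistinguishable_from_0")
  if (orth_ok) return("indistinguishable_from_90")
  "between_0_and_90"
}

#' Full angle/length test battery for one quartet
#'
#' Convenience wrapper running [quartet_vectors()],
#' [permutation_parallel_test()], [bootstrap_orthogonality_test()] and
#' [classify_quartet()] in one call.
#'
#' @inheritParams permutation_parallel_test
#' @param n_boot bootstrap replicates.
#' @param alpha significance level for the classification.
#' @return A list of class `angle_test`: `theta`, `delta_L`, `p_parallel`,
#'   `p_length`, `p_orthogonal`, `classification`, `n_perm`, `n_boot`,
#'   `seed`.
#' @export
quartet_angle_test <- function(quartet, traits, records, n_perm = 999L,
                               n_boot = 999L, seed = NULL, method = "welch",
                               alpha = 0.05) {
  perm <- permutation_parallel_test(quartet, traits, records, n_perm = n_perm,
                                    seed = seed, method = method)
  boot <- bootstrap_orthogonality_test(quartet, traits, records,
                                       n_boot = n_boot,
                                       seed = if (is.null(seed)) NULL
                                              else derive_seed(seed, "boot"),
                                       method = method)
  cls <- suppressWarnings(classify_quartet(perm$p_parallel,
                                           boot$p_orthogonal, alpha))
  structure(list(theta = perm$theta, delta_L = perm$delta_L,
                 p_parallel = perm$p_parallel, p_length = perm$p_length,
                 p_orthogonal = boot$p_orthogonal, classification = cls,
                 n_perm = n_perm, n_boot = n_boot, seed = seed),
            class = "angle_test")
}

#' @export
print.angle_test <- function(x, ...) {
  cat(sprintf(
    "angle_test: theta = %.2f deg, delta_L = %.2f; p_parallel = %.3f, p_length = %.3f, p_orthogonal = %.3f -> %s\n",
    x$theta, x$delta_L, x$p_parallel, x$p_length, x$p_orthogonal,
    x$classification))
  invisible(x)
}

#' Outlier scan over the elements of a trajectory vector
#'
#' Standardizes the per-trait t-values against their own distribution
#' (z = (t - mean) / sd over the vector's elements) and flags traits whose
#' |z| exceeds the normal quantile at `prob` — the traits with
#' significantly higher or lower t-values than the rest, i.e. the traits
#' contributing most to the contrast ("most divergent" / "most plastic"
#' trait sets).
#'
#' @param v a `trajectory_vector` or numeric vector with names.
#' @param prob two-sided flagging quantile (default 0.95).
#' @return A list of class `outlier_scan`: `z_scores`, `flagged` (column
#'   names), `prob`, `threshold`.
#' @export
outlier_traits <- function(v, prob = 0.95) {
  t <- .vec(v)
  if (is.null(names(t)) && inherits(v, "trajectory_vector"))
    names(t) <- names(v$t_values)
  s <- stats::sd(t)
  if (!is.finite(s) || s == 0) .stopf("constant trajectory vector")
  z <- (t - mean(t)) / s
  thr <- stats::qnorm(prob)
  flagged <- names(z)[abs(z) > thr]
  if (is.null(flagged)) flagged <- which(abs(z) > thr)
  structure(list(z_scores = z, flagged = flagged, prob = prob,
                 threshold = thr), class = "outlier_scan")
}

#' @export
print.outlier_scan <- function(x, ...) {
  cat(sprintf("outlier_scan: %d of %d traits flagged (|z| > %.3f at prob %.3g)\n",
              length(x$flagged), length(x$z_scores), x$threshold, x$prob))
  invisible(x)
}

#' Correlation of quartet angles between the two trajectory methods
#'
#' Pearson correlation across quartets between the angle theta computed
#' from t-value vectors and from mean-difference vectors — the cross-method
#' consistency check of the trajectory parameterisation.
#'
#' @param quartets a [enumerate_quartets()] table (>= 3 rows).
#' @param traits a standardized [trait_matrix()] or matrix.
#' @param records specimen metadata.
#' @param method the t-statistic variant for the first method.
#' @return Pearson correlation coefficient.
#' @export
angle_method_correlation <- function(quartets, traits, records,
                                     method = "welch") {
  if (nrow(quartets) < 3L) .stopf("need at least 3 quartets")
  th <- matrix(NA_real_, nrow(quartets), 2L)
  for (q in seq_len(nrow(quartets))) {
    qt <- quartets[q, ]
    vt <- quartet_vectors(qt, traits, records, method = method)
    vm <- quartet_vectors(qt, traits, records, method = "mean_difference")
    th[q, 1L] <- vector_angle(vt$v1, vt$v2)
    th[q, 2L] <- vector_angle(vm$v1, vm$v2)
  }
  stats::cor(th[, 1L], th[, 2L])
}
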