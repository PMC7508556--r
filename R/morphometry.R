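# From raw landmarks and linear bone measurements to the scaled trait
# matrix: mirroring, generalized Procrustes superimposition, PCA-based
# imputation, size correction, standard-normal-deviate scaling, Procrustes
# ANOVA repeatability and variance summaries.

#' Reflect a right-side landmark configuration onto the left side
#'
#' Negates one coordinate axis so that right-side girdles can be pooled
#' with left-side ones before superimposition (superimposition here is
#' rotation-only, so reflections must be undone beforehand). Applying the
#' mirror twice returns the input exactly.
#'
#' @param config a [landmark_configuration()] with `side = "right"` (a
#'   left-side input is mirrored to the right, for completeness).
#' @param axis which coordinate to negate: `"x"` (default), `"y"` or `"z"`.
#' @return The mirrored `landmark_config` with the side label flipped.
#' @export
mirror_configuration <- function(config, axis = "x") {
  stopifnot(inherits(config, "landmark_config"))
  j <- match(axis, c("x", "y", "z"))
  if (is.na(j)) .stopf("axis must be one of x, y, z")
  coords <- config$coords
  coords[, j] <- -coords[, j]
  landmark_configuration(coords, structure = config$structure,
                         side = if (config$side == "right") "left" else "right")
}

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks from their
#' centroid; the pelvic-girdle value serves as the body-size proxy.
#'
#' @param config a [landmark_configuration()] or a bare k x 3 matrix.
#' @return A single positive number (mm).
#' @export
centroid_size <- function(config) {
  coords <- if (inherits(config, "landmark_config")) config$coords
            else as.matrix(config)
  centered <- sweep(coords, 2L, colMeans(coords))
  sqrt(sum(centered^2))
}

# Right-handed principal-axis rotation of a centered configuration, with
# the sign of the first two axes fixed by the largest-magnitude projection
# (the third axis is their cross product, keeping det = +1).
.principal_axes <- function(m) {
  v <- svd(m)$v
  for (j in 1:2) {
    pc <- m %*% v[, j]
    if (pc[which.max(abs(pc))] < 0) v[, j] <- -v[, j]
  }
  v[, 3L] <- c(v[2L, 1L] * v[3L, 2L] - v[3L, 1L] * v[2L, 2L],
               v[3L, 1L] * v[1L, 2L] - v[1L, 1L] * v[3L, 2L],
               v[1L, 1L] * v[2L, 2L] - v[2L, 1L] * v[1L, 2L])
  v
}

# Optimal rotation-only (det = +1) alignment of X onto M, both centered.
.opa_rotate <- function(x, m) {
  s <- svd(crossprod(x, m))
  r <- s$u %*% t(s$v)
  if (det(r) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    r <- u %*% t(s$v)
  }
  x %*% r
}

#' Generalized Procrustes analysis of landmark configurations
#'
#' Translates each configuration to centroid origin, scales to unit
#' centroid size and iteratively rotates all configurations (rotation-only
#' orthogonal Procrustes, determinant +1) to the evolving mean shape until
#' the mean shape stabilises. No projection to tangent space and no
#' dimension reduction is applied: analyses proceed on the raw Procrustes
#' shape variables, redundant degrees of freedom included.
#'
#' @param configs list of [landmark_configuration()] objects, all of the
#'   same structure and all left-side (mirror right-side girdles first with
#'   [mirror_configuration()]).
#' @param tol convergence tolerance on the root-sum-square change of the
#'   mean shape between iterations.
#' @param max_iter iteration cap.
#' @return An object of class `gpa_result` with elements `aligned`
#'   (n x 18 x 3 array of Procrustes shape variables), `centroid_sizes`
#'   (original sizes, mm), `mean_shape` (18 x 3), `iterations`,
#'   `converged`, and `structure`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 200L) {
  if (!length(configs)) .stopf("gpa needs at least one configuration")
  stopifnot(all(vapply(configs, inherits, logical(1L), "landmark_config")))
  structs <- unique(vapply(configs, `[[`, character(1L), "structure"))
  if (length(structs) > 1L)
    .stopf("configurations mix structures: %s", paste(structs, collapse = ", "))
  sides <- vapply(configs, `[[`, character(1L), "side")
  if (any(sides != "left"))
    .stopf("%d right-side configuration(s); mirror them before gpa",
           sum(sides != "left"))
  n <- length(configs)
  k <- nrow(configs[[1L]]$coords)
  cs <- numeric(n)
  arr <- array(NA_real_, c(n, k, 3L))
  for (i in seq_len(n)) {
    centered <- sweep(configs[[i]]$coords, 2L, colMeans(configs[[i]]$coords))
    cs[i] <- sqrt(sum(centered^2))
    if (cs[i] < .Machine$double.eps^0.5)
      .stopf("degenerate configuration %d: zero centroid size", i)
    arr[i, , ] <- centered / cs[i]
  }
  names(cs) <- names(configs)
  dimnames(arr) <- list(names(configs), sprintf("L%02d", seq_len(k)),
                        c("x", "y", "z"))
  iterations <- 0L
  converged <- TRUE
  if (n > 1L) {
    mshape <- arr[1L, , ]
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      for (i in seq_len(n)) arr[i, , ] <- .opa_rotate(arr[i, , ], mshape)
      new_mean <- apply(arr, c(2L, 3L), mean)
      delta <- sqrt(sum((new_mean - mshape)^2))
      mshape <- new_mean
      iterations <- it
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
  } else {
    mshape <- arr[1L, , ]
  }
  # canonical orientation: principal axes of the mean shape with a
  # deterministic sign convention, so the output does not depend on the
  # (arbitrary) orientation of the input configurations; a single
  # configuration is returned as centred/unit-scaled without rotation
  if (n > 1L) {
    rot <- .principal_axes(mshape)
    mshape <- mshape %*% rot
    for (i in seq_len(n)) arr[i, , ] <- arr[i, , ] %*% rot
  }
  dimnames(mshape) <- dimnames(arr)[2:3]
  structure(list(aligned = arr, centroid_sizes = cs, mean_shape = mshape,
                 iterations = iterations, converged = converged,
                 structure = structs), class = "gpa_result")
}

#' @export
print.gpa_result <- function(x, ...) {
  cat(sprintf("gpa_result: %d %s configurations, %d iterations (%s)\n",
              dim(x$aligned)[1L], x$structure, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Flatten aligned configurations to a shape-variable matrix
#'
#' @param x a `gpa_result`.
#' @param prefix column-name prefix, e.g. `"shape_pec_"`.
#' @return n x (18*3) matrix with columns `<prefix>L01_x`, `<prefix>L01_y`, ...
#' @export
shape_variables <- function(x, prefix = "shape_") {
  stopifnot(inherits(x, "gpa_result"))
  d <- dim(x$aligned)
  out <- matrix(aperm(x$aligned, c(1L, 3L, 2L)), nrow = d[1L])
  colnames(out) <- as.vector(t(outer(sprintf("%sL%02d", prefix, seq_len(d[2L])),
                                     c("x", "y", "z"), paste, sep = "_")))
  rownames(out) <- dimnames(x$aligned)[[1L]]
  out
}

#' Impute missing linear measurements by iterative PCA
#'
#' Missing cells are initialised with column means, then alternately
#' replaced by a rank-`q` principal-component reconstruction of the
#' column-centred matrix until the largest absolute change falls below
#' `tol`. Observed cells are never altered.
#'
#' @param x numeric matrix or data.frame with `NA` cells; every column
#'   needs at least 2 observed values and every row at least 1.
#' @param q reconstruction rank (default 3, clamped to the data dimensions).
#' @param tol convergence tolerance on imputed cells.
#' @param max_iter iteration cap.
#' @return The completed matrix, with an attribute `"iterations"`.
#' @export
impute_missing <- function(x, q = 3L, tol = 1e-8, max_iter = 500L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  miss <- is.na(x)
  if (!any(miss)) return(x)
  if (any(rowSums(!miss) == 0L)) .stopf("row(s) entirely missing")
  if (any(colSums(!miss) < 2L))
    .stopf("column(s) with fewer than 2 observed values: %s",
           paste(colnames(x)[colSums(!miss) < 2L], collapse = ", "))
  frac <- mean(miss)
  if (frac > 0.1) .warnf("missing fraction %.1f%% exceeds 10%%", 100 * frac)
  q <- max(1L, min(q, nrow(x) - 1L, ncol(x)))
  mu <- colMeans(x, na.rm = TRUE)
  filled <- x
  filled[miss] <- rep(mu, each = nrow(x))[miss]
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    mu <- colMeans(filled)
    centred <- sweep(filled, 2L, mu)
    s <- svd(centred, nu = q, nv = q)
    recon <- s$u %*% (diag(s$d[seq_len(q)], q, q) %*% t(s$v))
    recon <- sweep(recon, 2L, mu, `+`)
    delta <- max(abs(recon[miss] - filled[miss]))
    filled[miss] <- recon[miss]
    iterations <- it
    if (delta < tol) break
  }
  attr(filled, "iterations") <- iterations
  filled
}

#' Size-correct linear measurements by the body-size proxy
#'
#' Divides each specimen's raw lengths and thicknesses by its pelvic-girdle
#' centroid size, yielding relative (size-free) measures.
#'
#' @param linear numeric matrix or data.frame of raw measurements (mm),
#'   rows = specimens.
#' @param sizes vector of strictly positive centroid sizes (mm), aligned to
#'   the rows of `linear`.
#' @return Matrix of the same shape as `linear`.
#' @export
size_correct <- function(linear, sizes) {
  linear <- as.matrix(linear)
  if (length(sizes) != nrow(linear))
    .stopf("sizes has length %d but linear has %d rows",
           length(sizes), nrow(linear))
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    .stopf("centroid sizes must be strictly positive")
  sweep(linear, 1L, sizes, `/`)
}

#' Construct a trait matrix
#'
#' @param values numeric matrix, rows = specimens, columns = traits.
#' @param column_class character vector (per column) in
#'   `{shape, length, thickness, size}`; derived from name prefixes when
#'   omitted.
#' @param scaling optional data.frame (`column`, `mean`, `sd`) recording the
#'   standardization applied.
#' @return An object of class `trait_matrix`.
#' @export
trait_matrix <- function(values, column_class = NULL, scaling = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(column_class))
    column_class <- .trait_class_from_name(colnames(values))
  if (length(column_class) != ncol(values))
    .stopf("column_class has length %d for %d columns",
           length(column_class), ncol(values))
  structure(list(values = values, column_class = column_class,
                 scaling = scaling), class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  tab <- table(factor(x$column_class, c("shape", "length", "thickness", "size")))
  cat(sprintf(
    "trait_matrix: %d specimens x %d traits (%d shape, %d length, %d thickness, %d size)%s\n",
    nrow(x$values), ncol(x$values), tab["shape"], tab["length"],
    tab["thickness"], tab["size"],
    if (is.null(x$scaling)) ", unscaled" else ", standardized"))
  invisible(x)
}

#' Scale traits to standard normal deviates
#'
#' Centres every column to zero and divides by its sample standard
#' deviation (n-1 denominator), placing shape variables and linear measures
#' on a commensurate scale so that vector-based trajectory analyses can
#' combine them. The per-column means and sds are stored so further rows
#' can be projected onto the same scale.
#'
#' @param x numeric matrix, data.frame, or `trait_matrix` of raw trait
#'   values (no missing cells).
#' @param scaling optional scaling record from a previous call; when given,
#'   its means/sds are applied instead of recomputing (projection onto an
#'   existing scale).
#' @return A [trait_matrix()] whose `scaling` field records the transform.
#' @export
standardize_traits <- function(x, scaling = NULL) {
  cls <- NULL
  if (inherits(x, "trait_matrix")) {
    cls <- x$column_class
    x <- x$values
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) .stopf("trait matrix contains missing values; impute first")
  if (is.null(scaling)) {
    m <- colMeans(x)
    s <- apply(x, 2L, stats::sd)
    const <- which(s == 0 | !is.finite(s))
    if (length(const))
      .stopf("constant trait column(s): %s",
             paste(colnames(x)[const], collapse = ", "))
    scaling <- data.frame(column = colnames(x), mean = m, sd = s,
                          row.names = NULL, stringsAsFactors = FALSE)
  } else {
    if (!all(scaling$column == colnames(x)))
      .stopf("scaling record columns do not match the trait matrix")
    m <- scaling$mean
    s <- scaling$sd
  }
  z <- sweep(sweep(x, 2L, m), 2L, s, `/`)
  trait_matrix(z, column_class = cls, scaling = scaling)
}

#' Write / read a trait matrix with its scaling record
#'
#' The matrix goes to `path` as a delimited table (first column
#' `specimen_id`); the per-column (mean, sd) scaling record goes to a
#' plain-text sidecar `<path>.scaling`.
#'
#' @param traits a [trait_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_matrix <- function(traits, path) {
  stopifnot(inherits(traits, "trait_matrix"))
  df <- data.frame(specimen_id = rownames(traits$values),
                   traits$values, check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  if (!is.null(traits$scaling))
    utils::write.table(traits$scaling, paste0(path, ".scaling"), sep = ",",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_matrix
#' @export
read_trait_matrix <- function(path) {
  df <- .read_delim_auto(path)
  values <- as.matrix(df[setdiff(names(df), "specimen_id")])
  rownames(values) <- df$specimen_id
  scaling <- NULL
  sidecar <- paste0(path, ".scaling")
  if (file.exists(sidecar)) scaling <- .read_delim_auto(sidecar)
  trait_matrix(values, scaling = scaling)
}

#' Assemble the combined trait matrix
#'
#' Binds, in fixed column order, the pectoral shape variables (54), pelvic
#' shape variables (54), size-corrected limb lengths (15), size-corrected
#' bone thicknesses (8) and the pelvic centroid size (1), then standardizes
#' every column over the supplied analysis population. Specimens present in
#' only one girdle superimposition are excluded with a warning.
#'
#' @param gpa_pec,gpa_pel `gpa_result` objects for the pectoral and pelvic
#'   girdles (aligned arrays must carry specimen names).
#' @param corrected_linear size-corrected linear table, rows named by
#'   specimen, columns prefixed `len_` / `thick_`.
#' @return A standardized [trait_matrix()] with specimens as row names.
#' @export
assemble_traits <- function(gpa_pec, gpa_pel, corrected_linear) {
  pec <- shape_variables(gpa_pec, "shape_pec_")
  pel <- shape_variables(gpa_pel, "shape_pel_")
  corrected_linear <- as.matrix(corrected_linear)
  lin_cls <- .trait_class_from_name(colnames(corrected_linear))
  if (anyNA(lin_cls))
    .stopf("linear column(s) lack a len_/thick_ prefix: %s",
           paste(colnames(corrected_linear)[is.na(lin_cls)], collapse = ", "))
  keep <- intersect(rownames(pec), rownames(pel))
  dropped <- setdiff(union(rownames(pec), rownames(pel)), keep)
  if (length(dropped))
    .warnf("excluding %d specimen(s) lacking one girdle: %s", length(dropped),
           paste(dropped, collapse = ", "))
  extra <- setdiff(keep, rownames(corrected_linear))
  extra2 <- setdiff(rownames(corrected_linear), keep)
  if (length(extra) || length(extra2))
    .stopf("specimen sets differ between landmarks and linear data: %s",
           paste(c(extra, extra2), collapse = ", "))
  ord <- order(lin_cls, decreasing = TRUE)       # length before thickness
  lin <- corrected_linear[keep, ord, drop = FALSE]
  size <- matrix(gpa_pel$centroid_sizes[keep], ncol = 1L,
                 dimnames = list(keep, "size_cs_pelvic"))
  raw <- cbind(pec[keep, , drop = FALSE], pel[keep, , drop = FALSE], lin, size)
  standardize_traits(raw)
}

# One-way ANOVA intraclass correlation on pooled coordinates; `x` is an
# observation x variable matrix, `groups` the individual labels.
.icc_anova <- function(x, groups) {
  x <- as.matrix(x)
  groups <- as.factor(groups)
  n <- nlevels(groups)
  big_n <- nrow(x)
  if (n < 2L) .stopf("repeatability needs at least 2 individuals")
  k <- tabulate(groups)
  if (any(k < 2L)) .stopf("every individual needs at least 2 replicates")
  grand <- colMeans(x)
  ss_among <- 0
  ss_within <- 0
  for (g in seq_len(n)) {
    rows <- x[groups == levels(groups)[g], , drop = FALSE]
    m <- colMeans(rows)
    ss_among <- ss_among + nrow(rows) * sum((m - grand)^2)
    ss_within <- ss_within + sum(sweep(rows, 2L, m)^2)
  }
  ms_among <- ss_among / (n - 1L)
  ms_within <- ss_within / (big_n - n)
  # unbalanced-design effective replicate number
  k0 <- (big_n - sum(k^2) / big_n) / (n - 1L)
  s2a <- (ms_among - ms_within) / k0
  r <- if (s2a <= 0) 0 else s2a / (s2a + ms_within)
  list(R = min(max(r, 0), 1), ms_among = ms_among, ms_within = ms_within,
       n_individuals = n, n_replicates = k0)
}

#' Repeatability of the landmarking procedure
#'
#' Superimposes all replicate configurations together, then runs a
#' Procrustes one-way ANOVA with individual as the categorical factor
#' (sums of squared deviations pooled over all aligned coordinates). The
#' intraclass correlation R = s2_among / (s2_among + MS_within), with
#' s2_among = (MS_among - MS_within) / k0 and k0 the unbalanced-design
#' effective replicate count, is clamped to [0, 1].
#'
#' @param replicates list over individuals, each element a list of at least
#'   2 replicate [landmark_configuration()]s of the same structure.
#' @return A list of class `repeatability_result`: `R`, `ms_among`,
#'   `ms_within`, `n_individuals`, `n_replicates`, `structure`.
#' @export
repeatability <- function(replicates) {
  if (length(replicates) < 2L) .stopf("repeatability needs >= 2 individuals")
  configs <- unlist(replicates, recursive = FALSE)
  groups <- rep(seq_along(replicates),
                vapply(replicates, length, integer(1L)))
  fit <- gpa(configs)
  res <- .icc_anova(matrix(aperm(fit$aligned, c(1L, 3L, 2L)),
                           nrow = dim(fit$aligned)[1L]), groups)
  res$structure <- fit$structure
  class(res) <- "repeatability_result"
  res
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("repeatability (%s girdle): R = %.3f (%d individuals, k0 = %.2f)\n",
              x$structure, x$R, x$n_individuals, x$n_replicates))
  invisible(x)
}

#' Principal-component variance summary of the trait space
#'
#' Eigen-decomposition of the covariance of the (already standardized)
#' trait matrix, at the level of individuals or of per-species means.
#'
#' @param traits a [trait_matrix()] or numeric matrix.
#' @param level `"individual"` (default) or `"species-mean"`.
#' @param species species label per row; required for the species-mean
#'   level.
#' @return A list of class `pca_summary`: `variance_fractions` (sums to 1,
#'   non-increasing), `scores`, `loadings`.
#' @export
pca_variance <- function(traits, level = c("individual", "species-mean"),
                         species = NULL) {
  level <- match.arg(level)
  x <- if (inherits(traits, "trait_matrix")) traits$values else as.matrix(traits)
  if (level == "species-mean") {
    if (is.null(species) || length(species) != nrow(x))
      .stopf("species labels (one per row) required at species-mean level")
    x <- rowsum(x, species) / as.vector(table(species)[sort(unique(species))])
  }
  if (nrow(x) <= 2L) .stopf("need more than 2 rows for a PCA")
  k <- min(nrow(x) - 1L, ncol(x))
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  ev <- fit$sdev^2
  structure(list(variance_fractions = ev / sum(ev),
                 scores = fit$x, loadings = fit$rotation),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  v <- x$variance_fractions
  cat(sprintf("pca_summary: PC1 %.2f%%, PC2 %.2f%% of variance (%d components)\n",
              100 * v[1L], if (length(v) > 1L) 100 * v[2L] else NA_real_,
              length(v)))
  invisible(x)
}
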