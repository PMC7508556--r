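# Synthetic study generator: a pure-birth phylogeny, an island radiation
# with ecomorph effects shared across islands (Brownian motion + ecomorph
# effect + island-specific deviation + individual noise), landmark-level
# shape emulation, a two-species rearing experiment, and random missingness
# for the linear measurements. Every generator records its ground truth so
# parameter recovery can be verified.

#' Default island x ecomorph presence matrix
#'
#' Two islands carry all six ecomorphs, one lacks one ecomorph and one
#' lacks two (nested absences), which yields exactly 53 testable quartet
#' comparisons (15 ecomorph pairs x 6 island pairs minus the combinations
#' precluded by the absences) when every present cell is sampled. Which
#' ecomorphs are absent where is a free choice of the emulation and can be
#' overridden.
#'
#' @return 4 x 6 logical matrix, islands x ecomorphs.
#' @export
default_presence_matrix <- function() {
  m <- matrix(TRUE, 4L, 6L, dimnames = list(ISLANDS, ECOMORPHS))
  m["Jamaica", "trunk"] <- FALSE
  m["PuertoRico", c("trunk", "crown-giant")] <- FALSE
  m
}

#' Parameters of the simulated island radiation
#'
#' Generative model for species trait means on the 132-trait layout
#' (54 pectoral shape + 54 pelvic shape + 15 lengths + 8 thicknesses +
#' 1 size): `mean = BM(tree) + beta[ecomorph] + delta * dev[island,
#' ecomorph]`, individuals iid Gaussian around their species mean. The
#' ecomorph effect vectors `beta` are shared across islands, so `delta = 0`
#' makes island trajectories for any ecomorph pair exactly parallel in
#' expectation, while growing `delta` decouples them toward random
#' alignment.
#'
#' Defaults emulate the study design: 95 species on 4 islands x 6 ecomorphs
#' with 3 absences, 1-14 individuals per species with mean about 2.7, and a
#' deviation scale chosen so that between-island trajectory angles land in
#' the moderately-parallel mid-50-degree regime observed in island
#' radiations of this kind.
#'
#' @param n_species number of species.
#' @param presence island x ecomorph logical matrix.
#' @param ind_mean mean individuals per species (truncated-Poisson, range
#'   `ind_range`).
#' @param ind_range inclusive range of individuals per species.
#' @param sigma2 Brownian-motion rate on the unit-height tree.
#' @param beta_sd per-trait sd of the shared ecomorph effect vectors.
#' @param delta island-deviation scale (0 = perfectly parallel divergence).
#' @param noise_sd individual (within-species) noise sd.
#' @param missing_rate fraction of linear measurements deleted by
#'   [simulate_study()].
#' @param n_len,n_thick,n_shape trait-layout sizes (per structure for
#'   shape).
#' @return List of class `radiation_params`.
#' @export
radiation_params <- function(n_species = 95L,
                             presence = default_presence_matrix(),
                             ind_mean = 2.73, ind_range = c(1L, 14L),
                             sigma2 = 1, beta_sd = 2, delta = 1.75,
                             noise_sd = 1, missing_rate = 0.0053,
                             n_shape = 54L, n_len = 15L, n_thick = 8L) {
  if (any(rowSums(presence) < 2L))
    .stopf("every island needs at least 2 ecomorphs present")
  stopifnot(sigma2 >= 0, beta_sd >= 0, delta >= 0, noise_sd >= 0)
  structure(list(n_species = n_species, presence = presence,
                 ind_mean = ind_mean, ind_range = ind_range,
                 sigma2 = sigma2, beta_sd = beta_sd, delta = delta,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 n_shape = n_shape, n_len = n_len, n_thick = n_thick),
            class = "radiation_params")
}

.default_trait_names <- function(n_shape = 54L, n_len = 15L, n_thick = 8L) {
  stopifnot(n_shape %% 3L == 0L)
  lm_names <- function(prefix) as.vector(t(outer(
    sprintf("%sL%02d", prefix, seq_len(n_shape / 3L)),
    c("x", "y", "z"), paste, sep = "_")))
  len_names <- c("len_humerus", "len_ulna", "len_femur", "len_tibia",
                 sprintf("len_fphal%d", 1:5), sprintf("len_hphal%d", 1:6))
  thick_names <- as.vector(t(outer(
    sprintf("thick_%s", c("humerus", "ulna", "femur", "tibia")),
    c("diam", "cort"), paste, sep = "_")))
  c(lm_names("shape_pec_"), lm_names("shape_pel_"),
    len_names[seq_len(n_len)], thick_names[seq_len(n_thick)],
    "size_cs_pelvic")
}

#' Simulate a pure-birth phylogeny
#'
#' Yule tree on `n_species` tips, ultrametric, rescaled to unit height.
#'
#' @param n_species number of tips (>= 2).
#' @param seed integer seed.
#' @return A `phylo` object with tips `sp001`, `sp002`, ...
#' @export
simulate_tree <- function(n_species, seed = NULL) {
  if (n_species < 2L) .stopf("need at least 2 species")
  tree <- with_seed(seed, ape::rphylo(n_species, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

# Round-robin assignment of species to present island x ecomorph cells,
# in randomized cell order so no cell is systematically larger.
.assign_species <- function(tree, presence) {
  cells <- which(presence, arr.ind = TRUE)
  ord <- sample.int(nrow(cells))
  cell_of <- cells[ord[(seq_len(ape::Ntip(tree)) - 1L) %% nrow(cells) + 1L], ,
                   drop = FALSE]
  data.frame(species = tree$tip.label,
             island = rownames(presence)[cell_of[, 1L]],
             ecomorph = colnames(presence)[cell_of[, 2L]],
             stringsAsFactors = FALSE)
}

#' Simulate an island radiation at the trait level
#'
#' Draws species means as Brownian motion on the tree plus the shared
#' ecomorph effect plus a `delta`-scaled island-specific deviation, then
#' individuals as iid Gaussian around their species mean. Values are on the
#' raw (unstandardized) trait scale; standardization happens downstream as
#' in the analysis chain.
#'
#' @param tree a `phylo` object (tips become the species).
#' @param params a [radiation_params()] list.
#' @param seed integer seed.
#' @return A [morph_dataset()] whose `traits` matrix is raw; the recorded
#'   ground truth (species assignment, effect vectors `beta`, island
#'   deviations `dev`, species means, params) is in `attr(, "truth")`.
#' @export
simulate_radiation <- function(tree, params = radiation_params(),
                               seed = NULL) {
  stopifnot(inherits(params, "radiation_params"))
  n_sp <- ape::Ntip(tree)
  p <- 2L * params$n_shape + params$n_len + params$n_thick + 1L
  trait_names <- .default_trait_names(params$n_shape, params$n_len,
                                      params$n_thick)
  with_seed(seed, {
    assign <- .assign_species(tree, params$presence)
    miss <- apply(params$presence, 1L, function(r) !any(r))
    # Brownian species effects: chol(V)' Z has covariance V per trait
    bm <- if (params$sigma2 > 0) {
      v <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
      crossprod(chol(v), matrix(stats::rnorm(n_sp * p), n_sp, p)) *
        sqrt(params$sigma2)
    } else matrix(0, n_sp, p)
    beta <- matrix(stats::rnorm(6L * p, sd = params$beta_sd), 6L, p,
                   dimnames = list(ECOMORPHS, trait_names))
    dev <- array(stats::rnorm(4L * 6L * p), c(4L, 6L, p),
                 dimnames = list(ISLANDS, ECOMORPHS, trait_names))
    sp_means <- bm + beta[assign$ecomorph, , drop = FALSE] +
      params$delta * t(vapply(seq_len(n_sp), function(i)
        dev[assign$island[i], assign$ecomorph[i], ], numeric(p)))
    rownames(sp_means) <- assign$species
    colnames(sp_means) <- trait_names
    k <- pmin(pmax(stats::rpois(n_sp, params$ind_mean - params$ind_range[1L]) +
                     params$ind_range[1L], params$ind_range[1L]),
              params$ind_range[2L])
    rows <- rep(seq_len(n_sp), k)
    traits <- sp_means[rows, , drop = FALSE] +
      matrix(stats::rnorm(length(rows) * p, sd = params$noise_sd),
             length(rows), p)
    records <- data.frame(
      specimen_id = sprintf("%s_i%02d", assign$species[rows],
                            sequence(k)),
      species = assign$species[rows], island = assign$island[rows],
      ecomorph = assign$ecomorph[rows], sex = "male", source = "museum",
      treatment = NA_character_, stringsAsFactors = FALSE)
    ds <- morph_dataset(records, traits = traits)
    attr(ds, "truth") <- list(assignment = assign, beta = beta, dev = dev,
                              species_means = sp_means, params = params)
    ds
  })
}

#' Template shape and deformation basis for landmark emulation
#'
#' A fixed, non-degenerate 18-landmark 3D template (drawn once from the
#' given seed) together with an orthonormal deformation basis in the
#' 54-dimensional landmark space. Specimen shapes are the template plus a
#' basis combination of per-specimen coefficients, so superimposition can
#' be checked against the injected coefficients.
#'
#' @param structure `"pectoral"` or `"pelvic"`.
#' @param q number of basis directions (<= 54; default full rank 54).
#' @param base_size approximate centroid size of the template (mm).
#' @param seed integer seed fixing template and basis.
#' @return A list of class `template_shape`: `structure`, `coords` (18 x
#'   3), `basis` (54 x q, orthonormal), `base_size`.
#' @export
template_shape <- function(structure = c("pectoral", "pelvic"), q = 54L,
                           base_size = 10, seed = 1L) {
  structure <- match.arg(structure)
  stopifnot(q >= 1L, q <= 54L)
  with_seed(seed + (structure == "pelvic"), {
    coords <- matrix(stats::rnorm(54L), 18L, 3L)
    coords <- sweep(coords, 2L, colMeans(coords))
    coords <- coords / sqrt(sum(coords^2)) * base_size
    basis <- qr.Q(qr(matrix(stats::rnorm(54L * q), 54L, q)))
    base::structure(list(structure = structure, coords = coords,
                         basis = basis, base_size = base_size),
                    class = "template_shape")
  })
}

.random_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  r <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(r) < 0) r[, 1L] <- -r[, 1L]
  r
}

#' Simulate raw landmark configurations from deformation coefficients
#'
#' Each specimen's shape is the template plus the deformation-basis
#' combination of its coefficients plus iid landmark noise, then a random
#' rotation, translation and scale are applied (the nuisance transforms the
#' superimposition must undo). A configurable fraction is emitted mirrored
#' as right-side structures.
#'
#' @param template a [template_shape()].
#' @param coefs n x q matrix of deformation coefficients (rows named by
#'   specimen); kept in the small-deformation regime by `deformation_scale`.
#' @param deformation_scale multiplier from coefficient units to landmark
#'   displacement (mm).
#' @param noise_sd iid landmark noise sd (mm).
#' @param scales optional per-specimen scale factors (default lognormal).
#' @param mirrored_fraction fraction of specimens emitted as right-side.
#' @param seed integer seed.
#' @return Named list of [landmark_configuration()]s; ground truth (shape
#'   coordinates before nuisance transforms, scales, sides) in
#'   `attr(, "truth")`.
#' @export
simulate_landmarks <- function(template, coefs, deformation_scale = 0.02,
                               noise_sd = 0, scales = NULL,
                               mirrored_fraction = 0, seed = NULL) {
  stopifnot(inherits(template, "template_shape"))
  coefs <- as.matrix(coefs)
  if (ncol(coefs) != ncol(template$basis))
    .stopf("coefs has %d columns but basis has %d directions",
           ncol(coefs), ncol(template$basis))
  n <- nrow(coefs)
  ids <- rownames(coefs)
  if (is.null(ids)) ids <- sprintf("spec%03d", seq_len(n))
  with_seed(seed, {
    if (is.null(scales)) scales <- exp(stats::rnorm(n, sd = 0.15))
    sides <- ifelse(stats::runif(n) < mirrored_fraction, "right", "left")
    out <- vector("list", n)
    true_shapes <- array(NA_real_, c(n, 18L, 3L))
    for (i in seq_len(n)) {
      shape <- template$coords +
        matrix(template$basis %*% coefs[i, ] * deformation_scale, 18L, 3L) +
        matrix(stats::rnorm(54L, sd = noise_sd), 18L, 3L)
      true_shapes[i, , ] <- shape
      placed <- (shape %*% .random_rotation()) * scales[i]
      placed <- sweep(placed, 2L, stats::rnorm(3L, sd = 10), `+`)
      cfg <- landmark_configuration(placed, structure = template$structure,
                                    side = "left")
      if (sides[i] == "right") cfg <- mirror_configuration(cfg)
      out[[i]] <- cfg
    }
    names(out) <- ids
    attr(out, "truth") <- list(shapes = true_shapes, scales = scales,
                               sides = sides, coefs = coefs)
    out
  })
}

#' Parameters of the simulated rearing experiment
#'
#' Two species raised under broad vs narrow microhabitat treatments, with
#' each species' treatment-effect vector constructed at an exact target
#' angle to a supplied ecomorph-divergence vector. Per-treatment sample
#' sizes default to the rearing design (41/34 males of the trunk-ground
#' species, 22/23 of the trunk-crown species). The default effect magnitude
#' (Euclidean length over the 132 traits, in trait-sd units) is in the
#' strong-signal regime where the t-vector noise floor (about sqrt(132))
#' attenuates recovered angles by only a few degrees.
#'
#' @param species labels of the two species.
#' @param n per-treatment sample sizes: list of two length-2 vectors
#'   (broad, narrow).
#' @param target_angle target angle (degrees, in [0, 180]) between each
#'   species' plasticity vector and the divergence vector.
#' @param effect_magnitude Euclidean length of each treatment-effect
#'   vector.
#' @param noise_sd individual noise sd.
#' @return List of class `plasticity_params`.
#' @export
plasticity_params <- function(species = c("A_sagrei", "A_carolinensis"),
                              n = list(c(41L, 34L), c(22L, 23L)),
                              target_angle = c(105.96, 81.22),
                              effect_magnitude = 30, noise_sd = 1) {
  stopifnot(length(species) == 2L, length(n) == 2L,
            all(target_angle >= 0 & target_angle <= 180))
  if (any(effect_magnitude <= 0))
    .stopf("target angle is undefined for a zero-magnitude effect")
  structure(list(species = species, n = n, target_angle = target_angle,
                 effect_magnitude = effect_magnitude, noise_sd = noise_sd),
            class = "plasticity_params")
}

#' Simulate the two-species rearing experiment
#'
#' Builds, for each species, a treatment-effect vector at exactly the
#' target angle to `divergence_vector` (Gram-Schmidt mixing of the
#' divergence direction with a random orthogonal direction), then draws
#' individuals as species baseline + effect (narrow treatment only) +
#' iid noise. The plasticity contrast is therefore narrow - broad.
#'
#' @param divergence_vector non-zero numeric vector (length = number of
#'   traits) the target angles refer to, e.g. a t-vector contrast between
#'   the corresponding ecomorphs.
#' @param params a [plasticity_params()] list.
#' @param seed integer seed.
#' @return A [morph_dataset()] of experimental specimens; ground truth
#'   (true effect vectors, baselines, params) in `attr(, "truth")`.
#' @export
simulate_plasticity_experiment <- function(divergence_vector,
                                           params = plasticity_params(),
                                           seed = NULL) {
  stopifnot(inherits(params, "plasticity_params"))
  d <- .vec(divergence_vector)
  if (sum(d^2) == 0) .stopf("divergence vector must be non-zero")
  p <- length(d)
  u <- d / sqrt(sum(d^2))
  with_seed(seed, {
    effects <- matrix(NA_real_, 2L, p)
    baselines <- matrix(stats::rnorm(2L * p, sd = 0.5), 2L, p)
    rows <- list()
    recs <- list()
    mag <- rep_len(params$effect_magnitude, 2L)
    for (s in 1:2) {
      r <- stats::rnorm(p)
      w <- r - sum(r * u) * u
      w <- w / sqrt(sum(w^2))
      ang <- params$target_angle[s] * pi / 180
      effects[s, ] <- mag[s] * (cos(ang) * u + sin(ang) * w)
      for (tr in 1:2) {
        n_st <- params$n[[s]][tr]
        treatment <- c("broad", "narrow")[tr]
        x <- matrix(rep(baselines[s, ], each = n_st), n_st, p)
        if (treatment == "narrow")
          x <- x + matrix(rep(effects[s, ], each = n_st), n_st, p)
        x <- x + matrix(stats::rnorm(n_st * p, sd = params$noise_sd), n_st, p)
        rows[[length(rows) + 1L]] <- x
        recs[[length(recs) + 1L]] <- data.frame(
          specimen_id = sprintf("%s_%s_%02d", params$species[s], treatment,
                                seq_len(n_st)),
          species = params$species[s], island = NA_character_,
          ecomorph = NA_character_, sex = "male", source = "experiment",
          treatment = treatment, stringsAsFactors = FALSE)
      }
    }
    traits <- do.call(rbind, rows)
    colnames(traits) <- if (!is.null(names(d))) names(d)
                        else .default_trait_names()[seq_len(p)]
    ds <- morph_dataset(do.call(rbind, recs), traits = traits)
    attr(ds, "truth") <- list(effects = effects, baselines = baselines,
                              params = params, divergence = d)
    ds
  })
}

#' Delete cells of a linear-measurement table at random
#'
#' Uniform random missingness at the given rate; the deletion mask is
#' attached so imputation error can be scored on exactly the deleted cells.
#'
#' @param x numeric matrix or data.frame.
#' @param rate missing rate in [0, 0.5).
#' @param seed integer seed.
#' @return The matrix with `NA`s inserted; logical mask in `attr(, "mask")`.
#' @export
inject_missing <- function(x, rate, seed = NULL) {
  if (!is.numeric(rate) || rate < 0 || rate >= 0.5)
    .stopf("rate must lie in [0, 0.5)")
  x <- as.matrix(x)
  mask <- matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
  if (rate > 0) {
    mask[] <- with_seed(seed, stats::runif(length(x)) < rate)
    x[mask] <- NA_real_
  }
  attr(x, "mask") <- mask
  x
}

#' Simulate a complete study: tree, radiation, landmarks, linear tables
#'
#' End-to-end generator exercising every pipeline stage: a pure-birth
#' phylogeny, trait-level radiation, per-specimen pectoral and pelvic
#' landmark configurations (shape trait values injected through the
#' deformation basis, then randomly rotated, translated, scaled, and
#' partly mirrored), strictly positive raw length/thickness tables that
#' co-scale with specimen size, and random missingness in the linear
#' measurements.
#'
#' @param params a [radiation_params()].
#' @param seed integer seed.
#' @param mirrored_fraction fraction of landmark configurations emitted
#'   right-side.
#' @param landmark_noise_sd iid landmark noise (mm).
#' @return List of class `synthetic_study`: `tree`, `dataset` (a
#'   [morph_dataset()] with records, landmarks and linear tables), and
#'   `truth`.
#' @export
simulate_study <- function(params = radiation_params(), seed = NULL,
                           mirrored_fraction = 0.05,
                           landmark_noise_sd = 0.005) {
  with_seed(seed, {
    tree <- simulate_tree(params$n_species, seed = NULL)
    rad <- simulate_radiation(tree, params, seed = NULL)
    truth <- attr(rad, "truth")
    n <- nrow(rad$records)
    ids <- rad$records$specimen_id
    i_shape1 <- seq_len(params$n_shape)
    i_shape2 <- params$n_shape + seq_len(params$n_shape)
    i_lin <- 2L * params$n_shape + seq_len(params$n_len + params$n_thick)
    i_size <- ncol(rad$traits)
    # specimen scale carries the size trait (lognormal around 1)
    scales <- exp(0.05 * rad$traits[, i_size] + stats::rnorm(n, sd = 0.02))
    tpl_pec <- template_shape("pectoral", q = params$n_shape)
    tpl_pel <- template_shape("pelvic", q = params$n_shape)
    coefs_pec <- rad$traits[, i_shape1, drop = FALSE]
    coefs_pel <- rad$traits[, i_shape2, drop = FALSE]
    rownames(coefs_pec) <- rownames(coefs_pel) <- ids
    lm_pec <- simulate_landmarks(tpl_pec, coefs_pec,
                                 noise_sd = landmark_noise_sd,
                                 scales = scales,
                                 mirrored_fraction = mirrored_fraction)
    lm_pel <- simulate_landmarks(tpl_pel, coefs_pel,
                                 noise_sd = landmark_noise_sd,
                                 scales = scales,
                                 mirrored_fraction = mirrored_fraction)
    landmarks <- lapply(seq_len(n), function(i)
      list(pectoral = lm_pec[[i]], pelvic = lm_pel[[i]]))
    names(landmarks) <- ids
    # strictly positive raw linear measurements, co-scaling with size
    lin_names <- colnames(rad$traits)[i_lin]
    base <- ifelse(startsWith(lin_names, "len_"), 8, 2)
    lin_raw <- sweep(sweep(rad$traits[, i_lin, drop = FALSE], 2L,
                           c(rep(0.2, params$n_len), rep(0.05, params$n_thick)),
                           `*`),
                     2L, base, `+`)
    lin_raw <- pmax(lin_raw, 0.05) * scales
    lin_missing <- inject_missing(lin_raw, params$missing_rate, seed = NULL)
    linear <- data.frame(specimen_id = ids, lin_missing,
                         check.names = FALSE, stringsAsFactors = FALSE)
    ds <- morph_dataset(rad$records, traits = rad$traits,
                        landmarks = landmarks, linear = linear)
    truth$scales <- scales
    truth$landmark_truth <- list(pectoral = attr(lm_pec, "truth"),
                                 pelvic = attr(lm_pel, "truth"))
    truth$missing_mask <- attr(lin_missing, "mask")
    structure(list(tree = tree, dataset = ds, truth = truth),
              class = "synthetic_study")
  })
}
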