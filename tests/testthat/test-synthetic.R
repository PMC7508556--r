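# Generators: tree, radiation, landmarks, plasticity experiment,
# missingness injection, and the end-to-end study.

test_that("simulated trees are ultrametric, unit-height and reproducible", {
  tr2 <- simulate_tree(2, seed = 1)
  depths <- ape::node.depth.edgelength(tr2)[1:2]
  expect_equal(depths, c(1, 1))

  tr <- simulate_tree(95, seed = 2)
  expect_equal(ape::Ntip(tr), 95L)
  d <- ape::node.depth.edgelength(tr)[1:95]
  expect_lt(diff(range(d)), 1e-9)
  expect_equal(max(d), 1)
  expect_identical(ape::write.tree(tr), ape::write.tree(simulate_tree(95, seed = 2)))
  expect_error(simulate_tree(1), "at least 2")
})

test_that("the degenerate radiation limit collapses to pure ecomorph effects", {
  tr <- simulate_tree(12, seed = 3)
  par0 <- radiation_params(n_species = 12, sigma2 = 0, noise_sd = 0,
                           delta = 0)
  ds <- simulate_radiation(tr, par0, seed = 4)
  truth <- attr(ds, "truth")
  # conspecifics identical
  for (sp in unique(ds$records$species)) {
    rows <- ds$traits[ds$records$species == sp, , drop = FALSE]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-12)
  }
  # within an ecomorph, species means identical across islands
  for (eco in unique(ds$records$ecomorph)) {
    rows <- unique(ds$traits[ds$records$ecomorph == eco, , drop = FALSE])
    expect_lt(max(abs(sweep(rows, 2, truth$beta[eco, ]))), 1e-12)
  }
})

test_that("parallel radiations give small angles; decoupled ones near 90", {
  # strong shared ecomorph effects, several species and individuals per
  # cell so Brownian species effects average out
  med_angle <- function(delta, n_reps = 8) {
    median(vapply(seq_len(n_reps), function(r) {
      tr <- simulate_tree(42, seed = 1000 * delta + r)
      ds <- simulate_radiation(
        tr, radiation_params(n_species = 42, sigma2 = 0.05, beta_sd = 4,
                             delta = delta, noise_sd = 0.5,
                             ind_mean = 8, ind_range = c(6L, 12L)),
        seed = 2000 * delta + r)
      q <- enumerate_quartets(ds$records, min_n = 2)
      if (!nrow(q)) return(NA_real_)
      v <- quartet_vectors(q[1, ], ds$traits, ds$records)
      vector_angle(v$v1, v$v2)
    }, numeric(1L)), na.rm = TRUE)
  }
  expect_lt(med_angle(0), 15)
  a90 <- med_angle(25)
  expect_true(a90 > 75 && a90 < 105)
})

test_that("landmark emulation is exact at zero deformation and noise", {
  tpl <- template_shape("pectoral")
  cfgs <- simulate_landmarks(tpl, matrix(0, 4, 54), noise_sd = 0, seed = 5)
  fit <- gpa(cfgs)
  # all aligned shapes equal the (unitized) template
  tpl_unit <- sweep(tpl$coords, 2, colMeans(tpl$coords))
  tpl_unit <- tpl_unit / sqrt(sum(tpl_unit^2))
  s <- svd(crossprod(fit$mean_shape, tpl_unit))
  rot <- s$u %*% t(s$v)
  expect_lt(sqrt(sum((fit$mean_shape %*% rot - tpl_unit)^2)), 1e-9)
  for (i in 1:4)
    expect_lt(sqrt(sum((fit$aligned[i, , ] - fit$mean_shape)^2)), 1e-9)
})

test_that("an injected deformation gradient is recovered as PC1", {
  tpl <- template_shape("pectoral", q = 54)
  grad <- seq(-3, 3, length.out = 30)
  coefs <- matrix(0, 30, 54)
  coefs[, 7] <- grad
  cfgs <- simulate_landmarks(tpl, coefs, noise_sd = 1e-4, seed = 6)
  fit <- gpa(cfgs)
  sv <- shape_variables(fit)
  pc <- pca_variance(sv)
  expect_gt(abs(cor(pc$scores[, 1], grad)), 0.99)
})

test_that("mirrored specimens carry no side signal after mirroring back", {
  tpl <- template_shape("pelvic", q = 54)
  set.seed(7)
  coefs <- matrix(rnorm(40 * 54, sd = 0.5), 40, 54)
  cfgs <- simulate_landmarks(tpl, coefs, noise_sd = 0.002,
                             mirrored_fraction = 0.5, seed = 8)
  sides <- attr(cfgs, "truth")$sides
  expect_true(all(c("left", "right") %in% sides))
  lefted <- lapply(cfgs, function(cfg)
    if (cfg$side == "right") mirror_configuration(cfg) else cfg)
  sv <- shape_variables(gpa(lefted))
  # permutation test on the side label: distance between side means
  stat <- function(lab) {
    sqrt(sum((colMeans(sv[lab == "right", , drop = FALSE]) -
                colMeans(sv[lab == "left", , drop = FALSE]))^2))
  }
  obs <- stat(sides)
  null <- replicate(199, stat(sample(sides)))
  p <- (sum(null >= obs) + 1) / 200
  expect_gt(p, 0.05)
})

test_that("plasticity experiment hits its target angles in expectation", {
  set.seed(9)
  d <- rnorm(132)
  prm <- plasticity_params(target_angle = c(0, 90), effect_magnitude = 30,
                           n = list(c(40L, 40L), c(40L, 40L)))
  ds <- simulate_plasticity_experiment(d, prm, seed = 10)
  truth <- attr(ds, "truth")
  expect_equal(vector_angle(truth$effects[1, ], d), 0, tolerance = 1e-8)
  expect_equal(vector_angle(truth$effects[2, ], d), 90, tolerance = 1e-8)
  expect_equal(sqrt(sum(truth$effects[1, ]^2)), 30, tolerance = 1e-8)

  # estimated angles from t-vectors recover the targets
  est <- vapply(unique(ds$records$species), function(sp) {
    idn <- ds$records$treatment == "narrow" & ds$records$species == sp
    idb <- ds$records$treatment == "broad" & ds$records$species == sp
    v <- t_vector(ds$traits[idn, ], ds$traits[idb, ])
    vector_angle(v, d)
  }, numeric(1L))
  expect_lt(est[1], 15)
  expect_true(est[2] > 75 && est[2] < 105)

  # zero-magnitude effects are rejected at parameter construction
  expect_error(plasticity_params(effect_magnitude = 0), "zero-magnitude")
})

test_that("missingness injection has the right rate, mask, and value", {
  x <- matrix(abs(rnorm(300)) + 1, 30, 10)
  expect_equal(unname(inject_missing(x, 0)[, ]), unname(x))

  holed <- inject_missing(x, 0.1, seed = 11)
  mask <- attr(holed, "mask")
  expect_identical(is.na(holed[, ]), mask)
  expect_lt(abs(sum(mask) - 30), 20)   # 300 cells at 10%
  expect_error(inject_missing(x, 0.6), "rate")

  # imputation beats the column-mean baseline under rank-2 structure
  set.seed(12)
  u <- matrix(rnorm(60), 30, 2)
  v <- matrix(rnorm(20), 10, 2)
  low <- u %*% t(v)
  holed2 <- inject_missing(low, 0.08, seed = 13)
  mask2 <- attr(holed2, "mask")
  done <- impute_missing(holed2[, ], q = 2)
  rmse_pca <- sqrt(mean((done[mask2] - low[mask2])^2))
  colmean_fill <- matrix(rep(colMeans(holed2, na.rm = TRUE), each = 30), 30, 10)
  rmse_naive <- sqrt(mean((colmean_fill[mask2] - low[mask2])^2))
  expect_lt(rmse_pca, rmse_naive)
})

test_that("the full study generator is reproducible and internally consistent", {
  prm <- radiation_params(n_species = 15)
  s1 <- simulate_study(prm, seed = 14)
  s2 <- simulate_study(prm, seed = 14)
  expect_identical(s1$dataset$traits, s2$dataset$traits)
  expect_identical(s1$dataset$linear, s2$dataset$linear)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))

  ds <- s1$dataset
  expect_length(ds$landmarks, nrow(ds$records))
  lin <- as.matrix(ds$linear[-1])
  expect_true(all(lin > 0, na.rm = TRUE))
  expect_length(validate_dataset(ds)$errors, 0L)
})
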