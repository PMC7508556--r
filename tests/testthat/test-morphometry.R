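# Mirroring, centroid size, GPA (with closed-form oracle), imputation,
# size correction, standardization, assembly, repeatability, PCA.

test_that("mirroring negates one axis and is an involution", {
  cfg <- make_config(seed = 1)
  cfg$side <- "right"
  m <- mirror_configuration(cfg, axis = "x")
  expect_equal(m$coords[, "x"], -cfg$coords[, "x"])
  expect_equal(m$coords[, c("y", "z")], cfg$coords[, c("y", "z")])
  expect_equal(m$side, "left")
  back <- mirror_configuration(m, axis = "x")
  expect_equal(back$coords, cfg$coords)
  expect_error(mirror_configuration(cfg, axis = "w"), "axis")
})

test_that("a mirrored configuration realigns to its left-side original", {
  set.seed(3)
  left <- make_config(seed = 3)
  right <- mirror_configuration(left)      # pretend right side
  recovered <- mirror_configuration(right) # mirrored back to left
  fit <- gpa(list(left, recovered))
  expect_lt(sqrt(sum((fit$aligned[1, , ] - fit$aligned[2, , ])^2)), 1e-9)
})

test_that("centroid size matches its definition and scaling laws", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
              matrix(rep(c(0.5, 0.5, 0), 14), ncol = 3, byrow = TRUE))
  cfg <- landmark_configuration(sq, "pelvic")
  expect_equal(centroid_size(cfg), sqrt(2), tolerance = 1e-12)
  # homogeneity and translation invariance
  expect_equal(centroid_size(sq * 3.7), 3.7 * sqrt(2), tolerance = 1e-12)
  expect_equal(centroid_size(sweep(sq, 2, c(5, -2, 9), `+`)), sqrt(2),
               tolerance = 1e-12)
})

test_that("gpa centres, unit-scales and is invariant to similarity transforms", {
  set.seed(7)
  base <- replicate(4, make_config(noise = 0.1), simplify = FALSE)
  fit <- gpa(base)
  for (i in 1:4) {
    a <- fit$aligned[i, , ]
    expect_lt(sqrt(sum(colMeans(a)^2)), 1e-9)
    expect_lt(abs(sqrt(sum(a^2)) - 1), 1e-9)
  }
  expect_equal(fit$mean_shape, apply(fit$aligned, c(2, 3), mean),
               tolerance = 1e-8)

  # random rotation + translation + scale of the inputs changes nothing
  moved <- lapply(base, function(cfg) {
    landmark_configuration(
      sweep(cfg$coords %*% random_rotation3() * runif(1, 0.5, 3),
            2, rnorm(3, sd = 10), `+`),
      structure = cfg$structure)
  })
  fit2 <- gpa(moved)
  expect_lt(max(abs(fit2$aligned - fit$aligned)), 1e-8)
})

test_that("two-configuration gpa matches the closed-form Procrustes solution", {
  set.seed(11)
  x <- make_config()
  # perturbation of x: the optimal alignment is a genuine rotation, so the
  # reflection-permitting reference implementation finds the same optimum
  y <- landmark_configuration(
    sweep(x$coords %*% random_rotation3() * 1.7, 2, c(3, -1, 2), `+`) +
      matrix(rnorm(54, sd = 0.05), 18, 3),
    structure = x$structure)
  # independent closed-form oracle: centre, unit-scale, single SVD rotation
  unitize <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  a <- unitize(x$coords)
  b <- unitize(y$coords)
  s <- svd(crossprod(a, b))
  r <- s$u %*% t(s$v)
  if (det(r) < 0) {
    u <- s$u; u[, 3] <- -u[, 3]; r <- u %*% t(s$v)
  }
  d_closed <- sqrt(sum((a %*% r - b)^2))
  fit <- gpa(list(x, y))
  d_gpa <- sqrt(sum((fit$aligned[1, , ] - fit$aligned[2, , ])^2))
  expect_equal(d_gpa, d_closed, tolerance = 1e-9)
  # vegan's Procrustes of the unit configurations agrees on the distance
  veg <- vegan::procrustes(b, a, scale = FALSE)
  expect_equal(d_gpa, sqrt(sum((veg$Yrot - b)^2)), tolerance = 1e-6)
})

test_that("gpa recovers a noisy template and degenerate inputs error", {
  set.seed(13)
  template <- matrix(rnorm(54), 18, 3)
  cfgs <- replicate(5, landmark_configuration(
    template + matrix(rnorm(54, sd = 0.02), 18, 3), "pelvic"),
    simplify = FALSE)
  fit <- gpa(cfgs)
  tpl_unit <- sweep(template, 2, colMeans(template))
  tpl_unit <- tpl_unit / sqrt(sum(tpl_unit^2))
  # align mean shape to the template before comparing
  s <- svd(crossprod(fit$mean_shape, tpl_unit))
  rot <- s$u %*% t(s$v)
  expect_lt(max(abs(fit$mean_shape %*% rot - tpl_unit)), 0.02)

  single <- gpa(cfgs[1])
  expect_equal(single$centroid_sizes[[1]], centroid_size(cfgs[[1]]))
  degen <- landmark_configuration(matrix(1, 18, 3), "pelvic")
  expect_error(gpa(list(degen)), "centroid size")
})

test_that("iterative PCA imputation recovers structured missing cells", {
  x <- matrix(rnorm(40), 8, 5)
  expect_identical(impute_missing(x), x)  # nothing missing -> identity

  # rank-1 oracle: u v' with one deleted cell has a closed-form completion
  u <- c(1, 2, 3, 4, 5, 6)
  v <- c(2, 1, 3, 0.5)
  full <- outer(u, v)
  holed <- full
  holed[3, 2] <- NA
  done <- impute_missing(holed, q = 1)
  expect_equal(done[3, 2], full[3, 2], tolerance = 1e-6)
  expect_equal(done[-3, ], full[-3, ])   # observed cells untouched

  allmiss <- full
  allmiss[, 2] <- NA
  expect_error(impute_missing(allmiss, q = 1), "fewer than 2 observed")
  rowmiss <- full
  rowmiss[2, ] <- NA
  expect_error(impute_missing(rowmiss, q = 1), "entirely missing")
})

test_that("size correction divides by centroid size and is scale-invariant", {
  lin <- rbind(c(10, 4), c(6, 2))
  out <- size_correct(lin, c(5, 2))
  expect_equal(out, rbind(c(2, 0.8), c(3, 1)))
  # doubling a specimen's measurements and its size leaves it unchanged
  expect_equal(size_correct(lin * 2, c(10, 4)), out)
  expect_error(size_correct(lin, c(5, 0)), "strictly positive")
})

test_that("standardization gives exact z-columns and is idempotent", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 1, 0))
  z <- standardize_traits(x)
  expect_equal(unname(z$values[, "a"]), c(-1, 0, 1))
  expect_lt(max(abs(colMeans(z$values))), 1e-10)
  expect_lt(max(abs(apply(z$values, 2, sd) - 1)), 1e-10)
  z2 <- standardize_traits(z$values)
  expect_equal(z2$values, z$values, tolerance = 1e-12)
  expect_error(standardize_traits(cbind(a = c(1, 1, 1))), "constant.*a")
  # projection onto a stored scale reproduces the same transform
  z3 <- standardize_traits(x, scaling = z$scaling)
  expect_equal(z3$values, z$values)
})

test_that("assemble_traits produces the 132-column layout and excludes
           specimens lacking a girdle", {
  set.seed(17)
  n <- 10
  ids <- sprintf("s%02d", 1:n)
  mk <- function(struct) {
    cfgs <- replicate(n, make_config(noise = 0.05, structure = struct),
                      simplify = FALSE)
    names(cfgs) <- ids
    gpa(cfgs)
  }
  g_pec <- mk("pectoral")
  g_pel <- mk("pelvic")
  lin <- matrix(abs(rnorm(n * 23)) + 1, n, 23,
                dimnames = list(ids, c(sprintf("len_%02d", 1:15),
                                       sprintf("thick_%02d", 1:8))))
  corrected <- size_correct(lin, g_pel$centroid_sizes)
  tm <- assemble_traits(g_pec, g_pel, corrected)
  expect_equal(dim(tm$values), c(10L, 132L))
  expect_equal(as.vector(table(factor(tm$column_class,
                                      c("shape", "length", "thickness",
                                        "size")))),
               c(108L, 15L, 8L, 1L))
  expect_lt(max(abs(colMeans(tm$values))), 1e-10)

  # dropping one specimen's pelvic data excludes it with a warning
  g_pel9 <- morphotraj:::.subset_gpa(g_pel, ids[-1])
  expect_warning(
    tm9 <- assemble_traits(g_pec, g_pel9, corrected[ids[-1], ]),
    "excluding")
  expect_equal(nrow(tm9$values), 9L)
  # mismatched specimen sets between landmarks and linear are an error
  expect_error(assemble_traits(g_pec, g_pel, corrected[1:5, ]),
               "specimen sets differ")
})

test_that("repeatability matches a hand one-way ANOVA and its limits", {
  # hand-computable 1D case: 2 individuals, k = 2
  x <- matrix(c(1, 3, 10, 14), ncol = 1)   # means 2 and 12, grand 7
  res <- morphotraj:::.icc_anova(x, c("a", "a", "b", "b"))
  # SS_among = 2*(2-7)^2 + 2*(12-7)^2 = 100 on 1 df;
  # SS_within = (1+1) + (4+4) = 10 on 2 df
  expect_equal(res$ms_among, 100)
  expect_equal(res$ms_within, 5)
  s2a <- (100 - 5) / 2
  expect_equal(res$R, s2a / (s2a + 5))

  # identical replicates per individual, distinct individuals -> R = 1
  set.seed(19)
  reps <- lapply(1:3, function(i) {
    cfg <- make_config(noise = 0.3)
    list(cfg, cfg)
  })
  expect_equal(repeatability(reps)$R, 1)

  # no individual effect -> R near 0 (within Monte Carlo tolerance)
  template <- matrix(rnorm(54), 18, 3)
  reps0 <- lapply(1:50, function(i)
    replicate(2, landmark_configuration(
      template + matrix(rnorm(54, sd = 0.1), 18, 3), "pectoral"),
      simplify = FALSE))
  expect_lt(repeatability(reps0)$R, 0.25)

  # invariance to a global scale change of every configuration
  reps_big <- lapply(reps0[1:10], function(pair)
    lapply(pair, function(cfg)
      landmark_configuration(cfg$coords * 250, cfg$structure)))
  expect_equal(repeatability(reps_big)$R, repeatability(reps0[1:10])$R,
               tolerance = 1e-8)
})

test_that("pca_variance fractions behave as variance shares", {
  set.seed(23)
  iso <- matrix(rnorm(3000), 1000, 3)
  fr <- pca_variance(iso)$variance_fractions
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_true(all(abs(fr - 1 / 3) < 0.05))
  expect_true(all(diff(fr) <= 1e-12))

  # collinear data put everything on PC1
  line <- cbind(1:10, 2 * (1:10), -0.5 * (1:10))
  expect_equal(pca_variance(line)$variance_fractions[1], 1, tolerance = 1e-12)

  # species-mean level averages rows first
  x <- rbind(iso[1:4, ], iso[5:8, ])
  sp <- rep(c("a", "b"), each = 4)
  expect_error(pca_variance(x, level = "species-mean"), "species labels")
  pm <- pca_variance(rbind(x, iso[9:12, ]), level = "species-mean",
                     species = c(sp, rep("c", 4)))
  expect_equal(nrow(pm$scores), 3L)
})
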