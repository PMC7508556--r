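# Trajectory vectors, angles, quartet enumeration, permutation/bootstrap
# tests, classification, outlier scans and cross-method correlation.

test_that("t vectors match hand formulas and basic equivariances", {
  a <- matrix(c(0, 1, 2), ncol = 1)
  b <- matrix(c(3, 4, 5), ncol = 1)
  v <- t_vector(a, b, method = "pooled")
  # mean diff -3, pooled sd 1, se sqrt(2/3)
  expect_equal(unname(v$t_values), -3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(v$L, abs(-3 / sqrt(2 / 3)), tolerance = 1e-9)
  # Welch equals pooled for equal group sizes and variances here
  expect_equal(t_vector(a, b, method = "welch")$t_values, v$t_values,
               tolerance = 1e-9)

  # identical groups give the zero vector
  same <- matrix(rnorm(10), 5, 2)
  v0 <- t_vector(same, same)
  expect_equal(unname(v0$t_values), c(0, 0))
  expect_equal(v0$L, 0)
  # a zero-variance trait is zeroed with a warning instead of aborting
  expect_warning(vz <- t_vector(cbind(matrix(rnorm(5)), 1),
                                cbind(matrix(rnorm(5)), 2)),
                 "zero variance")
  expect_equal(unname(vz$t_values[2]), 0)

  # flipping one trait's sign in both groups flips only that t
  set.seed(1)
  x <- matrix(rnorm(20), 5, 4)
  y <- matrix(rnorm(20) + 1, 5, 4)
  v1 <- t_vector(x, y)
  xf <- x; yf <- y
  xf[, 2] <- -xf[, 2]; yf[, 2] <- -yf[, 2]
  v2 <- t_vector(xf, yf)
  expect_equal(v2$t_values[-2], v1$t_values[-2])
  expect_equal(v2$t_values[2], -v1$t_values[2])

  expect_error(t_vector(x[1, , drop = FALSE], y), "at least 2")
})

test_that("mean-difference vectors and the L bookkeeping", {
  a <- rbind(c(1, 0), c(1, 0))
  b <- rbind(c(0, 0), c(0, 0))
  v <- mean_difference_vector(a, b)
  expect_equal(unname(v$t_values), c(1, 0))
  expect_equal(v$L, 1)
  expect_equal(mean_difference_vector(a, a)$L, 0)
  expect_equal(v$L, sqrt(sum(v$t_values^2)), tolerance = 1e-12)
})

test_that("angles and length differences follow the closed-form geometry", {
  expect_equal(vector_angle(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(vector_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(vector_angle(c(1, 1, 0), c(1, 0, 0)), 45, tolerance = 1e-12)
  expect_equal(vector_angle(c(1, 2), c(-2, -4)), 180)
  expect_error(vector_angle(c(0, 0), c(1, 0)), "zero-length")

  expect_equal(delta_length(c(3, 4), c(0, 1)), 4)
  expect_equal(delta_length(c(3, 4), c(3, 4)), 0)
  expect_equal(delta_length(c(0, 1), c(3, 4)), -4)

  # symmetry and positive/negative scaling of one argument
  set.seed(2)
  a <- rnorm(20)
  b <- rnorm(20)
  expect_equal(vector_angle(a, b), vector_angle(b, a))
  expect_equal(vector_angle(a, 3 * a), 0, tolerance = 1e-6)
  expect_equal(vector_angle(a, -2 * a), 180, tolerance = 1e-6)
})

test_that("random trajectory vectors average 90 degrees", {
  set.seed(3)
  angles <- replicate(500, vector_angle(rnorm(132), rnorm(132)))
  expect_lt(abs(mean(angles) - 90), 1)
})

test_that("quartet enumeration respects presence and minimum cell sizes", {
  # 3 ecomorphs fully present on 2 islands -> C(3,2) x C(2,2) = 3 quartets
  recs <- do.call(rbind, lapply(c("twig", "trunk", "grass-bush"), function(e)
    rbind(make_records(2, island = "Cuba", ecomorph = e, prefix = paste0(e, "c")),
          make_records(2, island = "Jamaica", ecomorph = e,
                       prefix = paste0(e, "j")))))
  q <- enumerate_quartets(recs)
  expect_equal(nrow(q), 3L)
  # deterministic lexicographic ordering
  expect_equal(q$e1, c("grass-bush", "grass-bush", "trunk"))

  # removing one ecomorph from one island leaves 1 quartet
  recs2 <- recs[!(recs$ecomorph == "grass-bush" & recs$island == "Jamaica"), ]
  q2 <- enumerate_quartets(recs2)
  expect_equal(nrow(q2), 1L)
  expect_equal(unlist(q2[1, ], use.names = FALSE),
               c("trunk", "twig", "Cuba", "Jamaica"))

  # min_n filters small cells
  q3 <- enumerate_quartets(recs, min_n = 3L)
  expect_equal(nrow(q3), 0L)
})

test_that("the replicated study design yields 53 quartets", {
  pres <- default_presence_matrix()
  expect_equal(sum(pres), 21L)
  recs <- do.call(rbind, lapply(rownames(pres), function(i)
    do.call(rbind, lapply(colnames(pres)[pres[i, ]], function(e)
      make_records(2, island = i, ecomorph = e, prefix = paste0(i, e))))))
  expect_equal(nrow(enumerate_quartets(recs)), 53L)
})

test_that("permutation test is deterministic under seed and detects
           orthogonal divergence", {
  p <- 30
  shift_par <- rbind(3 * diag(p)[1, ], rep(0, p), 3 * diag(p)[1, ], rep(0, p))
  dat <- make_quartet_data(n_cell = 20, p = p, shift = shift_par, seed = 4)
  r1 <- permutation_parallel_test(dat$quartet, dat$traits, dat$records,
                                  n_perm = 99, seed = 101)
  r2 <- permutation_parallel_test(dat$quartet, dat$traits, dat$records,
                                  n_perm = 99, seed = 101)
  expect_identical(r1, r2)
  expect_true(r1$p_parallel > 0 && r1$p_parallel <= 1)

  # orthogonal true divergence with strong signal is detected
  shift_orth <- rbind(6 * diag(p)[1, ], rep(0, p), 6 * diag(p)[2, ], rep(0, p))
  dat_o <- make_quartet_data(n_cell = 40, p = p, shift = shift_orth, seed = 5)
  r_o <- permutation_parallel_test(dat_o$quartet, dat_o$traits, dat_o$records,
                                   n_perm = 199, seed = 7)
  expect_lte(r_o$p_parallel, 0.01)
  expect_error(permutation_parallel_test(dat$quartet, dat$traits,
                                         dat$records, n_perm = 50),
               "at least 99")
})

test_that("bootstrap orthogonality test rejects 90 for strongly parallel
           divergence and is seed-stable", {
  p <- 30
  # identical strong divergence on both islands: true angle ~ 0, far from 90
  shift <- rbind(5 * diag(p)[1, ], rep(0, p), 5 * diag(p)[1, ], rep(0, p))
  dat <- make_quartet_data(n_cell = 40, p = p, shift = shift, seed = 6)
  b1 <- bootstrap_orthogonality_test(dat$quartet, dat$traits, dat$records,
                                     n_boot = 199, seed = 11)
  expect_lt(b1$p_orthogonal, 0.05)
  b2 <- bootstrap_orthogonality_test(dat$quartet, dat$traits, dat$records,
                                     n_boot = 199, seed = 11)
  expect_identical(b1, b2)
})

test_that("quartet classification applies the two-test rule", {
  expect_equal(classify_quartet(0.40, 0.001), "indistinguishable_from_0")
  expect_equal(classify_quartet(0.001, 0.30), "indistinguishable_from_90")
  expect_equal(classify_quartet(0.001, 0.001), "between_0_and_90")
  expect_warning(amb <- classify_quartet(0.5, 0.5), "ambiguous")
  expect_equal(amb, "ambiguous")
})

test_that("outlier scan flags exactly the deviant traits", {
  v <- c(rep(0, 131), 10)
  names(v) <- sprintf("t%03d", 1:132)
  scan <- outlier_traits(v)
  expect_equal(scan$flagged, "t132")

  set.seed(8)
  mild <- rnorm(132)
  names(mild) <- sprintf("t%03d", 1:132)
  expect_length(outlier_traits(mild, prob = 0.999999)$flagged, 0L)
  expect_error(outlier_traits(rep(1, 132)), "constant")

  # calibration: ~ 132 * 2 * 0.05 = 13.2 flags expected on iid normals
  counts <- replicate(300, length(outlier_traits(rnorm(132))$flagged))
  expect_lt(abs(mean(counts) - 13.2), 1.5)
})

test_that("t-based and mean-difference angles agree across quartets", {
  set.seed(9)
  p <- 25
  th <- sapply(1:8, function(k) {
    shift <- rbind(rnorm(p, sd = 2), rep(0, p), rnorm(p, sd = 2), rep(0, p))
    dat <- make_quartet_data(n_cell = 30, p = p, shift = shift, seed = 100 + k)
    vt <- quartet_vectors(dat$quartet, dat$traits, dat$records)
    vm <- quartet_vectors(dat$quartet, dat$traits, dat$records,
                          method = "mean_difference")
    c(vector_angle(vt$v1, vt$v2), vector_angle(vm$v1, vm$v2))
  })
  expect_gt(cor(th[1, ], th[2, ]), 0.9)

  dat <- make_quartet_data(n_cell = 10, p = 10, seed = 10)
  expect_error(angle_method_correlation(dat$quartet, dat$traits, dat$records),
               "at least 3")
})

test_that("derived seeds are stable, label-sensitive and in integer range", {
  s1 <- derive_seed(42, "twig", "trunk", "Cuba", "Jamaica")
  s2 <- derive_seed(42, "twig", "trunk", "Cuba", "Jamaica")
  s3 <- derive_seed(42, "twig", "trunk", "Cuba", "Hispaniola")
  expect_identical(s1, s2)
  expect_false(s1 == s3)
  expect_true(s1 >= 0 && s1 < 2^31)
  expect_true(is.integer(s1))
})
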