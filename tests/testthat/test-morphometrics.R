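test_that("centroid size has its closed forms and scaling law", {
  sq <- rbind(c(0.5, 0.5, 0), c(0.5, -0.5, 0), c(-0.5, 0.5, 0),
              c(-0.5, -0.5, 0))
  expect_equal(centroid_size(sq), sqrt(2))
  set.seed(71)
  cfg <- matrix(rnorm(90), 30, 3)
  expect_equal(centroid_size(2 * cfg), 2 * centroid_size(cfg))
  # brute-force loop oracle
  cen <- colMeans(cfg)
  acc <- 0
  for (k in seq_len(nrow(cfg))) acc <- acc + sum((cfg[k, ] - cen)^2)
  expect_equal(centroid_size(cfg), sqrt(acc), tolerance = 1e-12)
})

test_that("GPA removes rigid motion and scale exactly", {
  set.seed(72)
  A <- matrix(rnorm(36), 12, 3)
  B <- 2.5 * A %*% random_rotation() + rep(1, 12) %o% c(3, -2, 7)
  gpa <- generalized_procrustes(configs_array(A, B))
  expect_lt(procrustes_distance(gpa$aligned[1, , ], gpa$aligned[2, , ]), 1e-10)
  expect_true(gpa$converged)
  # consensus centred at origin with unit centroid size
  expect_lt(max(abs(colMeans(gpa$consensus))), 1e-9)
  expect_equal(centroid_size(gpa$consensus), 1, tolerance = 1e-9)
  # aligned configurations centred
  expect_lt(max(abs(colMeans(gpa$aligned[1, , ]))), 1e-9)
  # original centroid sizes returned
  expect_equal(gpa$centroid_sizes[2] / gpa$centroid_sizes[1], 2.5,
               tolerance = 1e-9)
  expect_error(generalized_procrustes(configs_array(A, matrix(0, 12, 3))),
               "zero centroid size")
})

test_that("pairwise GPA agrees with the two-configuration Kabsch oracle", {
  set.seed(73)
  for (rep in 1:50) {
    A <- matrix(rnorm(60), 20, 3)
    B <- matrix(rnorm(60), 20, 3)
    gpa <- generalized_procrustes(configs_array(A, B))
    d_pkg <- procrustes_distance(gpa$aligned[1, , ], gpa$aligned[2, , ])
    d_oracle <- oracle_opa_distance(A, B)
    # GPA aligns both to the consensus; for n = 2 the residual distance
    # matches ordinary Procrustes superimposition
    expect_equal(d_pkg, d_oracle, tolerance = 1e-8)
  }
})

test_that("reflections are never used to superimpose mirror images", {
  set.seed(74)
  A <- matrix(rnorm(45), 15, 3)
  B <- A %*% diag(c(1, 1, -1))    # mirror image
  gpa <- generalized_procrustes(configs_array(A, B))
  d <- procrustes_distance(gpa$aligned[1, , ], gpa$aligned[2, , ])
  expect_gt(d, 1e-3)
  expect_equal(d, oracle_opa_distance(A, B, allow_reflection = FALSE),
               tolerance = 1e-8)
  # with reflections a perfect fit would exist
  expect_lt(oracle_opa_distance(A, B, allow_reflection = TRUE), 1e-10)
})

test_that("GPA distances are invariant under rigid motion of any input", {
  set.seed(75)
  configs <- lapply(1:5, function(i) matrix(rnorm(30), 10, 3))
  gpa1 <- generalized_procrustes(do.call(configs_array, configs))
  moved <- configs
  moved[[3]] <- 1.7 * configs[[3]] %*% random_rotation() +
    rep(1, 10) %o% c(5, 5, -5)
  gpa2 <- generalized_procrustes(do.call(configs_array, moved))
  d1 <- as.vector(sapply(1:5, function(i)
    procrustes_distance(gpa1$aligned[i, , ], gpa1$consensus)))
  d2 <- as.vector(sapply(1:5, function(i)
    procrustes_distance(gpa2$aligned[i, , ], gpa2$consensus)))
  expect_lt(max(abs(d1 - d2)), 1e-9)
})

test_that("semilandmark sliding projects onto tangents and never worsens fit", {
  # single curve semilandmark between two fixed neighbours: displacement is
  # the analytic projection of (consensus - position) onto the tangent
  config <- rbind(c(0, 0, 0), c(1, 0.2, 0), c(2, 0, 0))
  consensus <- rbind(c(0, 0, 0), c(1.4, 0.9, 0), c(2, 0, 0))
  roles <- c("curve_semi", "curve_semi", "curve_semi")
  # middle point slides along tangent from neighbours = (2,0,0) - (0,0,0)
  slid <- slide_semilandmarks(config, consensus, roles)
  tvec <- c(1, 0, 0)
  expected_mid <- config[2, ] + sum((consensus[2, ] - config[2, ]) * tvec) * tvec
  expect_equal(slid[2, ], expected_mid, tolerance = 1e-12)
  # already-optimal semilandmark does not move
  slid2 <- slide_semilandmarks(slid, consensus, roles)
  expect_equal(slid2[2, ], slid[2, ], tolerance = 1e-12)
  # objective never increases on random configurations (both criteria)
  set.seed(76)
  base <- .sphere_lattice_for_tests(24)
  roles24 <- rep(c("fixed", "surface_semi"), c(4, 20))
  for (rep in 1:5) {
    cfg <- base + matrix(rnorm(72, sd = 0.1), 24, 3)
    cons <- base
    d_before <- sum((cfg - cons)^2)
    d_after <- sum((slide_semilandmarks(cfg, cons, roles24, "procd") - cons)^2)
    expect_lte(d_after, d_before + 1e-12)
    be <- .bending_energy_for_tests(cons)
    bend <- function(x) sum(vapply(1:3, function(d)
      drop(t(x[, d] - cons[, d]) %*% be %*% (x[, d] - cons[, d])), numeric(1)))
    b_before <- bend(cfg)
    b_after <- bend(slide_semilandmarks(cfg, cons, roles24, "bending"))
    expect_lte(b_after, b_before + 1e-9)
  }
  # coincident curve neighbours give an informative error
  bad <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0))
  expect_error(slide_semilandmarks(bad, consensus, roles), "tangent")
})

test_that("sliding inside GPA reduces semilandmark variance", {
  set.seed(77)
  base <- .sphere_lattice_for_tests(30)
  roles <- rep(c("fixed", "surface_semi"), c(6, 24))
  configs <- lapply(1:8, function(i) base + matrix(rnorm(90, sd = 0.05), 30, 3))
  arr <- do.call(configs_array, configs)
  g_plain <- generalized_procrustes(arr)
  g_slide <- generalized_procrustes(arr, roles = roles, slide = "procd")
  ss <- function(g) sum(vapply(seq_len(dim(g$aligned)[1]), function(i)
    procrustes_distance(g$aligned[i, , ], g$consensus)^2, numeric(1)))
  expect_lt(ss(g_slide), ss(g_plain))
})

test_that("TPS interpolates anchors exactly and reduces to affine maps", {
  set.seed(78)
  S <- matrix(rnorm(24), 8, 3)
  Tg <- S + matrix(rnorm(24, sd = 0.3), 8, 3)
  # exact at anchors
  warped <- tps_warp_3d(S, Tg, S)
  diam <- max(dist(S))
  expect_lt(max(abs(warped - Tg)), 1e-8 * diam)
  # identity when target = source
  Q <- matrix(rnorm(30), 10, 3)
  expect_equal(tps_warp_3d(S, S, Q), Q, tolerance = 1e-10)
  # affine targets: nonlinear weights vanish, warp equals the affine map
  A <- matrix(c(1.2, 0.1, 0, -0.2, 0.9, 0.05, 0, 0.1, 1.1), 3, 3)
  b <- c(2, -1, 0.5)
  T_aff <- S %*% A + rep(1, 8) %o% b
  Q100 <- matrix(rnorm(300), 100, 3)
  expect_equal(tps_warp_3d(S, T_aff, Q100),
               Q100 %*% A + rep(1, 100) %o% b, tolerance = 1e-8)
  # degenerate anchors (coplanar) are singular
  S_flat <- cbind(matrix(rnorm(16), 8, 2), 0)
  expect_error(tps_warp_3d(S_flat, Tg, Q), "singular|degenerate")
})

test_that("surface patches land on the mesh and follow uniform scaling", {
  ico <- .unit_sphere_mesh_for_tests()
  set.seed(79)
  anchors <- ico$vertices[sample(nrow(ico$vertices), 8), ]
  surface <- ico$vertices[sample(nrow(ico$vertices), 25), ]
  # identical template and target: landmarks reproduced
  placed <- place_surface_patch(anchors, surface, anchors, ico)
  bbox <- sqrt(sum((apply(ico$vertices, 2, max) -
                    apply(ico$vertices, 2, min))^2))
  expect_lt(max(abs(placed - surface)), 1e-6 * bbox)
  # uniform x2 scaling: output is scaled template surface
  mesh2 <- triangle_mesh(2 * ico$vertices, ico$faces)
  placed2 <- place_surface_patch(anchors, surface, 2 * anchors, mesh2)
  expect_equal(placed2, 2 * surface, tolerance = 1e-6 * 2 * bbox)
  # contract: outputs lie on the mesh surface
  tgt <- triangle_mesh(ico$vertices * 1.3, ico$faces)
  placed3 <- place_surface_patch(anchors, surface, 1.3 * anchors, tgt)
  d_surf <- vapply(seq_len(nrow(placed3)), function(i)
    sqrt(sum((placed3[i, ] - project_to_mesh(placed3[i, , drop = FALSE], tgt))^2)),
    numeric(1))
  expect_lt(max(d_surf), 1e-6 * 1.3 * bbox)
})

test_that("shape PCA orients, centres and ranks components correctly", {
  set.seed(80)
  # variation along a single coordinate: PC1 carries 100% of variance
  base <- matrix(rnorm(30), 10, 3)
  n <- 12
  arr <- array(NA_real_, c(n, 10, 3))
  for (i in 1:n) { cfg <- base; cfg[1, 1] <- cfg[1, 1] + rnorm(1); arr[i, , ] <- cfg }
  pca <- shape_pca(arr)
  expect_equal(pca$proportion[1], 1, tolerance = 1e-9)
  expect_lt(max(abs(colMeans(pca$scores))), 1e-12)
  # two planted orthogonal directions with variances 4 and 1
  n2 <- 200
  X <- matrix(0, n2, 6)
  X[, 1] <- rnorm(n2, sd = 2)
  X[, 2] <- rnorm(n2, sd = 1)
  pca2 <- shape_pca(X)
  expect_equal(pca2$eigenvalues[1] / pca2$eigenvalues[2], 4, tolerance = 0.4)
  # sign convention: largest loading positive
  for (j in seq_len(ncol(pca2$loadings))) {
    l <- pca2$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  expect_error(shape_pca(X[1, , drop = FALSE]), "at least 2")
})

test_that("two-block PLS finds planted associations with exact p floor", {
  set.seed(81)
  X <- matrix(rnorm(200), 20)
  expect_equal(two_block_pls(X, X, n_perm = 99, seed = 1)$r_pls, 1)
  # planted rank-1 shared factor
  n <- 50
  f <- rnorm(n)
  u_true <- rep(1 / sqrt(8), 8); v_true <- rep(1 / sqrt(6), 6)
  B1 <- f %o% u_true + matrix(rnorm(n * 8, sd = 0.05), n)
  B2 <- f %o% v_true + matrix(rnorm(n * 6, sd = 0.05), n)
  pls <- two_block_pls(B1, B2, n_perm = 199, seed = 5)
  expect_equal(pls$p, 1 / 200)
  expect_gt(abs(sum(pls$u * u_true)), 0.99)
  expect_gt(pls$Z, 2)
  expect_error(two_block_pls(B1, B2[1:10, ], 99), "different numbers of rows")
  expect_error(two_block_pls(B1, matrix(1, n, 3), 99), "zero-variance")
})

test_that("Procrustes regression matches the univariate F and finds perfect fits", {
  set.seed(82)
  n <- 25
  x <- rnorm(n)
  # single-coordinate response: textbook simple-regression F
  y <- 2 * x + rnorm(n)
  pr <- procrustes_regression(matrix(y, ncol = 1), x, n_perm = 99, seed = 3)
  expect_equal(pr$F, oracle_univariate_F(y, x), tolerance = 1e-9)
  # exact linear multivariate response: R^2 = 1, p at the floor
  B <- matrix(rnorm(12), 1)
  Y <- x %o% as.vector(B) + rep(1, n) %o% rnorm(12)
  pr2 <- procrustes_regression(Y, x, n_perm = 199, seed = 3)
  expect_equal(pr2$R2, 1, tolerance = 1e-9)
  expect_equal(pr2$p, 1 / 200)
  expect_error(procrustes_regression(Y, rep(1, n), 99), "constant predictor")
})

test_that("permutation p values are reproducible and within (0, 1]", {
  set.seed(83)
  X <- matrix(rnorm(160), 16)
  Y <- matrix(rnorm(160), 16)
  a <- two_block_pls(X, Y, n_perm = 199, seed = 42)
  b <- two_block_pls(X, Y, n_perm = 199, seed = 42)
  expect_identical(a$r_perm, b$r_perm)
  expect_identical(a$p, b$p)
  expect_gte(a$p, 1 / 200); expect_lte(a$p, 1)
  pr_a <- procrustes_regression(Y, X[, 1], n_perm = 199, seed = 42)
  pr_b <- procrustes_regression(Y, X[, 1], n_perm = 199, seed = 42)
  expect_identical(pr_a$F_perm, pr_b$F_perm)
})
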