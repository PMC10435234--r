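toy_model <- function(p = 4, delta = 0, h = 0.5, L = 8) {
  regions <- sprintf("R%02d", seq_len(p))
  genetic_model(n_loci = L,
                delta = setNames(rep_len(delta, p), regions), h = h)
}

toy_spec <- function(p = 4, rw = 0.6, rb = -0.4) {
  regions <- sprintf("R%02d", seq_len(p))
  module_spec(setNames(rep(c("dorsal", "ventral"), each = p / 2), regions),
              rho_within = rw, rho_between = rb)
}

test_that("genotype scores match the cross design and binomial algebra", {
  model <- toy_model(L = 4)
  g <- simulate_genotypes(c(P1 = 5, P2 = 5, F1 = 5), model, seed = 1)
  expect_true(all(g$g[g$population == "P1"] == 0))
  expect_true(all(g$g[g$population == "P2"] == 1))
  expect_true(all(g$g[g$population == "F1"] == 0.5))
  # F2: mean 0.5, Var(g) = 0.125 / L
  f2 <- simulate_genotypes(c(F2 = 10000), model, seed = 2)
  expect_lt(abs(mean(f2$g) - 0.5), 0.01)
  expect_lt(abs(var(f2$g) - 0.03125), 0.005)
  expect_error(genetic_model(n_loci = 0, delta = c(A = 1)), "n_loci")
})

test_that("dominance map is additive at h = 0.5 and saturates at extremes", {
  g <- seq(0, 1, by = 0.25)
  expect_equal(dominance_value(g, 0.5), g)
  expect_equal(dominance_value(g, 1), pmin(1, 2 * g))       # P2 dominant
  expect_equal(dominance_value(g, 0), 1 - pmin(1, 2 * (1 - g)))
  expect_equal(dominance_value(0, 0.9), 0)                   # parents fixed
  expect_equal(dominance_value(1, 0.1), 1)
})

test_that("simulated volumes close to 1 and carry no spurious group effect", {
  model <- toy_model(p = 6, delta = 0)
  spec <- toy_spec(p = 6)
  g <- simulate_genotypes(c(P1 = 500, P2 = 500), model, seed = 3)
  sim <- simulate_volume_table(g, spec, model, sigma = 0.15, seed = 3)
  expect_lt(max(abs(rowSums(sim$table$fractions) - 1)), 1e-12)
  # delta = 0: population mean log-volume difference within 3 SE of 0
  lraw <- log(sim$raw)
  for (j in seq_len(ncol(lraw))) {
    a <- lraw[g$population == "P1", j]; b <- lraw[g$population == "P2", j]
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    expect_lt(abs(mean(a) - mean(b)), 3 * se + 1e-9)
  }
})

test_that("raw log-volume correlations converge to the module spec", {
  model <- toy_model(p = 10, delta = 0)
  spec <- toy_spec(p = 10)
  g <- simulate_genotypes(c(F2 = 500), model, seed = 5)
  sim <- simulate_volume_table(g, spec, model, sigma = 0.2, seed = 5)
  r <- cor(log(sim$raw))
  same <- outer(spec$assignment, spec$assignment, `==`)
  within <- r[same & upper.tri(r)]
  between <- r[!same & upper.tri(r)]
  expect_lt(abs(mean(within) - 0.6), 0.1)
  expect_lt(abs(mean(between) + 0.4), 0.1)
  expect_error(simulate_volume_table(g, spec, model, sigma = 0), "sigma")
})

test_that("compositional closure induces negative correlation at delta = 0", {
  model <- toy_model(p = 6, delta = 0)
  regions <- names(model$delta)
  spec <- module_spec(setNames(rep("m1", 6), regions),
                      rho_within = 0, rho_between = 0)
  g <- simulate_genotypes(c(F2 = 400), model, seed = 6)
  sim <- simulate_volume_table(g, spec, model, sigma = 0.2, seed = 6)
  raw_mean <- mean(cor(log(sim$raw))[upper.tri(diag(6))])
  frac_mean <- mean(cor(sim$table$fractions)[upper.tri(diag(6))])
  expect_lt(abs(raw_mean), 0.05)     # independent by construction
  expect_lt(frac_mean, -0.1)         # closure pushes fractions negative
})

test_that("non-PSD module specs are repaired or rejected as requested", {
  regions <- sprintf("R%02d", 1:9)
  assign3 <- setNames(rep(c("a", "b", "c"), each = 3), regions)
  # three modules with strongly negative between-correlation is non-PSD
  expect_error(module_spec(assign3, 0.9, -0.6, repair = FALSE),
               "positive semi-definite")
  spec <- module_spec(assign3, 0.9, -0.6, repair = TRUE)
  expect_true(spec$repaired)
  expect_gte(min(eigen(spec$R, symmetric = TRUE)$values), -1e-10)
  expect_equal(unname(diag(spec$R)), rep(1, 9))
})

test_that("rendered phantoms hit target fractions and are deterministic", {
  # two regions at 0.5/0.5 on a 64^3 grid
  fr <- matrix(c(0.5, 0.5), 1, dimnames = list("S1", c("A", "B")))
  assign2 <- c(A = "dorsal", B = "ventral")
  lv <- render_cohort_label_volumes(fr, assign2, grid_shape = c(64, 64, 64),
                                    seed = 9)[[1]]
  counts <- region_voxel_counts(lv)
  fracs <- relative_volumes(counts)
  expect_true(all(fracs >= 0.475 & fracs <= 0.525))
  # single region fills the whole brain by definition
  fr1 <- matrix(1, 1, dimnames = list("S1", "A"))
  lv1 <- render_cohort_label_volumes(fr1, c(A = "dorsal"),
                                     grid_shape = c(32, 32, 32), seed = 1)[[1]]
  expect_equal(unname(relative_volumes(region_voxel_counts(lv1))), 1)
  # same seed twice -> identical grids
  lv_b <- render_cohort_label_volumes(fr, assign2, grid_shape = c(64, 64, 64),
                                      seed = 9)[[1]]
  expect_identical(lv$grid, lv_b$grid)
  # voxel counts within 5% of target for regions >= 200 voxels
  sc <- default_scenario()
  cohort <- simulate_cohort(sc, seed = 2)
  lv20 <- render_cohort_label_volumes(
    cohort$volumes$table$fractions[1, , drop = FALSE],
    cohort$spec$assignment, seed = 2)[[1]]
  counts <- region_voxel_counts(lv20)
  target <- cohort$volumes$table$fractions[1, ] * sum(counts)
  rel_err <- abs(counts[paste0(1:20)] - target) / target
  expect_lt(max(rel_err[target >= 200]), 0.05)
})

test_that("dorsal module regions render at lower dorsoventral depth", {
  sc <- default_scenario()
  cohort <- simulate_cohort(sc, seed = 3)
  lv <- render_cohort_label_volumes(
    cohort$volumes$table$fractions[1, , drop = FALSE],
    cohort$spec$assignment, seed = 3)
  labels <- attr(lv, "region_labels")
  grid <- lv[[1]]$grid
  dv <- slice.index(grid, 3)
  dorsal <- names(cohort$spec$assignment)[cohort$spec$assignment == "dorsal"]
  mean_dv <- function(regs) mean(dv[grid %in% labels[regs]])
  expect_lt(mean_dv(dorsal),
            mean_dv(setdiff(names(labels), dorsal)))
})

test_that("landmark cohorts couple size to volume and are deterministic", {
  model <- toy_model(p = 4, delta = 0.3)
  spec <- toy_spec(p = 4)
  g <- simulate_genotypes(c(F2 = 8), model, seed = 11)
  sim <- simulate_volume_table(g, spec, model, seed = 11)
  # noise 0, no deformation: configurations identical up to scale and
  # centroid size exactly proportional to cube root of raw volume
  lm0 <- simulate_landmark_cohort(sim, deform_scale = 0, noise_sd = 0,
                                  seed = 11)
  arr <- landmark_array(lm0, "R01")
  cs <- apply(arr$coords, 1, centroid_size)
  vols <- sim$raw[arr$specimens, "R01"]
  ratio <- cs / vols^(1 / 3)
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
  norm1 <- arr$coords[1, , ] / cs[1]
  for (i in 2:dim(arr$coords)[1])
    expect_equal(arr$coords[i, , ] / cs[i], norm1, tolerance = 1e-9)
  # determinism
  lm_a <- simulate_landmark_cohort(sim, seed = 12)
  lm_b <- simulate_landmark_cohort(sim, seed = 12)
  expect_identical(as.data.frame(lm_a), as.data.frame(lm_b))
  expect_error(simulate_landmark_cohort(sim, noise_sd = -1), "noise_sd")
})

test_that("planted shared module scores are detected by two-block PLS", {
  model <- toy_model(p = 4, delta = 0.3)
  spec <- toy_spec(p = 4)
  g <- simulate_genotypes(c(F2 = 30), model, seed = 13)
  sim <- simulate_volume_table(g, spec, model, seed = 13)
  lm_tab <- simulate_landmark_cohort(sim, deform_scale = 15, noise_sd = 0.5,
                                     seed = 13)
  # R01 and R02 share the dorsal module score
  a1 <- landmark_array(lm_tab, "R01"); a2 <- landmark_array(lm_tab, "R02")
  g1 <- generalized_procrustes(a1$coords); g2 <- generalized_procrustes(a2$coords)
  pls <- two_block_pls(g1, g2, n_perm = 199, seed = 17)
  expect_lte(pls$p, 0.05)
})

test_that("segmentation perturbation preserves labels and degrades smoothly", {
  sc <- default_scenario(n_regions = 6L, grid_shape = c(32L, 32L, 32L))
  cohort <- simulate_cohort(sc, seed = 21)
  lv <- render_cohort_label_volumes(
    cohort$volumes$table$fractions[1, , drop = FALSE],
    cohort$spec$assignment, grid_shape = sc$grid_shape, brain_fill = 0.1,
    seed = 21)[[1]]
  # q = 0, shift = 0 is the identity
  expect_identical(perturb_segmentation(lv, 0, 0, seed = 1)$grid, lv$grid)
  labs <- names(region_voxel_counts(lv))
  summaries <- vapply(c(0, 0.1, 0.3), function(q) {
    pert <- perturb_segmentation(lv, shift_voxels = 1, flip_rate = q, seed = 5)
    expect_setequal(names(region_voxel_counts(pert)), labs)
    segmentation_concordance(lv, pert)$summary[["mean_r"]]
  }, numeric(1))
  expect_true(all(diff(summaries) <= 1e-12))
})

test_that("identical seeds reproduce entire cohorts exactly", {
  sc <- default_scenario(n_regions = 8L)
  a <- simulate_cohort(sc, seed = 33)
  b <- simulate_cohort(sc, seed = 33)
  expect_identical(a$volumes$raw, b$volumes$raw)
  expect_identical(a$volumes$table$fractions, b$volumes$table$fractions)
  expect_identical(as.data.frame(a$landmarks), as.data.frame(b$landmarks))
})
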