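# Independent oracles used to check the package's computations. These are
# deliberately naive re-derivations (loops, closed forms, text-book
# formulas) kept separate from the implementation under test.

# per-label voxel tally by explicit looping over labels
oracle_voxel_tally <- function(grid) {
  labs <- sort(unique(as.vector(grid)))
  labs <- labs[labs != 0]
  counts <- integer(length(labs))
  for (i in seq_along(labs)) {
    n <- 0L
    v <- as.vector(grid)
    for (chunk in split(v, ceiling(seq_along(v) / 65536)))
      n <- n + sum(chunk == labs[i])
    counts[i] <- n
  }
  names(counts) <- labs
  counts
}

# ordinary (two-configuration) Procrustes superimposition: centre both,
# scale to unit centroid size, rotate B onto A by the proper rotation from
# the SVD of the cross-product, and return the residual distance.
oracle_opa_distance <- function(A, B, allow_reflection = FALSE) {
  cenA <- sweep(A, 2, colMeans(A)); cenB <- sweep(B, 2, colMeans(B))
  cenA <- cenA / sqrt(sum(cenA^2)); cenB <- cenB / sqrt(sum(cenB^2))
  M <- t(cenB) %*% cenA
  sv <- svd(M)
  d <- diag(3)
  if (!allow_reflection) d[3, 3] <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% d %*% t(sv$v)
  sqrt(sum((cenA - cenB %*% R)^2))
}

# text-book univariate simple-regression F statistic
oracle_univariate_F <- function(y, x) {
  fit <- lm(y ~ x)
  summary(fit)$fstatistic[["value"]]
}

# Pearson correlation from first principles
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# small deterministic test ontology: 6 fine under 2 developmental under 1
# major, ids chosen non-contiguously on purpose
toy_ontology <- function() {
  region_ontology(data.frame(
    region_id = c(1:6, 10, 11, 20),
    name = c(paste0("fine", 1:6), "dev_a", "dev_b", "brain"),
    parent_id = c(10, 10, 10, 11, 11, 11, 20, 20, NA),
    level = c(rep("fine", 6), rep("developmental", 2), "major")))
}

# random multi-region phantom on a small grid
toy_phantom <- function(n_labels = 6, dims = c(12, 12, 12), seed = 1) {
  set.seed(seed)
  label_volume(array(sample(0:n_labels, prod(dims), replace = TRUE), dims))
}

# n x K x 3 array from a list of matrices
configs_array <- function(...) {
  lst <- list(...)
  K <- nrow(lst[[1]])
  arr <- array(NA_real_, c(length(lst), K, 3))
  for (i in seq_along(lst)) arr[i, , ] <- lst[[i]]
  arr
}

# independent golden-spiral sphere lattice (same construction the generator
# documents, re-derived here)
.sphere_lattice_for_tests <- function(K) {
  i <- seq_len(K) - 0.5
  phi <- acos(1 - 2 * i / K)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# bending energy matrix re-derived from the 3-D TPS system; the kernel-r
# block is negative semidefinite, so the energy form is its negation
.bending_energy_for_tests <- function(ref) {
  K <- nrow(ref)
  L <- rbind(cbind(as.matrix(dist(ref)), cbind(1, ref)),
             cbind(t(cbind(1, ref)), matrix(0, 4, 4)))
  B <- -solve(L)[1:K, 1:K]
  (B + t(B)) / 2
}

# UV-sphere triangle mesh (unit radius) built from a lat-long grid
.unit_sphere_mesh_for_tests <- function(n_lat = 12, n_lon = 18) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 2)[2:(n_lat + 1)]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[seq_len(n_lon)]
  grid <- expand.grid(lat = lat, lon = lon)
  v <- with(grid, cbind(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat)))
  v <- rbind(v, c(0, 0, -1), c(0, 0, 1))
  south <- nrow(v) - 1L; north <- nrow(v)
  idx <- function(i, j) (j - 1L) * n_lat + i   # i = lat row, j = lon col
  faces <- list()
  for (j in seq_len(n_lon)) {
    jn <- j %% n_lon + 1L
    for (i in seq_len(n_lat - 1L)) {
      faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i, jn))
      faces[[length(faces) + 1L]] <- c(idx(i + 1L, j), idx(i + 1L, jn), idx(i, jn))
    }
    faces[[length(faces) + 1L]] <- c(south, idx(1L, j), idx(1L, jn))
    faces[[length(faces) + 1L]] <- c(north, idx(n_lat, jn), idx(n_lat, j))
  }
  triangle_mesh(v, do.call(rbind, faces))
}

random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_res)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
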