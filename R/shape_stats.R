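# flatten aligned configurations to an n x 3K matrix (x-block, y-block,
# z-block per specimen, column-major over landmarks)
.flatten_shapes <- function(x) {
  if (inherits(x, "gpa_result")) x <- x$aligned
  if (length(dim(x)) == 3L) {
    n <- dim(x)[1L]
    matrix(x, nrow = n)
  } else as.matrix(x)
}

#' Principal component analysis of aligned shapes
#'
#' Singular value decomposition of the row-centred flattened Procrustes
#' coordinates, giving the orthogonal axes that best represent shape
#' variation. Each component is oriented so that its largest-magnitude
#' loading is positive (the SVD sign is otherwise arbitrary).
#'
#' @param gpa a `gpa_result`, an n x K x 3 array, or an n x p matrix.
#' @return An object of class `shape_pca`: `scores` (n x p), `eigenvalues`
#'   (variances, non-increasing), `loadings` (columns = components),
#'   `proportion` (variance proportions).
#' @export
shape_pca <- function(gpa) {
  X <- .flatten_shapes(gpa)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 specimens")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  keep <- sv$d > max(sv$d[1L], 1) * 1e-12
  d <- sv$d[keep]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d, nrow = length(d))
  loadings <- sv$v[, keep, drop = FALSE]
  flip <- vapply(seq_len(ncol(loadings)), function(j) {
    l <- loadings[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(scores, 2L, flip, `*`)
  loadings <- sweep(loadings, 2L, flip, `*`)
  eig <- d^2 / (n - 1)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_along(d))
  structure(list(scores = scores, eigenvalues = eig, loadings = loadings,
                 proportion = eig / sum(eig)),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("shape_pca: %d specimens, %d components; PC1 %.1f%% of variance\n",
              nrow(x$scores), length(x$eigenvalues), 100 * x$proportion[1L]))
  invisible(x)
}

#' Two-block partial least squares with permutation test
#'
#' Measures the association between two multivariate trait blocks (e.g. the
#' complete landmark configurations of two brain regions) as the singular
#' structure of their cross-block covariance: both blocks are column
#' centred, the cross-covariance `t(X1) X2 / (n - 1)` is decomposed by SVD,
#' and `r_pls` is the absolute Pearson correlation of the first paired
#' scores. Significance comes from a permutation null that row-shuffles the
#' second block; `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)` and `Z` is
#' the plain standardization of the observed value against the permutation
#' distribution.
#'
#' @param block1,block2 n x p matrices (or `gpa_result`s, flattened).
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed for the permutation stream.
#' @return An object of class `pls_result`: `r_pls`, `u`, `v` (first
#'   singular vectors), `scores1`, `scores2`, `Z`, `p`, `n_perm`, `seed`,
#'   `r_perm`.
#' @export
two_block_pls <- function(block1, block2, n_perm = 999L, seed = 1L) {
  X1 <- .flatten_shapes(block1); X2 <- .flatten_shapes(block2)
  if (nrow(X1) != nrow(X2)) stop("blocks have different numbers of rows")
  n <- nrow(X1)
  if (n < 4L) stop("need at least 4 specimens")
  n_perm <- as.integer(n_perm)
  if (n_perm < 99L) stop("n_perm must be at least 99")
  if (all(apply(X1, 2L, stats::sd) == 0) || all(apply(X2, 2L, stats::sd) == 0))
    stop("zero-variance block")
  X1c <- scale(X1, center = TRUE, scale = FALSE)
  X2c <- scale(X2, center = TRUE, scale = FALSE)
  r_of <- function(B2c) {
    sv <- svd(crossprod(X1c, B2c) / (n - 1), nu = 1L, nv = 1L)
    s1 <- X1c %*% sv$u; s2 <- B2c %*% sv$v
    if (stats::sd(s1) == 0 || stats::sd(s2) == 0) return(0)
    abs(stats::cor(s1, s2)[1L])
  }
  sv <- svd(crossprod(X1c, X2c) / (n - 1), nu = 1L, nv = 1L)
  s1 <- X1c %*% sv$u; s2 <- X2c %*% sv$v
  r_obs <- abs(stats::cor(s1, s2)[1L])
  r_perm <- numeric(n_perm)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (b in seq_len(n_perm))
    r_perm[b] <- r_of(X2c[sample.int(n), , drop = FALSE])
  p <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  Z <- (r_obs - mean(r_perm)) / stats::sd(r_perm)
  structure(list(r_pls = r_obs, u = sv$u[, 1L], v = sv$v[, 1L],
                 scores1 = as.vector(s1), scores2 = as.vector(s2),
                 Z = Z, p = p, n_perm = n_perm, seed = seed, r_perm = r_perm),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("two-block PLS: r-PLS = %.4f, Z = %.3f, p = %.4g (%d permutations)\n",
              x$r_pls, x$Z, x$p, x$n_perm))
  invisible(x)
}

#' Procrustes regression with residual randomization
#'
#' Multivariate regression of aligned shape coordinates on a single
#' predictor (centroid size for allometry, relative volume for shape~volume
#' association). Sums of squares are traces over all coordinates of the
#' full (`~ 1 + x`) versus reduced (`~ 1`) least-squares fits;
#' `F = SS_effect / (SSR_full / (n - 2))` and `R^2 = SS_effect / SS_total`.
#' Significance uses residual-randomization permutation (RRPP): reduced-
#' model residuals are row-permuted, added back to the reduced fit, and F
#' recomputed; `p` and `Z` follow the same conventions as [two_block_pls()].
#'
#' @param shapes a `gpa_result`, n x K x 3 array, or n x p matrix.
#' @param predictor numeric length-n, non-constant.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed.
#' @return An object of class `procd_result`: `SS_effect`, `SS_residual`,
#'   `SS_total`, `F`, `R2`, `df`, `Z`, `p`, `n_perm`, `seed`, `F_perm`.
#' @export
procrustes_regression <- function(shapes, predictor, n_perm = 999L,
                                  seed = 1L) {
  Y <- .flatten_shapes(shapes)
  x <- as.numeric(predictor)
  n <- nrow(Y)
  if (length(x) != n) stop("predictor length must match specimen count")
  if (n < 4L) stop("need at least 4 specimens")
  if (stats::sd(x) == 0) stop("constant predictor")
  n_perm <- as.integer(n_perm)
  if (n_perm < 99L) stop("n_perm must be at least 99")
  Yc <- scale(Y, center = TRUE, scale = FALSE)   # reduced-model residuals
  xc <- x - mean(x)
  SS_total <- sum(Yc^2)
  F_of <- function(E) {
    # E: reduced-model residuals; effect SS from regressing E on centred x
    beta <- crossprod(xc, E) / sum(xc^2)
    ss_eff <- sum(xc^2) * sum(beta^2)
    ssr_full <- sum(E^2) - ss_eff
    (ss_eff / 1) / (ssr_full / (n - 2))
  }
  F_obs <- F_of(Yc)
  beta <- crossprod(xc, Yc) / sum(xc^2)
  SS_effect <- sum(xc^2) * sum(beta^2)
  SS_resid <- SS_total - SS_effect
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  F_perm <- numeric(n_perm)
  for (b in seq_len(n_perm))
    F_perm[b] <- F_of(Yc[sample.int(n), , drop = FALSE])
  p <- (1 + sum(F_perm >= F_obs)) / (1 + n_perm)
  Z <- (F_obs - mean(F_perm)) / stats::sd(F_perm)
  structure(list(SS_effect = SS_effect, SS_residual = SS_resid,
                 SS_total = SS_total, F = F_obs,
                 R2 = SS_effect / SS_total, df = c(1L, n - 2L),
                 Z = Z, p = p, n_perm = n_perm, seed = seed, F_perm = F_perm),
            class = "procd_result")
}

#' @export
print.procd_result <- function(x, ...) {
  cat(sprintf("Procrustes regression: F(%d, %d) = %.4f, R2 = %.4f, Z = %.3f, Pr(>F) = %.4g\n",
              x$df[1L], x$df[2L], x$F, x$R2, x$Z, x$p))
  invisible(x)
}

# save/restore the global RNG state so seeded permutation tests do not
# disturb the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
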