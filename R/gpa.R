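#' Centroid size of a landmark configuration
#'
#' The standard size measure in geometric morphometrics: the square root of
#' the summed squared distances of all landmarks from their centroid.
#'
#' @param config K x 3 numeric matrix of landmark coordinates.
#' @return Centroid size (non-negative scalar).
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  cen <- colMeans(config)
  sqrt(sum(sweep(config, 2L, cen)^2))
}

# Optimal rotation (det = +1, no reflection) carrying X onto Y:
# minimizes ||Y - X R||_F over proper rotations R.
.kabsch_rotation <- function(X, Y) {
  C <- crossprod(X, Y)
  sv <- svd(C)
  s <- sign(det(sv$u) * det(sv$v))
  sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
}

#' Procrustes distance between two aligned configurations
#' @param a,b K x 3 matrices (already superimposed).
#' @return `sqrt(sum((a - b)^2))`.
#' @export
procrustes_distance <- function(a, b) sqrt(sum((a - b)^2))

#' Generalized Procrustes analysis
#'
#' Iteratively removes translation, rotation and (optionally) scale from a
#' set of landmark configurations: each configuration is centred, scaled to
#' unit centroid size (if `scale`), and rotated onto the running consensus
#' by the optimal proper rotation (no reflections — specimens share
#' chirality); the consensus is the re-centred, re-scaled mean. Curve and
#' surface semilandmarks may additionally slide within their tangent spaces
#' each outer iteration (see [slide_semilandmarks()]). Iteration stops when
#' the root-sum-square change of the consensus drops below `tol`.
#'
#' @param coords n x K x 3 array of configurations (or list of K x 3
#'   matrices).
#' @param scale if `TRUE` (default) remove size by scaling to unit centroid
#'   size; centroid sizes are always returned so allometry can be studied
#'   explicitly.
#' @param roles optional length-K character vector (`fixed`, `curve_semi`,
#'   `surface_semi`); needed when `slide != "none"`.
#' @param slide sliding criterion for semilandmarks: `"none"` (default),
#'   `"procd"` (minimize Procrustes distance to consensus) or `"bending"`
#'   (minimize thin-plate-spline bending energy).
#' @param mesh optional [triangle_mesh()] supplying surface normals for
#'   surface semilandmark tangent planes.
#' @param slide_iters number of outer iterations during which semilandmarks
#'   slide (default 5). Sliding re-estimates tangents from the current
#'   configuration, so indefinitely repeated sliding chases the moving
#'   consensus at a small plateau instead of converging; a fixed number of
#'   sliding passes followed by pure alignment iterations is the standard
#'   remedy and keeps the procedure deterministic.
#' @param tol convergence tolerance on the consensus (default 1e-10).
#' @param max_iter maximum outer iterations (default 200).
#' @return An object of class `gpa_result`: `aligned` (n x K x 3),
#'   `consensus` (K x 3, centred, unit centroid size), `centroid_sizes`
#'   (original sizes), `iterations`, `converged`.
#' @export
generalized_procrustes <- function(coords, scale = TRUE, roles = NULL,
                                   slide = c("none", "procd", "bending"),
                                   mesh = NULL, slide_iters = 5L,
                                   tol = 1e-10, max_iter = 200L) {
  slide <- match.arg(slide)
  if (is.list(coords)) {
    n <- length(coords); K <- nrow(coords[[1L]])
    arr <- array(NA_real_, c(n, K, 3L))
    for (i in seq_len(n)) arr[i, , ] <- as.matrix(coords[[i]])
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3L] == 3L)
  n <- dim(coords)[1L]; K <- dim(coords)[2L]
  if (n < 2L) stop("need at least two configurations")
  if (K < 3L) stop("need at least three landmarks")
  if (slide != "none" && is.null(roles))
    stop("`roles` required when sliding semilandmarks")
  X <- coords
  cs <- numeric(n)
  for (i in seq_len(n)) {
    xi <- X[i, , ]
    xi <- sweep(xi, 2L, colMeans(xi))
    cs[i] <- sqrt(sum(xi^2))
    if (cs[i] == 0) stop("configuration ", i, " has zero centroid size")
    if (scale) xi <- xi / cs[i]
    X[i, , ] <- xi
  }
  consensus <- X[1L, , ]
  consensus <- consensus / sqrt(sum(consensus^2))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (i in seq_len(n)) {
      R <- .kabsch_rotation(X[i, , ], consensus)
      X[i, , ] <- X[i, , ] %*% R
    }
    if (slide != "none" && it <= slide_iters) {
      for (i in seq_len(n)) {
        xi <- slide_semilandmarks(X[i, , ], consensus, roles,
                                  criterion = slide, mesh = mesh)
        xi <- sweep(xi, 2L, colMeans(xi))
        if (scale) xi <- xi / sqrt(sum(xi^2))
        X[i, , ] <- xi
      }
    }
    new_cons <- apply(X, c(2L, 3L), mean)
    new_cons <- sweep(new_cons, 2L, colMeans(new_cons))
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("generalized Procrustes did not converge in ", max_iter,
            " iterations")
  structure(list(aligned = X, consensus = consensus, centroid_sizes = cs,
                 iterations = it, converged = converged, scale = scale),
            class = "gpa_result")
}

#' @export
print.gpa_result <- function(x, ...) {
  cat(sprintf("gpa_result: %d specimens x %d landmarks, %d iteration(s)%s\n",
              dim(x$aligned)[1L], dim(x$aligned)[2L], x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

# Bending energy matrix of a reference configuration (K x K). For the 3-D
# kernel U(r) = r the upper-left block of the inverse TPS system is
# negative semidefinite on the complement of the affine subspace (the
# kernel -r is the conditionally positive definite one), so the energy
# quadratic form is its negation.
.bending_energy_matrix <- function(ref) {
  K <- nrow(ref)
  D <- as.matrix(stats::dist(ref))
  P <- cbind(1, ref)
  L <- rbind(cbind(D, P), cbind(t(P), matrix(0, 4L, 4L)))
  Li <- solve(L)
  B <- -Li[seq_len(K), seq_len(K), drop = FALSE]
  (B + t(B)) / 2
}

# Orthonormal tangent basis per semilandmark: list of 3 x p matrices
# (p = 1 for curves, 2 for surfaces); NULL for fixed landmarks.
.tangent_bases <- function(config, roles, mesh = NULL, k_neighbors = 8L) {
  K <- nrow(config)
  bases <- vector("list", K)
  curve_idx <- which(roles == "curve_semi")
  for (j in seq_len(K)) {
    if (roles[j] == "curve_semi") {
      pos <- match(j, curve_idx)
      prev <- if (pos > 1L) curve_idx[pos - 1L] else j
      nxt <- if (pos < length(curve_idx)) curve_idx[pos + 1L] else j
      tvec <- config[nxt, ] - config[prev, ]
      nt <- sqrt(sum(tvec^2))
      if (nt < 1e-12)
        stop("undefined curve tangent at landmark ", j,
             " (coincident neighbours)")
      bases[[j]] <- matrix(tvec / nt, ncol = 1L)
    } else if (roles[j] == "surface_semi") {
      if (!is.null(mesh)) {
        nrm <- .mesh_normal_at(config[j, ], mesh)
      } else {
        d2 <- rowSums(sweep(config, 2L, config[j, ])^2)
        nb <- order(d2)[seq_len(min(k_neighbors + 1L, K))]
        pts <- config[nb, , drop = FALSE]
        pts <- sweep(pts, 2L, colMeans(pts))
        sv <- svd(pts)
        if (sv$d[2L] < 1e-12)
          stop("undefined surface tangent at landmark ", j,
               " (degenerate neighbourhood)")
        nrm <- sv$v[, 3L]
      }
      # orthonormal basis of the plane orthogonal to the normal
      b1 <- if (abs(nrm[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      t1 <- b1 - sum(b1 * nrm) * nrm; t1 <- t1 / sqrt(sum(t1^2))
      t2 <- c(nrm[2L] * t1[3L] - nrm[3L] * t1[2L],
              nrm[3L] * t1[1L] - nrm[1L] * t1[3L],
              nrm[1L] * t1[2L] - nrm[2L] * t1[1L])
      bases[[j]] <- cbind(t1, t2)
    }
  }
  bases
}

.mesh_normal_at <- function(p, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  cent <- (v[f[, 1L], , drop = FALSE] + v[f[, 2L], , drop = FALSE] +
           v[f[, 3L], , drop = FALSE]) / 3
  t <- which.min(rowSums(sweep(cent, 2L, p)^2))
  e1 <- v[f[t, 2L], ] - v[f[t, 1L], ]
  e2 <- v[f[t, 3L], ] - v[f[t, 1L], ]
  nrm <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
           e1[3L] * e2[1L] - e1[1L] * e2[3L],
           e1[1L] * e2[2L] - e1[2L] * e2[1L])
  nrm / sqrt(sum(nrm^2))
}

#' Slide semilandmarks within their tangent spaces
#'
#' Curve semilandmarks slide along the 1-D tangent estimated from their
#' neighbouring curve landmarks; surface semilandmarks slide within the 2-D
#' tangent plane estimated from the 8 nearest landmarks (or the mesh normal
#' when a mesh is supplied). Under the `"procd"` criterion each semilandmark
#' is displaced by the orthogonal projection of its offset from the
#' consensus onto the tangent space — the landmark-wise closed-form
#' minimizer of squared Procrustes distance. Under `"bending"` all sliding
#' parameters are solved jointly from the thin-plate-spline bending-energy
#' linear system of the consensus. Either way the criterion value cannot
#' increase (the unslid position is the zero of the sliding parameters).
#'
#' @param config K x 3 configuration to slide.
#' @param consensus K x 3 reference configuration.
#' @param roles length-K roles (`fixed`, `curve_semi`, `surface_semi`).
#' @param criterion `"procd"` (default) or `"bending"`.
#' @param mesh optional [triangle_mesh()] for surface tangents.
#' @return The updated K x 3 configuration.
#' @export
slide_semilandmarks <- function(config, consensus, roles,
                                criterion = c("procd", "bending"),
                                mesh = NULL) {
  criterion <- match.arg(criterion)
  config <- as.matrix(config)
  K <- nrow(config)
  stopifnot(length(roles) == K)
  semi <- which(roles != "fixed")
  if (!length(semi)) return(config)
  bases <- .tangent_bases(config, roles, mesh)
  if (criterion == "procd") {
    for (j in semi) {
      Tj <- bases[[j]]
      off <- consensus[j, ] - config[j, ]
      config[j, ] <- config[j, ] + as.vector(Tj %*% crossprod(Tj, off))
    }
    return(config)
  }
  # bending energy: minimize sum_d (y_d + U_d t)' Be (y_d + U_d t) over the
  # stacked sliding parameters t, with y the offset from the consensus
  Be <- .bending_energy_matrix(consensus)
  p_j <- vapply(seq_len(K), function(j)
    if (is.null(bases[[j]])) 0L else ncol(bases[[j]]), integer(1))
  P <- sum(p_j)
  offs <- c(0L, cumsum(p_j))[seq_len(K)]
  A <- matrix(0, P, P); b <- numeric(P)
  Y <- config - consensus
  for (d in 1:3) {
    Ud <- matrix(0, K, P)
    for (j in semi)
      Ud[j, offs[j] + seq_len(p_j[j])] <- bases[[j]][d, ]
    BU <- Be %*% Ud
    A <- A + crossprod(Ud, BU)
    b <- b - crossprod(Ud, Be %*% Y[, d])
  }
  t_par <- tryCatch(solve(A, b),
                    error = function(e) solve(A + diag(1e-10, P), b))
  for (j in semi) {
    tj <- t_par[offs[j] + seq_len(p_j[j])]
    config[j, ] <- config[j, ] + as.vector(bases[[j]] %*% tj)
  }
  config
}
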