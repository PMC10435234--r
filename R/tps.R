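#' Three-dimensional thin-plate-spline warp
#'
#' Fits the 3-D thin-plate spline interpolant (radial kernel U(r) = r plus
#' an affine term) that carries `source_lms` exactly onto `target_lms`, and
#' evaluates it at `query_points`. When source and target are related by an
#' affine map the nonlinear weights vanish and the warp reduces to that
#' affine map everywhere.
#'
#' @param source_lms K x 3 matrix of anchor landmarks (K >= 4, not coplanar).
#' @param target_lms K x 3 matrix of corresponding targets.
#' @param query_points Q x 3 matrix of points to warp.
#' @return Q x 3 matrix of warped points.
#' @export
tps_warp_3d <- function(source_lms, target_lms, query_points) {
  S <- as.matrix(source_lms); Tg <- as.matrix(target_lms)
  Q <- matrix(as.numeric(query_points), ncol = 3L)
  if (nrow(S) != nrow(Tg)) stop("source and target landmark counts differ")
  K <- nrow(S)
  if (K < 4L) stop("need at least 4 anchor landmarks")
  D <- as.matrix(stats::dist(S))
  P <- cbind(1, S)
  L <- rbind(cbind(D, P), cbind(t(P), matrix(0, 4L, 4L)))
  rhs <- rbind(Tg, matrix(0, 4L, 3L))
  coef <- tryCatch(solve(L, rhs), error = function(e)
    stop("degenerate landmark geometry: TPS system is singular"))
  W <- coef[seq_len(K), , drop = FALSE]
  A <- coef[K + 1:4, , drop = FALSE]
  # distances from each query point to each source landmark
  U <- sqrt(pmax(outer(rowSums(Q^2), rep(1, K)) +
                 outer(rep(1, nrow(Q)), rowSums(S^2)) -
                 2 * Q %*% t(S), 0))   # clamp float negatives before sqrt
  cbind(1, Q) %*% A + U %*% W
}

#' Transfer template surface landmarks onto a specimen mesh
#'
#' The semi-automated surface patching used to landmark smooth regions: the
#' template's surface semilandmarks are carried over by a thin-plate-spline
#' warp anchored on the shared fixed and curve landmarks, then snapped onto
#' the specimen surface by exact closest-point projection onto its triangle
#' mesh.
#'
#' @param template_anchors K x 3 fixed/curve landmarks of the template.
#' @param template_surface S x 3 surface semilandmarks of the template.
#' @param target_anchors K x 3 corresponding landmarks on the specimen.
#' @param target_mesh [triangle_mesh()] of the specimen surface.
#' @return S x 3 matrix of surface landmarks on the specimen mesh.
#' @export
place_surface_patch <- function(template_anchors, template_surface,
                                target_anchors, target_mesh) {
  stopifnot(inherits(target_mesh, "triangle_mesh"))
  warped <- tps_warp_3d(template_anchors, target_anchors, template_surface)
  project_to_mesh(warped, target_mesh)
}
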