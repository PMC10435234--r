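#' Per-region shape PC1 score matrix
#'
#' For every requested region: generalized Procrustes alignment, shape PCA,
#' and extraction of the first principal component scores over the common
#' specimen set. Because a principal component's sign is arbitrary, each
#' region's PC1 is oriented so that its Pearson correlation with that
#' region's relative volume is non-negative (ties fall back to the
#' largest-loading-positive convention of [shape_pca()]); the applied flips
#' are recorded, making the cross-region correlation sign structure
#' well-defined.
#'
#' @param landmarks a `landmark_table`.
#' @param volumes a `volume_table` whose columns include the landmarked
#'   regions and whose specimens cover the landmark specimens.
#' @param regions regions to include (default: all in `landmarks`).
#' @param slide,mesh passed to [generalized_procrustes()].
#' @return An object of class `pc1_matrix`: `scores` (individuals x
#'   regions, columns mean 0), `flipped` (named logical), `specimens`.
#' @export
pc1_score_matrix <- function(landmarks, volumes, regions = NULL,
                             slide = "none", mesh = NULL) {
  stopifnot(inherits(landmarks, "landmark_table"),
            inherits(volumes, "volume_table"))
  if (is.null(regions)) regions <- unique(landmarks$region)
  miss <- setdiff(regions, colnames(volumes$fractions))
  if (length(miss))
    stop("region(s) missing from volume table: ", paste(miss, collapse = ", "))
  # common specimen set across all regions and the volume table
  specs <- volumes$specimen_id
  for (reg in regions) {
    la <- landmark_array(landmarks, reg)
    specs <- intersect(specs, la$specimens)
  }
  if (length(specs) < 3L) {
    missing <- setdiff(volumes$specimen_id, specs)
    stop("fewer than 3 specimens shared across regions and volumes; missing: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  dropped <- length(volumes$specimen_id) - length(specs)
  scores <- matrix(NA_real_, length(specs), length(regions),
                   dimnames = list(specs, regions))
  flipped <- stats::setNames(logical(length(regions)), regions)
  for (reg in regions) {
    la <- landmark_array(landmarks, reg)
    keep <- match(specs, la$specimens)
    gpa <- generalized_procrustes(la$coords[keep, , , drop = FALSE],
                                  roles = la$roles, slide = slide,
                                  mesh = mesh)
    pc1 <- shape_pca(gpa)$scores[, 1L]
    vol <- volumes$fractions[specs, reg]
    r <- suppressWarnings(stats::cor(pc1, vol))
    if (is.finite(r) && r < 0) {
      pc1 <- -pc1
      flipped[reg] <- TRUE
    }
    scores[, reg] <- pc1
  }
  structure(list(scores = scores, flipped = flipped, specimens = specs,
                 n_dropped = dropped),
            class = "pc1_matrix")
}

#' Shape-covariation module analysis
#'
#' Clusters regions by the covariation of their shape PC1 scores across
#' individuals, with exactly the conventions of the volume analysis
#' (Pearson correlation; distance 1 - r; [cluster_regions()]), so shape and
#' volume partitions are directly comparable.
#'
#' @param pc1 a `pc1_matrix` (or individuals x regions matrix).
#' @param linkage,k,h passed to [cluster_regions()].
#' @return List with `correlation` (a `correlation_matrix`) and `partition`
#'   (a `cluster_partition`).
#' @export
shape_module_analysis <- function(pc1, linkage = "average", k = NULL,
                                  h = NULL) {
  scores <- if (inherits(pc1, "pc1_matrix")) pc1$scores else as.matrix(pc1)
  corr <- volume_correlation_matrix(scores)
  partition <- cluster_regions(corr, linkage = linkage, k = k, h = h)
  list(correlation = corr, partition = partition)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions,
#' about 0 for independent random ones. Accepts `cluster_partition`s or
#' plain named membership vectors over the same region set.
#'
#' @param p1,p2 partitions of the same regions.
#' @return The adjusted Rand index.
#' @export
partition_agreement <- function(p1, p2) {
  c1 <- if (inherits(p1, "cluster_partition")) p1$cluster else p1
  c2 <- if (inherits(p2, "cluster_partition")) p2$cluster else p2
  if (is.null(names(c1)) || is.null(names(c2))) {
    if (length(c1) != length(c2))
      stop("unnamed partitions must have equal length")
  } else {
    if (!setequal(names(c1), names(c2)))
      stop("partitions cover different region sets")
    c2 <- c2[names(c1)]
  }
  tab <- table(c1, c2)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}
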