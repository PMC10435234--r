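#' Cross-individual region-volume correlation matrix
#'
#' Pearson correlation of every region pair across individuals (typically F2
#' hybrids, where trait segregation makes covariation informative about
#' shared developmental control). Regions with zero variance are an error —
#' they carry no covariation signal and would produce undefined entries.
#'
#' @param vt a `volume_table`, or a plain specimens x regions numeric matrix.
#' @return An object of class `correlation_matrix`: list with `r` (regions x
#'   regions), `regions`, `n` (individuals used).
#' @export
volume_correlation_matrix <- function(vt) {
  mat <- if (inherits(vt, "volume_table")) vt$fractions else as.matrix(vt)
  if (nrow(mat) < 3L) stop("need at least 3 individuals")
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant region(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "))
  r <- stats::cor(mat)
  # numerical guard: exact symmetry and unit diagonal
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(list(r = r, regions = colnames(mat), n = nrow(mat)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  cat(sprintf("correlation_matrix: %d regions, n = %d individuals; off-diagonal r in [%.3f, %.3f]\n",
              length(x$regions), x$n, min(off), max(off)))
  invisible(x)
}

#' Cluster regions by correlation distance
#'
#' Converts the correlation matrix to the distance d = 1 - r (so perfectly
#' positively covarying regions are at distance 0 and perfectly
#' anticorrelated ones at distance 2 — modules are sets of *positively*
#' covarying regions) and applies agglomerative hierarchical clustering.
#' The tree is cut either into `k` clusters or at a height threshold
#' (default 0.7 x the maximum merge height). Cluster ids are renumbered
#' canonically by each cluster's smallest member (in region-name order), so
#' the partition is invariant to the input ordering of regions.
#'
#' @param corr a `correlation_matrix`.
#' @param linkage linkage method for [stats::hclust()]: `"average"`
#'   (default), `"complete"`, `"ward.D2"`, or `"single"`.
#' @param k integer number of clusters; overrides `h` if given.
#' @param h height threshold; default `0.7 * max(merge height)`.
#' @return An object of class `cluster_partition`: list with `cluster`
#'   (named integer vector, region -> cluster id), `tree` (the hclust
#'   object), `cut` (description of the criterion used), `linkage`.
#' @export
cluster_regions <- function(corr, linkage = c("average", "complete", "ward.D2",
                                              "single"),
                            k = NULL, h = NULL) {
  stopifnot(inherits(corr, "correlation_matrix"))
  linkage <- match.arg(linkage)
  d <- stats::as.dist(1 - corr$r)
  tree <- stats::hclust(d, method = linkage)
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 1L || k > length(corr$regions))
      stop("k must be between 1 and the number of regions")
    cl <- stats::cutree(tree, k = k)
    cut <- sprintf("k=%d", k)
  } else {
    if (is.null(h)) h <- 0.7 * max(tree$height)
    cl <- stats::cutree(tree, h = h)
    cut <- sprintf("h=%.6g", h)
  }
  names(cl) <- corr$regions
  cl <- .canonical_clusters(cl)
  structure(list(cluster = cl, tree = tree, cut = cut, linkage = linkage),
            class = "cluster_partition")
}

# renumber cluster ids 1..K by order of each cluster's smallest member name
.canonical_clusters <- function(cl) {
  first <- tapply(names(cl), cl, function(nm) sort(nm)[1L])
  new_id <- stats::setNames(seq_along(first), names(first)[order(first)])
  out <- new_id[as.character(cl)]
  names(out) <- names(cl)
  storage.mode(out) <- "integer"
  out[order(names(out))][names(cl)]   # preserve original region order
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("cluster_partition: %d regions in %d cluster(s) (%s linkage, cut %s)\n",
              length(x$cluster), length(unique(x$cluster)), x$linkage, x$cut))
  invisible(x)
}

#' Within- vs between-cluster correlation block test
#'
#' For a pair of clusters, collects the within-cluster correlation
#' coefficients (each unordered region pair once, both clusters pooled,
#' diagonal excluded) and the between-cluster coefficients, and compares the
#' two sets with a Welch two-sample t test (two-sided). A positive t with
#' small p says the blocks are coherent modules: tight within, weak or
#' negative between.
#'
#' @param corr a `correlation_matrix`.
#' @param partition a `cluster_partition` on the same regions.
#' @param pair length-2 vector of cluster ids to compare.
#' @return List with `t`, `df`, `p`, `n_within`, `n_between`,
#'   `mean_within`, `mean_between`, `pair`.
#' @export
cluster_block_test <- function(corr, partition, pair) {
  stopifnot(inherits(corr, "correlation_matrix"),
            inherits(partition, "cluster_partition"))
  cl <- partition$cluster[corr$regions]
  if (anyNA(cl)) stop("partition does not cover all regions")
  pair <- as.integer(pair)
  ia <- which(cl == pair[1L]); ib <- which(cl == pair[2L])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("both clusters need >= 2 regions for a within-block correlation")
  r <- corr$r
  within <- c(r[ia, ia][upper.tri(r[ia, ia])],
              r[ib, ib][upper.tri(r[ib, ib])])
  between <- as.vector(r[ia, ib])
  tt <- stats::t.test(within, between)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       n_within = length(within), n_between = length(between),
       mean_within = mean(within), mean_between = mean(between),
       pair = pair)
}

#' Dorsoventral depth profile of clusters
#'
#' For each cluster, the mean and standard deviation of its member voxels'
#' normalized position along the dorsoventral axis (0 = dorsal surface,
#' 1 = ventral), plus a voxel map carrying the cluster id — the rendering
#' that shows dorsal vs ventral module territories.
#'
#' @param partition a `cluster_partition` whose region names are label ids.
#' @param vol a [label_volume()] containing those labels.
#' @param path optional NIfTI output path for the cluster-id map.
#' @return List with `profile` (data frame: cluster, mean_depth, sd_depth,
#'   n_voxels) and `map` (3-D integer array of cluster ids).
#' @export
cluster_depth_profile <- function(partition, vol, path = NULL) {
  stopifnot(inherits(partition, "cluster_partition"),
            inherits(vol, "label_volume"))
  labs <- as.integer(names(partition$cluster))
  present <- names(region_voxel_counts(vol))
  missing <- setdiff(labs, as.integer(present))
  if (length(missing))
    stop("region(s) absent from volume: ", paste(missing, collapse = ", "))
  dims <- dim(vol$grid)
  ax <- vol$dv_axis
  idx <- slice.index(vol$grid, ax)
  depth <- (idx - 0.5) / dims[ax]
  if (!vol$dv_increasing_ventral) depth <- 1 - depth
  lut <- integer(max(labs) + 1L)
  lut[labs + 1L] <- partition$cluster
  map <- array(0L, dims)
  nz <- vol$grid != 0L & vol$grid <= max(labs)
  map[nz] <- lut[vol$grid[nz] + 1L]
  ids <- sort(unique(partition$cluster))
  prof <- data.frame(cluster = ids, mean_depth = NA_real_,
                     sd_depth = NA_real_, n_voxels = NA_integer_)
  for (i in seq_along(ids)) {
    sel <- map == ids[i]
    n <- sum(sel)
    if (n == 0L) stop("cluster ", ids[i], " has zero voxels in the volume")
    prof$mean_depth[i] <- mean(depth[sel])
    prof$sd_depth[i] <- stats::sd(depth[sel])
    prof$n_voxels[i] <- n
  }
  if (!is.null(path)) write_voxel_map(map, vol, path)
  list(profile = prof, map = map)
}

#' Write a correlation matrix / partition to TSV
#' @param corr a `correlation_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(corr, path) {
  df <- data.frame(region = corr$regions, corr$r, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_correlation_matrix
#' @param partition a `cluster_partition`.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(region = names(partition$cluster),
                   cluster = unname(partition$cluster))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
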