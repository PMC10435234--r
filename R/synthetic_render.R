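# deterministic near-uniform K-point lattice on the unit sphere
# (golden-angle spiral); the base landmark configuration for phantom regions
.sphere_lattice <- function(K) {
  i <- seq_len(K) - 0.5
  phi <- acos(1 - 2 * i / K)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta),
        y = sin(phi) * sin(theta),
        z = cos(phi))
}

# voxel count of the ellipsoid with semi-axes `ax` centred at `cen` within
# the grid; used by the binary search that hits a target voxel count
.ellipsoid_mask <- function(grid_shape, cen, ax) {
  lo <- pmax(1L, floor(cen - ax)); hi <- pmin(grid_shape, ceiling(cen + ax))
  xs <- lo[1L]:hi[1L]; ys <- lo[2L]:hi[2L]; zs <- lo[3L]:hi[3L]
  d1 <- ((xs - cen[1L]) / ax[1L])^2
  d2 <- ((ys - cen[2L]) / ax[2L])^2
  d3 <- ((zs - cen[3L]) / ax[3L])^2
  m <- outer(outer(d1, d2, `+`), d3, `+`) <= 1
  list(lo = lo, hi = hi, mask = m)
}

#' Render individual label volumes from target volume fractions
#'
#' Draws each region as an ellipsoid on a 3-D grid, with voxel counts tuned
#' by binary search to the individual's target fraction of the total brain
#' voxel budget. The layout is module-aware and guaranteed overlap-free:
#' the dorsoventral extent is divided into one slab per module (dorsal
#' module at low dorsoventral index, ventral at high), each slab is
#' partitioned into per-region boxes, and every ellipsoid is inscribed
#' strictly inside its own box. Box centres are jittered by up to one voxel
#' per axis (seeded) so phantoms differ between individuals.
#'
#' @param fractions individuals x regions matrix of target volume fractions
#'   (rows sum to 1), or a single named row.
#' @param assignment named region -> module vector ordering the slabs
#'   (module names sorted; first = most dorsal).
#' @param grid_shape integer length-3 grid dimensions (default 64^3).
#' @param brain_fill fraction of the grid occupied by the whole brain
#'   (default 0.15).
#' @param voxel_size voxel edge lengths, micrometres.
#' @param dv_axis dorsoventral grid axis (default 3).
#' @param seed integer seed for the centre jitter.
#' @return Named list of [label_volume()]s, one per row of `fractions`;
#'   region labels are 1..p in column order, recorded in the attribute
#'   `region_labels`.
#' @export
render_cohort_label_volumes <- function(fractions, assignment,
                                        grid_shape = c(64L, 64L, 64L),
                                        brain_fill = 0.15,
                                        voxel_size = c(2, 2, 2),
                                        dv_axis = 3L, seed = 1L) {
  if (is.null(dim(fractions))) fractions <- matrix(fractions, nrow = 1L,
                                                   dimnames = list("S1", names(fractions)))
  regions <- colnames(fractions)
  if (!setequal(regions, names(assignment)))
    stop("fraction columns do not match assignment regions")
  grid_shape <- as.integer(grid_shape)
  mods <- sort(unique(as.character(assignment)))
  other <- setdiff(1:3, dv_axis)
  # slab extent per module along the dorsoventral axis
  n_mod <- length(mods)
  dv_len <- grid_shape[dv_axis]
  slab_breaks <- round(seq(0, dv_len, length.out = n_mod + 1L))
  V_brain <- brain_fill * prod(grid_shape)
  # per-region boxes within each slab: near-square grid over the other axes
  boxes <- list()
  for (mi in seq_along(mods)) {
    rs <- regions[as.character(assignment[regions]) == mods[mi]]
    nr <- ceiling(sqrt(length(rs)))
    nc <- ceiling(length(rs) / nr)
    b1 <- round(seq(0, grid_shape[other[1L]], length.out = nr + 1L))
    b2 <- round(seq(0, grid_shape[other[2L]], length.out = nc + 1L))
    for (k in seq_along(rs)) {
      i <- (k - 1L) %% nr + 1L; j <- (k - 1L) %/% nr + 1L
      lo <- hi <- integer(3L)
      lo[dv_axis] <- slab_breaks[mi] + 1L; hi[dv_axis] <- slab_breaks[mi + 1L]
      lo[other[1L]] <- b1[i] + 1L; hi[other[1L]] <- b1[i + 1L]
      lo[other[2L]] <- b2[j] + 1L; hi[other[2L]] <- b2[j + 1L]
      boxes[[rs[k]]] <- list(lo = lo, hi = hi)
    }
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- vector("list", nrow(fractions))
  names(out) <- rownames(fractions)
  for (ind in seq_len(nrow(fractions))) {
    g <- array(0L, grid_shape)
    for (ri in seq_along(regions)) {
      reg <- regions[ri]
      bx <- boxes[[reg]]
      half <- (bx$hi - bx$lo + 1) / 2
      cen <- (bx$lo + bx$hi) / 2 + sample(-1:1, 3L, replace = TRUE)
      ax_max <- pmax(half - 1.5, 0.8)
      target <- fractions[ind, reg] * V_brain
      # ellipsoid at full box size must be able to reach the target
      full <- .ellipsoid_mask(grid_shape, cen, ax_max)
      if (sum(full$mask) < target)
        stop("layout overflow: region ", reg, " needs ", round(target),
             " voxels but its box holds only ", sum(full$mask),
             "; reduce brain_fill or enlarge the grid")
      lo_s <- 0; hi_s <- 1
      for (iter in 1:40) {
        s <- (lo_s + hi_s) / 2
        cnt <- sum(.ellipsoid_mask(grid_shape, cen, pmax(s * ax_max, 0.6))$mask)
        if (cnt < target) lo_s <- s else hi_s <- s
      }
      em <- .ellipsoid_mask(grid_shape, cen, pmax(hi_s * ax_max, 0.6))
      sub <- g[em$lo[1L]:em$hi[1L], em$lo[2L]:em$hi[2L], em$lo[3L]:em$hi[3L]]
      if (any(sub[em$mask] != 0L))
        stop("internal error: region ", reg, " overlaps an earlier region")
      sub[em$mask] <- ri
      g[em$lo[1L]:em$hi[1L], em$lo[2L]:em$hi[2L], em$lo[3L]:em$hi[3L]] <- sub
    }
    out[[ind]] <- label_volume(g, voxel_size = voxel_size, dv_axis = dv_axis)
  }
  attr(out, "region_labels") <- stats::setNames(seq_along(regions), regions)
  out
}

#' Simulate a landmark cohort coupled to volumes and module scores
#'
#' Each region's base configuration is a deterministic sphere lattice; the
#' configuration of individual i is
#' `base * volume_i^(1/3) * coord_scale + m_i * deform_scale * D_r + noise`,
#' where `m_i` is the individual's latent score for the region's module and
#' `D_r` a fixed unit-norm deformation field per region — so shape covaries
#' within modules exactly as volume does, and centroid size is strictly
#' proportional to the cube root of volume when `noise_sd = 0` and
#' `deform_scale = 0`.
#'
#' @param volumes result of [simulate_volume_table()] (uses `$raw`,
#'   `$module_scores`, `$truth`, and the table's metadata).
#' @param n_landmarks landmarks per region (default 20).
#' @param deform_scale magnitude (micrometres) of the module deformation
#'   (default 10).
#' @param noise_sd isotropic landmark noise, micrometres (default 1).
#' @param coord_scale scale from cube-root volume to micrometres
#'   (default 100).
#' @param deform_fields optional named list of K x 3 unit-norm deformation
#'   fields per region; generated (seeded) when `NULL`.
#' @param seed integer seed.
#' @return A `landmark_table` covering all regions and specimens (roles all
#'   `fixed`), with the deformation fields in attribute `deform_fields`.
#' @export
simulate_landmark_cohort <- function(volumes, n_landmarks = 20L,
                                     deform_scale = 10, noise_sd = 1,
                                     coord_scale = 100,
                                     deform_fields = NULL, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  raw <- volumes$raw
  scores <- volumes$module_scores
  truth <- volumes$truth
  regions <- colnames(raw)
  specs <- rownames(raw)
  pop <- volumes$table$population
  K <- as.integer(n_landmarks)
  base <- .sphere_lattice(K)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(deform_fields)) {
    deform_fields <- lapply(regions, function(r) {
      D <- matrix(stats::rnorm(K * 3L), K, 3L)
      D / sqrt(sum(D^2))
    })
    names(deform_fields) <- regions
  }
  n <- length(specs)
  rows <- vector("list", length(regions))
  for (ri in seq_along(regions)) {
    reg <- regions[ri]
    m <- scores[, as.character(truth[reg])]
    D <- deform_fields[[reg]]
    coords <- matrix(NA_real_, n * K, 3L)
    for (i in seq_len(n)) {
      cfg <- base * raw[i, reg]^(1 / 3) * coord_scale +
        m[i] * deform_scale * D
      if (noise_sd > 0)
        cfg <- cfg + matrix(stats::rnorm(K * 3L, sd = noise_sd), K, 3L)
      coords[(i - 1L) * K + seq_len(K), ] <- cfg
    }
    rows[[ri]] <- data.frame(
      specimen_id = rep(specs, each = K),
      population = rep(pop, each = K),
      region = reg,
      landmark_id = rep(seq_len(K), n),
      role = "fixed",
      x = coords[, 1L], y = coords[, 2L], z = coords[, 3L])
  }
  out <- landmark_table(do.call(rbind, rows))
  attr(out, "deform_fields") <- deform_fields
  out
}

#' Perturb a segmentation for concordance testing
#'
#' Emulates registration/segmentation error: every region is translated by
#' a random integer offset of magnitude at most `shift_voxels` per axis,
#' then a fraction `flip_rate` of boundary voxels (voxels with a differently
#' labelled nonzero 6-neighbour) is reassigned to the modal differing
#' neighbour label. The label set is preserved.
#'
#' @param vol a [label_volume()].
#' @param shift_voxels maximum per-axis translation (default 1).
#' @param flip_rate fraction of boundary voxels to flip, in \[0, 1\].
#' @param seed integer seed.
#' @return A perturbed [label_volume()].
#' @export
perturb_segmentation <- function(vol, shift_voxels = 1L, flip_rate = 0,
                                 seed = 1L) {
  stopifnot(inherits(vol, "label_volume"))
  if (flip_rate < 0 || flip_rate > 1) stop("flip_rate must be in [0, 1]")
  shift_voxels <- as.integer(shift_voxels)
  g <- vol$grid
  labs <- as.integer(names(region_voxel_counts(vol)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  dims <- dim(g)
  if (shift_voxels > 0L) {
    out <- array(0L, dims)
    for (lab in labs) {
      off <- sample(seq(-shift_voxels, shift_voxels), 3L, replace = TRUE)
      idx <- which(g == lab, arr.ind = TRUE)
      idx <- sweep(idx, 2L, off, `+`)
      keep <- idx[, 1L] >= 1L & idx[, 1L] <= dims[1L] &
              idx[, 2L] >= 1L & idx[, 2L] <= dims[2L] &
              idx[, 3L] >= 1L & idx[, 3L] <= dims[3L]
      out[idx[keep, , drop = FALSE]] <- lab
    }
    g <- out
  }
  if (flip_rate > 0) {
    # boundary voxels: nonzero with a differing nonzero 6-neighbour
    nb_off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    nz <- which(g != 0L, arr.ind = TRUE)
    nb_lab <- matrix(0L, nrow(nz), 6L)
    for (k in 1:6) {
      nb <- sweep(nz, 2L, nb_off[k, ], `+`)
      ok <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
            nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
            nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
      v <- integer(nrow(nz)); v[ok] <- g[nb[ok, , drop = FALSE]]
      nb_lab[, k] <- v
    }
    own <- g[nz]
    has_diff <- rowSums(nb_lab != 0L & nb_lab != own) > 0L
    bidx <- which(has_diff)
    n_flip <- floor(flip_rate * length(bidx))
    if (n_flip > 0L) {
      flip <- sample(bidx, n_flip)
      new_lab <- vapply(flip, function(i) {
        cand <- nb_lab[i, ]
        cand <- cand[cand != 0L & cand != own[i]]
        as.integer(names(which.max(table(cand))))
      }, integer(1))
      # preserve the label set: never flip away a region's last voxels
      cnt <- table(factor(own, levels = labs))
      loss <- table(factor(own[flip], levels = labs))
      risky <- labs[as.integer(cnt) - as.integer(loss) < 1L]
      ok <- !(own[flip] %in% risky)
      g[nz[flip[ok], , drop = FALSE]] <- new_lab[ok]
    }
  }
  label_volume(g, voxel_size = vol$voxel_size, dv_axis = vol$dv_axis,
               dv_increasing_ventral = vol$dv_increasing_ventral)
}
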