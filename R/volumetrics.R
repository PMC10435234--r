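#' Region voxel counts
#'
#' Counts voxels per nonzero label. The brain is defined as the union of all
#' nonzero labels at the analyzed ontology level, so the counts sum to the
#' total brain voxel count.
#'
#' @param vol a [label_volume()].
#' @return Named integer vector of voxel counts (names = label ids).
#' @export
region_voxel_counts <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  g <- as.vector(vol$grid)
  nz <- g[g != 0L]
  if (!length(nz)) stop("empty brain: no nonzero voxels")
  tab <- tabulate(nz)
  labs <- which(tab > 0L)
  stats::setNames(tab[labs], labs)
}

#' Relative region volumes (percent of total brain)
#'
#' Each region's voxel count divided by the total nonzero voxel count —
#' "pixels of brain region / total pixels in brain" expressed as a fraction.
#'
#' @param counts named numeric vector of voxel counts.
#' @return Named numeric vector of fractions summing to 1.
#' @export
relative_volumes <- function(counts) {
  if (!length(counts)) stop("empty counts")
  total <- sum(counts)
  if (total <= 0) stop("total voxel count is zero")
  counts / total
}

#' Assemble a volume table from label volumes
#'
#' @param vols named list of [label_volume()] (names = specimen ids).
#' @param population character vector of population labels per specimen.
#' @param onto optional `region_ontology` for aggregation.
#' @param level ontology level at which to measure.
#' @return A `volume_table`: list with `fractions` (specimens x regions
#'   matrix), `specimen_id`, `population`, `level`.
#' @export
volume_table_from_volumes <- function(vols, population,
                                      onto = NULL, level = "fine") {
  stopifnot(length(vols) == length(population))
  if (!is.null(onto) && level != "fine")
    vols <- lapply(vols, aggregate_labels, onto = onto, level = level)
  counts <- lapply(vols, region_voxel_counts)
  regions <- sort(unique(as.integer(unlist(lapply(counts, names)))))
  mat <- matrix(0, length(vols), length(regions),
                dimnames = list(names(vols), regions))
  for (i in seq_along(counts)) {
    fr <- relative_volumes(counts[[i]])
    mat[i, names(fr)] <- fr
  }
  volume_table(mat, specimen_id = names(vols), population = population,
               level = level)
}

#' Construct a volume table
#'
#' @param fractions specimens x regions numeric matrix of relative volumes.
#' @param specimen_id character vector (defaults to rownames).
#' @param population character vector of population labels.
#' @param level ontology level the columns live at.
#' @param check if `TRUE`, require rows to sum to 1 within 1e-9.
#' @return A `volume_table` object.
#' @export
volume_table <- function(fractions, specimen_id = rownames(fractions),
                         population, level = "fine", check = TRUE) {
  fractions <- as.matrix(fractions)
  if (is.null(specimen_id)) specimen_id <- paste0("S", seq_len(nrow(fractions)))
  if (any(fractions < 0)) stop("negative volume fractions")
  if (check && any(abs(rowSums(fractions) - 1) > 1e-9))
    stop("volume fractions must sum to 1 per individual (within 1e-9)")
  rownames(fractions) <- specimen_id
  structure(list(fractions = fractions,
                 specimen_id = as.character(specimen_id),
                 population = as.character(population),
                 level = level),
            class = "volume_table")
}

#' @export
print.volume_table <- function(x, ...) {
  cat(sprintf("volume_table: %d specimens x %d regions (level: %s)\n",
              nrow(x$fractions), ncol(x$fractions), x$level))
  cat("populations:", paste(sprintf("%s (%d)", names(table(x$population)),
                                    table(x$population)), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read volume tables as TSV
#' @param vt a `volume_table`.
#' @param path file path.
#' @return `path` (write) or a `volume_table` (read).
#' @export
write_volume_table <- function(vt, path) {
  df <- data.frame(specimen_id = vt$specimen_id, population = vt$population,
                   vt$fractions, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_volume_table
#' @param level ontology level recorded in the returned object.
#' @export
read_volume_table <- function(path, level = "fine") {
  df <- utils::read.delim(path, check.names = FALSE)
  mat <- as.matrix(df[, -(1:2), drop = FALSE])
  volume_table(mat, specimen_id = df$specimen_id,
               population = df$population, level = level)
}

#' Holm-Sidak step-down adjustment
#'
#' Orders the m raw p values ascending and sets
#' `adj_i = 1 - (1 - p_(i))^(m - i + 1)`, then enforces monotonicity by a
#' running maximum and caps at 1. The adjusted values are returned in the
#' original order.
#'
#' @param p numeric vector of raw p values.
#' @return Adjusted p values, same order as input.
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Compare region volumes across groups
#'
#' Per region: with two groups a two-sample t test; with more, a one-way
#' fixed-effects ANOVA (F = MS_between / MS_within). Requested pairwise
#' contrasts are computed as t statistics on the pooled within-group mean
#' square (the classical post-ANOVA procedure; a Welch variant is available)
#' and corrected by the Holm-Sidak step-down across the contrasts of each
#' region.
#'
#' @param vt a `volume_table`.
#' @param grouping factor/character of group membership per specimen
#'   (default: the table's `population`).
#' @param contrasts list of length-2 character vectors naming group pairs;
#'   `NULL` = all pairs.
#' @param welch if `TRUE`, pairwise contrasts use Welch t (unpooled).
#' @return A data frame with one row per region: `region`, `statistic_type`,
#'   `statistic`, `df1`, `df2`, `p`, group means, and one pair of columns
#'   (`t_<A>_vs_<B>`, `p_raw_...`, `p_adj_...`) per contrast.
#' @export
compare_groups <- function(vt, grouping = NULL, contrasts = NULL,
                           welch = FALSE) {
  stopifnot(inherits(vt, "volume_table"))
  g <- factor(if (is.null(grouping)) vt$population else grouping)
  if (nlevels(g) < 2L) stop("need at least two groups")
  ns <- table(g)
  if (any(ns < 2L)) stop("each group needs at least two individuals")
  lev <- levels(g)
  if (is.null(contrasts))
    contrasts <- utils::combn(lev, 2L, simplify = FALSE)
  rows <- vector("list", ncol(vt$fractions))
  for (j in seq_len(ncol(vt$fractions))) {
    y <- vt$fractions[, j]
    means <- tapply(y, g, mean)
    vars <- tapply(y, g, stats::var)
    if (all(vars == 0)) stop("zero within-group variance in all groups for region ",
                             colnames(vt$fractions)[j])
    N <- length(y); k <- nlevels(g)
    if (k == 2L) {
      tt <- stats::t.test(y[g == lev[1]], y[g == lev[2]], var.equal = !welch)
      stat <- unname(tt$statistic); df1 <- 1; df2 <- unname(tt$parameter)
      p <- tt$p.value; type <- "t"
      msw <- sum((ns - 1) * vars) / (N - k)
      dfw <- N - k
    } else {
      fit <- stats::aov(y ~ g)
      an <- summary(fit)[[1L]]
      stat <- an[1L, "F value"]; df1 <- an[1L, "Df"]; df2 <- an[2L, "Df"]
      p <- an[1L, "Pr(>F)"]; type <- "F"
      msw <- an[2L, "Mean Sq"]
      dfw <- df2
    }
    crow <- list()
    praw <- numeric(length(contrasts))
    tvals <- numeric(length(contrasts))
    for (ci in seq_along(contrasts)) {
      pr <- contrasts[[ci]]
      if (!all(pr %in% lev)) stop("contrast names unknown group: ",
                                  paste(pr, collapse = " vs "))
      if (welch) {
        se <- sqrt(vars[pr[1]] / ns[pr[1]] + vars[pr[2]] / ns[pr[2]])
        dfc <- se^4 / ((vars[pr[1]] / ns[pr[1]])^2 / (ns[pr[1]] - 1) +
                       (vars[pr[2]] / ns[pr[2]])^2 / (ns[pr[2]] - 1))
      } else {
        se <- sqrt(msw * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
        dfc <- dfw
      }
      tvals[ci] <- (means[pr[1]] - means[pr[2]]) / se
      praw[ci] <- 2 * stats::pt(-abs(tvals[ci]), dfc)
    }
    padj <- holm_sidak(praw)
    for (ci in seq_along(contrasts)) {
      nm <- paste(contrasts[[ci]], collapse = "_vs_")
      crow[[paste0("t_", nm)]] <- unname(tvals[ci])
      crow[[paste0("p_raw_", nm)]] <- unname(praw[ci])
      crow[[paste0("p_adj_", nm)]] <- unname(padj[ci])
    }
    rows[[j]] <- c(list(region = colnames(vt$fractions)[j],
                        statistic_type = type, statistic = unname(stat),
                        df1 = df1, df2 = df2, p = p),
                   stats::setNames(as.list(unname(means)),
                                   paste0("mean_", lev)),
                   crow)
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}

#' One-way ANOVA on a wide table of normalized volumes
#'
#' Convenience for re-analyzing published per-figure source-data tables: a
#' CSV whose columns are groups (e.g. surface, Pachon, Molino) and whose
#' cells are normalized region volumes for individual specimens; columns may
#' have unequal lengths (blank cells allowed). Returns the one-way
#' fixed-effects F, degrees of freedom and p value.
#'
#' @param x path to such a CSV, or a data frame of group columns.
#' @param groups optional subset of column names to analyze.
#' @return List with `F`, `df1`, `df2`, `p`, `n` (per group).
#' @export
wildtype_volume_anova <- function(x, groups = NULL) {
  df <- if (is.character(x)) utils::read.csv(x, check.names = FALSE) else x
  if (!is.null(groups)) df <- df[, groups, drop = FALSE]
  vals <- lapply(df, function(col) col[is.finite(col)])
  vals <- vals[vapply(vals, length, 1L) > 0L]
  if (length(vals) < 2L) stop("need at least two group columns")
  y <- unlist(vals, use.names = FALSE)
  g <- factor(rep(names(vals), vapply(vals, length, 1L)))
  an <- summary(stats::aov(y ~ g))[[1L]]
  list(F = an[1L, "F value"], df1 = an[1L, "Df"], df2 = an[2L, "Df"],
       p = an[1L, "Pr(>F)"], n = vapply(vals, length, 1L))
}

#' Population difference map
#'
#' Paints each region's voxels with the difference in mean relative volume
#' between two populations (`mean_B - mean_A`); background stays 0. This is
#' the voxelwise "colorimetric" rendering of volumetric change.
#'
#' @param meansA,meansB named numeric vectors of mean fractions per label.
#' @param vol a [label_volume()] whose labels are all covered by both vectors.
#' @param path optional NIfTI output path.
#' @return 3-D numeric array of signed differences (invisibly written to
#'   `path` if given).
#' @export
population_difference_map <- function(meansA, meansB, vol, path = NULL) {
  stopifnot(inherits(vol, "label_volume"))
  labs <- names(region_voxel_counts(vol))
  missing <- setdiff(labs, intersect(names(meansA), names(meansB)))
  if (length(missing))
    stop("label(s) without mean in both tables: ", paste(missing, collapse = ", "))
  lut <- numeric(max(as.integer(labs)) + 1L)
  lut[as.integer(labs) + 1L] <- meansB[labs] - meansA[labs]
  out <- array(0, dim(vol$grid))
  nz <- vol$grid != 0L
  out[nz] <- lut[vol$grid[nz] + 1L]
  if (!is.null(path)) write_voxel_map(out, vol, path)
  out
}

#' Voxelwise Pearson correlation of two volumes
#'
#' Both volumes are vectorized in identical voxel order within the mask and
#' their Pearson correlation returned — the QC statistic used to compare
#' registered image stacks and segmentations.
#'
#' @param volA,volB 3-D arrays or [label_volume()]s on the same grid.
#' @param mask optional logical array; default all voxels.
#' @return Pearson correlation coefficient.
#' @export
voxelwise_correlation <- function(volA, volB, mask = NULL) {
  a <- if (inherits(volA, "label_volume")) volA$grid else volA
  b <- if (inherits(volB, "label_volume")) volB$grid else volB
  if (!identical(dim(a), dim(b))) stop("grid shapes differ")
  if (is.null(mask)) mask <- array(TRUE, dim(a))
  if (!any(mask)) stop("empty mask")
  x <- as.numeric(a[mask]); y <- as.numeric(b[mask])
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input within mask: correlation undefined")
  stats::cor(x, y)
}

#' Segmentation concordance by per-region mask correlation
#'
#' For each requested region, the Pearson correlation of the two binary
#' indicator vectors (automated vs manual segmentation) over the brain mask
#' (union of nonzero voxels of both volumes). A Dice coefficient is reported
#' alongside as a secondary overlap measure.
#'
#' @param auto,manual [label_volume()]s on the same grid.
#' @param regions integer label ids to evaluate (default: labels present in
#'   both volumes).
#' @return List with `per_region` (data frame: region, r, dice, n_auto,
#'   n_manual) and `summary` (mean and min r over evaluable regions).
#' @export
segmentation_concordance <- function(auto, manual, regions = NULL) {
  stopifnot(inherits(auto, "label_volume"), inherits(manual, "label_volume"))
  if (!identical(dim(auto$grid), dim(manual$grid))) stop("grid shapes differ")
  if (is.null(regions))
    regions <- intersect(names(region_voxel_counts(auto)),
                         names(region_voxel_counts(manual)))
  regions <- as.integer(regions)
  mask <- auto$grid != 0L | manual$grid != 0L
  a <- auto$grid[mask]; m <- manual$grid[mask]
  res <- data.frame(region = regions, r = NA_real_, dice = NA_real_,
                    n_auto = NA_integer_, n_manual = NA_integer_)
  for (i in seq_along(regions)) {
    ia <- a == regions[i]; im <- m == regions[i]
    res$n_auto[i] <- sum(ia); res$n_manual[i] <- sum(im)
    if (!any(ia) || !any(im)) {
      warning("region ", regions[i], " empty in one volume; excluded from summary")
      next
    }
    if (all(ia) || all(im)) {
      warning("region ", regions[i], " fills the mask; correlation undefined")
      next
    }
    res$r[i] <- stats::cor(as.numeric(ia), as.numeric(im))
    res$dice[i] <- 2 * sum(ia & im) / (sum(ia) + sum(im))
  }
  ok <- is.finite(res$r)
  list(per_region = res,
       summary = c(mean_r = mean(res$r[ok]), min_r = min(res$r[ok])))
}
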