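#' Genetic model for a two-population cross
#'
#' Quantitative-genetic model for the synthetic cohort: each individual
#' carries a genotype score `g` in \[0, 1\] (0 = pure population 1, 1 = pure
#' population 2), and each region responds with an additive effect `delta`
#' on log volume, modulated by a per-region dominance parameter `h` in
#' \[0, 1\] (`h = 0.5` is pure additivity, `h > 0.5` population-2 dominant,
#' `h < 0.5` population-1 dominant). F2 genotype scores segregate as the
#' mean of `n_loci` independent biallelic loci.
#'
#' @param n_loci number of loci L (>= 1; default 8).
#' @param delta named numeric vector of per-region additive effects on log
#'   volume (sign encodes the dorsal-contraction / ventral-expansion
#'   tradeoff).
#' @param h per-region dominance in \[0, 1\]; scalar recycled.
#' @return An object of class `genetic_model`.
#' @export
genetic_model <- function(n_loci = 8L, delta, h = 0.5) {
  n_loci <- as.integer(n_loci)
  if (n_loci < 1L) stop("n_loci must be >= 1")
  if (is.null(names(delta))) stop("delta must be named by region")
  h <- rep_len(h, length(delta))
  if (any(h < 0 | h > 1)) stop("dominance h must be in [0, 1]")
  names(h) <- names(delta)
  structure(list(n_loci = n_loci, delta = delta, h = h),
            class = "genetic_model")
}

#' Dominance-adjusted genotype value
#'
#' Piecewise map from genotype score `g` and dominance `h` to the phenotypic
#' genotype value `a` in \[0, 1\]: for `h >= 0.5` (population-2 allele
#' dominant) `a = min(1, 2 h g)`; for `h < 0.5` the mirror-image rule
#' `a = 1 - min(1, 2 (1 - h) (1 - g))`. Both branches reduce to `a = g` at
#' `h = 0.5` (pure additivity) and saturate at the dominant parent's value.
#'
#' @param g genotype score(s) in \[0, 1\].
#' @param h dominance in \[0, 1\].
#' @return Genotype value(s) in \[0, 1\].
#' @export
dominance_value <- function(g, h) {
  n <- max(length(g), length(h))
  g <- rep_len(g, n); h <- rep_len(h, n)
  hi <- h >= 0.5
  out <- numeric(n)
  out[hi] <- pmin(1, 2 * h[hi] * g[hi])
  out[!hi] <- 1 - pmin(1, 2 * (1 - h[!hi]) * (1 - g[!hi]))
  out
}

#' Module specification for volume covariance
#'
#' Assigns regions to modules (e.g. dorsal vs ventral) and specifies the
#' within- and between-module correlations of the log-volume noise. The
#' implied correlation matrix is checked for positive semi-definiteness at
#' construction and, if requested, repaired by clipping eigenvalues at 1e-8
#' and renormalizing the diagonal.
#'
#' @param assignment named vector mapping region -> module id.
#' @param rho_within within-module correlation in (-1, 1); default 0.6.
#' @param rho_between between-module correlation in (-1, 1); default -0.4.
#' @param repair if `TRUE` (default) repair a non-PSD matrix by eigenvalue
#'   clipping; if `FALSE`, error instead.
#' @return An object of class `module_spec` with the (possibly repaired)
#'   correlation matrix in `$R` and a `repaired` flag.
#' @export
module_spec <- function(assignment, rho_within = 0.6, rho_between = -0.4,
                        repair = TRUE) {
  if (is.null(names(assignment))) stop("assignment must be named by region")
  if (abs(rho_within) >= 1 || abs(rho_between) >= 1)
    stop("correlations must be in (-1, 1)")
  mods <- as.character(assignment)
  p <- length(mods)
  same <- outer(mods, mods, `==`)
  R <- ifelse(same, rho_within, rho_between)
  diag(R) <- 1
  dimnames(R) <- list(names(assignment), names(assignment))
  ev <- eigen(R, symmetric = TRUE)
  repaired <- FALSE
  if (min(ev$values) < -1e-10) {
    if (!repair) stop("module correlation matrix is not positive semi-definite")
    vals <- pmax(ev$values, 1e-8)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    s <- sqrt(diag(R))
    R <- R / outer(s, s)
    dimnames(R) <- list(names(assignment), names(assignment))
    repaired <- TRUE
  }
  structure(list(assignment = assignment, rho_within = rho_within,
                 rho_between = rho_between, R = R, repaired = repaired),
            class = "module_spec")
}

#' Simulate genotype scores for a four-population design
#'
#' Parental populations are fixed (`P1`: g = 0, `P2`: g = 1), F1 hybrids
#' are exactly intermediate (g = 0.5), and F2 individuals segregate: g is
#' the mean over L loci of dosage/2 with dosage ~ Binomial(2, 1/2)
#' independently per locus, so Var(g) = 1 / (8 L).
#'
#' @param n_per_pop named integer vector, e.g. `c(P1 = 10, P2 = 10, F2 = 37)`;
#'   names from `P1`, `P2`, `F1`, `F2`.
#' @param model a [genetic_model()].
#' @param seed integer seed.
#' @return Data frame with `specimen_id`, `population`, `g`.
#' @export
simulate_genotypes <- function(n_per_pop, model, seed = 1L) {
  stopifnot(inherits(model, "genetic_model"))
  bad <- setdiff(names(n_per_pop), c("P1", "P2", "F1", "F2"))
  if (length(bad)) stop("unknown population(s): ", paste(bad, collapse = ", "))
  if (any(n_per_pop < 1L)) stop("need n >= 1 per requested population")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- list()
  for (pop in names(n_per_pop)) {
    n <- n_per_pop[[pop]]
    g <- switch(pop,
                P1 = rep(0, n),
                P2 = rep(1, n),
                F1 = rep(0.5, n),
                F2 = rowMeans(matrix(
                  stats::rbinom(n * model$n_loci, 2L, 0.5) / 2,
                  nrow = n)))
    out[[pop]] <- data.frame(
      specimen_id = sprintf("%s_%03d", pop, seq_len(n)),
      population = pop, g = g)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Simulate region volumes with module-structured covariance
#'
#' Log raw volume of region r in individual i is
#' `mu_r + delta_r * a(g_i, h_r) + eps_{i,r}`, with `a` the
#' dominance-adjusted genotype value ([dominance_value()]) and the noise
#' rows drawn from a multivariate normal whose correlation comes from the
#' module specification, scaled by `sigma`. Volumes are log-normal (volumes
#' are positive and developmental effects act multiplicatively). Normalized
#' volumes are raw volumes divided by the individual's total, i.e. closed
#' compositions summing to 1; both raw and normalized are returned so the
#' closure-induced negative correlation can be quantified.
#'
#' @param genotypes data frame from [simulate_genotypes()].
#' @param spec a [module_spec()].
#' @param model a [genetic_model()] whose `delta` names match the spec's
#'   regions.
#' @param sigma noise scale on log volumes (> 0; default 0.15).
#' @param mu named baseline log volumes; default equal across regions.
#' @param seed integer seed.
#' @return List: `raw` (individuals x regions), `table` (a `volume_table`
#'   of normalized fractions), `module_scores` (individuals x modules,
#'   standardized latent noise means), `truth` (region -> module),
#'   `repaired` (PSD repair flag).
#' @export
simulate_volume_table <- function(genotypes, spec, model, sigma = 0.15,
                                  mu = NULL, seed = 1L) {
  stopifnot(inherits(spec, "module_spec"), inherits(model, "genetic_model"))
  if (sigma <= 0) stop("sigma must be > 0")
  regions <- names(spec$assignment)
  if (!setequal(regions, names(model$delta)))
    stop("model delta regions do not match module spec regions")
  n <- nrow(genotypes)
  p <- length(regions)
  if (is.null(mu)) mu <- stats::setNames(rep(log(1 / p), p), regions)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  eps <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = sigma^2 * spec$R)
  dimnames(eps) <- list(genotypes$specimen_id, regions)
  a <- vapply(regions, function(r)
    dominance_value(genotypes$g, model$h[r]), numeric(n))
  logv <- sweep(a %*% diag(model$delta[regions], nrow = p), 2L,
                mu[regions], `+`) + eps
  dimnames(logv) <- list(genotypes$specimen_id, regions)
  raw <- exp(logv)
  fractions <- raw / rowSums(raw)
  mods <- sort(unique(as.character(spec$assignment)))
  scores <- vapply(mods, function(m) {
    cols <- regions[as.character(spec$assignment) == m]
    as.vector(scale(rowMeans(eps[, cols, drop = FALSE])))
  }, numeric(n))
  dimnames(scores) <- list(genotypes$specimen_id, mods)
  list(raw = raw,
       table = volume_table(fractions, specimen_id = genotypes$specimen_id,
                            population = genotypes$population),
       module_scores = scores,
       truth = spec$assignment,
       repaired = spec$repaired)
}
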