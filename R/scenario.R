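#' Default synthetic scenario
#'
#' The study conditions used throughout the package's recovery tests: an F2
#' hybrid cohort of 37 individuals, 20 regions in two modules (dorsal,
#' ventral), within-module noise correlation 0.6 and between-module -0.4,
#' a dorsal-contraction / ventral-expansion genotype effect of magnitude
#' 0.3 on log volume, log-volume noise sigma = 0.15, and F2 segregation
#' over 8 additive loci. Any field can be overridden by name.
#'
#' @param ... named overrides of scenario fields.
#' @return A named list (class `scenario`).
#' @export
default_scenario <- function(...) {
  sc <- list(
    n_regions = 20L,
    n_modules = 2L,
    module_names = c("dorsal", "ventral"),
    rho_within = 0.6,
    rho_between = -0.4,
    delta_magnitude = 0.3,
    sigma = 0.15,
    n_per_pop = c(F2 = 37L),
    n_loci = 8L,
    h = 0.5,
    grid_shape = c(64L, 64L, 64L),
    brain_fill = 0.15,
    voxel_size = c(2, 2, 2),
    dv_axis = 3L,
    n_landmarks = 20L,
    deform_scale = 10,
    noise_sd = 1,
    coord_scale = 100,
    render = FALSE)
  over <- list(...)
  bad <- setdiff(names(over), names(sc))
  if (length(bad)) stop("unknown scenario field(s): ", paste(bad, collapse = ", "))
  sc[names(over)] <- over
  class(sc) <- "scenario"
  sc
}

#' Read a scenario from a YAML file
#'
#' Fields missing from the file take their [default_scenario()] values.
#'
#' @param path YAML file of scenario key/value pairs.
#' @return A `scenario` list.
#' @export
read_scenario <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_scenario, vals)
}

#' Simulate a complete synthetic cohort
#'
#' Runs the full generator chain for a scenario: genotypes, module-
#' structured volumes (raw and normalized), landmark cohort, and (when
#' `scenario$render` is `TRUE`) per-individual label volumes. All ground
#' truth (module assignment, latent module scores, genotypes) is retained.
#' Identical scenario and seed produce identical cohorts.
#'
#' @param scenario a [default_scenario()] list.
#' @param seed integer seed; the stage generators use seeds derived from it.
#' @return List with `genotypes`, `volumes` (see
#'   [simulate_volume_table()]), `landmarks`, `label_volumes` (or `NULL`),
#'   `spec`, `model`, `scenario`, `seed`.
#' @export
simulate_cohort <- function(scenario = default_scenario(), seed = 1L) {
  sc <- scenario
  p <- sc$n_regions
  regions <- sprintf("R%02d", seq_len(p))
  mod_of <- rep(sc$module_names, length.out = sc$n_modules)[
    ceiling(seq_len(p) / (p / sc$n_modules))]
  assignment <- stats::setNames(mod_of, regions)
  # tradeoff: first (dorsal) module contracts, later modules expand
  delta <- ifelse(assignment == sc$module_names[1L],
                  -sc$delta_magnitude, sc$delta_magnitude)
  names(delta) <- regions
  model <- genetic_model(n_loci = sc$n_loci, delta = delta, h = sc$h)
  spec <- module_spec(assignment, rho_within = sc$rho_within,
                      rho_between = sc$rho_between)
  seed <- as.integer(seed)
  genotypes <- simulate_genotypes(sc$n_per_pop, model, seed = seed)
  volumes <- simulate_volume_table(genotypes, spec, model, sigma = sc$sigma,
                                   seed = seed + 1L)
  landmarks <- simulate_landmark_cohort(
    volumes, n_landmarks = sc$n_landmarks, deform_scale = sc$deform_scale,
    noise_sd = sc$noise_sd, coord_scale = sc$coord_scale, seed = seed + 2L)
  label_volumes <- NULL
  if (isTRUE(sc$render))
    label_volumes <- render_cohort_label_volumes(
      volumes$table$fractions, assignment, grid_shape = sc$grid_shape,
      brain_fill = sc$brain_fill, voxel_size = sc$voxel_size,
      dv_axis = sc$dv_axis, seed = seed + 3L)
  list(genotypes = genotypes, volumes = volumes, landmarks = landmarks,
       label_volumes = label_volumes, spec = spec, model = model,
       scenario = sc, seed = seed)
}
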