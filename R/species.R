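#' Define a factor species
#'
#' A factor species is a population of identical diffusing spheres of
#' one color that bind reversibly (via a short-range attractive well)
#' to cognate beads of the same color.  Factors stochastically switch
#' between a binding-competent ("phosphorylated") and an incompetent
#' state at first-order rates; with the default equal rates of 1e-5 per
#' Brownian time (~0.001 per second under the default time mapping)
#' half the population is competent at steady state.
#'
#' @param color Color label; must match bead colors to bind.
#' @param count Number of factors of this species (>= 0).
#' @param diameter_nm Sphere diameter (nm).
#' @param specific_affinity_kT Depth (kT) of the attractive well felt
#'   by competent factors at cognate beads.
#' @param nonspecific_affinity_kT Depth (kT) of the well felt by
#'   competent factors at *all* beads (default 0 = purely repulsive at
#'   non-cognate beads).
#' @param switch_off_rate,switch_on_rate Competence loss/gain rates in
#'   inverse Brownian times.
#' @return An object of class `factor_species`.
#' @examples
#' factor_species("red", count = 25)
#' @export
factor_species <- function(color, count,
                           diameter_nm = 30,
                           specific_affinity_kT = 7,
                           nonspecific_affinity_kT = 0,
                           switch_off_rate = 1e-5,
                           switch_on_rate = 1e-5) {
  if (!is.character(color) || length(color) != 1L)
    stopf("color must be a single label")
  if (count < 0 || count != round(count)) stopf("count must be an integer >= 0")
  if (diameter_nm <= 0) stopf("diameter_nm must be positive")
  if (specific_affinity_kT <= 0) stopf("specific_affinity_kT must be > 0")
  if (nonspecific_affinity_kT < 0) stopf("nonspecific_affinity_kT must be >= 0")
  if (switch_off_rate < 0 || switch_on_rate < 0) stopf("rates must be >= 0")
  structure(list(color = color, count = as.integer(count),
                 diameter_nm = diameter_nm,
                 specific_affinity_kT = specific_affinity_kT,
                 nonspecific_affinity_kT = nonspecific_affinity_kT,
                 switch_off_rate = switch_off_rate,
                 switch_on_rate = switch_on_rate),
            class = "factor_species")
}

#' Convert a switching rate between Brownian times and seconds
#'
#' The default mapping (one Brownian time = 0.01 s) makes a rate of
#' 1e-5 per Brownian time equal to 1e-3 per second.
#'
#' @param rate_per_tauB Rate in inverse Brownian times.
#' @param brownian_time_seconds Physical duration of one Brownian time.
#' @return Rate in inverse seconds.
#' @export
rate_per_second <- function(rate_per_tauB, brownian_time_seconds = 0.01) {
  rate_per_tauB / brownian_time_seconds
}

#' Define the force field
#'
#' Force laws follow standard coarse-grained chromatin practice:
#' consecutive beads are joined by stiff harmonic bonds; all particle
#' pairs repel through a purely repulsive (WCA) excluded-volume core at
#' contact, force-capped into a soft core at deep overlap; a
#' binding-competent factor and a cognate bead additionally attract
#' through a smooth half-cosine well whose depth is the species'
#' affinity and which closes at `attraction_range_factor` times the
#' contact distance (1.8 x 30 nm = 54 nm for default spheres, the same
#' scale as the transcription criterion).  The bounded well force keeps
#' the overdamped update stable at the default timestep for wells
#' several kT deep.  An optional harmonic spherical confinement mimics
#' the nuclear envelope; an optional bending rigidity stiffens the
#' fiber.
#'
#' @param bond_spring_constant_kT_sigma2 Bond stiffness in kT per
#'   bead-diameter squared.
#' @param bond_rest_length_nm Bond rest length; default (`NULL`) = bead
#'   diameter.
#' @param excluded_volume_kT Energy scale of the repulsive core.
#' @param attraction_range_factor Attractive cutoff as a multiple of
#'   the contact distance (must exceed 1).
#' @param bending_rigidity_kT Kratky-Porod bending modulus (0 =
#'   flexible fiber).
#' @param confinement_radius_nm Radius of the confining sphere, or
#'   `NULL` for an unconfined system.
#' @return An object of class `force_field`.
#' @examples
#' force_field()
#' @export
force_field <- function(bond_spring_constant_kT_sigma2 = 100,
                        bond_rest_length_nm = NULL,
                        excluded_volume_kT = 1,
                        attraction_range_factor = 1.8,
                        bending_rigidity_kT = 0,
                        confinement_radius_nm = NULL) {
  if (bond_spring_constant_kT_sigma2 < 0) stopf("bond stiffness must be >= 0")
  if (excluded_volume_kT < 0) stopf("excluded_volume_kT must be >= 0")
  if (attraction_range_factor <= 1)
    stopf("attraction_range_factor must exceed 1 (range beyond contact)")
  if (bending_rigidity_kT < 0) stopf("bending_rigidity_kT must be >= 0")
  if (!is.null(confinement_radius_nm) && confinement_radius_nm <= 0)
    stopf("confinement_radius_nm must be positive or NULL")
  structure(list(
    bond_spring_constant_kT_sigma2 = bond_spring_constant_kT_sigma2,
    bond_rest_length_nm = bond_rest_length_nm,
    excluded_volume_kT = excluded_volume_kT,
    attraction_range_factor = attraction_range_factor,
    bending_rigidity_kT = bending_rigidity_kT,
    confinement_radius_nm = confinement_radius_nm),
    class = "force_field")
}

#' Confinement radius for a target volume fraction
#'
#' Radius of the sphere in which the given particles occupy the stated
#' volume fraction (default 10%, a typical nuclear chromatin density).
#'
#' @param string A `genome_string`.
#' @param species List of `factor_species`.
#' @param volume_fraction Target particle volume fraction.
#' @return Radius in nm.
#' @export
confinement_for_fraction <- function(string, species = list(),
                                     volume_fraction = 0.1) {
  stopifnot(volume_fraction > 0, volume_fraction < 0.64)
  vols <- n_beads(string) * (pi / 6) * string$bead_diameter_nm^3
  for (sp in species) vols <- vols + sp$count * (pi / 6) * sp$diameter_nm^3
  ((3 / (4 * pi)) * vols / volume_fraction)^(1 / 3)
}

#' Simulation run configuration
#'
#' @param n_steps Total number of BD steps.
#' @param equilibration_steps Steps discarded before any frame is
#'   recorded.
#' @param timestep_tauB Integration timestep in Brownian times.
#' @param frame_interval Record one frame every this many steps (after
#'   equilibration).
#' @param seed Integer RNG seed for the run.
#' @param brownian_time_seconds Physical mapping of one Brownian time.
#' @return An object of class `sim_config`.  Temperature is fixed at
#'   kT = 1.
#' @examples
#' sim_config(n_steps = 1e4, equilibration_steps = 2e3)
#' @export
sim_config <- function(n_steps, equilibration_steps = 0,
                       timestep_tauB = 0.01, frame_interval = 100,
                       seed = 1, brownian_time_seconds = 0.01) {
  if (timestep_tauB <= 0) stopf("timestep must be positive")
  if (n_steps < equilibration_steps || equilibration_steps < 0)
    stopf("need n_steps >= equilibration_steps >= 0")
  if (frame_interval < 1) stopf("frame_interval must be >= 1")
  structure(list(n_steps = as.integer(n_steps),
                 equilibration_steps = as.integer(equilibration_steps),
                 timestep_tauB = timestep_tauB,
                 frame_interval = as.integer(frame_interval),
                 temperature_kT = 1,
                 seed = as.integer(seed),
                 brownian_time_seconds = brownian_time_seconds),
            class = "sim_config")
}

# hash of everything that defines an experiment except the seed and the
# bead coloring (wild-type and mutant arms share this hash)
config_hash <- function(string, species, field, config) {
  rlang::hash(list(
    n_beads = n_beads(string),
    bp = string$bp_per_bead, diam = string$bead_diameter_nm,
    palette = string$palette,
    species = lapply(species, unclass),
    field = unclass(field),
    config = unclass(config)[setdiff(names(config), "seed")]))
}
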