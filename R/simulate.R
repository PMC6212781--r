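#' @title Brownian-dynamics simulation of fiber and factors
#' @description Overdamped Langevin dynamics at kT = 1.  Each particle
#'   moves by `D F dt` plus Gaussian noise of variance `2 D dt` per
#'   coordinate and step; the diffusion constant scales inversely with
#'   particle diameter, normalised so a chromatin bead diffuses its own
#'   diameter in one Brownian time.
#' @name dynamics
NULL

# per-run arrays handed to the C++ engine
pack_system <- function(string, species, field) {
  validate_genome_string(string)
  if (inherits(species, "factor_species")) species <- list(species)
  for (sp in species) stopifnot(inherits(sp, "factor_species"))
  stopifnot(inherits(field, "force_field"))
  sigma <- string$bead_diameter_nm
  n <- n_beads(string)
  pal <- string$palette

  fcol <- integer(0); fdiam <- numeric(0)
  eps_spec <- numeric(0); eps_ns <- numeric(0)
  koff <- numeric(0); kon <- numeric(0); fcolor_chr <- character(0)
  for (sp in species) {
    k <- match(sp$color, pal)
    cnt <- sp$count
    fcol <- c(fcol, rep(if (is.na(k)) -1L else k - 1L, cnt))
    fdiam <- c(fdiam, rep(sp$diameter_nm, cnt))
    eps_spec <- c(eps_spec, rep(sp$specific_affinity_kT, cnt))
    eps_ns <- c(eps_ns, rep(sp$nonspecific_affinity_kT, cnt))
    koff <- c(koff, rep(sp$switch_off_rate, cnt))
    kon <- c(kon, rep(sp$switch_on_rate, cnt))
    fcolor_chr <- c(fcolor_chr, rep(sp$color, cnt))
  }
  m <- length(fcol)
  diam <- c(rep(sigma, n), fdiam)
  # bead diffuses its own diameter in one Brownian time: 6 D tauB = sigma^2
  D0 <- sigma^2 / 6
  D <- D0 * sigma / diam

  beadcol <- bead_color_matrix(string)
  storage.mode(beadcol) <- "integer"
  if (ncol(beadcol) == 0L) beadcol <- matrix(0L, nrow = n, ncol = 1L)

  flist <- list(
    kbond = field$bond_spring_constant_kT_sigma2 / sigma^2,
    r0 = field$bond_rest_length_nm %||% sigma,
    eps_ev = field$excluded_volume_kT,
    range_factor = field$attraction_range_factor,
    kappa = field$bending_rigidity_kT,
    Rconf = field$confinement_radius_nm %||% -1,
    kconf = 1.0,
    sigma_ref = sigma)

  list(n = n, m = m, beadcol = beadcol, fcol = fcol, diam = diam, D = D,
       eps_spec = eps_spec, eps_ns = eps_ns, koff = koff, kon = kon,
       fcolor = fcolor_chr, field = flist, sigma = sigma)
}

new_frame <- function(time, bead_positions, factor_positions,
                      factor_colors, binding_competent) {
  structure(list(time = time,
                 bead_positions = bead_positions,
                 factor_positions = factor_positions,
                 factor_colors = factor_colors,
                 binding_competent = binding_competent),
            class = "sim_frame")
}

#' @export
print.sim_frame <- function(x, ...) {
  cat(sprintf("<sim_frame> t = %g tauB, %d beads, %d factors (%d competent)\n",
              x$time, nrow(x$bead_positions), nrow(x$factor_positions),
              sum(x$binding_competent)))
  invisible(x)
}

frame_positions <- function(frame) {
  rbind(frame$bead_positions, frame$factor_positions)
}

#' Grow an initial self-avoiding conformation
#'
#' Beads are grown as a random walk with overlap rejection (a new bead
#' must be at least 0.9 diameters from all non-adjacent beads); factors
#' are scattered uniformly in the confinement sphere, or in a box
#' around the polymer when unconfined.
#'
#' @param string A `genome_string`.
#' @param species List of `factor_species`.
#' @param field A `force_field`.
#' @return A `sim_frame` at time 0 (all factors competent; competence is
#'   redrawn from the switching rates at the start of
#'   [run_simulation()]).
#' @export
initial_conformation <- function(string, species = list(),
                                 field = force_field()) {
  sys <- pack_system(string, species, field)
  sigma <- sys$sigma
  r0 <- sys$field$r0
  Rconf <- sys$field$Rconf
  n <- sys$n
  pos <- matrix(0, n, 3)
  if (Rconf > 0) pos[1, ] <- runif(3, -Rconf / 4, Rconf / 4)
  min2 <- (0.9 * sigma)^2
  for (i in seq_len(n)[-1]) {
    best <- NULL
    best_d2 <- -Inf
    for (try in 1:200) {
      u <- rnorm(3)
      cand <- pos[i - 1, ] + r0 * u / sqrt(sum(u^2))
      if (Rconf > 0 && sum(cand^2) > (Rconf - sigma / 2)^2) {
        # pull the candidate back inside the sphere along its radius
        cand <- cand * (Rconf - sigma / 2) / sqrt(sum(cand^2))
      }
      d2 <- if (i > 2) {
        prev <- pos[seq_len(i - 2), , drop = FALSE]
        min((prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
              (prev[, 3] - cand[3])^2)
      } else Inf
      if (d2 > best_d2) { best <- cand; best_d2 <- d2 }
      if (d2 >= min2) break
    }
    # dense or trapped growth keeps the least-overlapping candidate
    pos[i, ] <- best
  }
  m <- sys$m
  fpos <- matrix(0, m, 3)
  if (m > 0) {
    lo <- apply(pos, 2, min) - 3 * sigma
    hi <- apply(pos, 2, max) + 3 * sigma
    for (f in seq_len(m)) {
      df <- sys$diam[n + f]
      ok <- FALSE
      for (try in 1:500) {
        cand <- if (Rconf > 0) runif(3, -Rconf, Rconf)
                else runif(3, lo, hi)
        if (Rconf > 0 && sum(cand^2) > (Rconf - df / 2)^2) next
        # overlap rejection against beads and earlier factors
        others <- rbind(pos, fpos[seq_len(f - 1L), , drop = FALSE])
        odiam <- c(rep(sigma, n), sys$diam[n + seq_len(f - 1L)])
        d2 <- (others[, 1] - cand[1])^2 + (others[, 2] - cand[2])^2 +
          (others[, 3] - cand[3])^2
        if (all(d2 >= (0.95 * (odiam + df) / 2)^2)) { ok <- TRUE; break }
      }
      fpos[f, ] <- cand  # dense limit: last candidate stands
      if (ok) next
    }
  }
  new_frame(0, pos, fpos, sys$fcolor, rep(TRUE, m))
}

#' Compute forces on every particle
#'
#' Evaluates the full force field at one configuration.  Internal
#' forces obey Newton's third law pairwise, so without confinement they
#' sum to zero; factors that are not binding-competent (or beads
#' without the factor's color) feel only excluded volume.
#'
#' @param frame A `sim_frame`.
#' @param string A `genome_string`.
#' @param species List of `factor_species` (order defines factor
#'   order).
#' @param field A `force_field`.
#' @return List with `bead_forces` and `factor_forces` matrices
#'   (kT/nm).
#' @export
compute_forces <- function(frame, string, species = list(),
                           field = force_field()) {
  sys <- pack_system(string, species, field)
  check_frame(frame, sys)
  pos <- frame_positions(frame)
  F <- engine_forces(pos, sys$n, sys$beadcol, sys$fcol,
                     frame$binding_competent, sys$diam, sys$D,
                     sys$eps_spec, sys$eps_ns, sys$field)
  list(bead_forces = F[seq_len(sys$n), , drop = FALSE],
       factor_forces = if (sys$m > 0)
         F[sys$n + seq_len(sys$m), , drop = FALSE]
       else matrix(0, 0, 3))
}

#' Total potential energy of a configuration
#'
#' @inheritParams compute_forces
#' @return Energy in kT.
#' @export
total_energy <- function(frame, string, species = list(),
                         field = force_field()) {
  sys <- pack_system(string, species, field)
  check_frame(frame, sys)
  engine_energy(frame_positions(frame), sys$n, sys$beadcol, sys$fcol,
                frame$binding_competent, sys$diam, sys$D,
                sys$eps_spec, sys$eps_ns, sys$field)
}

check_frame <- function(frame, sys) {
  stopifnot(inherits(frame, "sim_frame"))
  if (nrow(frame$bead_positions) != sys$n)
    stopf("frame has %d beads, string has %d",
          nrow(frame$bead_positions), sys$n)
  if (nrow(frame$factor_positions) != sys$m)
    stopf("frame has %d factors, species declare %d",
          nrow(frame$factor_positions), sys$m)
  invisible(frame)
}

#' One overdamped Langevin update
#'
#' `x <- x + D F dt + sqrt(2 D dt) * N(0, 1)` per coordinate.  Uses the
#' current R random-number stream, so the update is reproducible under
#' `set.seed()`.  With `dt = 0` the frame is returned unchanged.
#'
#' @inheritParams compute_forces
#' @param dt Timestep in Brownian times.
#' @param noise Disable to take a deterministic steepest-descent step.
#' @return The updated `sim_frame`.
#' @export
bd_step <- function(frame, string, species = list(),
                    field = force_field(), dt = 0.01, noise = TRUE) {
  sys <- pack_system(string, species, field)
  check_frame(frame, sys)
  if (dt < 0) stopf("dt must be non-negative")
  pos <- engine_step(frame_positions(frame), sys$n, sys$beadcol,
                     sys$fcol, frame$binding_competent, sys$diam, sys$D,
                     sys$eps_spec, sys$eps_ns, sys$field, dt, noise)
  out <- frame
  out$time <- frame$time + dt
  out$bead_positions <- pos[seq_len(sys$n), , drop = FALSE]
  out$factor_positions <- if (sys$m > 0)
    pos[sys$n + seq_len(sys$m), , drop = FALSE] else matrix(0, 0, 3)
  out
}

#' Stochastic phosphorylation switching of binding competence
#'
#' Each binding-competent factor loses competence with probability
#' `switch_off_rate * dt`, each incompetent one regains it with
#' probability `switch_on_rate * dt`, independently (a two-state Markov
#' chain per factor; with equal rates the stationary competent fraction
#' is 1/2).
#'
#' @param frame A `sim_frame`.
#' @param species List of `factor_species` (order defines factor
#'   order).
#' @param dt Timestep in Brownian times.
#' @return The frame with updated `binding_competent` flags.
#' @export
switch_states <- function(frame, species, dt) {
  stopifnot(inherits(frame, "sim_frame"))
  if (inherits(species, "factor_species")) species <- list(species)
  rates <- unlist(lapply(species, function(sp)
    rep(max(sp$switch_off_rate, sp$switch_on_rate), sp$count)))
  if (length(rates) && any(rates * dt >= 1))
    stopf("rate * dt must be < 1 for the first-order approximation")
  p_off <- unlist(lapply(species, function(sp)
    rep(sp$switch_off_rate * dt, sp$count)))
  p_on <- unlist(lapply(species, function(sp)
    rep(sp$switch_on_rate * dt, sp$count)))
  comp <- frame$binding_competent
  m <- length(comp)
  if (m == 0L) return(frame)
  u <- runif(m)
  flip <- ifelse(comp, u < p_off, u < p_on)
  frame$binding_competent <- xor(comp, flip)
  frame
}

#' Run a Brownian-dynamics simulation
#'
#' Integrates the bead-spring fiber and diffusing factors for
#' `config$n_steps` steps of `config$timestep_tauB`, recording a frame
#' every `config$frame_interval` steps after
#' `config$equilibration_steps`.  Factor competence is initialised from
#' the stationary law of the switching rates and then evolves
#' stochastically.  The run aborts with an informative error if any
#' particle moves more than half a bead diameter in one step.
#'
#' @param string A `genome_string`.
#' @param species A `factor_species` or list thereof.
#' @param field A `force_field`.
#' @param config A `sim_config`; `config$seed` fixes the whole run.
#' @param pin_beads Freeze all bead positions (used for tethered-site
#'   reference calculations).
#' @param initial Optional starting `sim_frame`; default grows one with
#'   [initial_conformation()].
#' @return A `trajectory`: list of `sim_frame`s plus the inputs and a
#'   run log (seed, configuration hash, stability diagnostics).
#' @examples
#' gs <- generate_random_string(30, "red", 0.2, seed = 1)
#' sp <- factor_species("red", count = 4, switch_off_rate = 0,
#'                      switch_on_rate = 0)
#' tr <- run_simulation(gs, sp, force_field(confinement_radius_nm = 100),
#'                      sim_config(n_steps = 500, frame_interval = 100))
#' length(tr$frames)
#' @export
run_simulation <- function(string, species, field = force_field(),
                           config, pin_beads = FALSE, initial = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(species, "factor_species")) species <- list(species)
  sys <- pack_system(string, species, field)
  hash <- config_hash(string, species, field, config)

  res <- with_private_seed(config$seed, {
    frame0 <- initial %||% initial_conformation(string, species, field)
    check_frame(frame0, sys)
    # stationary competence draw
    ptot <- sys$kon + sys$koff
    p_comp <- ifelse(ptot > 0, sys$kon / ptot, 1)
    comp0 <- runif(length(p_comp)) < p_comp
    raw <- engine_run(frame_positions(frame0), sys$n, sys$beadcol,
                      sys$fcol, comp0, sys$diam, sys$D, sys$eps_spec,
                      sys$eps_ns, sys$koff, sys$kon, sys$field,
                      config$timestep_tauB, config$n_steps,
                      config$equilibration_steps, config$frame_interval,
                      TRUE, pin_beads)
    raw
  })

  frames <- vector("list", length(res$frames))
  for (t in seq_along(frames)) {
    p <- res$frames[[t]]
    frames[[t]] <- new_frame(res$times[t],
                             p[seq_len(sys$n), , drop = FALSE],
                             if (sys$m > 0)
                               p[sys$n + seq_len(sys$m), , drop = FALSE]
                             else matrix(0, 0, 3),
                             sys$fcolor, res$competent[[t]])
  }
  r0 <- sys$field$r0
  if (res$max_bond_length > 1.5 * r0)
    warnf("max bond length %.1f nm exceeded 1.5 x rest length",
          res$max_bond_length)
  clamp_frac <- res$n_clamped /
    (as.numeric(config$n_steps) * max(1, sys$n + sys$m))
  if (clamp_frac > 1e-3)
    warnf(paste("deterministic displacement was capped in %.2g%% of",
                "particle updates; consider a smaller timestep"),
          100 * clamp_frac)
  structure(list(frames = frames, string = string, species = species,
                 field = field, config = config,
                 log = list(seed = config$seed, config_hash = hash,
                            max_bond_length = res$max_bond_length,
                            max_step_displacement =
                              res$max_step_displacement,
                            n_clamped = res$n_clamped,
                            n_rebuilds = res$n_rebuilds,
                            stable = TRUE)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d frames, %d beads + %d factors, dt = %g tauB, seed %d\n",
    length(x$frames), n_beads(x$string),
    if (length(x$frames)) nrow(x$frames[[1]]$factor_positions) else 0L,
    x$config$timestep_tauB, x$config$seed))
  invisible(x)
}

# shared post-processing arrays for a trajectory (or list of them)
traj_arrays <- function(trajectory) {
  stopifnot(inherits(trajectory, "trajectory"))
  list(beads = lapply(trajectory$frames, `[[`, "bead_positions"),
       factors = lapply(trajectory$frames, `[[`, "factor_positions"),
       comp = lapply(trajectory$frames, `[[`, "binding_competent"),
       times = vapply(trajectory$frames, `[[`, numeric(1), "time"))
}

#' Per-factor bound status over frames
#'
#' A factor counts as bound when it is binding-competent and within
#' `radius_nm` of any bead it can bind.
#'
#' @param trajectory A `trajectory`.
#' @param radius_nm Binding cutoff; defaults to the attractive range of
#'   the force field (1.8 x contact distance).
#' @return Logical factors x frames matrix.
#' @export
bound_matrix <- function(trajectory, radius_nm = NULL) {
  sys <- pack_system(trajectory$string, trajectory$species,
                     trajectory$field)
  if (sys$m == 0L) return(matrix(FALSE, 0, length(trajectory$frames)))
  radius_nm <- radius_nm %||%
    (trajectory$field$attraction_range_factor * sys$sigma)
  arr <- traj_arrays(trajectory)
  factor_bound(arr$beads, arr$factors, arr$comp, sys$beadcol, sys$fcol,
               sys$eps_ns > 0, radius_nm)
}
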