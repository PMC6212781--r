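#' Per-bead transcription probabilities from an ensemble
#'
#' A chromatin bead counts as transcribed in a frame when it lies
#' within `radius_nm` (default 54 nm) of a binding-competent factor of
#' a matching color.  The per-bead probability is the mean over runs of
#' each run's frame-average (run-level statistics, because frames
#' within a run are autocorrelated); the standard error is taken across
#' runs.
#'
#' Only binding (colored) beads carry entries.
#'
#' @param ensemble A `trajectory` or list of trajectories sharing the
#'   same string and configuration.
#' @param string The `genome_string` the runs used.
#' @param radius_nm Transcription capture radius (nm).
#' @return An object of class `transcription_profile`: `data.frame`
#'   with `bead_index`, `color`, `probability`, `se`, plus attributes
#'   `n_runs`, `radius_nm` and `run_means` (binding beads x runs
#'   matrix).
#' @export
transcription_profile <- function(ensemble, string, radius_nm = 54) {
  if (inherits(ensemble, "trajectory")) ensemble <- list(ensemble)
  if (radius_nm < 0) stopf("radius_nm must be non-negative")
  validate_genome_string(string)
  for (tr in ensemble) {
    stopifnot(inherits(tr, "trajectory"))
    if (!identical(lapply(tr$string$beads$colors, sort),
                   lapply(string$beads$colors, sort)))
      stopf("all trajectories must share the profile's string")
  }
  run_means <- vapply(ensemble, function(tr) {
    transcribed_fraction_per_bead(tr, radius_nm)
  }, numeric(n_beads(string)))
  run_means <- matrix(run_means, nrow = n_beads(string))
  bind <- binding_beads(string)
  rm_b <- run_means[bind + 1L, , drop = FALSE]
  n_runs <- length(ensemble)
  prob <- rowMeans(rm_b)
  se <- if (n_runs > 1) apply(rm_b, 1, stats::sd) / sqrt(n_runs)
        else rep(NA_real_, length(bind))
  out <- data.frame(
    bead_index = bind,
    color = vapply(string$beads$colors[bind + 1L],
                   paste, character(1), collapse = ","),
    probability = prob,
    se = se)
  rownames(rm_b) <- bind
  structure(out, n_runs = n_runs, radius_nm = radius_nm,
            run_means = rm_b,
            class = c("transcription_profile", "data.frame"))
}

# per-bead frame-average transcription indicator for one run
transcribed_fraction_per_bead <- function(trajectory, radius_nm) {
  sys <- pack_system(trajectory$string, trajectory$species,
                     trajectory$field)
  arr <- traj_arrays(trajectory)
  if (length(arr$beads) == 0L) stopf("trajectory has no frames")
  if (sys$m == 0L || radius_nm == 0) return(numeric(sys$n))
  tf <- transcribing_factor(arr$beads, arr$factors, arr$comp,
                            sys$beadcol, sys$fcol, radius_nm)
  rowMeans(tf > 0L)
}

#' Association between transcription and cluster membership
#'
#' Among (bead, frame) observations in which a bead is transcribed,
#' computes the fraction whose transcribing factor belongs to a cluster
#' of size >= 2, and compares it with the unconditional fraction of
#' competent factors in such clusters.  In the bridging regime the
#' conditional fraction exceeds the unconditional one: a transcribed
#' bead is typically caught in a cluster.
#'
#' @param trajectory A `trajectory`.
#' @param radius_nm Transcription capture radius (nm).
#' @param cluster_cutoff_nm Cluster edge cutoff (nm).
#' @return List with `conditional`, `unconditional` and
#'   `n_transcribed_observations`.
#' @export
transcription_cluster_association <- function(trajectory, radius_nm = 54,
                                              cluster_cutoff_nm = 60) {
  sys <- pack_system(trajectory$string, trajectory$species,
                     trajectory$field)
  arr <- traj_arrays(trajectory)
  tf <- transcribing_factor(arr$beads, arr$factors, arr$comp,
                            sys$beadcol, sys$fcol, radius_nm)
  cond_num <- 0L; cond_den <- 0L
  unc_num <- 0L; unc_den <- 0L
  for (t in seq_along(trajectory$frames)) {
    cl <- detect_clusters(trajectory$frames[[t]], cluster_cutoff_nm)
    in_cl <- cl$sizes[cl$membership] >= 2
    comp <- arr$comp[[t]]
    unc_num <- unc_num + sum(in_cl & comp)
    unc_den <- unc_den + sum(comp)
    fs <- tf[, t]
    fs <- fs[fs > 0L]
    cond_num <- cond_num + sum(in_cl[fs])
    cond_den <- cond_den + length(fs)
  }
  list(conditional = if (cond_den) cond_num / cond_den else NaN,
       unconditional = if (unc_den) unc_num / unc_den else NaN,
       n_transcribed_observations = cond_den)
}
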