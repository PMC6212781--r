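#' Run an ensemble of independent simulations
#'
#' Runs `n_runs` independent trajectories of the same system with
#' per-run seeds `master_seed + 1 ... master_seed + n_runs`, reducing
#' each to per-bead run-level transcription means.  Runs are
#' independent, so the ensemble is order-insensitive and trivially
#' parallel by seed.
#'
#' @param string A `genome_string`.
#' @param species A `factor_species` or list thereof.
#' @param field A `force_field`.
#' @param config A `sim_config` (its seed field is overridden per run).
#' @param n_runs Number of runs (>= 2).
#' @param master_seed Base seed for the ensemble.
#' @param radius_nm Transcription capture radius (nm).
#' @return An `ensemble_result`: list with `run_means` (binding beads x
#'   runs), `bead_index`, `color`, `n_runs`, `seeds`, `string`,
#'   `config_hash`, `radius_nm`.
#' @export
run_ensemble <- function(string, species, field = force_field(), config,
                         n_runs, master_seed, radius_nm = 54) {
  if (n_runs < 2) stopf("n_runs must be at least 2")
  if (inherits(species, "factor_species")) species <- list(species)
  seeds <- master_seed + seq_len(n_runs)
  bind <- binding_beads(string)
  run_means <- matrix(NA_real_, nrow = length(bind), ncol = n_runs,
                      dimnames = list(bind, NULL))
  for (i in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[i])
    tr <- tryCatch(
      run_simulation(string, species, field, cfg),
      error = function(e)
        stopf("ensemble aborted: run %d (seed %d) failed: %s",
              i, seeds[i], conditionMessage(e)))
    pm <- transcribed_fraction_per_bead(tr, radius_nm)
    run_means[, i] <- pm[bind + 1L]
  }
  structure(list(run_means = run_means,
                 bead_index = bind,
                 color = vapply(string$beads$colors[bind + 1L],
                                paste, character(1), collapse = ","),
                 n_runs = n_runs, seeds = seeds, string = string,
                 config_hash = config_hash(string, species, field,
                                           config),
                 radius_nm = radius_nm),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d runs, %d binding beads, hash %s\n",
              x$n_runs, length(x$bead_index),
              substr(x$config_hash, 1, 8)))
  invisible(x)
}

# build an ensemble_result from a subset of another's runs (used for
# null calibration on wild-type splits)
subset_ensemble <- function(ens, runs) {
  stopifnot(inherits(ens, "ensemble_result"), length(runs) >= 2)
  out <- ens
  out$run_means <- ens$run_means[, runs, drop = FALSE]
  out$seeds <- ens$seeds[runs]
  out$n_runs <- length(runs)
  out
}

#' Compare wild-type and mutant ensembles bead by bead
#'
#' Two-sample z-test on run-level transcription means, assuming
#' Gaussian statistics: `z = (mean_mut - mean_wt) /
#' sqrt(se_wt^2 + se_mut^2)` with a two-sided normal p-value.  No
#' multiple-testing correction is applied; instead the expected number
#' of beads changing by chance, `alpha * n_binding_beads`, is reported
#' alongside (the convention of reporting "< k expected by chance").
#' The mutated bead — identified as the one binding in one arm only —
#' is reported but excluded from distal-change counts.
#'
#' Beads with zero variance in both arms carry no evidence of change
#' and get `p = 1` (flagged in the `degenerate` column).
#'
#' @param wt,mut `ensemble_result`s sharing the configuration hash and
#'   a string that differs at most at the mutated bead.
#' @param alpha Per-bead significance threshold (default 0.009).
#' @return A `differential_report`: `data.frame` with `bead_index`,
#'   `color`, `position_bp`, `mean_wt`, `mean_mut`, `delta`, `z_score`,
#'   `p_value`, `significant`, `degenerate`, `is_mutated`; attributes
#'   `alpha`, `n_binding_beads`, `expected_false_positives`,
#'   `mutated_bead`, `n_runs`.
#' @export
compare_ensembles <- function(wt, mut, alpha = 0.009) {
  stopifnot(inherits(wt, "ensemble_result"),
            inherits(mut, "ensemble_result"))
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (!identical(wt$config_hash, mut$config_hash))
    stopf("ensembles were run under different configurations")
  only_wt <- setdiff(wt$bead_index, mut$bead_index)
  only_mut <- setdiff(mut$bead_index, wt$bead_index)
  if (length(only_wt) + length(only_mut) > 1)
    stopf("strings differ at %d beads; expected at most the mutated one",
          length(only_wt) + length(only_mut))
  mutated <- if (length(only_wt)) only_wt else
    if (length(only_mut)) only_mut else NA_integer_

  beads <- wt$bead_index
  n_binding <- length(beads)
  mw <- rowMeans(wt$run_means)
  sew <- apply(wt$run_means, 1, stats::sd) / sqrt(wt$n_runs)
  idx_mut <- match(beads, mut$bead_index)
  mm <- sem <- rep(NA_real_, n_binding)
  present <- !is.na(idx_mut)
  mm[present] <- rowMeans(mut$run_means[idx_mut[present], , drop = FALSE])
  sem[present] <- apply(mut$run_means[idx_mut[present], , drop = FALSE],
                        1, stats::sd) / sqrt(mut$n_runs)
  # the mutated bead is absent from the mutant's binding set: its
  # transcription probability there is identically zero
  mm[!present] <- 0
  sem[!present] <- 0

  delta <- mm - mw
  pooled <- sqrt(sew^2 + sem^2)
  degenerate <- pooled == 0
  z <- ifelse(degenerate, 0, delta / pooled)
  p <- ifelse(degenerate & delta == 0, 1, 2 * stats::pnorm(-abs(z)))
  p[degenerate & delta != 0] <- 0  # deterministic difference
  sig <- p < alpha

  out <- data.frame(
    bead_index = beads,
    color = wt$color,
    position_bp = (beads + 0.5) * wt$string$bp_per_bead,
    mean_wt = mw, mean_mut = mm, delta = delta,
    z_score = z, p_value = p, significant = sig,
    degenerate = degenerate,
    is_mutated = beads %in% mutated)
  structure(out,
            alpha = alpha,
            n_binding_beads = n_binding,
            expected_false_positives = alpha * n_binding,
            mutated_bead = mutated,
            n_runs = c(wt = wt$n_runs, mut = mut$n_runs),
            class = c("differential_report", "data.frame"))
}

#' Summarize a differential report
#'
#' Counts significantly up- and down-regulated beads per color
#' (excluding the mutated bead itself, which is reported separately)
#' and tabulates their positions, sorted by bead index.
#'
#' @param report A `differential_report`.
#' @return List with `counts` (`data.frame`: color, up, down),
#'   `n_significant`, `n_distal` (significant beads other than the
#'   mutated one), `expected_false_positives`, `mutated` (one-row
#'   `data.frame` or `NULL`) and `table` (significant beads sorted by
#'   index).
#' @export
differential_summary <- function(report) {
  stopifnot(inherits(report, "differential_report"))
  sig <- report[report$significant & !report$is_mutated, , drop = FALSE]
  sig <- sig[order(sig$bead_index), , drop = FALSE]
  cols <- sort(unique(report$color))
  counts <- data.frame(
    color = cols,
    up = vapply(cols, function(cc)
      sum(sig$color == cc & sig$delta > 0), integer(1)),
    down = vapply(cols, function(cc)
      sum(sig$color == cc & sig$delta < 0), integer(1)),
    row.names = NULL)
  mut <- report[report$is_mutated, , drop = FALSE]
  list(counts = counts,
       n_significant = sum(report$significant),
       n_distal = nrow(sig),
       expected_false_positives = attr(report, "expected_false_positives"),
       mutated = if (nrow(mut)) mut else NULL,
       table = sig)
}
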