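# hand-built ensemble_result (bypasses simulation; exercises statistics)
fake_ensemble <- function(run_means, bead_index, color = NULL,
                          hash = "h", string = NULL) {
  if (is.null(color)) color <- rep("red", length(bead_index))
  if (is.null(string)) {
    n <- max(bead_index) + 1L
    gs <- generate_random_string(n, "red", 0, seed = 1)
    for (b in bead_index) gs$beads$colors[[b + 1L]] <- "red"
    string <- gs
  }
  structure(list(run_means = run_means, bead_index = bead_index,
                 color = color, n_runs = ncol(run_means),
                 seeds = seq_len(ncol(run_means)), string = string,
                 config_hash = hash, radius_nm = 54),
            class = "ensemble_result")
}

test_that("the two-sample z-test matches direct computation", {
  set.seed(70)
  nb <- 6; nr <- 20
  wt_m <- matrix(runif(nb * nr), nb, nr)
  mut_m <- wt_m + rnorm(nb * nr, sd = 0.05)
  mut_m[1, ] <- mut_m[1, ] + 0.6  # one strongly shifted bead
  mut_m <- pmin(pmax(mut_m, 0), 1)
  beads <- c(0L, 5L, 10L, 15L, 20L, 25L)
  wt <- fake_ensemble(wt_m, beads)
  mut <- fake_ensemble(mut_m, beads, string = wt$string)
  rep <- compare_ensembles(wt, mut, alpha = 0.009)
  for (k in seq_len(nb)) {
    d <- mean(mut_m[k, ]) - mean(wt_m[k, ])
    se <- sqrt(sd(wt_m[k, ])^2 / nr + sd(mut_m[k, ])^2 / nr)
    z <- d / se
    expect_equal(rep$z_score[k], z, tolerance = 1e-10)
    expect_equal(rep$p_value[k], 2 * pnorm(-abs(z)), tolerance = 1e-10)
  }
  expect_true(rep$significant[1])
  expect_equal(attr(rep, "expected_false_positives"), 0.009 * nb)
  expect_identical(attr(rep, "n_binding_beads"), as.integer(nb))
})

test_that("zero-variance beads get p = 1 and a degenerate flag", {
  beads <- c(0L, 3L)
  wt <- fake_ensemble(matrix(c(0, 0, 0, 0.5, 0.5, 0.5), 2, 3,
                             byrow = TRUE), beads)
  mut <- fake_ensemble(matrix(c(0, 0, 0, 0.5, 0.5, 0.5), 2, 3,
                              byrow = TRUE), beads, string = wt$string)
  rep <- compare_ensembles(wt, mut, alpha = 0.05)
  expect_identical(rep$p_value[1], 1)
  expect_true(rep$degenerate[1])
  expect_false(rep$significant[1])
})

test_that("mismatched configurations are rejected", {
  beads <- c(0L, 2L)
  a <- fake_ensemble(matrix(runif(6), 2, 3), beads, hash = "aaa")
  b <- fake_ensemble(matrix(runif(6), 2, 3), beads, hash = "bbb",
                     string = a$string)
  expect_error(compare_ensembles(a, b), "different configurations")
})

test_that("strings differing at more than the mutated bead are rejected", {
  gs <- generate_random_string(50, "red", 0.3, seed = 2)
  wt_beads <- binding_beads(gs)
  m1 <- suppressWarnings(apply_mutation(apply_mutation(gs, wt_beads[1]),
                                        wt_beads[2]))
  wt <- fake_ensemble(matrix(runif(2 * length(wt_beads)),
                             ncol = 2), wt_beads, string = gs)
  mut <- fake_ensemble(matrix(runif(2 * (length(wt_beads) - 2)),
                              ncol = 2), binding_beads(m1), string = m1)
  expect_error(compare_ensembles(wt, mut), "at most the mutated")
})

test_that("the mutated bead is identified and reported separately", {
  gs <- generate_random_string(50, "red", 0.3, seed = 2)
  bb <- binding_beads(gs)
  mut_bead <- bb[3]
  mutg <- apply_mutation(gs, mut_bead)
  wt_m <- matrix(0.5 + rnorm(length(bb) * 4, sd = 0.02),
                 length(bb), 4)
  mut_m <- wt_m[-3, , drop = FALSE]
  wt <- fake_ensemble(wt_m, bb, string = gs)
  mut <- fake_ensemble(mut_m, binding_beads(mutg), string = mutg)
  rep <- compare_ensembles(wt, mut, alpha = 0.009)
  expect_identical(attr(rep, "mutated_bead"), mut_bead)
  row <- rep[rep$is_mutated, ]
  expect_identical(row$bead_index, mut_bead)
  expect_equal(row$mean_mut, 0)
  expect_lt(row$delta, 0)
  # summary excludes the mutated bead from distal counts
  smry <- differential_summary(rep)
  expect_false(mut_bead %in% smry$table$bead_index)
  expect_identical(smry$mutated$bead_index, mut_bead)
})

test_that("differential summaries partition the significant set", {
  set.seed(71)
  beads <- seq(0L, 38L, by = 2L)
  nb <- length(beads)
  wt_m <- matrix(runif(nb * 10, 0.3, 0.7), nb, 10)
  mut_m <- wt_m
  mut_m[c(2, 5), ] <- mut_m[c(2, 5), ] + 0.4   # up
  mut_m[9, ] <- mut_m[9, ] - 0.4               # down
  colr <- rep(c("red", "green"), length.out = nb)
  wt <- fake_ensemble(wt_m, beads, color = colr)
  mut <- fake_ensemble(mut_m, beads, color = colr, string = wt$string)
  rep <- compare_ensembles(wt, mut, alpha = 0.009)
  smry <- differential_summary(rep)
  expect_identical(sum(smry$counts$up) + sum(smry$counts$down),
                   smry$n_distal)
  expect_identical(smry$n_distal, sum(rep$significant))
  expect_true(!is.unsorted(smry$table$bead_index))
  # empty significant set
  rep0 <- compare_ensembles(wt, fake_ensemble(wt_m, beads, color = colr,
                                              string = wt$string))
  smry0 <- differential_summary(rep0)
  expect_identical(smry0$n_distal, 0L)
  expect_true(all(smry0$counts$up == 0L & smry0$counts$down == 0L))
})

test_that("ensembles demand at least two runs and reproduce by seed", {
  gs <- generate_random_string(30, "red", 0.2, seed = 3)
  sp <- factor_species("red", 3, switch_off_rate = 0,
                       switch_on_rate = 0)
  ff <- force_field(confinement_radius_nm = 120)
  cfg <- sim_config(n_steps = 2000, equilibration_steps = 500,
                    frame_interval = 250, seed = 1)
  expect_error(run_ensemble(gs, sp, ff, cfg, n_runs = 1,
                            master_seed = 1), "at least 2")
  a <- run_ensemble(gs, sp, ff, cfg, n_runs = 2, master_seed = 7)
  b <- run_ensemble(gs, sp, ff, cfg, n_runs = 2, master_seed = 7)
  expect_identical(a$run_means, b$run_means)
  expect_identical(a$seeds, c(8, 9))
  # distinct seeds give distinct runs
  expect_false(identical(a$run_means[, 1], a$run_means[, 2]))
})

test_that("per-bead run SEs are positive for intermediate probabilities", {
  fx <- eqtl_fixture()
  pm <- rowMeans(fx$wt$run_means)
  sds <- apply(fx$wt$run_means, 1, sd)
  mid <- pm > 0.05 & pm < 0.95
  expect_gt(sum(mid), 10)
  expect_true(all(sds[mid] > 0))
})

test_that("a one-kT affinity change preserves the mutant-bead effect", {
  # robustness of the eQTL readout to the binding-affinity choice: the
  # same experiment as the main fixture, one kT stronger binding
  fx <- eqtl_fixture()
  sps <- lapply(fx$species, function(sp) {
    sp$specific_affinity_kT <- sp$specific_affinity_kT + 1
    sp
  })
  wt <- run_ensemble(fx$string, sps, fx$field, fx$config, n_runs = 8,
                     master_seed = 3000)
  mut <- run_ensemble(apply_mutation(fx$string, fx$mut_bead), sps,
                      fx$field, fx$config, n_runs = 8,
                      master_seed = 4000)
  rep <- compare_ensembles(wt, mut, alpha = 0.009)
  row <- rep[rep$is_mutated, ]
  expect_lt(row$delta, 0)
  expect_lt(row$p_value, 0.009)
})
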