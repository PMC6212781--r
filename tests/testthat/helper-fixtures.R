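# Shared fixtures.  Simulation-backed fixtures are computed lazily and
# cached for the whole test run; problem sizes are scaled to desk
# proportions (a few hundred beads, 1e5-2e5 steps) while keeping the
# study design: random multi-color strings, default affinity 7 kT,
# weak spherical confinement at 2% particle volume fraction (the
# dilute-chromatin regime of coarse-grained nuclear models).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# independent union-find connected components (oracle for clusters)
oracle_components <- function(pos, cutoff) {
  m <- nrow(pos)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (m >= 2) {
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  match(roots, unique(roots))
}

# canonical form of a partition for comparison
partition_canonical <- function(membership) {
  split(seq_along(membership), membership) |>
    lapply(sort) |>
    (\(x) x[order(vapply(x, min, integer(1)))])()
}

# a small equilibrated two-color system used by several observable tests
demo_trajectory <- function() {
  cached("demo_traj", {
    gs <- generate_random_string(120, c("red", "green"), 0.1, seed = 5)
    sps <- list(
      factor_species("red", 8, switch_off_rate = 0, switch_on_rate = 0),
      factor_species("green", 8, switch_off_rate = 0, switch_on_rate = 0))
    ff <- force_field(
      confinement_radius_nm = confinement_for_fraction(gs, sps, 0.02))
    run_simulation(gs, sps, ff,
                   sim_config(n_steps = 4e4, equilibration_steps = 2e4,
                              frame_interval = 1000, seed = 31))
  })
}

# polymer-only run (no factors), unconfined
polymer_trajectory <- function() {
  cached("polymer_traj", {
    gs <- generate_random_string(150, "red", 0, seed = 6)
    run_simulation(gs, list(), force_field(),
                   sim_config(n_steps = 2e5, equilibration_steps = 6e4,
                              frame_interval = 2000, seed = 32))
  })
}

# bridging run and its zero-affinity control: 300-bead string with 20%
# cognate beads, 30 factors, 2e5 steps
bridging_pair <- function() {
  cached("bridging_pair", {
    make <- function(eps) {
      gs <- generate_random_string(300, "red", 0.2, seed = 1)
      sp <- factor_species("red", 30, specific_affinity_kT = eps,
                           switch_off_rate = 0, switch_on_rate = 0)
      ff <- force_field(
        confinement_radius_nm = confinement_for_fraction(gs, list(sp), 0.02))
      run_simulation(gs, sp, ff,
                     sim_config(n_steps = 2e5, equilibration_steps = 1e5,
                                frame_interval = 2500, seed = 101))
    }
    list(bridging = make(7), control = make(1e-9))
  })
}

# pooled cluster statistics for a trajectory
cluster_stats <- function(tr, cutoff = 60) {
  bm <- bound_matrix(tr)
  num <- 0; den <- 0; mixn <- 0; mixd <- 0; singles <- 0
  for (t in seq_along(tr$frames)) {
    cl <- detect_clusters(tr$frames[[t]], cutoff)
    incl <- cl$sizes[cl$membership] >= 2
    num <- num + sum(incl & bm[, t]); den <- den + sum(bm[, t])
    ids <- which(cl$sizes >= 2)
    mixd <- mixd + length(ids)
    mixn <- mixn + sum(vapply(ids, function(id)
      length(unique(cl$colors[cl$membership == id])) > 1L, logical(1)))
  }
  list(bound_fraction = mean(bm),
       clustered_given_bound = num / max(den, 1),
       n_bound_obs = den,
       mixed_fraction = if (mixd) mixn / mixd else NaN,
       n_clusters = mixd)
}

# two-color demixing run: sparse disjoint cognate sets
demix_run <- function(seed) {
  cached(paste0("demix_", seed), {
    gs <- generate_random_string(400, c("red", "green"), 0.05, seed = seed)
    sps <- list(
      factor_species("red", 10, switch_off_rate = 0, switch_on_rate = 0),
      factor_species("green", 10, switch_off_rate = 0, switch_on_rate = 0))
    ff <- force_field(
      confinement_radius_nm = confinement_for_fraction(gs, sps, 0.02))
    run_simulation(gs, sps, ff,
                   sim_config(n_steps = 2e5, equilibration_steps = 1e5,
                              frame_interval = 2500, seed = seed + 100))
  })
}

# alternating 50-bead block strings (colors recycled; NA = non-binding)
block_string <- function(n_blocks = 6, block = 50,
                         colors = c("pink", NA)) {
  n <- n_blocks * block
  pal <- unique(colors[!is.na(colors)])
  idx <- seq_len(n) - 1L
  beads <- data.frame(index = idx, chrom = "sim", start = idx * 3000,
                      end = (idx + 1L) * 3000)
  cols <- rep(colors, length.out = n_blocks)
  beads$colors <- lapply(seq_len(n), function(i) {
    cc <- cols[((i - 1) %/% block) + 1]
    if (is.na(cc)) character(0) else cc
  })
  bridgesim:::validate_genome_string(
    bridgesim:::new_genome_string(beads, 3000L, 30, pal))
}

tad_fixture <- function() {
  cached("tad_fixture", {
    gs <- block_string(6, 50, c("pink", NA))
    sp <- factor_species("pink", 20, switch_off_rate = 0,
                         switch_on_rate = 0)
    ff <- force_field(
      confinement_radius_nm = confinement_for_fraction(gs, list(sp), 0.02))
    tr <- run_simulation(gs, sp, ff,
                         sim_config(n_steps = 3e5,
                                    equilibration_steps = 1e5,
                                    frame_interval = 4000, seed = 21))
    list(string = gs, traj = tr, map = compute_contact_map(tr),
         blocks = lapply(0:5, function(b) c(b * 50, b * 50 + 49)))
  })
}

compartment_fixture <- function() {
  cached("compartment_fixture", {
    gs <- block_string(6, 50, c("pink", "green"))
    sps <- list(
      factor_species("pink", 10, switch_off_rate = 0, switch_on_rate = 0),
      factor_species("green", 10, switch_off_rate = 0,
                     switch_on_rate = 0))
    ff <- force_field(
      confinement_radius_nm = confinement_for_fraction(gs, sps, 0.02))
    tr <- run_simulation(gs, sps, ff,
                         sim_config(n_steps = 3e5,
                                    equilibration_steps = 1e5,
                                    frame_interval = 4000, seed = 22))
    list(string = gs, traj = tr, map = compute_contact_map(tr))
  })
}

# tethered two-particle system: BD time average vs a direct
# Monte-Carlo Boltzmann oracle over the documented potential
two_particle_stats <- function() {
  cached("two_particle", {
    eps <- 4; R <- 120
    gs <- generate_random_string(1, "red", 1, seed = 1)
    sp <- factor_species("red", 1, specific_affinity_kT = eps,
                         switch_off_rate = 0, switch_on_rate = 0)
    ff <- force_field(confinement_radius_nm = R)
    init <- bridgesim:::new_frame(0, matrix(0, 1, 3),
                                  matrix(c(40, 0, 0), 1, 3), "red", TRUE)
    cfg <- sim_config(n_steps = 6e5, equilibration_steps = 2e4,
                      frame_interval = 50, seed = 11)
    tr <- run_simulation(gs, sp, ff, cfg, pin_beads = TRUE,
                         initial = init)
    bm <- as.numeric(bound_matrix(tr))
    blocks <- tapply(bm, (seq_along(bm) - 1) %/% 200, mean)
    # oracle: uniform positions reweighted by the pair + wall potential
    set.seed(5)
    u <- matrix(runif(3e6, -R, R), ncol = 3)
    r <- sqrt(rowSums(u^2))
    d <- 30; cut <- 1.8 * d; wca <- 2^(1 / 6) * d; rcap <- 0.95 * d
    re <- pmax(r, rcap); s6 <- (d / re)^6
    core <- ifelse(r < wca,
                   4 * (s6^2 - s6) + 1 +
                     ifelse(r < rcap,
                            24 * s6 * (2 * s6 - 1) / re * (rcap - r), 0),
                   0)
    well <- ifelse(r <= d, -eps,
                   ifelse(r < cut,
                          -eps / 2 * (1 + cos(pi * (r - d) / (cut - d))),
                          0))
    over <- pmax(r + 15 - R, 0)
    w <- exp(-(core + well + 0.5 * over^2))
    list(p_bd = mean(bm),
         se_bd = sd(blocks) / sqrt(length(blocks)),
         p_mc = sum(w * (r < cut)) / sum(w))
  })
}

# free-factor diffusion: pooled disjoint-increment MSD per 0.1 tauB
free_msd_stats <- function() {
  cached("free_msd", {
    gs <- generate_random_string(1, "x", 0, seed = 1)
    sp <- factor_species("x", 1200, switch_off_rate = 0,
                         switch_on_rate = 0)
    ff <- force_field(excluded_volume_kT = 0)
    cfg <- sim_config(n_steps = 1000, equilibration_steps = 0,
                      frame_interval = 10, seed = 7)
    tr <- run_simulation(gs, sp, ff, cfg, pin_beads = TRUE)
    fp <- lapply(tr$frames, `[[`, "factor_positions")
    incs <- vapply(2:length(fp), function(t)
      mean(rowSums((fp[[t]] - fp[[t - 1]])^2)), numeric(1))
    list(msd = mean(incs), expected = 6 * (30^2 / 6) * 0.1)
  })
}

# The scaled eQTL experiment: 400-bead 5-color string, 4 factors per
# color with default phosphorylation switching, 6 kT affinity (fast
# enough factor exchange for ergodic runs; factors scarce relative to
# cognate beads so that freed factors redistribute across the whole
# string), 40 runs per arm.  The
# mutated bead is the most-transcribed binding bead of the middle
# third of the wild-type string — a cluster hub, as in the headline
# experiment where the wild-type bead is typically found in a cluster.
eqtl_fixture <- function() {
  cached("eqtl_fixture", {
    pal <- c("red", "green", "blue", "yellow", "purple")
    gs <- generate_random_string(400, pal, 0.04, seed = 42)
    sps <- lapply(pal, function(cc)
      factor_species(cc, 4, specific_affinity_kT = 6))
    ff <- force_field(
      confinement_radius_nm = confinement_for_fraction(gs, sps, 0.02))
    cfg <- sim_config(n_steps = 2.5e5, equilibration_steps = 5e4,
                      frame_interval = 2000, seed = 1)
    bb <- binding_beads(gs)
    wt <- run_ensemble(gs, sps, ff, cfg, n_runs = 40, master_seed = 1000)
    mid <- bb[bb > 133 & bb < 266]
    pm <- rowMeans(wt$run_means)[match(mid, wt$bead_index)]
    mut_bead <- mid[which.max(pm)]
    mut_string <- apply_mutation(gs, mut_bead)
    mut <- run_ensemble(mut_string, sps, ff, cfg, n_runs = 40,
                        master_seed = 5000)
    list(string = gs, species = sps, field = ff, config = cfg,
         mut_bead = mut_bead, wt = wt, mut = mut,
         report = compare_ensembles(wt, mut, alpha = 0.009))
  })
}
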