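test_that("cluster detection equals brute-force connected components", {
  set.seed(40)
  for (rep in 1:6) {
    m <- sample(5:40, 1)
    pos <- matrix(runif(3 * m, 0, 300), m, 3)
    fr <- bridgesim:::new_frame(0, matrix(0, 1, 3), pos,
                                rep("x", m), rep(TRUE, m))
    cl <- detect_clusters(fr, cutoff_nm = 70)
    expect_identical(partition_canonical(cl$membership),
                     partition_canonical(oracle_components(pos, 70)))
  }
  # and on real simulation frames
  tr <- demo_trajectory()
  for (t in c(3, 11, 19)) {
    fr <- tr$frames[[t]]
    cl <- detect_clusters(fr, 60)
    expect_identical(
      partition_canonical(cl$membership),
      partition_canonical(oracle_components(fr$factor_positions, 60)))
  }
})

test_that("well-separated factors are all singletons", {
  pos <- 200 * diag(3)
  fr <- bridgesim:::new_frame(0, matrix(0, 1, 3), pos,
                              rep("x", 3), rep(TRUE, 3))
  cl <- detect_clusters(fr, cutoff_nm = 60)
  expect_identical(sort(cl$sizes), rep(1L, 3))
  expect_equal(clustered_fraction(cl), 0)
  # empty frame
  fr0 <- bridgesim:::new_frame(0, matrix(0, 1, 3), matrix(0, 0, 3),
                               character(0), logical(0))
  expect_length(detect_clusters(fr0, 60)$membership, 0L)
})

test_that("cluster-size histogram mass equals the factor count", {
  tr <- demo_trajectory()
  dist <- cluster_size_distribution(tr, 60)
  m <- nrow(tr$frames[[1]]$factor_positions)
  total <- sum(as.integer(names(dist$histogram)) * dist$histogram)
  expect_identical(total, m * length(tr$frames))
  expect_gte(dist$mean_size, 1)
})

test_that("contact maps equal an O(n^2) per-frame oracle", {
  tr <- demo_trajectory()
  short <- tr
  short$frames <- tr$frames[1:4]
  map <- compute_contact_map(short, capture_radius_nm = 54)
  n <- n_beads(tr$string)
  oracle <- matrix(0, n, n)
  for (fr in short$frames) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (sqrt(sum((fr$bead_positions[i, ] -
                      fr$bead_positions[j, ])^2)) < 54) {
        oracle[i, j] <- oracle[i, j] + 1
        oracle[j, i] <- oracle[j, i] + 1
      }
    }
  }
  oracle <- oracle / 4
  expect_equal(map$matrix, oracle, tolerance = 1e-12)
  expect_identical(map$n_observations, 4L)
})

test_that("contact maps are symmetric with entries in [0, 1]", {
  map <- compute_contact_map(demo_trajectory())
  expect_identical(map$matrix, t(map$matrix))
  expect_true(all(map$matrix >= 0 & map$matrix <= 1))
  expect_true(all(diag(map$matrix) == 0))
})

test_that("a stretched straight fiber contacts only nearby beads", {
  n <- 40
  pos <- cbind(30 * (seq_len(n) - 1), 0, 0)
  fr <- bridgesim:::new_frame(0, pos, matrix(0, 0, 3), character(0),
                              logical(0))
  gs <- generate_random_string(n, "x", 0, seed = 1)
  tr <- structure(list(frames = list(fr), string = gs, species = list(),
                       field = force_field(), config = NULL, log = NULL),
                  class = "trajectory")
  map <- compute_contact_map(tr, capture_radius_nm = 54)
  sep <- abs(row(map$matrix) - col(map$matrix))
  expect_true(all(map$matrix[sep >= 2] == 0))
  expect_true(all(map$matrix[sep == 1] == 1))
})

test_that("ideal-coil contact frequency decays with separation", {
  map <- compute_contact_map(polymer_trajectory(), capture_radius_nm = 54)
  n <- nrow(map$matrix)
  # bin means over log-spaced separations within half the chain, where
  # pair counts keep the estimates stable
  sep <- abs(row(map$matrix) - col(map$matrix))
  brks <- c(1, 2, 4, 8, 16, 32, 64)
  freq <- vapply(seq_len(length(brks) - 1), function(k) {
    keep <- sep >= brks[k] & sep < brks[k + 1]
    mean(map$matrix[keep])
  }, numeric(1))
  expect_true(all(diff(freq) <= 0))
  expect_gt(freq[1], freq[length(freq)])
  expect_true(all(diff(freq[freq > 0]) < 0))
})

test_that("TAD strength is ~1 on a uniform random map and errors on a single block", {
  set.seed(50)
  n <- 120
  m <- matrix(runif(n * n, 0.1, 0.2), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 0
  map <- bridgesim:::new_contact_map(m, 54, 100L)
  ts <- tad_strength(map, lapply(0:3, function(b) c(b * 30, b * 30 + 29)))
  expect_true(all(abs(ts$ratio - 1) < 0.1))
  expect_error(tad_strength(map, list(c(0, n - 1))), "single block")
  expect_error(tad_strength(map, list(c(0, 0))), "at least 2 beads")
  expect_error(tad_strength(map, list(c(0, 10), c(5, 20))), "disjoint")
})

test_that("bridging blocks form TADs (intra/inter ratio >= 2)", {
  fx <- tad_fixture()
  ts <- tad_strength(fx$map, fx$blocks)
  pink <- c(1, 3, 5)
  expect_true(all(ts$ratio[pink] >= 2))
  # non-binding blocks show no such enrichment
  expect_true(all(ts$ratio[-pink] < 2))
})

test_that("compartment enrichment: bridging > 1, shuffled labels ~ 1", {
  fx <- compartment_fixture()
  cs <- compartment_signal(fx$map, fx$string, min_separation = 100)
  expect_gt(cs$enrichment, 1)
  set.seed(60)
  null <- replicate(20, {
    g <- fx$string
    g$beads$colors <- sample(g$beads$colors)
    compartment_signal(fx$map, g, min_separation = 100)$enrichment
  })
  se <- sd(null) / sqrt(length(null))
  expect_lt(abs(mean(null) - 1), 3 * max(se, 0.02))
  # the true enrichment stands far outside the null spread
  expect_gt(cs$enrichment, mean(null) + 3 * sd(null))
})

test_that("compartment signal demands two colors and long-range pairs", {
  fx <- tad_fixture()  # single color
  expect_error(compartment_signal(fx$map, fx$string), "two bead colors")
  fx2 <- compartment_fixture()
  expect_error(compartment_signal(fx2$map, fx2$string,
                                  min_separation = 500),
               "min_separation")
})

test_that("compartment enrichment is invariant under color relabeling", {
  fx <- compartment_fixture()
  base <- compartment_signal(fx$map, fx$string)$enrichment
  g <- fx$string
  swap <- c(pink = "green", green = "pink")
  g$beads$colors <- lapply(g$beads$colors, function(cc) unname(swap[cc]))
  g$palette <- c("green", "pink")
  expect_equal(compartment_signal(fx$map, g)$enrichment, base,
               tolerance = 1e-12)
})

test_that("transcription probabilities behave in limiting cases", {
  tr <- demo_trajectory()
  gs <- tr$string
  # zero radius: nothing is transcribed
  p0 <- transcription_profile(tr, gs, radius_nm = 0)
  expect_true(all(p0$probability == 0))
  # enormous radius with competent factors of each color: everything is
  expect_true(all(
    transcription_profile(tr, gs, radius_nm = 1e9)$probability == 1))
  # probabilities are monotone non-decreasing in the radius
  radii <- c(20, 40, 54, 80, 150)
  probs <- vapply(radii, function(r)
    transcription_profile(tr, gs, radius_nm = r)$probability,
    numeric(length(binding_beads(gs))))
  expect_true(all(apply(probs, 1, function(x) all(diff(x) >= 0))))
  # only binding beads carry entries
  expect_setequal(p0$bead_index, binding_beads(gs))
})

test_that("a zero-factor ensemble transcribes nothing", {
  tr <- polymer_trajectory()
  gs <- tr$string
  prof <- transcription_profile(tr, gs)
  expect_true(all(prof$probability == 0))
})

test_that("transcription profiles refuse mismatched strings", {
  tr <- demo_trajectory()
  other <- generate_random_string(n_beads(tr$string), c("red", "green"),
                                  0.1, seed = 99)
  expect_error(transcription_profile(tr, other), "share")
})

test_that("transcribed beads are typically caught in clusters", {
  tr <- bridging_pair()$bridging
  assoc <- transcription_cluster_association(tr)
  expect_gt(assoc$n_transcribed_observations, 50)
  expect_gte(assoc$conditional, assoc$unconditional)
})
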