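#' Visit profile of a loop tethered to a factory sphere
#'
#' Monte-Carlo estimate of how often each monomer of a chromatin loop
#' visits the neighbourhood of the cluster ("factory") it is anchored
#' to.  The loop (default 77 kb at 3 kb per 30-nm segment, i.e. ~26
#' segments) is modelled as a closed Gaussian ring with both ends
#' anchored at one point on the surface of an impenetrable sphere
#' (default 75 nm diameter); conformations intersecting the sphere are
#' rejected.  A monomer "visits" when it lies within `shell_nm` of the
#' sphere surface.
#'
#' Monomers near the anchors visit almost always; the loop midpoint
#' visits least — tether length controls how often a promoter meets the
#' factory.
#'
#' @param loop_kbp Loop contour length in kb.
#' @param sphere_diameter_nm Factory sphere diameter (nm).
#' @param n_samples Number of Monte-Carlo ring conformations (>= 1e4).
#' @param seed Integer seed.
#' @param segment_nm Segment length (nm).
#' @param kb_per_segment Genomic span of one segment (kb).
#' @param shell_nm Width of the visiting shell beyond the sphere
#'   surface (nm).
#' @return `data.frame` with `monomer` (1 .. n_segments - 1),
#'   `contour_kbp` (genomic distance from the anchor), `visit_prob`,
#'   `se`; attributes `n_accepted` and `acceptance`.
#' @examples
#' prof <- tether_visit_profile(n_samples = 1e4, seed = 1)
#' head(prof)
#' @export
tether_visit_profile <- function(loop_kbp = 77, sphere_diameter_nm = 75,
                                 n_samples = 2e4, seed = 1,
                                 segment_nm = 30, kb_per_segment = 3,
                                 shell_nm = 30) {
  if (n_samples < 1e4) stopf("n_samples must be at least 1e4")
  n_seg <- max(2L, round(loop_kbp / kb_per_segment))
  if (n_seg * segment_nm < sphere_diameter_nm)
    stopf("loop contour (%g nm) shorter than the sphere diameter",
          n_seg * segment_nm)
  Rs <- sphere_diameter_nm / 2
  anchor <- c(Rs, 0, 0)
  shell2 <- (Rs + shell_nm)^2
  sphere2 <- Rs^2
  sd_step <- segment_nm / sqrt(3)  # per-coordinate step sd

  nv <- n_seg - 1L  # interior monomers
  visits <- numeric(nv)
  counts <- numeric(nv)
  accepted <- 0L
  block <- 5000L
  with_private_seed(seed, {
    done <- 0L
    while (done < n_samples) {
      nb <- min(block, n_samples - done)
      # Gaussian bridge: cumulative sums conditioned to return to 0
      g <- array(rnorm(nb * n_seg * 3, sd = sd_step),
                 dim = c(n_seg, 3, nb))
      w <- apply(g, c(2, 3), cumsum)          # n_seg x 3 x nb
      endv <- w[n_seg, , , drop = FALSE]      # 1 x 3 x nb
      frac <- (seq_len(n_seg)) / n_seg
      for (c3 in 1:3)
        w[, c3, ] <- w[, c3, ] - outer(frac, endv[1, c3, ])
      # interior vertex positions relative to sphere centre
      d2 <- (w[seq_len(nv), 1, , drop = FALSE] + anchor[1])^2 +
            (w[seq_len(nv), 2, , drop = FALSE] + anchor[2])^2 +
            (w[seq_len(nv), 3, , drop = FALSE] + anchor[3])^2
      d2 <- matrix(d2, nrow = nv)
      ok <- colSums(d2 < sphere2) == 0L       # no sphere penetration
      if (any(ok)) {
        accepted <- accepted + sum(ok)
        counts <- counts + sum(ok)
        visits <- visits + rowSums(d2[, ok, drop = FALSE] < shell2)
      }
      done <- done + nb
    }
  })
  if (accepted == 0L) stopf("no conformation avoided the sphere")
  p <- visits / counts
  se <- sqrt(p * (1 - p) / counts)
  out <- data.frame(monomer = seq_len(nv),
                    contour_kbp = seq_len(nv) * kb_per_segment,
                    visit_prob = p, se = se)
  structure(out, n_accepted = accepted, acceptance = accepted / n_samples)
}
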