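#' Compute a Hi-C-like contact map from trajectories
#'
#' Entry (i, j) is the fraction of pooled observations (frames across
#' all supplied runs) in which bead centres i and j lie within the
#' capture radius.  The matrix is symmetric with a zero diagonal by
#' convention.  The default capture radius of 54 nm matches the
#' geometric transcription criterion.
#'
#' @param trajectory A `trajectory` or a list of trajectories over the
#'   same string (observations are pooled over frames and runs).
#' @param capture_radius_nm Contact threshold (nm).
#' @return An object of class `contact_map`: list with `matrix`,
#'   `capture_radius_nm`, `n_observations` and `diagonal = "zero"`.
#' @export
compute_contact_map <- function(trajectory, capture_radius_nm = 54) {
  if (inherits(trajectory, "trajectory")) trajectory <- list(trajectory)
  if (capture_radius_nm <= 0) stopf("capture_radius_nm must be positive")
  frames <- list()
  nb <- NULL
  for (tr in trajectory) {
    stopifnot(inherits(tr, "trajectory"))
    if (is.null(nb)) nb <- n_beads(tr$string)
    else if (nb != n_beads(tr$string))
      stopf("all trajectories must share a string of the same length")
    frames <- c(frames, lapply(tr$frames, `[[`, "bead_positions"))
  }
  if (length(frames) == 0L) stopf("no post-equilibration frames")
  mat <- contacts_accumulate(frames, capture_radius_nm)
  new_contact_map(mat, capture_radius_nm, length(frames))
}

new_contact_map <- function(mat, capture_radius_nm, n_observations) {
  structure(list(matrix = mat,
                 capture_radius_nm = capture_radius_nm,
                 n_observations = as.integer(n_observations),
                 diagonal = "zero"),
            class = "contact_map")
}

validate_contact_map <- function(map, tol = 1e-9) {
  stopifnot(inherits(map, "contact_map"))
  m <- map$matrix
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > tol)
    stopf("contact map must be symmetric")
  if (any(m < -tol) || any(m > 1 + tol))
    stopf("contact frequencies must lie in [0, 1]")
  invisible(map)
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d x %d beads, capture %g nm, %d observations\n",
              nrow(x$matrix), ncol(x$matrix), x$capture_radius_nm,
              x$n_observations))
  invisible(x)
}

#' Contact-frequency decay with genomic separation
#'
#' Mean contact frequency in (optionally log-spaced) bins of bead
#' separation |i - j|.
#'
#' @param map A `contact_map`.
#' @param log_bins Use log-spaced separation bins.
#' @param n_bins Number of bins.
#' @return `data.frame` with `separation` (bin mid, beads) and
#'   `frequency`.
#' @export
contact_decay <- function(map, log_bins = TRUE, n_bins = 12) {
  validate_contact_map(map)
  n <- nrow(map$matrix)
  sep <- abs(row(map$matrix) - col(map$matrix))
  keep <- sep > 0
  s <- sep[keep]; f <- map$matrix[keep]
  brk <- if (log_bins)
    unique(round(exp(seq(log(1), log(n - 1), length.out = n_bins + 1))))
  else unique(round(seq(1, n - 1, length.out = n_bins + 1)))
  if (length(brk) < 2) brk <- c(1, n - 1)
  bin <- cut(s, breaks = c(0, brk[-1]), include.lowest = TRUE)
  data.frame(separation = tapply(s, bin, mean),
             frequency = tapply(f, bin, mean),
             row.names = NULL)
}

# mean contact frequency at each bead separation for a set of pairs
.sep_means <- function(mat, idx_i, idx_j) {
  s <- abs(idx_i - idx_j)
  f <- mat[cbind(idx_i + 1L, idx_j + 1L)]
  list(sep = s, f = f)
}

#' Separation-matched TAD strength
#'
#' For each annotated block, the mean intra-block contact frequency is
#' compared to the mean between-block frequency *at the same genomic
#' separations*, removing the trivial distance decay: at every bead
#' separation occurring both within the block and between blocks the
#' two means are formed, and their weighted ratio (weights = pair
#' counts at the rarer category) is reported.
#'
#' @param map A `contact_map`.
#' @param blocks List of 0-based inclusive bead-index ranges
#'   `c(start, end)`; blocks must be disjoint, within the map, and at
#'   least two beads long.
#' @return `data.frame` with one row per block: `block`, `start`,
#'   `end`, `intra`, `inter`, `ratio`.
#' @export
tad_strength <- function(map, blocks) {
  validate_contact_map(map)
  n <- nrow(map$matrix)
  if (length(blocks) < 1) stopf("need at least one block")
  bid <- rep(NA_integer_, n)
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    if (length(b) != 2 || b[2] - b[1] < 1)
      stopf("block %d must span at least 2 beads", k)
    if (b[1] < 0 || b[2] >= n) stopf("block %d outside map", k)
    sel <- (b[1]:b[2]) + 1L
    if (any(!is.na(bid[sel]))) stopf("blocks must be disjoint")
    bid[sel] <- k
  }
  ij <- which(upper.tri(map$matrix), arr.ind = TRUE)
  i0 <- ij[, 1] - 1L; j0 <- ij[, 2] - 1L
  f <- map$matrix[ij]
  s <- j0 - i0
  gi <- bid[ij[, 1]]; gj <- bid[ij[, 2]]
  intra_of <- ifelse(!is.na(gi) & !is.na(gj) & gi == gj, gi, NA)
  inter <- !is.na(gi) & !is.na(gj) & gi != gj
  if (!any(inter))
    stopf("no between-block pairs; TAD strength undefined for a single block")

  out <- data.frame(block = seq_along(blocks),
                    start = vapply(blocks, `[`, numeric(1), 1),
                    end = vapply(blocks, `[`, numeric(1), 2),
                    intra = NA_real_, inter = NA_real_,
                    ratio = NA_real_)
  inter_by_sep <- tapply(f[inter], s[inter], mean)
  inter_n_by_sep <- tapply(f[inter], s[inter], length)
  for (k in seq_along(blocks)) {
    sel <- !is.na(intra_of) & intra_of == k
    if (!any(sel)) next
    intra_by_sep <- tapply(f[sel], s[sel], mean)
    intra_n <- tapply(f[sel], s[sel], length)
    common <- intersect(names(intra_by_sep), names(inter_by_sep))
    if (length(common) == 0L) next
    w <- pmin(intra_n[common], inter_n_by_sep[common])
    intra_m <- sum(w * intra_by_sep[common]) / sum(w)
    inter_m <- sum(w * inter_by_sep[common]) / sum(w)
    out$intra[k] <- intra_m
    out$inter[k] <- inter_m
    out$ratio[k] <- intra_m / inter_m
  }
  out
}

#' Separation-matched compartment signal
#'
#' Long-range enrichment of same-color over different-color contacts
#' among binding beads: at every bead separation of at least
#' `min_separation`, mean same-color and different-color contact
#' frequencies are formed and combined with weights equal to the pair
#' count of the rarer category.  An enrichment above 1 indicates
#' compartment-like segregation; shuffling the color labels gives ~1.
#'
#' @param map A `contact_map`.
#' @param string The `genome_string` the map was computed on.
#' @param min_separation Minimum bead separation counted as long range.
#' @return List with `enrichment`, `same`, `different`, `n_pairs`.
#' @export
compartment_signal <- function(map, string, min_separation = 100) {
  validate_contact_map(map)
  validate_genome_string(string)
  n <- nrow(map$matrix)
  if (n != n_beads(string)) stopf("map and string sizes differ")
  lab <- vapply(string$beads$colors, function(cc)
    if (length(cc)) paste(sort(cc), collapse = "+") else NA_character_,
    character(1))
  if (length(unique(stats::na.omit(lab))) < 2)
    stopf("need at least two bead colors for a compartment signal")
  ij <- which(upper.tri(map$matrix), arr.ind = TRUE)
  s <- ij[, 2] - ij[, 1]
  li <- lab[ij[, 1]]; lj <- lab[ij[, 2]]
  keep <- s >= min_separation & !is.na(li) & !is.na(lj)
  if (!any(keep))
    stopf("no colored bead pairs beyond min_separation = %d",
          min_separation)
  f <- map$matrix[ij][keep]; s <- s[keep]
  same <- li[keep] == lj[keep]
  same_by <- tapply(f[same], s[same], mean)
  diff_by <- tapply(f[!same], s[!same], mean)
  n_same <- tapply(f[same], s[same], length)
  n_diff <- tapply(f[!same], s[!same], length)
  common <- intersect(names(same_by), names(diff_by))
  if (length(common) == 0L)
    stopf("no separations with both same- and different-color pairs")
  w <- pmin(n_same[common], n_diff[common])
  sm <- sum(w * same_by[common]) / sum(w)
  dm <- sum(w * diff_by[common]) / sum(w)
  list(enrichment = sm / dm, same = sm, different = dm,
       n_pairs = sum(keep))
}
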