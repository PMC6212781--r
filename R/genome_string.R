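#' @title Genome strings: coarse-grained chromatin fibers
#' @description A genome string is an ordered sequence of beads, each
#'   carrying a (possibly empty) set of color labels that determine
#'   which factor species can bind it.  By default one 30-nm bead
#'   represents 3 kb.
#' @name genome_string
NULL

new_genome_string <- function(beads, bp_per_bead, bead_diameter_nm,
                              palette) {
  structure(list(beads = beads,
                 bp_per_bead = as.integer(bp_per_bead),
                 bead_diameter_nm = bead_diameter_nm,
                 palette = palette),
            class = "genome_string")
}

validate_genome_string <- function(gs) {
  stopifnot(inherits(gs, "genome_string"))
  b <- gs$beads
  if (!identical(b$index, seq_len(nrow(b)) - 1L))
    stopf("bead indices must be 0-based, contiguous and unique")
  if (gs$bp_per_bead <= 0L) stopf("bp_per_bead must be positive")
  if (gs$bead_diameter_nm <= 0) stopf("bead_diameter_nm must be positive")
  bad <- !vapply(b$colors, function(cc) all(cc %in% gs$palette), logical(1))
  if (any(bad))
    stopf("bead %d carries a color outside the declared palette",
          b$index[which(bad)[1]])
  invisible(gs)
}

#' Number of beads in a genome string
#' @param string A `genome_string`.
#' @return Integer bead count.
#' @export
n_beads <- function(string) {
  stopifnot(inherits(string, "genome_string"))
  nrow(string$beads)
}

#' Bead-by-color membership matrix
#'
#' @param string A `genome_string`.
#' @return Integer 0/1 matrix of dimension beads x palette colors.
#' @export
bead_color_matrix <- function(string) {
  stopifnot(inherits(string, "genome_string"))
  pal <- string$palette
  m <- matrix(0L, nrow = n_beads(string), ncol = length(pal),
              dimnames = list(NULL, pal))
  for (k in seq_along(pal)) {
    m[, k] <- vapply(string$beads$colors, function(cc) pal[k] %in% cc,
                     logical(1))
  }
  m
}

#' Indices of binding (colored) beads
#' @param string A `genome_string`.
#' @return 0-based bead indices with a non-empty color set.
#' @export
binding_beads <- function(string) {
  stopifnot(inherits(string, "genome_string"))
  string$beads$index[lengths(string$beads$colors) > 0L]
}

#' @export
print.genome_string <- function(x, ...) {
  nb <- n_beads(x)
  ncol_beads <- sum(lengths(x$beads$colors) > 0L)
  cat(sprintf(
    "<genome_string> %d beads (%d binding), %d bp/bead, %g nm beads\n",
    nb, ncol_beads, x$bp_per_bead, x$bead_diameter_nm))
  cat("palette:", paste(x$palette, collapse = ", "), "\n")
  tab <- colSums(bead_color_matrix(x))
  if (length(tab)) {
    cat("beads per color:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Generate a random wild-type genome string
#'
#' Cognate beads of each color are scattered randomly and independently
#' along the fiber: each bead receives at most one color, color `k`
#' with probability `density[k]`, and no color otherwise.  Per-color
#' bead counts are therefore Binomial(`n_beads`, density).
#'
#' @param n_beads Number of beads (>= 1).
#' @param palette Character vector of color labels.
#' @param density Per-color probability that a bead carries that color;
#'   a scalar is recycled across the palette.  Densities must be
#'   non-negative and sum to at most 1.
#' @param seed Integer seed; the same arguments and seed always return
#'   the identical string.
#' @param bp_per_bead Genomic span of one bead (bp).
#' @param bead_diameter_nm Bead diameter (nm).
#' @param chrom Chromosome name recorded in each bead's genomic span.
#' @return A `genome_string`.
#' @examples
#' gs <- generate_random_string(1000, palette = c("red", "green"),
#'                              density = 0.04, seed = 1)
#' gs
#' @export
generate_random_string <- function(n_beads, palette, density, seed,
                                   bp_per_bead = 3000L,
                                   bead_diameter_nm = 30,
                                   chrom = "sim") {
  if (!is.numeric(n_beads) || length(n_beads) != 1L || n_beads < 1)
    stopf("n_beads must be a single integer >= 1")
  n_beads <- as.integer(n_beads)
  palette <- as.character(palette)
  if (anyDuplicated(palette)) stopf("palette colors must be unique")
  if (length(density) == 1L) density <- rep(density, length(palette))
  if (length(density) != length(palette))
    stopf("density must have length 1 or length(palette)")
  if (any(density < 0)) stopf("densities must be non-negative")
  if (sum(density) > 1 + 1e-12)
    stopf("densities must sum to at most 1 (got %g)", sum(density))

  draw <- with_private_seed(seed, {
    # categorical draw per bead: colors 1..K with prob density, else 0
    u <- runif(n_beads)
    edges <- cumsum(density)
    findInterval(u, c(0, edges), left.open = TRUE)
  })
  colors <- vector("list", n_beads)
  for (i in seq_len(n_beads)) {
    k <- draw[i]
    colors[[i]] <- if (k >= 1 && k <= length(palette)) palette[k]
                   else character(0)
  }
  idx <- seq_len(n_beads) - 1L
  beads <- data.frame(index = idx,
                      chrom = chrom,
                      start = idx * bp_per_bead,
                      end = (idx + 1L) * bp_per_bead,
                      stringsAsFactors = FALSE)
  beads$colors <- colors
  validate_genome_string(
    new_genome_string(beads, bp_per_bead, bead_diameter_nm, palette))
}

#' Introduce an eQTL-style mutation
#'
#' Returns a copy of the string in which the given bead has lost all
#' colors (it becomes non-binding); every other bead is untouched.
#' This emulates a regulatory variant abolishing factor binding at a
#' single cognate site.
#'
#' @param string A `genome_string`.
#' @param bead_index 0-based index of the bead to mutate.
#' @return A new `genome_string`; the input is not modified.
#' @examples
#' gs <- generate_random_string(100, "yellow", 0.1, seed = 1)
#' mut <- apply_mutation(gs, 50L)
#' @export
apply_mutation <- function(string, bead_index) {
  validate_genome_string(string)
  if (!is.numeric(bead_index) || length(bead_index) != 1L ||
      bead_index != round(bead_index))
    stopf("bead_index must be a single integer")
  if (bead_index < 0 || bead_index >= n_beads(string))
    stopf("bead_index %d out of range [0, %d)", bead_index,
          n_beads(string))
  i <- as.integer(bead_index) + 1L
  if (length(string$beads$colors[[i]]) == 0L)
    warnf("bead %d is already non-binding; mutation has no effect",
          bead_index)
  out <- string
  out$beads$colors[[i]] <- character(0)
  out
}

#' A chromatin-state annotation track
#'
#' Half-open genomic intervals labelled with chromatin states (e.g.
#' highly active / weakly active / silent), plus a mapping from state
#' labels to factor colors.  States mapped to `NA` color no beads.
#'
#' @param intervals `data.frame` with columns `chrom`, `start`, `end`,
#'   `state` (0-based half-open coordinates).
#' @param state_to_color Named character vector mapping state labels to
#'   color labels; defaults to the identity mapping over the states
#'   present.
#' @return An object of class `state_track`.
#' @export
state_track <- function(intervals, state_to_color = NULL) {
  req <- c("chrom", "start", "end", "state")
  if (!all(req %in% names(intervals)))
    stopf("intervals must have columns %s", paste(req, collapse = ", "))
  iv <- intervals[req]
  if (any(iv$start < 0) || any(iv$start >= iv$end))
    stopf("intervals must satisfy 0 <= start < end")
  if (is.null(state_to_color)) {
    states <- unique(iv$state)
    state_to_color <- setNames(states, states)
  }
  structure(list(intervals = iv,
                 state_to_color = state_to_color),
            class = "state_track")
}

#' Bin a chromatin-state track onto beads
#'
#' Divides the region into windows of `bp_per_bead` (the last, possibly
#' partial, window is kept) and colors each bead with the color of
#' every state covering at least `threshold` of its window — so a
#' window split 50/50 between an active and a silent state yields a
#' doubly-colored bead at the default threshold.
#'
#' @param track A [state_track()].
#' @param region `list(chrom =, start =, end =)` or a length-3 vector
#'   `c(chrom, start, end)`; 0-based half-open.
#' @param bp_per_bead Window size in bp.
#' @param threshold Minimum fraction of the window a state must cover
#'   to color the bead (default 0.5).
#' @param bead_diameter_nm Bead diameter (nm).
#' @return A `genome_string` whose palette is the set of mapped colors,
#'   in first-appearance order of the mapping.
#' @examples
#' trk <- state_track(data.frame(chrom = "chr1", start = 0, end = 9000,
#'                               state = "active"),
#'                    c(active = "pink"))
#' beads_from_track(trk, list(chrom = "chr1", start = 0, end = 9000),
#'                  bp_per_bead = 3000)
#' @export
beads_from_track <- function(track, region, bp_per_bead = 3000L,
                             threshold = 0.5, bead_diameter_nm = 30) {
  stopifnot(inherits(track, "state_track"))
  if (is.character(region) && length(region) == 3L)
    region <- list(chrom = region[1], start = as.numeric(region[2]),
                   end = as.numeric(region[3]))
  chrom <- region$chrom; rstart <- region$start; rend <- region$end
  if (rend - rstart < bp_per_bead)
    stopf("region length must be at least bp_per_bead")
  if (threshold <= 0 || threshold > 1)
    stopf("threshold must be in (0, 1]")

  starts <- seq(rstart, rend - 1, by = bp_per_bead)
  ends <- pmin(starts + bp_per_bead, rend)
  nb <- length(starts)
  windows <- IRanges::IRanges(start = starts + 1L, end = ends)  # 1-based

  map <- track$state_to_color
  palette <- unique(unname(map[!is.na(map)]))
  colors <- rep(list(character(0)), nb)

  iv <- track$intervals[track$intervals$chrom == chrom, , drop = FALSE]
  if (nrow(iv) > 0L) {
    for (col in palette) {
      states <- names(map)[!is.na(map) & map == col]
      sub <- iv[iv$state %in% states, , drop = FALSE]
      if (nrow(sub) == 0L) next
      ir <- IRanges::reduce(
        IRanges::IRanges(start = sub$start + 1L, end = sub$end))
      ov <- IRanges::findOverlaps(windows, ir)
      if (length(ov) == 0L) next
      wq <- S4Vectors::queryHits(ov)
      inter <- IRanges::pintersect(windows[wq],
                                   ir[S4Vectors::subjectHits(ov)])
      cov <- tapply(IRanges::width(inter), wq, sum)
      widx <- as.integer(names(cov))
      hit <- widx[cov >= threshold * IRanges::width(windows)[widx]]
      for (i in hit) colors[[i]] <- c(colors[[i]], col)
    }
  }
  idx <- seq_len(nb) - 1L
  beads <- data.frame(index = idx, chrom = chrom, start = starts,
                      end = ends, stringsAsFactors = FALSE)
  beads$colors <- colors
  validate_genome_string(
    new_genome_string(beads, bp_per_bead, bead_diameter_nm, palette))
}
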