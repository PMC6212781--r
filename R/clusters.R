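#' Detect factor clusters in a frame
#'
#' Builds the graph on factors whose centre-centre distance is below
#' `cutoff_nm` and returns its connected components.  Every factor
#' belongs to exactly one component; components of size one are
#' singletons, and "clusters" conventionally means components of size
#' two or more.  The default cutoff of 60 nm is two touching 30-nm
#' spheres with tolerance.
#'
#' @param frame A `sim_frame`.
#' @param cutoff_nm Edge cutoff (nm).
#' @return An object of class `cluster_set`: list with `membership`
#'   (component id per factor), `sizes`, `colors` (per factor),
#'   `cutoff_nm` and `frame_time`.
#' @export
detect_clusters <- function(frame, cutoff_nm = 60) {
  stopifnot(inherits(frame, "sim_frame"))
  if (cutoff_nm <= 0) stopf("cutoff_nm must be positive")
  m <- nrow(frame$factor_positions)
  if (m == 0L) {
    return(structure(list(membership = integer(0), sizes = integer(0),
                          colors = character(0), cutoff_nm = cutoff_nm,
                          frame_time = frame$time),
                     class = "cluster_set"))
  }
  adj <- factor_adjacency(frame$factor_positions, cutoff_nm)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  structure(list(membership = as.integer(comp$membership),
                 sizes = as.integer(comp$csize),
                 colors = frame$factor_colors,
                 cutoff_nm = cutoff_nm,
                 frame_time = frame$time),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  nc <- sum(x$sizes >= 2)
  cat(sprintf("<cluster_set> %d factors, %d clusters (size >= 2), cutoff %g nm\n",
              length(x$membership), nc, x$cutoff_nm))
  invisible(x)
}

#' Fraction of factors residing in clusters of a minimum size
#'
#' @param clusters A `cluster_set`.
#' @param min_size Minimum component size to count as clustered.
#' @param subset Optional logical vector selecting factors (e.g. bound
#'   ones); the fraction is computed among the selected factors.
#' @return Fraction in `[0, 1]` (`NaN` if no factor selected).
#' @export
clustered_fraction <- function(clusters, min_size = 2, subset = NULL) {
  stopifnot(inherits(clusters, "cluster_set"))
  in_cluster <- clusters$sizes[clusters$membership] >= min_size
  if (!is.null(subset)) in_cluster <- in_cluster[subset]
  mean(in_cluster)
}

#' Fraction of clusters containing more than one factor color
#'
#' @param clusters A `cluster_set`.
#' @param min_size Minimum component size considered a cluster.
#' @return Fraction of mixed-color clusters (`NaN` if none).
#' @export
mixed_cluster_fraction <- function(clusters, min_size = 2) {
  stopifnot(inherits(clusters, "cluster_set"))
  ids <- which(clusters$sizes >= min_size)
  if (length(ids) == 0L) return(NaN)
  mixed <- vapply(ids, function(id) {
    length(unique(clusters$colors[clusters$membership == id])) > 1L
  }, logical(1))
  mean(mixed)
}

#' Cluster-size distribution over a trajectory
#'
#' Pools component sizes over all recorded frames.  The histogram's
#' total mass per frame equals the factor count (every factor sits in
#' exactly one component).
#'
#' @param trajectory A `trajectory`.
#' @param cutoff_nm Cluster edge cutoff (nm).
#' @return List with `histogram` (named vector: count of components by
#'   size, summed over frames), `mean_size` (mean component size
#'   weighted per factor), `se` (standard error of the per-frame mean),
#'   and `n_frames`.
#' @export
cluster_size_distribution <- function(trajectory, cutoff_nm = 60) {
  stopifnot(inherits(trajectory, "trajectory"))
  if (length(trajectory$frames) == 0L) stopf("trajectory has no frames")
  sizes_all <- integer(0)
  per_frame_mean <- numeric(length(trajectory$frames))
  for (t in seq_along(trajectory$frames)) {
    cl <- detect_clusters(trajectory$frames[[t]], cutoff_nm)
    sizes_all <- c(sizes_all, cl$sizes)
    per_frame_mean[t] <- if (length(cl$membership))
      mean(cl$sizes[cl$membership]) else NaN
  }
  hist <- table(factor(sizes_all, levels = seq_len(max(sizes_all, 1))))
  list(histogram = setNames(as.integer(hist), names(hist)),
       mean_size = mean(per_frame_mean),
       se = stats::sd(per_frame_mean) / sqrt(length(per_frame_mean)),
       n_frames = length(trajectory$frames))
}
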