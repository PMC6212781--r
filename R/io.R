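#' Read a chromatin-state track from a BED-like file
#'
#' Expects at least four tab- or space-separated columns: chrom, start,
#' end, state name (0-based half-open coordinates, the BED convention;
#' strand and further columns are ignored).  Malformed lines are
#' reported with their line number.
#'
#' @param path File path.
#' @param state_to_color Optional named character vector mapping state
#'   labels to factor colors (default: identity).
#' @return A [state_track()].
#' @export
read_state_track <- function(path, state_to_color = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stopf("%s contains no intervals", path)
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    ln <- idx[k]
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(f) < 4)
      stopf("parse error in %s line %d: expected at least 4 columns, got %d",
            path, ln, length(f))
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end))
      stopf("parse error in %s line %d: non-numeric coordinates", path, ln)
    if (start < 0 || start >= end)
      stopf("parse error in %s line %d: need 0 <= start < end", path, ln)
    rows[[k]] <- data.frame(chrom = f[1], start = start, end = end,
                            state = f[4], stringsAsFactors = FALSE)
  }
  state_track(do.call(rbind, rows), state_to_color)
}

#' Write a state track as BED
#' @param track A `state_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_state_track <- function(track, path) {
  stopifnot(inherits(track, "state_track"))
  iv <- track$intervals
  writeLines(sprintf("%s\t%d\t%d\t%s", iv$chrom, as.integer(iv$start),
                     as.integer(iv$end), iv$state), path)
  invisible(path)
}

#' Serialize a genome string as TSV
#'
#' Columns: bead_index, colors (comma-joined, "." if none), chrom,
#' start, end.  Metadata (bp per bead, bead diameter, palette) is kept
#' in `#key=value` header lines so the file round-trips.
#'
#' @param string A `genome_string`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_string <- function(string, path) {
  validate_genome_string(string)
  hdr <- c(sprintf("#bp_per_bead=%d", string$bp_per_bead),
           sprintf("#bead_diameter_nm=%g", string$bead_diameter_nm),
           sprintf("#palette=%s", paste(string$palette, collapse = ",")),
           "bead_index\tcolors\tchrom\tstart\tend")
  cols <- vapply(string$beads$colors, function(cc)
    if (length(cc)) paste(cc, collapse = ",") else ".", character(1))
  body <- sprintf("%d\t%s\t%s\t%d\t%d", string$beads$index, cols,
                  string$beads$chrom, as.integer(string$beads$start),
                  as.integer(string$beads$end))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a genome string written by [write_genome_string()]
#' @param path File path.
#' @return A `genome_string`.
#' @export
read_genome_string <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default = NULL) {
    h <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(h)) sub(paste0("^#", key, "="), "", h[1]) else default
  }
  bp <- as.integer(get_meta("bp_per_bead", "3000"))
  diam <- as.numeric(get_meta("bead_diameter_nm", "30"))
  pal <- get_meta("palette", "")
  palette <- if (nzchar(pal)) strsplit(pal, ",")[[1]] else character(0)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  colors <- lapply(df$colors, function(s)
    if (identical(s, ".")) character(0) else strsplit(s, ",")[[1]])
  beads <- data.frame(index = as.integer(df$bead_index),
                      chrom = as.character(df$chrom),
                      start = df$start, end = df$end,
                      stringsAsFactors = FALSE)
  beads$colors <- colors
  validate_genome_string(new_genome_string(beads, bp, diam, palette))
}

#' Write a contact map as dense TSV with a metadata header
#'
#' @param map A `contact_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path) {
  validate_contact_map(map)
  hdr <- c(sprintf("#capture_radius_nm=%g", map$capture_radius_nm),
           sprintf("#n_observations=%d", map$n_observations),
           sprintf("#diagonal=%s", map$diagonal))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(map$matrix, digits = 12, trim = TRUE,
                     scientific = FALSE),
              con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a contact map written by [write_contact_map()]
#'
#' Fails with an integrity error if the stored matrix is not symmetric.
#'
#' @param path File path.
#' @return A `contact_map`.
#' @export
read_contact_map <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    h <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (!length(h)) stopf("missing header %s in %s", key, path)
    sub(paste0("^#", key, "="), "", h[1])
  }
  mat <- as.matrix(read.table(path, sep = "\t", comment.char = "#"))
  dimnames(mat) <- NULL
  map <- new_contact_map(mat, as.numeric(get_meta("capture_radius_nm")),
                         as.integer(get_meta("n_observations")))
  map$diagonal <- get_meta("diagonal")
  tryCatch(validate_contact_map(map, tol = 1e-9),
           error = function(e)
             stopf("integrity error reading %s: %s", path,
                   conditionMessage(e)))
  map
}

#' Write a trajectory as extended-XYZ frames
#'
#' One block per frame: particle count, a comment line with the time,
#' then one line per particle: type (`bead`/`factor`), color (`.` for
#' colorless beads), competence flag (1/0; beads carry `.`), x, y, z in
#' nm.
#'
#' @param trajectory A `trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  bcol <- vapply(trajectory$string$beads$colors, function(cc)
    if (length(cc)) paste(cc, collapse = ",") else ".", character(1))
  for (fr in trajectory$frames) {
    n <- nrow(fr$bead_positions); m <- nrow(fr$factor_positions)
    writeLines(as.character(n + m), con)
    writeLines(sprintf("time=%g tauB", fr$time), con)
    writeLines(sprintf("bead\t%s\t.\t%.4f\t%.4f\t%.4f", bcol,
                       fr$bead_positions[, 1], fr$bead_positions[, 2],
                       fr$bead_positions[, 3]), con)
    if (m > 0)
      writeLines(sprintf("factor\t%s\t%d\t%.4f\t%.4f\t%.4f",
                         fr$factor_colors,
                         as.integer(fr$binding_competent),
                         fr$factor_positions[, 1],
                         fr$factor_positions[, 2],
                         fr$factor_positions[, 3]), con)
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory_xyz()]
#'
#' Restores frames only (positions, colors, competence); the string,
#' species and configuration must be re-supplied by the caller if
#' needed.
#'
#' @param path File path.
#' @return List of `sim_frame`s.
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    np <- as.integer(lines[i])
    if (is.na(np)) stopf("parse error in %s line %d: expected particle count",
                         path, i)
    tm <- as.numeric(sub("^time=([-0-9.eE+]+).*$", "\\1", lines[i + 1]))
    block <- lines[(i + 2):(i + 1 + np)]
    f <- strsplit(block, "\t")
    type <- vapply(f, `[`, character(1), 1)
    col <- vapply(f, `[`, character(1), 2)
    compf <- vapply(f, `[`, character(1), 3)
    xyz <- matrix(as.numeric(unlist(lapply(f, `[`, 4:6))),
                  ncol = 3, byrow = TRUE)
    isb <- type == "bead"
    frames[[length(frames) + 1L]] <- new_frame(
      tm, xyz[isb, , drop = FALSE], xyz[!isb, , drop = FALSE],
      col[!isb], compf[!isb] == "1")
    i <- i + 2L + np
  }
  frames
}

#' Write a reproducibility manifest
#'
#' Records tool version, master seed, configuration hash, per-run
#' seeds, digests of the declared inputs/outputs and a timestamp as
#' JSON.  Re-running with the manifest's seeds and configuration
#' reproduces all deterministic outputs bit for bit.
#'
#' @param path Output path (JSON).
#' @param master_seed Master seed of the invocation.
#' @param config_hash Configuration hash string.
#' @param seeds Per-run seeds.
#' @param files Character vector of input/output file paths to digest.
#' @param extra Named list of further fields to record.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, master_seed = NA, config_hash = NA,
                           seeds = integer(0), files = character(0),
                           extra = list()) {
  files <- files[file.exists(files)]
  manifest <- c(list(
    tool = "bridgesim",
    version = as.character(utils::packageVersion("bridgesim")),
    master_seed = master_seed,
    config_hash = config_hash,
    seeds = seeds,
    file_digests = as.list(setNames(unname(tools::md5sum(files)),
                                    basename(files))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Read a simulation run configuration file
#'
#' Flat YAML with three optional sections: `config` (fields of
#' [sim_config()]), `field` (fields of [force_field()]) and `species`
#' (list of [factor_species()] argument sets).
#'
#' @param path YAML file path.
#' @return List with elements `config`, `field`, `species`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(sim_config, y$config %||% list(n_steps = 10000L))
  fld <- do.call(force_field, y$field %||% list())
  sps <- lapply(y$species %||% list(), function(s)
    do.call(factor_species, s))
  list(config = cfg, field = fld, species = sps)
}
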