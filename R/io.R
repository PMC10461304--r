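# Readers and writers. Internal units are nm / ps throughout; PDB
# coordinates (Angstrom) are converted on read. GRO is written with the
# fixed-width velocity columns; the extended-XYZ dialect carries
# `time=<ps> box="lx ly lz"` on the comment line followed by
# `label x y z vx vy vz` rows.

# default per-label mass table: generic CG beads
default_mass_table <- function() c(BB = 72, CG = 72, CA = 72, W = 72)

#' Read a structure file
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gro"`, `"pdb"` or `"xyz"`.
#' @param mass_table named numeric vector mapping atom labels to masses
#'   (amu); unmatched labels fall back to `default_mass`, and when that is
#'   `NA` an unknown label is an error.
#' @param default_mass mass for labels missing from `mass_table`
#'   (default 72 amu, the generic CG bead; set `NA` to make unknown labels
#'   fatal).
#' @return a [bead_structure()].
#' @export
read_structure <- function(path, format = c("auto", "gro", "pdb", "xyz"),
                           mass_table = default_mass_table(),
                           default_mass = 72) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  parsed <- switch(format,
                   gro = parse_gro(path, single = TRUE)[[1L]],
                   pdb = parse_pdb(path),
                   xyz = parse_extxyz(path, single = TRUE)[[1L]],
                   stop("unsupported structure format: ", format, call. = FALSE))
  masses <- lookup_masses(parsed$labels, mass_table, default_mass)
  bead_structure(parsed$positions, masses = masses, labels = parsed$labels)
}

#' Read a trajectory file
#'
#' Multi-frame GRO (concatenated blocks) or extended-XYZ. Velocities are
#' parsed when present; otherwise `has_velocities` is `FALSE` and
#' [finite_difference_velocities()] can supply them.
#'
#' @inheritParams read_structure
#' @param format `"auto"`, `"gro"` or `"extxyz"`.
#' @return a [bead_trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "gro", "extxyz"),
                            mass_table = default_mass_table(),
                            default_mass = 72) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- guess_format(path)
    if (format == "xyz") format <- "extxyz"
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  blocks <- switch(format,
                   gro = parse_gro(path),
                   extxyz = parse_extxyz(path),
                   stop("unsupported trajectory format: ", format, call. = FALSE))
  counts <- vapply(blocks, function(b) nrow(b$positions), integer(1L))
  if (length(unique(counts)) != 1L)
    stop("inconsistent bead count across frames", call. = FALSE)
  masses <- lookup_masses(blocks[[1L]]$labels, mass_table, default_mass)
  st <- bead_structure(blocks[[1L]]$positions, masses = masses,
                       labels = blocks[[1L]]$labels)
  times <- vapply(blocks, function(b) b$time %||% NA_real_, numeric(1L))
  if (any(is.na(times))) {
    if (all(is.na(times))) times <- seq_along(blocks) - 1
    else stop("missing time metadata on some frames", call. = FALSE)
  }
  frames <- Map(function(b, tt) traj_frame(tt, b$positions, b$velocities),
                blocks, times)
  dts <- diff(times)
  dt <- if (length(dts) && max(dts) - min(dts) < 1e-9 * max(mean(dts), 1e-300))
    mean(dts) else NULL
  bead_trajectory(st, frames, dt = dt)
}

#' Write a trajectory (or structure) as GRO
#'
#' Fixed-width GRO with velocity columns when present; frame time goes into
#' the title line (`t= <ps>`).
#'
#' @param trajectory a [bead_trajectory()].
#' @param path output path.
#' @param box length-3 box vector in nm written on the closing line.
#' @return the path, invisibly.
#' @export
write_trajectory_gro <- function(trajectory, path, box = c(10, 10, 10)) {
  stopifnot(inherits(trajectory, "bead_trajectory"))
  st <- trajectory$structure
  labels <- st$labels %||% rep("BB", st$n)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in trajectory$frames) {
    writeLines(sprintf("eckrot frame t= %.6f", f$time), con)
    writeLines(sprintf("%5d", st$n), con)
    for (a in seq_len(st$n)) {
      base <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                      a %% 100000L, "MOL", substr(labels[a], 1L, 5L),
                      a %% 100000L,
                      f$positions[a, 1L], f$positions[a, 2L], f$positions[a, 3L])
      if (!is.null(f$velocities))
        base <- paste0(base, sprintf("%8.4f%8.4f%8.4f",
                                     f$velocities[a, 1L], f$velocities[a, 2L],
                                     f$velocities[a, 3L]))
      writeLines(base, con)
    }
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1L], box[2L], box[3L]), con)
  }
  invisible(path)
}

#' Write a trajectory as extended XYZ
#'
#' @inheritParams write_trajectory_gro
#' @export
write_trajectory_extxyz <- function(trajectory, path, box = c(10, 10, 10)) {
  stopifnot(inherits(trajectory, "bead_trajectory"))
  st <- trajectory$structure
  labels <- st$labels %||% rep("BB", st$n)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in trajectory$frames) {
    writeLines(sprintf("%d", st$n), con)
    writeLines(sprintf('time=%.9g box="%g %g %g"', f$time,
                       box[1L], box[2L], box[3L]), con)
    v <- f$velocities
    for (a in seq_len(st$n)) {
      if (is.null(v)) {
        writeLines(sprintf("%-5s %15.9f %15.9f %15.9f", labels[a],
                           f$positions[a, 1L], f$positions[a, 2L],
                           f$positions[a, 3L]), con)
      } else {
        writeLines(sprintf("%-5s %15.9f %15.9f %15.9f %15.9f %15.9f %15.9f",
                           labels[a], f$positions[a, 1L], f$positions[a, 2L],
                           f$positions[a, 3L], v[a, 1L], v[a, 2L], v[a, 3L]),
                   con)
      }
    }
  }
  invisible(path)
}

#' Write the ground-truth motion sidecar
#'
#' Serializes a trajectory's `motion` record (the generator's ground truth)
#' as JSON next to the trajectory file.
#'
#' @param trajectory a [bead_trajectory()].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_motion_sidecar <- function(trajectory, path) {
  jsonlite::write_json(trajectory$motion %||% list(), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a flat key-value config file
#'
#' One `key = value` per line; `#` comments; numeric scalars and
#' comma-separated numeric vectors are converted, everything else stays
#' character.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (no '='): ", ln, call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (length(parts) && !any(is.na(nums))) nums else val
  }
  out
}

#' Write a data.frame as a schema-versioned CSV
#'
#' Plain CSV preceded by a `# eckrot csv v1` comment line; read back with
#' `read.csv(..., comment.char = "#")`.
#'
#' @param df data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_csv_versioned <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# eckrot csv v1", con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# ---- parsers ----

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, gro = "gro", pdb = "pdb", xyz = "xyz", extxyz = "xyz",
         stop("cannot guess format from extension: ", path, call. = FALSE))
}

parse_gro <- function(path, single = FALSE) {
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    if (i + 1L > length(lines)) stop("truncated GRO header at line ", i, call. = FALSE)
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 1L)
      stop("bad atom count at line ", i + 1L, call. = FALSE)
    if (i + 1L + nat + 1L > length(lines))
      stop("truncated GRO frame starting at line ", i,
           " (expected ", nat, " atoms)", call. = FALSE)
    atoms <- lines[(i + 2L):(i + 1L + nat)]
    labels <- trimws(substr(atoms, 11L, 15L))
    nums <- function(from, to) {
      v <- suppressWarnings(as.numeric(trimws(substr(atoms, from, to))))
      if (any(is.na(v)))
        stop("malformed GRO atom record near line ",
             i + 1L + which(is.na(v))[1L], call. = FALSE)
      v
    }
    pos <- cbind(nums(21L, 28L), nums(29L, 36L), nums(37L, 44L))
    vel <- NULL
    if (all(nchar(atoms) >= 68L)) {
      vel <- cbind(nums(45L, 52L), nums(53L, 60L), nums(61L, 68L))
    }
    tm <- NA_real_
    tmatch <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(tmatch)) tm <- as.numeric(sub("t=\\s*", "", tmatch))
    blocks[[length(blocks) + 1L]] <-
      list(time = if (is.na(tm)) NULL else tm, positions = pos,
           velocities = vel, labels = labels)
    i <- i + 1L + nat + 2L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
    if (single) break
  }
  if (!length(blocks)) stop("empty GRO file: ", path, call. = FALSE)
  blocks
}

parse_extxyz <- function(path, single = FALSE) {
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      stop("bad atom count at line ", i, call. = FALSE)
    if (i + 1L + nat > length(lines))
      stop("truncated XYZ frame starting at line ", i, call. = FALSE)
    comment <- lines[i + 1L]
    tm <- NA_real_
    tmatch <- regmatches(comment, regexpr("time=\\s*[-0-9.eE+]+", comment))
    if (length(tmatch)) tm <- as.numeric(sub("time=\\s*", "", tmatch))
    atoms <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(atoms), "\\s+")
    nt <- lengths(toks)
    if (any(nt < 4L))
      stop("malformed XYZ atom record near line ",
           i + 1L + which(nt < 4L)[1L], call. = FALSE)
    labels <- vapply(toks, `[[`, character(1L), 1L)
    getcol <- function(j) {
      v <- suppressWarnings(as.numeric(vapply(toks, `[[`, character(1L), j)))
      if (any(is.na(v)))
        stop("malformed XYZ numeric field near line ",
             i + 1L + which(is.na(v))[1L], call. = FALSE)
      v
    }
    pos <- cbind(getcol(2L), getcol(3L), getcol(4L))
    vel <- if (all(nt >= 7L)) cbind(getcol(5L), getcol(6L), getcol(7L)) else NULL
    blocks[[length(blocks) + 1L]] <-
      list(time = if (is.na(tm)) NULL else tm, positions = pos,
           velocities = vel, labels = labels)
    i <- i + 2L + nat
    if (single) break
  }
  if (!length(blocks)) stop("empty XYZ file: ", path, call. = FALSE)
  blocks
}

parse_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  atoms <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(atoms)) stop("no ATOM records in ", path, call. = FALSE)
  labels <- trimws(substr(atoms, 13L, 16L))
  num <- function(from, to) {
    v <- suppressWarnings(as.numeric(trimws(substr(atoms, from, to))))
    if (any(is.na(v)))
      stop("malformed PDB coordinate in ", path, " (record ",
           which(is.na(v))[1L], ")", call. = FALSE)
    v
  }
  # Angstrom -> nm
  pos <- cbind(num(31L, 38L), num(39L, 46L), num(47L, 54L)) / 10
  list(time = NULL, positions = pos, velocities = NULL, labels = labels)
}

lookup_masses <- function(labels, mass_table, default_mass) {
  m <- unname(mass_table[labels])
  missing <- is.na(m)
  if (any(missing)) {
    if (is.na(default_mass))
      stop("unknown atom label(s) without mass override: ",
           paste(unique(labels[missing]), collapse = ", "), call. = FALSE)
    m[missing] <- default_mass
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
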