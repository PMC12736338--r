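# File formats: multi-frame XYZ (with a sidecar molecule map), per-snapshot
# PDB (through bio3d), GRO reading, and the CSV/JSON artifact formats of the
# pipeline. XYZ and GRO are simple enough to read directly; PDB records go
# through bio3d's fixed-column reader/writer.

#' Write an ensemble as multi-frame XYZ
#'
#' One frame per snapshot; the comment line records the snapshot id. Element
#' symbols only — molecule grouping is written to a sidecar CSV map by
#' [write_molecule_map()] if needed.
#'
#' @param snapshots ensemble tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(snapshots, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in split_snapshots(snapshots)) {
    writeLines(as.character(nrow(fr)), con)
    writeLines(sprintf("snapshot=%d", unique(fr$snapshot_id)), con)
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f",
                       fr$element, fr$x, fr$y, fr$z), con)
  }
  invisible(path)
}

#' Sidecar molecule map for XYZ ensembles
#'
#' XYZ carries no residue information, so the per-atom grouping (`atom`,
#' `role`, `molecule_id`, `name`) of the first frame is stored as CSV.
#'
#' @param snapshots ensemble tibble.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_molecule_map <- function(snapshots, path) {
  fr <- split_snapshots(snapshots)[[1]]
  utils::write.csv(fr[, c("atom", "role", "molecule_id", "name")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a multi-frame XYZ ensemble
#'
#' @param path XYZ file written by [write_xyz()] (or any plain multi-frame
#'   XYZ; frames are numbered in order when no `snapshot=` comment is found).
#' @param molecule_map optional path to a sidecar CSV from
#'   [write_molecule_map()]; without it every atom becomes its own molecule
#'   with role `"solute"`.
#' @return an ensemble tibble.
#' @export
read_xyz <- function(path, molecule_map = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  fid <- 0
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) fq_abort(sprintf("bad XYZ atom count at line %d.", i),
                           "fqembed_bad_file")
    fid <- fid + 1
    comment <- lines[i + 1]
    id <- if (grepl("snapshot=", comment)) {
      as.integer(sub(".*snapshot=([0-9]+).*", "\\1", comment))
    } else fid
    rows <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(rows), "[[:space:]]+")
    frames[[fid]] <- tibble::tibble(
      snapshot_id = id,
      atom = seq_len(n),
      element = vapply(parts, `[`, "", 1),
      x = as.numeric(vapply(parts, `[`, "", 2)),
      y = as.numeric(vapply(parts, `[`, "", 3)),
      z = as.numeric(vapply(parts, `[`, "", 4))
    )
    i <- i + 2 + n
  }
  out <- dplyr::bind_rows(frames)
  if (!is.null(molecule_map)) {
    mp <- utils::read.csv(molecule_map, stringsAsFactors = FALSE)
    out <- dplyr::left_join(out, mp, by = "atom")
  } else {
    out$role <- "solute"
    out$molecule_id <- out$atom
    out$name <- out$element
  }
  out[, c("snapshot_id", "atom", "role", "molecule_id",
          "element", "name", "x", "y", "z")]
}

#' Write one snapshot as PDB
#'
#' Waters become `SOL` residues numbered by molecule id; the solute is `LIG`
#' residue 0. Written through bio3d.
#'
#' @param snapshot single-snapshot tibble.
#' @param path output PDB file.
#' @return `path`, invisibly.
#' @export
write_pdb_snapshot <- function(snapshot, path) {
  xyz <- as.numeric(t(as.matrix(snapshot[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = snapshot$molecule_id,
    resid = ifelse(snapshot$role == "water", "SOL", "LIG"),
    elety = snapshot$name,
    elesy = snapshot$element,
    chain = ifelse(snapshot$role == "water", "W", "A")
  )
  invisible(path)
}

#' Read a PDB snapshot
#'
#' Molecule grouping is taken from the residue numbering; residues named
#' `SOL`/`HOH`/`WAT`/`TIP3` are classified as water.
#'
#' @param path PDB file.
#' @param snapshot_id id to assign to the frame.
#' @return a single-snapshot tibble.
#' @export
read_pdb_snapshot <- function(path, snapshot_id = 1L) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  water_res <- c("SOL", "HOH", "WAT", "TIP3")
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(trimws(at$elety), 1, 1)
  }
  tibble::tibble(
    snapshot_id = as.integer(snapshot_id),
    atom = seq_len(nrow(at)),
    role = ifelse(at$resid %in% water_res, "water", "solute"),
    molecule_id = at$resno,
    element = trimws(elem),
    name = trimws(at$elety),
    x = at$x, y = at$y, z = at$z
  )
}

#' Read a GROMACS GRO frame
#'
#' Fixed-column reader for single-frame `.gro` files. Coordinates are
#' converted from nm to Angstrom; molecule grouping comes from the residue
#' number, and residues named like water (`SOL`, `HOH`, `WAT`, `TIP3`) get
#' role `"water"`.
#'
#' @param path GRO file.
#' @param snapshot_id id to assign to the frame.
#' @return a single-snapshot tibble (the box vector, in Angstrom, is stored
#'   in attribute `box`).
#' @export
read_gro <- function(path, snapshot_id = 1L) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  rows <- lines[3:(2 + n)]
  resno <- as.integer(substr(rows, 1, 5))
  resnm <- trimws(substr(rows, 6, 10))
  atomnm <- trimws(substr(rows, 11, 15))
  x <- as.numeric(substr(rows, 21, 28)) * 10
  y <- as.numeric(substr(rows, 29, 36)) * 10
  z <- as.numeric(substr(rows, 37, 44)) * 10
  water_res <- c("SOL", "HOH", "WAT", "TIP3")
  out <- tibble::tibble(
    snapshot_id = as.integer(snapshot_id),
    atom = seq_len(n),
    role = ifelse(toupper(resnm) %in% water_res, "water", "solute"),
    molecule_id = resno,
    element = substr(atomnm, 1, 1),
    name = atomnm,
    x = x, y = y, z = z
  )
  box_line <- trimws(lines[3 + n])
  if (!is.na(box_line) && nzchar(box_line)) {
    attr(out, "box") <- as.numeric(strsplit(box_line, "[[:space:]]+")[[1]]) * 10
  }
  out
}

# --- pipeline artifact formats ----------------------------------------------

#' Read/write stick spectra as CSV
#'
#' Canonical stick format: `snapshot_id`, `state`, `energy_ev`, `strength`
#' (plus any extra columns present, e.g. the projected field).
#'
#' @param sticks stick tibble.
#' @param path CSV path.
#' @return `write_sticks()` returns `path` invisibly; `read_sticks()` the
#'   tibble.
#' @export
write_sticks <- function(sticks, path) {
  utils::write.csv(sticks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sticks
#' @export
read_sticks <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read/write spectrum curves as two-column CSV
#'
#' @param curve a `spectrum_curve`.
#' @param path CSV path.
#' @return `write_curve()` returns `path` invisibly; `read_curve()` the
#'   `spectrum_curve` (FWHM and snapshot count restored from header comments
#'   are not attempted — they are re-attached by the caller when needed).
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  new_spectrum_curve(df$energy_ev, df$intensity, NA_real_, NA_integer_)
}

#' Write an embedding solution as CSV
#'
#' Columns: `site`, `q`, `mux`, `muy`, `muz`, `molecule_id`.
#'
#' @param solution an `embedding_solution`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_solution <- function(solution, path) {
  utils::write.csv(
    as.data.frame(solution$sites[, c("site", "q", "mux", "muy", "muz",
                                     "molecule_id")]),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_solution
#' @export
read_solution <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
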