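# Core containers: topology, trajectory, conformer. Coordinates are Angstrom
# throughout; atom indices are 1-based row numbers of the atoms tibble, and
# are converted to file serials only at the I/O boundary.

#' Build a molecular topology
#'
#' A topology holds an atoms table, an undirected bond list and a ligand
#' selection. It is the static half of a trajectory; per-frame coordinates
#' live in the trajectory object (the atoms table carries the first frame).
#'
#' @param atoms tibble with columns `name`, `element`, `resname`, `resnum`,
#'   `chain`, `x`, `y`, `z`, and optionally `is_ligand` (logical) and
#'   `formal_charge` (integer).
#' @param bonds tibble/data.frame with columns `i`, `j` (1-based atom row
#'   indices), or NULL for no bond records.
#' @return object of class `topology`.
#' @export
topology <- function(atoms, bonds = NULL) {
  atoms <- as_tibble(atoms)
  req <- c("name", "element", "resname", "resnum", "chain", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atoms table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("empty structure")
  if (!"is_ligand" %in% names(atoms)) atoms$is_ligand <- FALSE
  if (!"formal_charge" %in% names(atoms)) atoms$formal_charge <- 0L
  atoms$element <- toupper(atoms$element)
  atoms$formal_charge <- as.integer(atoms$formal_charge)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("non-finite coordinates in atoms table")
  }
  if (is.null(bonds)) {
    bonds <- tibble(i = integer(), j = integer())
  } else {
    bonds <- as_tibble(bonds)[, c("i", "j")]
    if (nrow(bonds) > 0) {
      if (any(bonds$i < 1 | bonds$i > nrow(atoms) |
              bonds$j < 1 | bonds$j > nrow(atoms))) {
        abort("bond endpoint out of range")
      }
      if (any(bonds$i == bonds$j)) abort("self-bond not allowed")
      # canonical unordered pairs, no duplicates
      lo <- pmin(bonds$i, bonds$j)
      hi <- pmax(bonds$i, bonds$j)
      bonds <- distinct(tibble(i = as.integer(lo), j = as.integer(hi)))
      bonds <- arrange(bonds, .data$i, .data$j)
    }
  }
  structure(list(atoms = atoms, bonds = bonds), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("<topology> ", nrow(x$atoms), " atoms (",
      sum(x$atoms$is_ligand), " ligand), ",
      nrow(x$bonds), " bonds, ",
      dplyr::n_distinct(paste(x$atoms$chain, x$atoms$resnum)),
      " residues\n", sep = "")
  invisible(x)
}

#' Coordinates of a topology as a matrix
#' @param topology a `topology`.
#' @return n x 3 numeric matrix.
#' @export
topology_coords <- function(topology) {
  m <- as.matrix(topology$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Ligand atom indices of a topology
#' @param topology a `topology`.
#' @return integer vector of atom row indices.
#' @export
ligand_indices <- function(topology) {
  which(topology$atoms$is_ligand)
}

#' Construct a trajectory from a topology and a coordinate array
#'
#' @param topology a `topology`.
#' @param coords numeric array `n_atoms x 3 x n_frames`, Angstrom.
#' @param frame_spacing time between saved frames, picoseconds
#'   (informational).
#' @return object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, coords, frame_spacing = 10) {
  stopifnot(inherits(topology, "topology"))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    abort("coords must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[1] != nrow(topology$atoms)) {
    abort("coords atom count does not match topology")
  }
  if (dim(coords)[3] < 1) abort("trajectory needs at least one frame")
  structure(list(topology = topology, coords = coords,
                 frame_spacing = frame_spacing),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("<md_trajectory> ", n_frames(x), " frames x ",
      nrow(x$topology$atoms), " atoms, saved every ",
      x$frame_spacing, " ps\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame's coordinates
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return n x 3 matrix.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  traj$coords[, , i, drop = TRUE]
}

#' Frames saved by an MD run
#'
#' Number of frames a simulation writes when coordinates are saved after
#' every `save_interval`, excluding the t = 0 structure: a 150 ns run
#' saved every 10 ps yields 15,000 frames. Both arguments must be in the
#' same time unit and the interval must divide the length exactly.
#'
#' @param sim_length total simulated time.
#' @param save_interval saving interval, same unit.
#' @return integer frame count.
#' @examples
#' expected_frame_count(150000, 10) # 150 ns saved every 10 ps
#' @export
expected_frame_count <- function(sim_length, save_interval) {
  if (save_interval <= 0) abort("save_interval must be positive")
  ratio <- sim_length / save_interval
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort("save_interval does not divide sim_length exactly")
  }
  as.integer(round(ratio))
}

#' Infer covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below 1.3 times the sum of
#' their covalent radii. Only used on request: PDB CONECT records are
#' unreliable and SDF bond blocks are authoritative.
#'
#' @param atoms atoms tibble (see [topology()]).
#' @return bonds tibble with columns `i`, `j`.
#' @export
infer_bonds <- function(atoms) {
  n <- nrow(atoms)
  if (n < 2) return(tibble(i = integer(), j = integer()))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- covalent_radius(atoms$element)
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(r, r, `+`) * 1.3
  hit <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  # guard against spurious ultra-short contacts
  keep <- d[hit] > 0.4
  tibble(i = as.integer(hit[keep, 1]), j = as.integer(hit[keep, 2]))
}

# ---- PDB I/O ---------------------------------------------------------------

.parse_pdb_atom_line <- function(line, lineno) {
  n <- nchar(line)
  if (n < 54) {
    abort(paste0("malformed ATOM/HETATM record at line ", lineno,
                 ": fewer than 54 columns"))
  }
  coords <- suppressWarnings(as.numeric(c(
    substr(line, 31, 38), substr(line, 39, 46), substr(line, 47, 54)
  )))
  if (any(is.na(coords))) {
    abort(paste0("malformed coordinates at line ", lineno))
  }
  name <- trimws(substr(line, 13, 16))
  element <- if (n >= 78) trimws(substr(line, 77, 78)) else ""
  if (element == "") {
    # derive from the atom name: strip digits, handle leading digit (e.g. 1HB)
    stripped <- gsub("[0-9']", "", name)
    element <- toupper(substr(stripped, 1, 1))
    two <- toupper(substr(stripped, 1, 2))
    if (two %in% c("CL", "BR", "FE", "ZN", "MG")) element <- two
  }
  resnum <- suppressWarnings(as.integer(trimws(substr(line, 23, 26))))
  if (is.na(resnum)) {
    abort(paste0("malformed residue number at line ", lineno))
  }
  list(
    record = trimws(substr(line, 1, 6)),
    name = name,
    resname = trimws(substr(line, 18, 20)),
    chain = substr(line, 22, 22),
    resnum = resnum,
    x = coords[1], y = coords[2], z = coords[3],
    element = toupper(element)
  )
}

#' Read a protein/ligand structure from a PDB file
#'
#' Parses ATOM and HETATM records under fixed-column PDB rules; only the
#' first MODEL of a multi-model file is read (use [read_trajectory()] for
#' the rest). HETATM atoms (excluding waters) form the ligand selection.
#'
#' @param path PDB file.
#' @param bonds_from_distance also infer covalent bonds by the distance
#'   rule (default FALSE).
#' @return a `topology` whose atoms table carries the first-frame
#'   coordinates.
#' @export
read_structure <- function(path, bonds_from_distance = FALSE) {
  lines <- readLines(path, warn = FALSE)
  first_end <- which(substr(lines, 1, 6) %in% c("ENDMDL"))
  if (length(first_end) > 0) lines_first <- lines[seq_len(first_end[1])]
  else lines_first <- lines
  sel <- which(substr(lines_first, 1, 6) %in% c("ATOM  ", "HETATM") |
                 substr(lines_first, 1, 4) == "ATOM")
  if (length(sel) == 0) abort("empty structure: no ATOM/HETATM records")
  parsed <- map(sel, function(i) .parse_pdb_atom_line(lines_first[i], i))
  atoms <- tibble(
    name = map_chr(parsed, "name"),
    element = map_chr(parsed, "element"),
    resname = map_chr(parsed, "resname"),
    resnum = map_int(parsed, "resnum"),
    chain = map_chr(parsed, "chain"),
    x = map_dbl(parsed, "x"),
    y = map_dbl(parsed, "y"),
    z = map_dbl(parsed, "z"),
    is_ligand = map_chr(parsed, "record") == "HETATM" &
      !map_chr(parsed, "resname") %in% c("HOH", "WAT", "SOL")
  )
  top <- topology(atoms)
  if (bonds_from_distance) top$bonds <- infer_bonds(top$atoms)
  top
}

#' Write a topology (single frame) as PDB
#'
#' @param topology a `topology`.
#' @param path output file.
#' @param coords optional n x 3 matrix overriding the atoms table
#'   coordinates.
#' @return `path`, invisibly.
#' @export
write_structure <- function(topology, path, coords = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.pdb_atom_lines(topology, coords), con)
  writeLines("END", con)
  invisible(path)
}

.pdb_atom_lines <- function(topology, coords = NULL) {
  at <- topology$atoms
  if (!is.null(coords)) {
    at$x <- coords[, 1]; at$y <- coords[, 2]; at$z <- coords[, 3]
  }
  record <- ifelse(at$is_ligand, "HETATM", "ATOM  ")
  # PDB name column: element right-aligned into cols 13-14 for short names
  name_fmt <- ifelse(nchar(at$name) >= 4, substr(at$name, 1, 4),
                     sprintf(" %-3s", at$name))
  sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, seq_len(nrow(at)) %% 100000, name_fmt, "",
          substr(at$resname, 1, 3), at$chain, at$resnum, "",
          at$x, at$y, at$z, 1.0, 0.0, at$element)
}

#' Read a multi-model PDB trajectory
#'
#' Every MODEL block must contain exactly one coordinate per topology
#' atom, in topology order.
#'
#' @param path multi-model PDB file.
#' @param topology the `topology` the frames belong to.
#' @param frame_spacing time between frames, ps (informational).
#' @return an `md_trajectory` with one frame per MODEL (a file with no
#'   MODEL records is a single frame).
#' @export
read_trajectory <- function(path, topology, frame_spacing = 10) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") | substr(lines, 1, 4) == "ATOM"
  model_starts <- which(substr(lines, 1, 5) == "MODEL")
  n_atoms <- nrow(topology$atoms)
  if (length(model_starts) == 0) {
    model_blocks <- list(which(is_atom))
  } else {
    bounds <- c(model_starts, length(lines) + 1L)
    model_blocks <- map(seq_along(model_starts), function(k) {
      idx <- seq(bounds[k], bounds[k + 1] - 1L)
      idx[is_atom[idx]]
    })
  }
  n_fr <- length(model_blocks)
  coords <- array(NA_real_, dim = c(n_atoms, 3, n_fr))
  for (k in seq_len(n_fr)) {
    idx <- model_blocks[[k]]
    if (length(idx) != n_atoms) {
      abort(paste0("model ", k, " has ", length(idx),
                   " atoms; topology expects ", n_atoms))
    }
    xs <- suppressWarnings(as.numeric(substr(lines[idx], 31, 38)))
    ys <- suppressWarnings(as.numeric(substr(lines[idx], 39, 46)))
    zs <- suppressWarnings(as.numeric(substr(lines[idx], 47, 54)))
    if (any(is.na(xs) | is.na(ys) | is.na(zs))) {
      abort(paste0("malformed coordinates in model ", k))
    }
    coords[, , k] <- cbind(xs, ys, zs)
  }
  md_trajectory(topology, coords, frame_spacing = frame_spacing)
}

#' Write a trajectory as multi-model PDB
#'
#' @param traj an `md_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL %8d", k), con)
    writeLines(.pdb_atom_lines(traj$topology, frame_coords(traj, k)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
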