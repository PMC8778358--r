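# SDF V2000 I/O for conformers and docking poses. The SDF bond block is
# authoritative (never re-inferred).

#' Construct a conformer record
#'
#' @param name compound/conformer identifier.
#' @param atoms atoms tibble (columns `element`, `x`, `y`, `z`; `name`,
#'   `resname`, `resnum`, `chain` are filled with ligand defaults when
#'   absent).
#' @param bonds bonds tibble (`i`, `j`), 1-based.
#' @param feature_points optional pre-annotated pharmacophore feature
#'   points: tibble with `kind` (HBA/HBD/Aro/Hyd), `x`, `y`, `z`.
#' @param fields named character vector of SDF data fields.
#' @return object of class `conformer`.
#' @export
conformer <- function(name, atoms, bonds = NULL, feature_points = NULL,
                      fields = character()) {
  atoms <- as_tibble(atoms)
  if (!"name" %in% names(atoms)) {
    atoms$name <- paste0(atoms$element, seq_len(nrow(atoms)))
  }
  if (!"resname" %in% names(atoms)) atoms$resname <- "LIG"
  if (!"resnum" %in% names(atoms)) atoms$resnum <- 1L
  if (!"chain" %in% names(atoms)) atoms$chain <- "X"
  atoms$is_ligand <- TRUE
  if (!"formal_charge" %in% names(atoms)) atoms$formal_charge <- 0L
  if (!is.null(feature_points)) {
    feature_points <- as_tibble(feature_points)
    bad <- setdiff(unique(feature_points$kind), c("HBA", "HBD", "Aro", "Hyd"))
    if (length(bad) > 0) {
      abort(paste0("unknown feature kind(s): ", paste(bad, collapse = ", ")))
    }
    if (!all(is.finite(as.matrix(feature_points[, c("x", "y", "z")])))) {
      abort("non-finite feature point coordinates")
    }
  }
  top <- topology(atoms, bonds)
  structure(list(name = name, atoms = top$atoms, bonds = top$bonds,
                 feature_points = feature_points, fields = fields),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat("<conformer> ", x$name, ": ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds",
      if (!is.null(x$feature_points))
        paste0(", ", nrow(x$feature_points), " feature points"),
      "\n", sep = "")
  invisible(x)
}

conformer_coords <- function(conf) as.matrix(conf$atoms[, c("x", "y", "z")])

#' Read an SDF (V2000) file into a list of conformers
#'
#' Multi-record files are supported; data fields (`> <tag>` blocks) are
#' kept. `M CHG` lines populate formal charges.
#'
#' @param path SDF file.
#' @return list of `conformer` objects.
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # split on $$$$ delimiters
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0) ends <- length(lines)
  starts <- c(1L, head(ends, -1) + 1L)
  records <- map(seq_along(ends), function(k) {
    block <- lines[starts[k]:ends[k]]
    if (all(trimws(block) %in% c("", "$$$$"))) return(NULL)
    .parse_sdf_record(block, starts[k])
  })
  purrr::compact(records)
}

.parse_sdf_record <- function(block, offset) {
  if (length(block) < 4) abort(paste0("truncated SDF record at line ", offset))
  name <- trimws(block[1])
  counts <- block[4]
  n_at <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bd <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_at) || is.na(n_bd)) {
    abort(paste0("malformed counts line at line ", offset + 3))
  }
  at_lines <- block[5:(4 + n_at)]
  atoms <- tibble(
    x = as.numeric(substr(at_lines, 1, 10)),
    y = as.numeric(substr(at_lines, 11, 20)),
    z = as.numeric(substr(at_lines, 21, 30)),
    element = toupper(trimws(substr(at_lines, 32, 34)))
  )
  if (any(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z))) {
    abort(paste0("malformed atom block near line ", offset + 4))
  }
  bonds <- NULL
  if (n_bd > 0) {
    bd_lines <- block[(5 + n_at):(4 + n_at + n_bd)]
    bonds <- tibble(
      i = as.integer(substr(bd_lines, 1, 3)),
      j = as.integer(substr(bd_lines, 4, 6))
    )
  }
  rest <- block[(5 + n_at + n_bd):length(block)]
  charges <- integer(nrow(atoms))
  for (ln in rest[startsWith(rest, "M  CHG")]) {
    toks <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    n_pairs <- toks[1]
    for (p in seq_len(n_pairs)) {
      charges[toks[2 * p]] <- toks[2 * p + 1]
    }
  }
  atoms$formal_charge <- charges
  # data fields
  tag_idx <- which(startsWith(rest, ">"))
  fields <- character()
  for (ti in tag_idx) {
    tag <- sub(".*<([^>]+)>.*", "\\1", rest[ti])
    val <- if (ti + 1 <= length(rest)) trimws(rest[ti + 1]) else ""
    fields[tag] <- val
  }
  # pre-annotated pharmacophore points survive the round-trip as a
  # JSON-encoded data field
  fp <- NULL
  if ("feature_points" %in% names(fields)) {
    fp <- as_tibble(jsonlite::fromJSON(fields[["feature_points"]]))
    fields <- fields[names(fields) != "feature_points"]
  }
  conformer(name = name, atoms = atoms, bonds = bonds,
            feature_points = fp, fields = fields)
}

#' Write conformers to an SDF (V2000) file
#'
#' @param conformers a `conformer` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(conformers, path) {
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in conformers) {
    writeLines(c(cf$name, "  trajpharm", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(cf$atoms), nrow(cf$bonds)), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       cf$atoms$x, cf$atoms$y, cf$atoms$z,
                       .sdf_element(cf$atoms$element)), con)
    if (nrow(cf$bonds) > 0) {
      writeLines(sprintf("%3d%3d%3d  0", cf$bonds$i, cf$bonds$j, 1L), con)
    }
    chg <- which(cf$atoms$formal_charge != 0)
    if (length(chg) > 0) {
      writeLines(paste0("M  CHG", sprintf("%3d", length(chg)),
                        paste0(sprintf("%4d%4d", chg,
                                       cf$atoms$formal_charge[chg]),
                               collapse = "")), con)
    }
    writeLines("M  END", con)
    fields <- cf$fields
    if (!is.null(cf$feature_points)) {
      fields["feature_points"] <- as.character(jsonlite::toJSON(
        as.data.frame(cf$feature_points), digits = NA))
    }
    if (length(fields) > 0) {
      for (tag in names(fields)) {
        writeLines(c(paste0(">  <", tag, ">"), fields[[tag]], ""), con)
      }
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

.sdf_element <- function(el) {
  # SDF uses mixed case symbols (Cl, Br)
  vapply(el, function(e) {
    if (nchar(e) == 1) e
    else paste0(substr(e, 1, 1), tolower(substr(e, 2, nchar(e))))
  }, character(1))
}

# ---- pose sets -------------------------------------------------------------

#' Construct a docking pose set
#'
#' All poses share one molecule (atom count and order) in a common
#' receptor frame; only coordinates differ.
#'
#' @param atoms atoms tibble of the ligand (template; coordinates ignored).
#' @param coords array `n_atoms x 3 x n_poses`.
#' @param labels character vector of pose labels (e.g. `"pO-1"` =
#'   scoring-function/search-algorithm combo plus rank).
#' @param scores optional numeric docking scores (lower = better).
#' @return object of class `pose_set`.
#' @export
pose_set <- function(atoms, coords, labels, scores = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  n_poses <- dim(coords)[3]
  if (length(labels) != n_poses) abort("one label per pose required")
  if (is.null(scores)) scores <- rep(NA_real_, n_poses)
  if (length(scores) != n_poses) abort("one score per pose required")
  if (dim(coords)[1] != nrow(atoms)) abort("coords/atoms atom-count mismatch")
  structure(list(atoms = as_tibble(atoms), coords = coords,
                 labels = as.character(labels), scores = as.numeric(scores)),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat("<pose_set> ", n_poses(x), " poses x ", nrow(x$atoms), " atoms\n",
      sep = "")
  invisible(x)
}

#' Number of poses in a pose set
#' @param poses a `pose_set`.
#' @export
n_poses <- function(poses) dim(poses$coords)[3]

pose_coords <- function(poses, i) poses$coords[, , i, drop = TRUE]

#' Read docking poses from an SDF file
#'
#' One SDF record per pose; the record name is the pose label and an
#' optional `Score` data field supplies the docking score.
#'
#' @param path SDF file.
#' @param score_field data field holding the score (default "Score").
#' @return a `pose_set`.
#' @export
read_poses_sdf <- function(path, score_field = "Score") {
  confs <- read_sdf(path)
  if (length(confs) == 0) abort("no poses in file")
  n_at <- nrow(confs[[1]]$atoms)
  if (!all(map_int(confs, ~ nrow(.x$atoms)) == n_at)) {
    abort("poses differ in atom count")
  }
  coords <- array(0, dim = c(n_at, 3, length(confs)))
  for (k in seq_along(confs)) coords[, , k] <- conformer_coords(confs[[k]])
  scores <- map_dbl(confs, function(cf) {
    v <- suppressWarnings(as.numeric(cf$fields[score_field]))
    if (length(v) == 0) NA_real_ else v
  })
  pose_set(confs[[1]]$atoms, coords, labels = map_chr(confs, "name"),
           scores = scores)
}

#' Write a pose set to SDF
#'
#' @param poses a `pose_set`.
#' @param path output file.
#' @param score_field data field name for scores.
#' @return `path`, invisibly.
#' @export
write_poses_sdf <- function(poses, path, score_field = "Score") {
  confs <- map(seq_len(n_poses(poses)), function(k) {
    at <- poses$atoms
    xyz <- pose_coords(poses, k)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    fields <- character()
    if (!is.na(poses$scores[k])) {
      fields[score_field] <- format(poses$scores[k])
    }
    conformer(poses$labels[k], at, fields = fields)
  })
  write_sdf(confs, path)
}
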