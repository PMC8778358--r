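# Deterministic, seeded generators for pockets, trajectories with planted
# interaction frequencies, docking pose sets with planted modes, and
# conformer libraries with planted hits. No physical realism is claimed:
# geometries are built to sit inside (or outside) the detector cutoffs.

# run code under a seed, restoring the caller's RNG state afterwards
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# hexagonal ring coordinates (radius 1.39 A) in the z = z0 plane
.hex_ring <- function(center = c(0, 0, 0), z0 = 0, phase = 0) {
  k <- 0:5
  ang <- phase + k * pi / 3
  cbind(center[1] + 1.39 * cos(ang), center[2] + 1.39 * sin(ang),
        center[3] + z0)
}

.atom_row <- function(name, element, resname, resnum, chain, xyz,
                      is_ligand = FALSE, charge = 0L) {
  tibble(name = name, element = element, resname = resname,
         resnum = as.integer(resnum), chain = chain,
         x = xyz[1], y = xyz[2], z = xyz[3],
         is_ligand = is_ligand, formal_charge = as.integer(charge))
}

#' Build the synthetic binding pocket
#'
#' A minimal pocket around a small aromatic ligand, with one protein
#' residue per planted interaction: a hinge-like leucine whose backbone
#' oxygen accepts the ligand amine's hydrogen bond, a serine whose
#' backbone nitrogen donates to the ligand carbonyl oxygen, a
#' phenylalanine stacked parallel over the ligand ring, a leucine side
#' chain in hydrophobic contact with the ligand methyl, and a
#' glutamate/lysine pair forming salt bridges with the ligand ammonium
#' and with each other. At the planted geometry the frame detector finds
#' all four default interaction types.
#'
#' @return a `topology` (ligand bonds included; protein atoms typed by
#'   residue templates) carrying a `planted` attribute that maps each
#'   planted interaction to the residue displaced to switch it off.
#' @examples
#' pocket <- make_pocket()
#' detect_frame(pocket)
#' @export
make_pocket <- function() {
  rows <- list()
  bonds <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- .atom_row(...)

  # ---- ligand (chain L, resnum 1): benzene core with substituents ----
  ring <- .hex_ring()
  ring_names <- paste0("C", 1:6)
  for (k in 1:6) add(ring_names[k], "C", "LIG", 1, "L", ring[k, ],
                     is_ligand = TRUE)
  add("N7", "N", "LIG", 1, "L", c(2.79, 0, 0), is_ligand = TRUE)     # amine
  add("H71", "H", "LIG", 1, "L", c(3.79, 0, 0), is_ligand = TRUE)
  add("O8", "O", "LIG", 1, "L", c(-2.74, 0, 0), is_ligand = TRUE)    # carbonyl
  add("C9", "C", "LIG", 1, "L", c(1.39, 2.41, 0), is_ligand = TRUE)  # methyl
  add("N10", "N", "LIG", 1, "L", c(-1.39, -2.41, 0), is_ligand = TRUE,
      charge = 1L)                                                   # ammonium
  lig_bond <- function(a, b) bonds[[length(bonds) + 1]] <<- c(a, b)
  for (k in 1:6) lig_bond(k, k %% 6 + 1)
  lig_bond(1, 7); lig_bond(7, 8); lig_bond(4, 9); lig_bond(2, 10)
  lig_bond(5, 11)

  # ---- protein residues (chain A) ----
  # LEU 85: backbone O accepts the ligand N7-H71 hydrogen bond (2.9 A)
  add("N", "N", "LEU", 85, "A", c(7.4, 1.6, 0))
  add("CA", "C", "LEU", 85, "A", c(6.9, 0.9, 1.2))
  add("C", "C", "LEU", 85, "A", c(6.4, -0.4, 0.7))
  add("O", "O", "LEU", 85, "A", c(5.69, 0, 0))
  add("CB", "C", "LEU", 85, "A", c(8.2, 0.6, 2.1))
  add("CG", "C", "LEU", 85, "A", c(9.0, 1.5, 3.0))
  add("CD1", "C", "LEU", 85, "A", c(10.2, 0.8, 3.6))
  add("CD2", "C", "LEU", 85, "A", c(9.5, 2.8, 2.4))

  # SER 88: backbone N donates to the ligand carbonyl O8 (2.9 A)
  add("N", "N", "SER", 88, "A", c(-5.64, 0, 0))
  add("CA", "C", "SER", 88, "A", c(-6.8, 0.8, 0.4))
  add("C", "C", "SER", 88, "A", c(-7.9, 0.0, 1.0))
  add("O", "O", "SER", 88, "A", c(-7.8, -1.2, 1.1))
  add("CB", "C", "SER", 88, "A", c(-6.6, 1.9, 1.4))
  add("OG", "O", "SER", 88, "A", c(-6.5, 3.1, 0.7))

  # PHE 20: ring stacked parallel over the ligand ring (centroid 4.3 A,
  # rotated 30 deg so no carbon pair gets inside the hydrophobic cutoff)
  phe_ring <- .hex_ring(z0 = 4.3, phase = pi / 6)
  phe_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  for (k in 1:6) add(phe_names[k], "C", "PHE", 20, "A", phe_ring[k, ])
  add("CB", "C", "PHE", 20, "A", c(2.3, 0.2, 5.2))
  add("N", "N", "PHE", 20, "A", c(0.5, 0.8, 7.5))
  add("CA", "C", "PHE", 20, "A", c(1.6, 0.1, 6.7))
  add("C", "C", "PHE", 20, "A", c(2.6, -0.7, 7.4))
  add("O", "O", "PHE", 20, "A", c(3.5, -1.3, 6.8))

  # LEU 135: side-chain CD1 3.6 A from the ligand methyl C9
  add("N", "N", "LEU", 135, "A", c(1.5, 8.8, 0.5))
  add("CA", "C", "LEU", 135, "A", c(1.3, 7.9, 1.6))
  add("C", "C", "LEU", 135, "A", c(0.9, 8.6, 2.9))
  add("O", "O", "LEU", 135, "A", c(0.8, 9.8, 3.0))
  add("CB", "C", "LEU", 135, "A", c(2.4, 6.9, 1.8))
  add("CG", "C", "LEU", 135, "A", c(2.2, 5.9, 0.9))
  add("CD1", "C", "LEU", 135, "A", c(1.39, 6.01, 0))
  add("CD2", "C", "LEU", 135, "A", c(3.4, 5.2, 0.5))

  # GLU 52: carboxylate centroid 3.0 A from the ligand ammonium N10
  add("N", "N", "GLU", 52, "A", c(-1.5, -8.3, 0.4))
  add("CA", "C", "GLU", 52, "A", c(-1.4, -7.6, -0.8))
  add("C", "C", "GLU", 52, "A", c(-1.2, -8.5, -2.0))
  add("O", "O", "GLU", 52, "A", c(-1.1, -9.7, -1.9))
  add("CB", "C", "GLU", 52, "A", c(-1.45, -7.0, 0.9))
  add("CG", "C", "GLU", 52, "A", c(-1.42, -6.3, -0.9))
  add("CD", "C", "GLU", 52, "A", c(-1.39, -5.9, 0.6))
  add("OE1", "O", "GLU", 52, "A", c(-0.29, -5.41, 0))
  add("OE2", "O", "GLU", 52, "A", c(-2.49, -5.41, 0))

  # LYS 38: ammonium NZ 3.2 A above the GLU 52 carboxylate centroid
  add("N", "N", "LYS", 38, "A", c(-2.0, -8.5, 4.8))
  add("CA", "C", "LYS", 38, "A", c(-1.9, -7.8, 6.0))
  add("C", "C", "LYS", 38, "A", c(-1.7, -8.7, 7.2))
  add("O", "O", "LYS", 38, "A", c(-1.6, -9.9, 7.1))
  add("CB", "C", "LYS", 38, "A", c(-1.8, -6.9, 5.2))
  add("CG", "C", "LYS", 38, "A", c(-1.7, -6.6, 6.6))
  add("CD", "C", "LYS", 38, "A", c(-1.6, -6.9, 4.0))
  add("NZ", "N", "LYS", 38, "A", c(-1.39, -5.41, 3.2))

  atoms <- bind_rows(rows)
  bond_tbl <- tibble(i = map_int(bonds, 1), j = map_int(bonds, 2))
  top <- topology(atoms, bond_tbl)

  res_atoms <- function(resnum) {
    which(!top$atoms$is_ligand & top$atoms$resnum == resnum)
  }
  crit <- interaction_criteria()
  planted <- tibble(
    chain = "A",
    resnum = c(85L, 88L, 20L, 135L, 52L, 38L),
    resname = c("LEU", "SER", "PHE", "LEU", "GLU", "LYS"),
    itype = c("hbond", "hbond", "pi_stack", "hydrophobic",
              "salt_bridge", "salt_bridge_protein"),
    move_atoms = list(res_atoms(85), res_atoms(88), res_atoms(20),
                      res_atoms(135), res_atoms(52), res_atoms(38)),
    off_shift = list(
      c(crit$hbond_max_da + 2, 0, 0),
      c(-(crit$hbond_max_da + 2), 0, 0),
      c(0, 0, crit$pistack_max_centroid + 2),
      c(0, crit$hydrophobic_max + 2, 0),
      c(0, -(crit$saltbridge_max + 2), 0),
      c(0, 0, crit$saltbridge_max + 2)
    )
  )
  attr(top, "planted") <- planted
  top
}

#' Specification for a planted-interaction trajectory
#'
#' Defaults state a world modeled on reported occurrence ranges for a
#' kinase-inhibitor complex: a near-permanent hinge hydrogen bond
#' (p = 0.99), a second hydrogen bond at the low end of the reported
#' hinge range (p = 0.88), ring stacking around 31%, a hydrophobic
#' contact around 63%, and a frequent salt bridge (p = 0.8).
#'
#' @param interactions tibble (`resnum`, `itype`, `p`) of per-frame
#'   on-probabilities for planted interactions of [make_pocket()]
#'   (default: the five ligand plants at the probabilities above).
#' @param n_frames frames to generate (default 200; test scale).
#' @param jitter_sigma per-coordinate thermal jitter, A (default 0.05).
#' @param seed RNG seed (single R Mersenne-Twister stream; generation is
#'   bit-reproducible per seed).
#' @return object of class `plant_spec`.
#' @export
plant_spec <- function(interactions = NULL, n_frames = 200,
                       jitter_sigma = 0.05, seed = 1) {
  if (is.null(interactions)) {
    interactions <- tibble(
      resnum = c(85L, 88L, 20L, 135L, 52L),
      itype = c("hbond", "hbond", "pi_stack", "hydrophobic", "salt_bridge"),
      p = c(0.99, 0.88, 0.31, 0.63, 0.80)
    )
  }
  interactions <- as_tibble(interactions)
  if (any(interactions$p < 0 | interactions$p > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  if (n_frames < 1) abort("n_frames must be >= 1")
  structure(list(interactions = interactions, n_frames = as.integer(n_frames),
                 jitter_sigma = jitter_sigma, seed = as.integer(seed)),
            class = "plant_spec")
}

#' Generate a trajectory with planted interaction frequencies
#'
#' Starts every frame from the pocket's planted geometry; each listed
#' interaction is switched on with its probability and otherwise
#' switched off by displacing the partner residue two Angstrom beyond
#' the relevant cutoff (so thermal jitter cannot flip the state).
#' Gaussian jitter is then added to all coordinates.
#'
#' @param spec a [plant_spec()].
#' @param pocket the pocket topology (default [make_pocket()]).
#' @return an `md_trajectory`.
#' @export
make_trajectory <- function(spec, pocket = make_pocket()) {
  stopifnot(inherits(spec, "plant_spec"))
  planted <- attr(pocket, "planted")
  plan <- left_join(spec$interactions, planted, by = c("resnum", "itype"))
  if (anyNA(plan$off_shift)) {
    abort("interaction spec names a residue/type the pocket did not plant")
  }
  base <- topology_coords(pocket)
  n_at <- nrow(base)
  coords <- array(0, dim = c(n_at, 3, spec$n_frames))
  .with_seed(spec$seed, {
    for (f in seq_len(spec$n_frames)) {
      x <- base
      for (r in seq_len(nrow(plan))) {
        if (runif(1) >= plan$p[r]) { # off
          ix <- plan$move_atoms[[r]]
          x[ix, ] <- sweep(x[ix, , drop = FALSE], 2, plan$off_shift[[r]], `+`)
        }
      }
      x <- x + matrix(rnorm(n_at * 3, sd = spec$jitter_sigma), n_at, 3)
      coords[, , f] <- x
    }
  })
  md_trajectory(pocket, coords)
}

#' Specification for a synthetic docking pose set
#'
#' Defaults mimic a consensus-docking design: 3 search algorithms x 4
#' scoring functions x 8 runs = 96 poses, planted around two binding
#' modes 10 A apart with the dominant mode holding two thirds of the
#' poses and better scores.
#'
#' @param modes list of modes, each `list(shift, count, jitter)`: rigid
#'   translation of the mode seat, number of poses, and rigid jitter
#'   scale (A).
#' @param seed RNG seed.
#' @return object of class `pose_set_spec`.
#' @export
pose_set_spec <- function(modes = NULL, seed = 1) {
  if (is.null(modes)) {
    modes <- list(
      list(shift = c(0, 0, 0), count = 64L, jitter = 0.3, score = -120),
      list(shift = c(10, 0, 0), count = 32L, jitter = 0.3, score = -100)
    )
  }
  if (any(map_int(modes, ~ as.integer(.x$count)) < 1)) {
    abort("mode counts must be >= 1")
  }
  structure(list(modes = modes, seed = as.integer(seed)),
            class = "pose_set_spec")
}

#' Generate a docking pose set with planted binding modes
#'
#' Pose labels follow the scoring-function/search-algorithm lettering
#' with a rank suffix (`"pO-1"` and so on); scores are drawn around each
#' mode's score level (lower = better).
#'
#' @param spec a [pose_set_spec()].
#' @return a `pose_set`; the planted mode of each pose is recorded in
#'   the `planted_mode` attribute.
#' @export
make_pose_set <- function(spec = pose_set_spec()) {
  stopifnot(inherits(spec, "pose_set_spec"))
  pocket <- make_pocket()
  lig <- ligand_indices(pocket)
  base <- topology_coords(pocket)[lig, , drop = FALSE]
  atoms <- pocket$atoms[lig, ]
  counts <- map_int(spec$modes, ~ as.integer(.x$count))
  n <- sum(counts)
  combos <- as.vector(t(outer(c("m", "M", "p", "P"), c("X", "S", "O"),
                              function(s, a) paste0(s, a))))
  labels <- paste0(rep_len(combos, n), "-",
                   rep(seq_len(ceiling(n / length(combos))),
                       each = length(combos))[seq_len(n)])
  coords <- array(0, dim = c(nrow(base), 3, n))
  scores <- numeric(n)
  mode_of <- rep(seq_along(spec$modes), counts)
  .with_seed(spec$seed, {
    mode_of <- sample(mode_of) # interleave modes across combos
    for (k in seq_len(n)) {
      m <- spec$modes[[mode_of[k]]]
      rot <- random_rotation()
      # small rigid perturbation: rotation blended toward identity
      blend <- 0.03
      rsmall <- (1 - blend) * diag(3) + blend * rot
      sv <- svd(rsmall)
      rsmall <- sv$u %*% t(sv$v)
      ctr <- colMeans(base)
      shift <- m$shift + rnorm(3, sd = m$jitter / sqrt(3))
      coords[, , k] <- sweep(sweep(base, 2, ctr) %*% rsmall, 2, ctr + shift,
                             `+`)
      scores[k] <- rnorm(1, mean = m$score %||% -100, sd = 3)
    }
  })
  ps <- pose_set(atoms, coords, labels, scores)
  attr(ps, "planted_mode") <- mode_of
  ps
}

#' Generate a conformer library with planted pharmacophore hits
#'
#' Hits carry feature points at the model's element positions (offset by
#' at most a quarter radius) under a random rigid transform; decoys keep
#' at most `min_match - 1` correct positions and scatter the rest far
#' outside the model's footprint, so they cannot reach the match
#' minimum. Ground truth is recorded in the conformer names
#' (`hit_*` / `decoy_*`).
#'
#' @param n library size.
#' @param model the `pharmacophore_model` to plant against.
#' @param hit_fraction fraction of conformers that are hits.
#' @param seed RNG seed.
#' @param min_match the match minimum decoys must fail (default: the
#'   model's).
#' @return list of `conformer` objects.
#' @export
make_conformer_library <- function(n, model, hit_fraction, seed = 1,
                                   min_match = NULL) {
  if (hit_fraction < 0 || hit_fraction > 1) {
    abort("hit_fraction must lie in [0, 1]")
  }
  min_match <- min_match %||% model$min_match
  positions <- .model_positions(model)
  npos <- length(positions)
  if (npos == 0) abort("model has no features")
  centers <- t(vapply(positions, `[[`, numeric(3), "center"))
  centroid <- colMeans(centers)
  rmax <- max(sqrt(rowSums(sweep(centers, 2, centroid)^2)))
  n_hits <- round(n * hit_fraction)
  .with_seed(seed, {
    map(seq_len(n), function(k) {
      is_hit <- k <= n_hits
      if (is_hit) {
        off <- matrix(rnorm(npos * 3), npos, 3)
        off <- off / sqrt(rowSums(off^2)) *
          runif(npos, 0, 0.25 * map_dbl(positions, "radius"))
        pts_xyz <- centers + off
        kinds <- map_chr(positions, function(p) {
          if (length(p$kinds) == 1) p$kinds else sample(p$kinds, 1)
        })
      } else {
        n_keep <- min(min_match - 1, npos)
        keep <- sort(sample(npos, n_keep))
        scatter <- npos - n_keep
        dirs <- matrix(rnorm(max(scatter, 1) * 3), ncol = 3)
        dirs <- dirs / sqrt(rowSums(dirs^2))
        far <- sweep(dirs * (rmax + 3 + runif(max(scatter, 1), 0, 5)), 2,
                     centroid, `+`)
        pts_xyz <- rbind(centers[keep, , drop = FALSE],
                         far[seq_len(scatter), , drop = FALSE])
        kinds <- c(map_chr(positions[keep], ~ .x$kinds[1]),
                   sample(.feature_kinds, scatter, replace = TRUE))
      }
      # rigid scramble of points and atoms together
      rot <- random_rotation()
      trans <- runif(3, -5, 5)
      pts_xyz <- sweep(pts_xyz %*% rot, 2, trans, `+`)
      name <- sprintf("%s_%03d", if (is_hit) "hit" else "decoy", k)
      atoms <- tibble(element = "C",
                      x = pts_xyz[, 1], y = pts_xyz[, 2], z = pts_xyz[, 3])
      conformer(name, atoms,
                feature_points = tibble(kind = kinds, x = pts_xyz[, 1],
                                        y = pts_xyz[, 2], z = pts_xyz[, 3]),
                fields = c(compound = name))
    })
  })
}
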