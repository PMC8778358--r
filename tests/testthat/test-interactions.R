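# Geometric interaction detectors: constructed examples, boundary
# conventions, and rigid-transform invariance. (Large randomized oracle
# suites live in test-acceptance.R.)

# a 3-atom hydrogen-bond probe: ligand N-H donor vs protein backbone O
hb_probe <- function(d_ox, h_on_axis = TRUE) {
  atoms <- tibble::tibble(
    name = c("N1", "H1", "O"),
    element = c("N", "H", "O"),
    resname = c("LIG", "LIG", "GLY"),
    resnum = c(1L, 1L, 10L),
    chain = c("L", "L", "A"),
    x = c(0, if (h_on_axis) 1 else 0, d_ox),
    y = c(0, if (h_on_axis) 0 else 1, 0),
    z = 0,
    is_ligand = c(TRUE, TRUE, FALSE))
  topology(atoms, bonds = data.frame(i = 1, j = 2))
}

test_that("hydrogen bonds respect distance cutoff and donor angle", {
  ev <- detect_hbonds(hb_probe(2.9))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$distance, 2.9)
  expect_equal(ev$angle, 180)
  expect_identical(ev$lig_role, "donor")
  # beyond the cutoff: nothing
  expect_equal(nrow(detect_hbonds(hb_probe(5.0))), 0)
  # hydrogen perpendicular to the donor-acceptor axis at 1 A: angle at H
  # is ~71 deg < 100 -> rejected even though the distance qualifies
  expect_equal(nrow(detect_hbonds(hb_probe(2.9, h_on_axis = FALSE))), 0)
  # boundary convention: exactly at the cutoff is out (strict <)
  expect_equal(nrow(detect_hbonds(hb_probe(4.1))), 0)
  expect_equal(nrow(detect_hbonds(hb_probe(4.0999))), 1)
})

test_that("heavy-atom fallback applies when the ligand has no hydrogens", {
  atoms <- tibble::tibble(
    name = c("N1", "O"), element = c("N", "O"),
    resname = c("LIG", "GLY"), resnum = c(1L, 10L),
    chain = c("L", "A"), x = c(0, 2.9), y = 0, z = 0,
    is_ligand = c(TRUE, FALSE))
  top <- topology(atoms)
  ev <- detect_hbonds(top)
  expect_equal(nrow(ev), 1) # under-valent N treated as implicit donor
  expect_true(is.na(ev$angle))
})

test_that("hydrophobic contacts require apolar typing on both sides", {
  # ligand methyl C 3.8 A from a LEU side-chain carbon -> one event
  atoms <- tibble::tibble(
    name = c("C1", "O1", "CD1"),
    element = c("C", "O", "C"),
    resname = c("LIG", "LIG", "LEU"),
    resnum = c(1L, 1L, 30L),
    chain = c("L", "L", "A"),
    x = c(0, -1.3, 3.8), y = 0, z = 0,
    is_ligand = c(TRUE, TRUE, FALSE))
  # C1 bonded only to... nothing polar: no bonds at all means not typed;
  # bond it to nothing -> graph rule needs bonds. Give it a C neighbour.
  atoms <- rbind(atoms, tibble::tibble(
    name = "C2", element = "C", resname = "LIG", resnum = 1L, chain = "L",
    x = -1.4, y = 1.2, z = 0, is_ligand = TRUE))
  top <- topology(atoms, bonds = data.frame(i = c(1, 2), j = c(4, 4)))
  ev <- detect_hydrophobic(top)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$distance, 3.8)
  expect_equal(ev$resnum, 30L)
  # carbon bonded to O is polar: no event even at 3.5 A
  atoms2 <- atoms
  atoms2$x[3] <- 3.5
  top2 <- topology(atoms2, bonds = data.frame(i = c(1, 1, 2), j = c(2, 4, 4)))
  expect_equal(nrow(detect_hydrophobic(top2)), 0)
})

test_that("ring stacking detects parallel and T-shaped, rejects offsets", {
  fix_at <- function(shift, rotate90 = FALSE) {
    hexagon <- function() {
      k <- 0:5
      cbind(1.39 * cos(k * pi / 3), 1.39 * sin(k * pi / 3), 0)
    }
    lig <- hexagon()
    prot <- hexagon()
    if (rotate90) prot <- prot[, c(1, 3, 2)] # flip into the xz plane
    prot <- sweep(prot, 2, shift, `+`)
    atoms <- rbind(
      tibble::tibble(name = paste0("C", 1:6), element = "C", resname = "LIG",
                     resnum = 1L, chain = "L", x = lig[, 1], y = lig[, 2],
                     z = lig[, 3], is_ligand = TRUE),
      tibble::tibble(name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                     element = "C", resname = "PHE", resnum = 20L,
                     chain = "A", x = prot[, 1], y = prot[, 2],
                     z = prot[, 3], is_ligand = FALSE))
    topology(atoms, bonds = tibble::tibble(i = 1:6, j = c(2:6, 1)))
  }
  # parallel, 3.8 A face-to-face, no offset
  ev <- detect_pistack(fix_at(c(0, 0, 3.8)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$angle, 0, tolerance = 1e-6)
  # coplanar at 3.8 A laterally: offset = 3.8 > 2.0 -> rejected
  expect_equal(nrow(detect_pistack(fix_at(c(3.8, 0, 0)))), 0)
  # perpendicular (T-shaped) at 5.0 A with 1.0 A offset
  ev_t <- detect_pistack(fix_at(c(1.0, 0, 4.9), rotate90 = TRUE))
  expect_equal(nrow(ev_t), 1)
  expect_equal(ev_t$angle, 90, tolerance = 1e-6)
})

test_that("salt bridges require opposite signs within the cutoff", {
  fix <- function(resname, dz) {
    side <- if (resname == "GLU") {
      tibble::tibble(name = c("OE1", "OE2"), element = "O",
                     resname = "GLU", x = c(-1.1, 1.1), y = 0, z = dz)
    } else {
      tibble::tibble(name = "NZ", element = "N", resname = "LYS",
                     x = 0, y = 0, z = dz)
    }
    atoms <- rbind(
      tibble::tibble(name = "N1", element = "N", resname = "LIG",
                     x = 0, y = 0, z = 0, resnum = 1L, chain = "L",
                     is_ligand = TRUE, formal_charge = 1L),
      dplyr::mutate(side, resnum = 52L, chain = "A", is_ligand = FALSE,
                    formal_charge = 0L))
    topology(atoms)
  }
  ev <- detect_saltbridge(fix("GLU", 3.0))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$distance, 3.0)
  # two cations at 3 A: no event
  expect_equal(nrow(detect_saltbridge(fix("LYS", 3.0))), 0)
  # beyond the cutoff
  expect_equal(nrow(detect_saltbridge(fix("GLU", 5.6))), 0)
})

test_that("detect_frame is the union of the four default detectors", {
  pocket <- make_pocket()
  ev <- detect_frame(pocket)
  parts <- dplyr::bind_rows(
    detect_hbonds(pocket), detect_hydrophobic(pocket),
    detect_pistack(pocket), detect_saltbridge(pocket))
  expect_equal(as.data.frame(ev[, 1:7]), as.data.frame(parts[, 1:7]))
  expect_setequal(unique(ev$itype),
                  c("hbond", "hydrophobic", "pi_stack", "salt_bridge"))
  # empty ligand selection -> no events at all
  apo <- pocket
  apo$atoms$is_ligand <- FALSE
  expect_equal(nrow(detect_frame(apo)), 0)
})

test_that("detector output is invariant under global rigid motion", {
  pocket <- make_pocket()
  base <- detect_frame(pocket)
  set.seed(99)
  for (i in 1:5) {
    rot <- trajpharm:::random_rotation()
    shift <- runif(3, -30, 30)
    moved <- sweep(topology_coords(pocket) %*% rot, 2, shift, `+`)
    ev <- detect_frame(pocket, moved)
    expect_identical(ev$itype, base$itype)
    expect_identical(ev$resnum, base$resnum)
    expect_equal(ev$distance, base$distance, tolerance = 1e-9)
  }
})

test_that("tightening any cutoff never adds events", {
  fixtures <- lapply(1:10, scrambled_pocket)
  loose <- interaction_criteria()
  tight <- interaction_criteria(hbond_max_da = 3.0, hydrophobic_max = 3.2,
                                pistack_max_centroid = 4.5,
                                pistack_max_offset = 1.0,
                                saltbridge_max = 4.0)
  for (f in fixtures) {
    n_loose <- nrow(detect_frame(f$topology, f$coords, loose))
    n_tight <- nrow(detect_frame(f$topology, f$coords, tight))
    expect_lte(n_tight, n_loose)
  }
})

test_that("cation-pi detector fires only across the boundary and in range", {
  pocket <- make_pocket()
  ev <- detect_pication(pocket)
  # planted geometry: ligand ammonium sits 5.1 A under the PHE ring
  expect_equal(nrow(ev), 1)
  expect_identical(ev$resname, "PHE")
  # excluded from the default frame union, included on request
  expect_false("pi_cation" %in% detect_frame(pocket)$itype)
  expect_true("pi_cation" %in%
                detect_frame(pocket, include_pication = TRUE)$itype)
})
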