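# Occurrence profiles, RMSD/RMSF series, salt-bridge prevalence.

test_that("occurrence_percent reproduces printed worked examples", {
  expect_equal(occurrence_percent(14998, 15000), 99.99)
  expect_equal(occurrence_percent(3239, 15000), 21.59)
  expect_equal(occurrence_percent(0, 15000), 0)
  expect_equal(occurrence_percent(15000, 15000), 100)
  expect_error(occurrence_percent(1, 0), "positive")
  expect_error(occurrence_percent(11, 10), "count")
  # monotone in count
  p <- occurrence_percent(0:100, 100)
  expect_true(all(diff(p) >= 0))
})

test_that("profiles count frames with >= 1 event, not event multiplicity", {
  # deterministic plant: LEU85 bond on in all frames, everything else off
  spec <- plant_spec(
    interactions = tibble::tibble(
      resnum = c(85L, 88L, 20L, 135L, 52L),
      itype = c("hbond", "hbond", "pi_stack", "hydrophobic", "salt_bridge"),
      p = c(1, 0, 0, 0, 0)),
    n_frames = 10, jitter_sigma = 0, seed = 2)
  prof <- profile_trajectory(make_trajectory(spec))
  td <- tidy(prof)
  expect_equal(nrow(td), 1)
  expect_equal(td$count, 10L)
  expect_equal(td$resnum, 85L)
  expect_equal(td$percent, 100)
})

test_that("a ligand far from the protein yields an all-zero profile", {
  pocket <- make_pocket()
  lig <- ligand_indices(pocket)
  pocket$atoms$x[lig] <- pocket$atoms$x[lig] + 50
  traj <- md_trajectory(pocket, array(topology_coords(pocket),
                                      dim = c(nrow(pocket$atoms), 3, 3)))
  prof <- profile_trajectory(traj)
  expect_equal(nrow(prof$counts), 0)
  expect_equal(nrow(relevant_interactions(prof)), 0)
})

test_that("profile counts are invariant to frame order", {
  traj <- make_trajectory(plant_spec(n_frames = 50, seed = 31))
  perm <- sample(50)
  traj2 <- md_trajectory(traj$topology, traj$coords[, , perm])
  p1 <- dplyr::arrange(tidy(profile_trajectory(traj)), resnum, itype)
  p2 <- dplyr::arrange(tidy(profile_trajectory(traj2)), resnum, itype)
  expect_equal(as.data.frame(p1), as.data.frame(p2))
})

test_that("relevance threshold is strictly greater-than", {
  prof <- structure(list(
    counts = tibble::tibble(
      chain = "A", resnum = c(1L, 2L, 3L), resname = "ALA",
      itype = "hbond", count = c(3000L, 3239L, 2999L)),
    total_frames = 15000L, criteria = interaction_criteria(),
    events = NULL), class = "interaction_profile")
  rel <- relevant_interactions(prof, 20)
  # exactly 20.00% (3000/15000) is excluded; 21.59% is included
  expect_identical(rel$resnum, 2L)
  expect_equal(rel$percent, 21.59)
})

test_that("backbone RMSD is zero for rigid motions and tracks the oracle", {
  traj <- make_trajectory(plant_spec(n_frames = 6, seed = 9,
                                     jitter_sigma = 0.15))
  # a rigidly rotated copy of frame 1 superposes to ~0
  rot <- trajpharm:::random_rotation()
  coords <- traj$coords
  coords[, , 2] <- sweep(coords[, , 1] %*% rot, 2, c(5, -3, 2), `+`)
  traj2 <- md_trajectory(traj$topology, coords)
  ser <- backbone_rmsd_series(traj2)
  expect_equal(ser$values[1], 0)
  expect_lt(ser$values[2], 1e-6)
  # jittered frames agree with the independent quaternion superposition
  bb <- trajpharm:::.backbone_indices(traj$topology)
  ref <- frame_coords(traj, 1)[bb, ]
  ser_all <- backbone_rmsd_series(traj)
  for (k in 2:6) {
    expect_equal(ser_all$values[k],
                 quaternion_rmsd(frame_coords(traj, k)[bb, ], ref),
                 tolerance = 1e-6)
  }
  # superposed RMSD never exceeds raw RMSD, framewise
  raw <- backbone_rmsd_series(traj, superpose = FALSE)
  expect_true(all(ser_all$values <= raw$values + 1e-12))
})

test_that("RMSF matches closed forms", {
  pocket <- make_pocket()
  base <- topology_coords(pocket)
  n_at <- nrow(base)
  # static trajectory: all RMSF zero
  static <- md_trajectory(pocket, array(base, dim = c(n_at, 3, 4)))
  expect_equal(rmsf_per_residue(static)$values, rep(0, 6))
  # one CA oscillating +/- d along x, superposition disabled -> RMSF = d
  d <- 0.8
  ca85 <- which(pocket$atoms$resnum == 85 & pocket$atoms$name == "CA")
  coords <- array(base, dim = c(n_at, 3, 10))
  coords[ca85, 1, ] <- base[ca85, 1] + d * rep(c(1, -1), 5)
  osc <- md_trajectory(pocket, coords)
  res <- rmsf_per_residue(osc, superpose = FALSE)
  td <- tidy(res)
  expect_equal(td$value[td$resnum == 85], d, tolerance = 1e-12)
  expect_equal(td$value[td$resnum != 85], rep(0, 5))
  # isotropic gaussian jitter sigma -> RMSF ~ sigma * sqrt(3)
  sigma <- 0.3
  set.seed(4)
  coords2 <- array(base, dim = c(n_at, 3, 2000)) +
    array(rnorm(n_at * 3 * 2000, sd = sigma), dim = c(n_at, 3, 2000))
  jit <- md_trajectory(pocket, coords2)
  vals <- rmsf_per_residue(jit, superpose = FALSE)$values
  expect_equal(mean(vals), sigma * sqrt(3), tolerance = 0.03)
})

test_that("salt-bridge prevalence recovers planted frequencies", {
  # bridge toggled through the lysine, glutamate fixed in place
  spec <- plant_spec(
    interactions = tibble::tibble(resnum = 38L,
                                  itype = "salt_bridge_protein", p = 0.5),
    n_frames = 100, jitter_sigma = 0, seed = 6)
  traj <- make_trajectory(spec)
  prev <- salt_bridge_prevalence(traj, c(chain = "A", resnum = 38),
                                 c(chain = "A", resnum = 52))
  # exact count of the seeded bernoulli draws
  set.seed(6)
  expect_equal(prev, occurrence_percent(sum(runif(100) < 0.5), 100))
  expect_error(
    salt_bridge_prevalence(traj, c(chain = "A", resnum = 999),
                           c(chain = "A", resnum = 52)),
    "not found")
  expect_error(
    salt_bridge_prevalence(traj, c(chain = "A", resnum = 52),
                           c(chain = "A", resnum = 52)),
    "opposite")
})

test_that("heatmap export filters residues and commutes with filtering", {
  t1 <- make_trajectory(plant_spec(n_frames = 40, seed = 1))
  t2 <- make_trajectory(plant_spec(
    interactions = tibble::tibble(
      resnum = c(85L, 88L, 20L, 135L, 52L),
      itype = c("hbond", "hbond", "pi_stack", "hydrophobic", "salt_bridge"),
      p = c(1, 0.1, 0.1, 0.1, 0.1)),
    n_frames = 40, seed = 2))
  profs <- list(sysA = profile_trajectory(t1), sysB = profile_trajectory(t2))
  wide <- profile_heatmap_export(profs, min_occurrence = 20)
  expect_true(all(c("sysA.hbond", "sysB.hbond") %in% names(wide)))
  vals <- as.matrix(wide[, setdiff(names(wide),
                                   c("chain", "resnum", "resname"))])
  expect_true(all(apply(vals, 1, max) > 20))
  # everything below the display threshold -> empty table
  empty <- profile_heatmap_export(profs, min_occurrence = 100)
  expect_equal(nrow(empty), 0)
})
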