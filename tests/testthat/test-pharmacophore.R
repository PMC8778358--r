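# Pharmacophore model construction, co-location, submodels, JSON I/O,
# and feature building from trajectories.

test_that("the packaged reference model has the published composition", {
  model <- ck1e_reference_model()
  expect_equal(nrow(model$features), 8)
  expect_equal(n_positions(model), 6)
  expect_equal(model$min_match, 6L)
  kinds <- table(model$features$kind)
  expect_equal(as.integer(kinds[c("HBA", "HBD", "Aro", "Hyd")]),
               c(1L, 2L, 2L, 3L))
  # the two dual elements are proper co-location groups
  groups <- split(model$features$name,
                  model$features$group)
  expect_setequal(groups[["Aro1/Hyd1"]], c("Aro1", "Hyd1"))
  expect_setequal(groups[["Hyd2/Aro2"]], c("Hyd2", "Aro2"))
})

test_that("assemble_reference_model validates and handles empty specs", {
  empty <- assemble_reference_model(tibble::tibble(
    name = character(), kind = character(), x = double(), y = double(),
    z = double()))
  expect_equal(nrow(empty$features), 0)
  spec <- tibble::tibble(name = c("A", "A"), kind = "HBA", x = 0, y = 0,
                         z = 0)
  expect_error(assemble_reference_model(spec), "duplicate")
  expect_error(assemble_reference_model(
    tibble::tibble(name = "A", kind = "XXX", x = 0, y = 0, z = 0)),
    "unknown feature kind")
})

test_that("add_colocated creates a one-position dual satisfiable by either", {
  base <- assemble_reference_model(tibble::tibble(
    name = c("Aro1", "HBA1"), kind = c("Aro", "HBA"),
    x = c(0, 5), y = 0, z = 0), min_match = 2)
  dual <- add_colocated(base, "Aro1", "Hyd")
  expect_equal(nrow(dual$features), 3)
  expect_equal(n_positions(dual), 2)
  expect_identical(dual$features$name[3], "Hyd1")
  expect_error(add_colocated(dual, "Aro1", "Hyd"), "group already exists")
  expect_error(add_colocated(base, "nope", "Hyd"), "unknown feature")
  # satisfying both members of a group counts once, not twice
  pts_both <- tibble::tibble(kind = c("Aro", "Hyd", "HBA"),
                             x = c(0, 0, 5), y = 0, z = 0)
  conf_both <- conformer("both", tibble::tibble(element = "C", x = pts_both$x,
                                                y = pts_both$y, z = pts_both$z),
                         feature_points = pts_both)
  m <- match_pharmacophore(dual, conf_both)
  expect_equal(m$matched_count, 2)
})

test_that("submodel drops co-location groups whole", {
  model <- ck1e_reference_model()
  sub <- submodel(model, c("Aro1", "Hyd1"))
  expect_equal(nrow(sub$features), 6)
  expect_equal(n_positions(sub), 5)
  # dropping one member of a dual removes the partner too
  sub2 <- submodel(model, "Aro1")
  expect_false(any(c("Aro1", "Hyd1") %in% sub2$features$name))
  expect_identical(submodel(model, character())$features, model$features)
  none <- submodel(model, model$features$name)
  expect_equal(nrow(none$features), 0)
  expect_null(match_pharmacophore(none, make_conformer_library(
    1, model, hit_fraction = 1, seed = 1)[[1]]))
  expect_error(submodel(model, "ghost"), "unknown feature")
})

test_that("model JSON round-trips exactly and rejects unknown kinds", {
  model <- ck1e_reference_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$features, model$features, tolerance = 1e-12)
  expect_identical(back$min_match, model$min_match)
  bad <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  bad$points[[1]]$kind <- "Magic"
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2, auto_unbox = TRUE, null = "null")
  expect_error(read_model(path2), "unknown feature kind")
})

test_that("build_features maps roles to kinds and recovers anchors", {
  # single planted ligand-donor hydrogen bond at 95%
  spec <- plant_spec(
    interactions = tibble::tibble(
      resnum = c(85L, 88L, 20L, 135L, 52L),
      itype = c("hbond", "hbond", "pi_stack", "hydrophobic", "salt_bridge"),
      p = c(0.95, 0, 0, 0, 0)),
    n_frames = 150, seed = 3)
  prof <- profile_trajectory(make_trajectory(spec), keep_events = TRUE)
  feats <- build_features(prof)
  expect_equal(nrow(feats), 1)
  expect_identical(feats$kind, "HBD")
  # anchor: the ligand amine nitrogen at (2.79, 0, 0)
  expect_equal(c(feats$x, feats$y, feats$z), c(2.79, 0, 0),
               tolerance = 0.05)
})

test_that("feature centers recover planted anchors across seeds", {
  anchors <- list(
    HBD = c(2.79, 0, 0),    # ligand amine N
    HBA = c(-2.74, 0, 0),   # ligand carbonyl O
    Aro = c(0, 0, 0),       # ligand ring centroid
    Hyd = c(1.39, 2.41, 0)) # ligand methyl C
  for (seed in 1:10) {
    traj <- make_trajectory(plant_spec(n_frames = 120, seed = seed))
    prof <- profile_trajectory(traj, keep_events = TRUE)
    feats <- build_features(prof)
    expect_setequal(feats$kind, names(anchors))
    for (r in seq_len(nrow(feats))) {
      expect_lt(sqrt(sum((c(feats$x[r], feats$y[r], feats$z[r]) -
                            anchors[[feats$kind[r]]])^2)), 0.2)
    }
  }
})

test_that("nearby hydrophobic anchors merge into one feature", {
  # synthetic events: two residues' contacts anchored 0.8 A apart (merge),
  # a third anchored 8 A away (kept separate)
  mk_events <- function(resnum, anchor, frames) {
    tibble::tibble(frame = frames, itype = "hydrophobic", chain = "A",
                   resnum = resnum, resname = "LEU",
                   distance = 3.5, angle = NA_real_,
                   lig_role = NA_character_,
                   lig_atoms = list(1L), prot_atoms = list(2L),
                   anchor_x = anchor[1], anchor_y = anchor[2],
                   anchor_z = anchor[3],
                   chain2 = NA_character_, resnum2 = NA_integer_,
                   resname2 = NA_character_)
  }
  events <- dplyr::bind_rows(
    mk_events(10L, c(0, 0, 0), 1:80),
    mk_events(11L, c(0.8, 0, 0), 1:60),
    mk_events(12L, c(8, 0, 0), 1:40))
  counts <- events |>
    dplyr::distinct(frame, chain, resnum, itype, .keep_all = TRUE) |>
    dplyr::count(chain, resnum, resname, itype, name = "count")
  prof <- structure(list(counts = counts, total_frames = 100L,
                         criteria = interaction_criteria(), events = events),
                    class = "interaction_profile")
  feats <- build_features(prof, merge_radius = 1.5)
  expect_equal(nrow(feats), 2)
  expect_identical(sort(feats$name), c("Hyd1", "Hyd2"))
  # merged center: occurrence-weighted mean of (0,0,0) x80 and (0.8,0,0) x60
  merged <- feats[which.min(feats$x), ]
  expect_equal(merged$x, 0.8 * 60 / 140, tolerance = 1e-9)
})
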