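# Conformer annotation, matching, molecular volume, screening pipeline.

test_that("conformer feature annotation follows the chemistry rules", {
  # benzene: one aromatic point at the centroid, no donors/acceptors
  hexagon <- local({
    k <- 0:5
    cbind(1.39 * cos(k * pi / 3), 1.39 * sin(k * pi / 3), 0)
  })
  benzene <- conformer("benzene",
                       tibble::tibble(element = "C", x = hexagon[, 1],
                                      y = hexagon[, 2], z = hexagon[, 3]),
                       bonds = data.frame(i = 1:6, j = c(2:6, 1)))
  pts <- annotate_conformer_features(benzene)
  expect_identical(sort(unique(pts$kind)), c("Aro", "Hyd"))
  aro <- pts[pts$kind == "Aro", ]
  expect_equal(c(aro$x, aro$y, aro$z), c(0, 0, 0), tolerance = 1e-9)
  expect_false(any(pts$kind %in% c("HBA", "HBD")))
  # methanol: O carries both a donor (has H) and an acceptor point
  methanol <- conformer("methanol",
                        tibble::tibble(element = c("C", "O", "H"),
                                       x = c(0, 1.4, 2.3), y = 0, z = 0),
                        bonds = data.frame(i = c(1, 2), j = c(2, 3)))
  mp <- annotate_conformer_features(methanol)
  expect_equal(sum(mp$kind == "HBD"), 1)
  expect_equal(sum(mp$kind == "HBA"), 1)
  expect_equal(mp$x[mp$kind == "HBD"], 1.4)
  # pre-annotated records pass through unchanged
  pre <- conformer("pre", tibble::tibble(element = "C", x = 0, y = 0, z = 0),
                   feature_points = tibble::tibble(kind = "Hyd", x = 9,
                                                   y = 9, z = 9))
  expect_equal(as.data.frame(annotate_conformer_features(pre)),
               data.frame(kind = "Hyd", x = 9, y = 9, z = 9))
})

test_that("matching finds exact and threshold-limited assignments", {
  model <- ck1e_reference_model()
  # conformer whose points equal the model centers exactly: full match
  lib <- make_conformer_library(1, model, hit_fraction = 1, seed = 2)
  exact_pts <- unique(model$features[, c("x", "y", "z")])
  kinds <- c("HBA", "HBD", "HBD", "Aro", "Hyd", "Hyd")
  conf <- conformer("exact",
                    tibble::tibble(element = "C", x = exact_pts$x,
                                   y = exact_pts$y, z = exact_pts$z),
                    feature_points = tibble::tibble(
                      kind = kinds, x = exact_pts$x, y = exact_pts$y,
                      z = exact_pts$z))
  m <- match_pharmacophore(model, conf)
  expect_equal(m$matched_count, 6)
  expect_lt(max(m$assignment$deviation), 1e-9)
  # only 5 satisfiable elements with min_match 6 -> no match
  conf5 <- conformer("five",
                     tibble::tibble(element = "C", x = exact_pts$x[1:5],
                                    y = exact_pts$y[1:5],
                                    z = exact_pts$z[1:5]),
                     feature_points = tibble::tibble(
                       kind = kinds[1:5], x = exact_pts$x[1:5],
                       y = exact_pts$y[1:5], z = exact_pts$z[1:5]))
  expect_null(match_pharmacophore(model, conf5))
  expect_equal(match_pharmacophore(model, conf5, min_match = 5)$matched_count,
               5)
})

test_that("matching is invariant under rigid transforms of the conformer", {
  model <- ck1e_reference_model()
  hit <- make_conformer_library(1, model, hit_fraction = 1, seed = 6)[[1]]
  m0 <- match_pharmacophore(model, hit)
  expect_false(is.null(m0))
  set.seed(10)
  for (i in 1:5) {
    rot <- trajpharm:::random_rotation()
    shift <- runif(3, -15, 15)
    moved <- hit
    for (col in c("x", "y", "z")) moved$atoms[[col]] <- 0
    xyz <- sweep(as.matrix(hit$atoms[, c("x", "y", "z")]) %*% rot, 2,
                 shift, `+`)
    moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]
    moved$atoms$z <- xyz[, 3]
    fp <- as.matrix(hit$feature_points[, c("x", "y", "z")]) %*% rot
    fp <- sweep(fp, 2, shift, `+`)
    moved$feature_points$x <- fp[, 1]
    moved$feature_points$y <- fp[, 2]
    moved$feature_points$z <- fp[, 3]
    m <- match_pharmacophore(model, moved)
    expect_equal(m$matched_count, m0$matched_count)
    expect_equal(m$total_deviation, m0$total_deviation, tolerance = 1e-6)
  }
})

test_that("removing a model feature never decreases matched counts", {
  model <- ck1e_reference_model()
  lib <- make_conformer_library(6, model, hit_fraction = 0.5, seed = 3)
  sub <- submodel(model, "Hyd3")
  for (cf in lib) {
    m_full <- match_pharmacophore(model, cf, min_match = 1)
    m_sub <- match_pharmacophore(sub, cf, min_match = 1)
    n_full <- if (is.null(m_full)) 0L else m_full$matched_count
    n_sub <- if (is.null(m_sub)) 0L else m_sub$matched_count
    # the submodel can lose at most the dropped element
    expect_gte(n_full, n_sub)
    expect_lte(n_full - n_sub, 1L)
  }
})

test_that("molecular volume matches analytic spheres and unions", {
  single <- conformer("C", tibble::tibble(element = "C", x = 0, y = 0,
                                          z = 0))
  v1 <- molecular_volume(single)
  expect_equal(v1, 4 / 3 * pi * 1.7^3, tolerance = 0.02)
  # two disjoint spheres: additive
  two <- conformer("CC", tibble::tibble(element = "C", x = c(0, 10),
                                        y = 0, z = 0))
  expect_equal(molecular_volume(two), 2 * v1, tolerance = 0.01)
  # coincident spheres: union equals one sphere
  coin <- conformer("CC0", tibble::tibble(element = "C", x = c(0, 0),
                                          y = 0, z = 0))
  expect_equal(molecular_volume(coin), v1, tolerance = 1e-9)
  expect_error(molecular_volume(
    conformer("X", tibble::tibble(element = "XX", x = 0, y = 0, z = 0))),
    "van der Waals")
})

test_that("screen applies the volume filter before matching", {
  model <- ck1e_reference_model()
  lib <- make_conformer_library(10, model, hit_fraction = 0.1, seed = 7)
  report <- screen_library(lib, model)
  expect_equal(sum(report$compounds$verdict == "hit"), 1)
  expect_identical(report$compounds$compound[report$compounds$verdict ==
                                               "hit"], "hit_001")
  # a matching conformer whose volume exceeds the cap is eliminated with
  # reason "volume" and never reaches the matcher
  big <- lib[[1]]
  # bolt on a far-away blob of carbons to inflate the volume
  blob <- expand.grid(x = seq(30, 36, 1.5), y = seq(0, 6, 1.5),
                      z = seq(0, 6, 1.5))
  big$atoms <- dplyr::bind_rows(
    big$atoms,
    tibble::tibble(name = paste0("B", seq_len(nrow(blob))), element = "C",
                   resname = "LIG", resnum = 1L, chain = "X",
                   x = blob$x, y = blob$y, z = blob$z, is_ligand = TRUE,
                   formal_charge = 0L))
  res <- screen_library(list(big), model)
  expect_identical(res$results$verdict, "eliminated")
  expect_identical(res$results$reason, "volume")
  expect_true(res$results$volume > 270)
})

test_that("pose agreement uses the match transform without refit", {
  model <- ck1e_reference_model()
  hit <- make_conformer_library(1, model, hit_fraction = 1, seed = 9)[[1]]
  m <- match_pharmacophore(model, hit)
  placed <- apply_transform(as.matrix(hit$atoms[, c("x", "y", "z")]),
                            m$transform)
  pa <- pose_agreement(placed, m, hit)
  expect_equal(pa$rmsd, 0, tolerance = 1e-9)
  expect_true(pa$selected)
  # shifted 5.2 A: clearly different binding mode, rejected
  pa_far <- pose_agreement(sweep(placed, 2, c(5.2, 0, 0), `+`), m, hit)
  expect_equal(pa_far$rmsd, 5.2, tolerance = 1e-9)
  expect_false(pa_far$selected)
  # boundary exactly at the cutoff is rejected (strict <)
  pa_edge <- pose_agreement(sweep(placed, 2, c(1.5, 0, 0), `+`), m, hit)
  expect_false(pa_edge$selected)
  expect_error(pose_agreement(placed[-1, ], m, hit), "atom count")
})
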