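# Frame-level geometric detection of noncovalent protein-ligand contacts.
# Boundary conventions (fixed for testability): strict "<" for all distance
# cutoffs, ">=" for angle minima, "<=" for angle-deviation windows and the
# in-plane stacking offset.
#
# Each detector has an internal *_rows() collector returning plain lists;
# the exported functions convert to a tibble once per call and
# profile_trajectory() converts once per trajectory (tibble construction
# per event would dominate the frame loop otherwise).

#' Geometric criteria for interaction detection
#'
#' Defaults mirror the published defaults of the PLIP profiler: hydrogen
#' bonds by donor-acceptor distance (and donor angle when explicit
#' hydrogens are present), hydrophobic contacts between apolar carbons,
#' ring stacking by centroid distance / interplanar angle / in-plane
#' offset, salt bridges by charged-group centroid distance.
#'
#' @param hbond_max_da max donor-acceptor distance, A.
#' @param hbond_min_donor_angle min D-H...A angle at the hydrogen, deg.
#' @param hydrophobic_max max apolar C...C distance, A.
#' @param pistack_max_centroid max ring-centroid distance, A.
#' @param pistack_max_angle_dev max deviation from 0 (parallel) or 90
#'   (T-shaped) deg.
#' @param pistack_max_offset max in-plane centroid offset, A.
#' @param saltbridge_max max charged-group centroid distance, A.
#' @param pication_max max cation-to-ring-centroid distance, A.
#' @return object of class `interaction_criteria`.
#' @export
interaction_criteria <- function(hbond_max_da = 4.1,
                                 hbond_min_donor_angle = 100,
                                 hydrophobic_max = 4.0,
                                 pistack_max_centroid = 5.5,
                                 pistack_max_angle_dev = 30,
                                 pistack_max_offset = 2.0,
                                 saltbridge_max = 5.5,
                                 pication_max = 6.0) {
  crit <- list(hbond_max_da = hbond_max_da,
               hbond_min_donor_angle = hbond_min_donor_angle,
               hydrophobic_max = hydrophobic_max,
               pistack_max_centroid = pistack_max_centroid,
               pistack_max_angle_dev = pistack_max_angle_dev,
               pistack_max_offset = pistack_max_offset,
               saltbridge_max = saltbridge_max,
               pication_max = pication_max)
  if (any(unlist(crit) <= 0)) abort("all criteria must be positive")
  structure(crit, class = "interaction_criteria")
}

.empty_events <- function() .rows_to_events(list())

.event_row <- function(itype, at, prot_idx, lig_idx, distance, angle,
                       lig_role, anchor, frame = 1L,
                       partner = NULL) {
  ri <- prot_idx[1]
  list(frame = as.integer(frame), itype = itype,
       chain = at$chain[ri], resnum = at$resnum[ri],
       resname = at$resname[ri],
       distance = distance, angle = angle,
       lig_role = lig_role,
       lig_atoms = as.integer(lig_idx),
       prot_atoms = as.integer(prot_idx),
       anchor_x = anchor[1], anchor_y = anchor[2], anchor_z = anchor[3],
       chain2 = if (is.null(partner)) NA_character_ else partner$chain,
       resnum2 = if (is.null(partner)) NA_integer_ else partner$resnum,
       resname2 = if (is.null(partner)) NA_character_ else partner$resname)
}

.rows_to_events <- function(rows) {
  g <- function(f, t) vapply(rows, function(r) r[[f]], t)
  tibble::new_tibble(list(
    frame = g("frame", integer(1)), itype = g("itype", character(1)),
    chain = g("chain", character(1)), resnum = g("resnum", integer(1)),
    resname = g("resname", character(1)),
    distance = g("distance", numeric(1)), angle = g("angle", numeric(1)),
    lig_role = g("lig_role", character(1)),
    lig_atoms = lapply(rows, `[[`, "lig_atoms"),
    prot_atoms = lapply(rows, `[[`, "prot_atoms"),
    anchor_x = g("anchor_x", numeric(1)),
    anchor_y = g("anchor_y", numeric(1)),
    anchor_z = g("anchor_z", numeric(1)),
    chain2 = g("chain2", character(1)),
    resnum2 = g("resnum2", integer(1)),
    resname2 = g("resname2", character(1))), nrow = length(rows))
}

# all-pairs euclidean distance matrix between two coordinate sets
.cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

.angle_deg <- function(v1, v2) {
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# ---- row collectors --------------------------------------------------------

.hbond_rows <- function(at, coords, criteria, roles, frame) {
  out <- list()
  if (length(roles$donors) == 0 || length(roles$acceptors) == 0) {
    return(out)
  }
  dm <- .cross_dist(coords[roles$donors, , drop = FALSE],
                    coords[roles$acceptors, , drop = FALSE])
  cross <- outer(at$is_ligand[roles$donors], at$is_ligand[roles$acceptors],
                 `!=`)
  hits <- which(cross & dm < criteria$hbond_max_da, arr.ind = TRUE)
  for (k in seq_len(nrow(hits))) {
    di <- roles$donors[hits[k, 1]]
    ai <- roles$acceptors[hits[k, 2]]
    d <- dm[hits[k, 1], hits[k, 2]]
    hs <- roles$donor_h[[hits[k, 1]]]
    ang <- NA_real_
    if (length(hs) > 0) {
      angs <- vapply(hs, function(h) {
        .angle_deg(coords[di, ] - coords[h, ], coords[ai, ] - coords[h, ])
      }, numeric(1))
      ang <- max(angs)
      if (!(ang >= criteria$hbond_min_donor_angle)) next
    }
    lig_is_donor <- at$is_ligand[di]
    lig_idx <- if (lig_is_donor) di else ai
    prot_idx <- if (lig_is_donor) ai else di
    out[[length(out) + 1]] <- .event_row(
      "hbond", at, prot_idx, lig_idx, d, ang,
      lig_role = if (lig_is_donor) "donor" else "acceptor",
      anchor = coords[lig_idx, ], frame = frame)
  }
  out
}

.hydrophobic_rows <- function(at, coords, criteria, roles, frame) {
  lig_c <- roles$apolar[at$is_ligand[roles$apolar]]
  prot_c <- roles$apolar[!at$is_ligand[roles$apolar]]
  if (length(lig_c) == 0 || length(prot_c) == 0) return(list())
  dmat <- .cross_dist(coords[lig_c, , drop = FALSE],
                      coords[prot_c, , drop = FALSE])
  hits <- which(dmat < criteria$hydrophobic_max, arr.ind = TRUE)
  if (nrow(hits) == 0) return(list())
  li <- lig_c[hits[, 1]]
  pi_ <- prot_c[hits[, 2]]
  d <- dmat[hits]
  # collapse to the closest pair per protein residue
  key <- paste(at$chain[pi_], at$resnum[pi_])
  ord <- order(key, d)
  best <- ord[!duplicated(key[ord])]
  lapply(best, function(r) {
    .event_row("hydrophobic", at, pi_[r], li[r], d[r],
               NA_real_, NA_character_, coords[li[r], ], frame = frame)
  })
}

.pistack_rows <- function(at, coords, criteria, roles, frame) {
  is_lig_ring <- vapply(roles$rings, function(r) all(at$is_ligand[r]),
                        logical(1))
  lig_rings <- roles$rings[is_lig_ring]
  prot_rings <- roles$rings[!is_lig_ring]
  if (length(lig_rings) == 0 || length(prot_rings) == 0) return(list())
  out <- list()
  for (lr in lig_rings) {
    c1 <- colMeans(coords[lr, , drop = FALSE])
    n1 <- plane_normal(coords[lr, , drop = FALSE])
    for (pr in prot_rings) {
      c2 <- colMeans(coords[pr, , drop = FALSE])
      d <- sqrt(sum((c1 - c2)^2))
      if (!(d < criteria$pistack_max_centroid)) next
      n2 <- plane_normal(coords[pr, , drop = FALSE])
      ang <- .angle_deg(n1, n2)
      if (ang > 90) ang <- 180 - ang # fold normals
      if (!(ang <= criteria$pistack_max_angle_dev ||
            abs(90 - ang) <= criteria$pistack_max_angle_dev)) next
      v <- c2 - c1
      off1 <- sqrt(max(0, sum(v^2) - sum(v * n1)^2))
      off2 <- sqrt(max(0, sum(v^2) - sum(v * n2)^2))
      if (!(min(off1, off2) <= criteria$pistack_max_offset)) next
      out[[length(out) + 1]] <- .event_row(
        "pi_stack", at, pr, lr, d, ang, NA_character_, c1, frame = frame)
    }
  }
  out
}

.saltbridge_rows <- function(at, coords, criteria, roles, frame,
                             pairs = "ligand-protein") {
  cg <- roles$charge_groups
  if (nrow(cg) < 2) return(list())
  is_lig <- vapply(cg$atoms, function(ix) all(at$is_ligand[ix]), logical(1))
  cent <- t(vapply(cg$atoms, function(ix) {
    colMeans(coords[ix, , drop = FALSE])
  }, numeric(3)))
  out <- list()
  for (a in seq_len(nrow(cg) - 1)) {
    for (b in seq((a + 1), nrow(cg))) {
      if (cg$sign[a] * cg$sign[b] >= 0) next # opposite signs only
      cross <- xor(is_lig[a], is_lig[b])
      if (pairs == "ligand-protein" && !cross) next
      if (!cross && is_lig[a]) next # ligand-ligand never
      d <- sqrt(sum((cent[a, ] - cent[b, ])^2))
      if (!(d < criteria$saltbridge_max)) next
      if (cross) {
        li <- if (is_lig[a]) a else b
        pi_ <- if (is_lig[a]) b else a
        out[[length(out) + 1]] <- .event_row(
          "salt_bridge", at, cg$atoms[[pi_]], cg$atoms[[li]], d, NA_real_,
          NA_character_, cent[li, ], frame = frame)
      } else {
        out[[length(out) + 1]] <- .event_row(
          "salt_bridge", at, cg$atoms[[a]], integer(), d, NA_real_,
          NA_character_, cent[a, ], frame = frame,
          partner = list(chain = cg$chain[b], resnum = cg$resnum[b],
                         resname = cg$resname[b]))
      }
    }
  }
  out
}

.pication_rows <- function(at, coords, criteria, roles, frame) {
  cg <- roles$charge_groups
  cations <- which(cg$sign > 0)
  if (length(cations) == 0 || length(roles$rings) == 0) return(list())
  out <- list()
  for (ci in cations) {
    c_atoms <- cg$atoms[[ci]]
    c_is_lig <- all(at$is_ligand[c_atoms])
    cc <- colMeans(coords[c_atoms, , drop = FALSE])
    for (ring in roles$rings) {
      r_is_lig <- all(at$is_ligand[ring])
      if (c_is_lig == r_is_lig) next
      rc <- colMeans(coords[ring, , drop = FALSE])
      d <- sqrt(sum((cc - rc)^2))
      if (!(d < criteria$pication_max)) next
      lig_idx <- if (c_is_lig) c_atoms else ring
      prot_idx <- if (c_is_lig) ring else c_atoms
      anchor <- if (c_is_lig) cc else rc
      out[[length(out) + 1]] <- .event_row(
        "pi_cation", at, prot_idx, lig_idx, d, NA_real_, NA_character_,
        anchor, frame = frame)
    }
  }
  out
}

.frame_rows <- function(topology, coords, criteria, roles, frame,
                        include_pication = FALSE) {
  at <- topology$atoms
  rows <- c(.hbond_rows(at, coords, criteria, roles, frame),
            .hydrophobic_rows(at, coords, criteria, roles, frame),
            .pistack_rows(at, coords, criteria, roles, frame),
            .saltbridge_rows(at, coords, criteria, roles, frame))
  if (include_pication) {
    rows <- c(rows, .pication_rows(at, coords, criteria, roles, frame))
  }
  rows
}

# ---- exported detectors ----------------------------------------------------

#' Detect hydrogen bonds in one frame
#'
#' Donor-acceptor pairs across the protein/ligand boundary with distance
#' below the cutoff; when the donor carries explicit hydrogens the
#' D-H...A angle at the hydrogen must also reach the minimum. Without
#' explicit hydrogens the heavy-atom distance criterion alone applies.
#'
#' @param topology a `topology`.
#' @param coords n x 3 coordinate matrix (default: topology coordinates).
#' @param criteria an [interaction_criteria()].
#' @param roles precomputed [atom_roles()] (recomputed when NULL).
#' @param frame frame index stamped on events.
#' @return tibble of interaction events (possibly empty), one row per
#'   qualifying donor-acceptor pair, with the ligand-side role and anchor
#'   position recorded.
#' @export
detect_hbonds <- function(topology, coords = NULL,
                          criteria = interaction_criteria(),
                          roles = NULL, frame = 1L) {
  if (is.null(coords)) coords <- topology_coords(topology)
  if (is.null(roles)) roles <- atom_roles(topology, coords)
  .rows_to_events(.hbond_rows(topology$atoms, coords, criteria, roles,
                              frame))
}

#' Detect hydrophobic contacts in one frame
#'
#' Apolar carbons (carbon bonded only to carbon or hydrogen; template
#' side-chain carbons on the protein side) of the ligand within the
#' cutoff of apolar protein carbons. Contacts with one residue collapse
#' to a single event recording the closest atom pair.
#'
#' @inheritParams detect_hbonds
#' @return tibble of events, at most one per protein residue.
#' @export
detect_hydrophobic <- function(topology, coords = NULL,
                               criteria = interaction_criteria(),
                               roles = NULL, frame = 1L) {
  if (is.null(coords)) coords <- topology_coords(topology)
  if (is.null(roles)) roles <- atom_roles(topology, coords)
  .rows_to_events(.hydrophobic_rows(topology$atoms, coords, criteria, roles,
                                    frame))
}

#' Detect ring-stacking interactions in one frame
#'
#' Ligand ring vs protein ring: centroid distance below the cutoff,
#' interplanar angle within the allowed deviation of 0 deg (parallel) or
#' 90 deg (T-shaped), and in-plane centroid offset (smaller of the two
#' projections) within the offset cap. Parallel and T-shaped geometries
#' are reported as one `pi_stack` type.
#'
#' @inheritParams detect_hbonds
#' @return tibble of events, one per qualifying ring pair.
#' @export
detect_pistack <- function(topology, coords = NULL,
                           criteria = interaction_criteria(),
                           roles = NULL, frame = 1L) {
  if (is.null(coords)) coords <- topology_coords(topology)
  if (is.null(roles)) roles <- atom_roles(topology, coords)
  .rows_to_events(.pistack_rows(topology$atoms, coords, criteria, roles,
                                frame))
}

#' Detect salt bridges in one frame
#'
#' Charged-group centroids of opposite sign within the cutoff. Groups are
#' residue templates on the protein side (Lys/Arg cations, Asp/Glu
#' carboxylates) and formally charged atoms on the ligand side.
#'
#' @inheritParams detect_hbonds
#' @param pairs `"ligand-protein"` (default) restricts to cross-boundary
#'   bridges; `"all"` also reports protein-protein bridges (partner
#'   residue in `chain2`/`resnum2`/`resname2`).
#' @return tibble of events, one per qualifying group pair.
#' @export
detect_saltbridge <- function(topology, coords = NULL,
                              criteria = interaction_criteria(),
                              roles = NULL, frame = 1L,
                              pairs = c("ligand-protein", "all")) {
  pairs <- match.arg(pairs)
  if (is.null(coords)) coords <- topology_coords(topology)
  if (is.null(roles)) roles <- atom_roles(topology, coords)
  .rows_to_events(.saltbridge_rows(topology$atoms, coords, criteria, roles,
                                   frame, pairs = pairs))
}

#' Detect cation-pi interactions in one frame
#'
#' Charged cation group centroid within the cutoff of an aromatic ring
#' centroid across the protein/ligand boundary. Not part of the default
#' [detect_frame()] union; enable there with `include_pication = TRUE`.
#'
#' @inheritParams detect_hbonds
#' @return tibble of events.
#' @export
detect_pication <- function(topology, coords = NULL,
                            criteria = interaction_criteria(),
                            roles = NULL, frame = 1L) {
  if (is.null(coords)) coords <- topology_coords(topology)
  if (is.null(roles)) roles <- atom_roles(topology, coords)
  .rows_to_events(.pication_rows(topology$atoms, coords, criteria, roles,
                                 frame))
}

#' Detect all interactions in one frame
#'
#' Union of the hydrogen-bond, hydrophobic, ring-stacking and salt-bridge
#' detectors, each event stamped with the frame index.
#'
#' @inheritParams detect_hbonds
#' @param include_pication also run the cation-pi detector.
#' @return tibble of events.
#' @examples
#' pocket <- make_pocket()
#' detect_frame(pocket)
#' @export
detect_frame <- function(topology, coords = NULL,
                         criteria = interaction_criteria(),
                         roles = NULL, frame = 1L,
                         include_pication = FALSE) {
  if (is.null(coords)) coords <- topology_coords(topology)
  if (is.null(roles)) roles <- atom_roles(topology, coords)
  .rows_to_events(.frame_rows(topology, coords, criteria, roles, frame,
                              include_pication))
}

#' Write interaction events to CSV
#'
#' Flattens list-columns (atom index sets become `;`-separated strings).
#'
#' @param events events tibble from the detectors.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  flat <- mutate(events,
                 lig_atoms = map_chr(.data$lig_atoms, paste, collapse = ";"),
                 prot_atoms = map_chr(.data$prot_atoms, paste, collapse = ";"))
  write.csv(flat, path, row.names = FALSE)
  invisible(path)
}
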