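# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. Oracles use plain nested loops and formulas,
# deliberately avoiding the package's vectorized code paths.

ang_deg_oracle <- function(v1, v2) {
  acos(min(1, max(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
}

# hydrogen bonds: all donor x acceptor pairs, plain loops
hbond_oracle <- function(top, coords, roles, crit) {
  at <- top$atoms
  out <- list()
  for (k in seq_along(roles$donors)) {
    di <- roles$donors[k]
    for (ai in roles$acceptors) {
      if (at$is_ligand[di] == at$is_ligand[ai]) next
      d <- sqrt(sum((coords[di, ] - coords[ai, ])^2))
      if (d >= crit$hbond_max_da) next
      hs <- roles$donor_h[[k]]
      if (length(hs) > 0) {
        best <- -Inf
        for (h in hs) {
          best <- max(best, ang_deg_oracle(coords[di, ] - coords[h, ],
                                           coords[ai, ] - coords[h, ]))
        }
        if (best < crit$hbond_min_donor_angle) next
      }
      prot <- if (at$is_ligand[di]) ai else di
      out[[length(out) + 1]] <- data.frame(
        itype = "hbond", resnum = at$resnum[prot], distance = d)
    }
  }
  do.call(rbind, c(out, list(data.frame(itype = character(),
                                        resnum = integer(),
                                        distance = double()))))
}

# hydrophobic: apolar pairs, closest per residue
hydrophobic_oracle <- function(top, coords, roles, crit) {
  at <- top$atoms
  res_best <- list()
  for (li in roles$apolar) {
    if (!at$is_ligand[li]) next
    for (pi_ in roles$apolar) {
      if (at$is_ligand[pi_]) next
      d <- sqrt(sum((coords[li, ] - coords[pi_, ])^2))
      if (d >= crit$hydrophobic_max) next
      key <- paste(at$chain[pi_], at$resnum[pi_])
      if (is.null(res_best[[key]]) || d < res_best[[key]]$distance) {
        res_best[[key]] <- data.frame(itype = "hydrophobic",
                                      resnum = at$resnum[pi_], distance = d)
      }
    }
  }
  do.call(rbind, c(unname(res_best),
                   list(data.frame(itype = character(), resnum = integer(),
                                   distance = double()))))
}

# salt bridges: opposite-sign group centroid pairs (ligand-protein)
saltbridge_oracle <- function(top, coords, roles, crit) {
  at <- top$atoms
  cg <- roles$charge_groups
  out <- list()
  if (nrow(cg) >= 2) {
    for (a in 1:(nrow(cg) - 1)) {
      for (b in (a + 1):nrow(cg)) {
        la <- all(at$is_ligand[cg$atoms[[a]]])
        lb <- all(at$is_ligand[cg$atoms[[b]]])
        if (la == lb) next
        if (cg$sign[a] * cg$sign[b] >= 0) next
        ca <- colMeans(coords[cg$atoms[[a]], , drop = FALSE])
        cb <- colMeans(coords[cg$atoms[[b]], , drop = FALSE])
        d <- sqrt(sum((ca - cb)^2))
        if (d >= crit$saltbridge_max) next
        prot <- if (la) b else a
        out[[length(out) + 1]] <- data.frame(
          itype = "salt_bridge", resnum = cg$resnum[prot], distance = d)
      }
    }
  }
  do.call(rbind, c(out, list(data.frame(itype = character(),
                                        resnum = integer(),
                                        distance = double()))))
}

# ring stacking for a single ligand-ring / protein-ring pair, with the
# normal from an edge cross product rather than an SVD plane fit
pistack_oracle_pair <- function(lig_ring_xyz, prot_ring_xyz, crit) {
  ctr1 <- colMeans(lig_ring_xyz)
  ctr2 <- colMeans(prot_ring_xyz)
  edge_normal <- function(xyz, ctr) {
    v1 <- xyz[1, ] - ctr
    v2 <- xyz[2, ] - ctr
    n <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
    n / sqrt(sum(n^2))
  }
  n1 <- edge_normal(lig_ring_xyz, ctr1)
  n2 <- edge_normal(prot_ring_xyz, ctr2)
  d <- sqrt(sum((ctr1 - ctr2)^2))
  if (d >= crit$pistack_max_centroid) return(FALSE)
  ang <- ang_deg_oracle(n1, n2)
  if (ang > 90) ang <- 180 - ang
  if (!(ang <= crit$pistack_max_angle_dev ||
        abs(90 - ang) <= crit$pistack_max_angle_dev)) return(FALSE)
  v <- ctr2 - ctr1
  off1 <- sqrt(max(0, sum(v^2) - sum(v * n1)^2))
  off2 <- sqrt(max(0, sum(v^2) - sum(v * n2)^2))
  min(off1, off2) <= crit$pistack_max_offset
}

# complete-linkage cutoff clustering via stats::hclust (independent route)
hclust_oracle <- function(m, cutoff) {
  hc <- stats::hclust(stats::as.dist(m), method = "complete")
  # strict "<": a merge at exactly the cutoff must be excluded
  grp <- stats::cutree(hc, h = cutoff * (1 - 1e-9))
  unname(split(seq_along(grp), grp))
}

# canonical form of a partition for comparison
canon_partition <- function(clusters) {
  sets <- lapply(clusters, function(x) sort(unlist(x)))
  sets[order(vapply(sets, min, numeric(1)))]
}

# exhaustive pharmacophore assignment search (no pruning): best matched
# count over all injective kind-compatible assignments passing the
# radius check after a rigid fit
match_oracle <- function(model, pts, min_match) {
  positions <- trajpharm:::.model_positions(model)
  g <- length(positions)
  centers <- t(vapply(positions, `[[`, numeric(3), "center"))
  radii <- vapply(positions, `[[`, numeric(1), "radius")
  pxyz <- as.matrix(pts[, c("x", "y", "z")])
  best <- 0L
  assignments <- function(slots, avail) {
    # all injective assignments of point indices to the given slots
    if (length(slots) == 0) return(list(integer()))
    res <- list()
    for (p in avail) {
      if (!pts$kind[p] %in% positions[[slots[1]]]$kinds) next
      for (rest in assignments(slots[-1], setdiff(avail, p))) {
        res[[length(res) + 1]] <- c(p, rest)
      }
    }
    res
  }
  for (k in seq(g, min_match)) {
    for (subset in utils::combn(g, k, simplify = FALSE)) {
      for (asg in assignments(subset, seq_len(nrow(pts)))) {
        fit <- kabsch_fit(pxyz[asg, , drop = FALSE],
                          centers[subset, , drop = FALSE])
        moved <- apply_transform(pxyz[asg, , drop = FALSE], fit)
        dev <- sqrt(rowSums((moved - centers[subset, , drop = FALSE])^2))
        if (all(dev <= radii[subset])) best <- max(best, k)
      }
      if (best == g) break
    }
    if (best >= k) break # larger k already found
  }
  if (best >= min_match) best else NA_integer_
}

# Horn quaternion superposition: minimal RMSD from the largest eigenvalue
# of the 4x4 key matrix (fully independent of the Kabsch/SVD route)
quaternion_rmsd <- function(moving, fixed) {
  a <- sweep(moving, 2, colMeans(moving))
  b <- sweep(fixed, 2, colMeans(fixed))
  s <- crossprod(a, b)
  k4 <- matrix(c(
    s[1, 1] + s[2, 2] + s[3, 3], s[2, 3] - s[3, 2],
    s[3, 1] - s[1, 3], s[1, 2] - s[2, 1],
    s[2, 3] - s[3, 2], s[1, 1] - s[2, 2] - s[3, 3],
    s[1, 2] + s[2, 1], s[3, 1] + s[1, 3],
    s[3, 1] - s[1, 3], s[1, 2] + s[2, 1],
    -s[1, 1] + s[2, 2] - s[3, 3], s[2, 3] + s[3, 2],
    s[1, 2] - s[2, 1], s[3, 1] + s[1, 3],
    s[2, 3] + s[3, 2], -s[1, 1] - s[2, 2] + s[3, 3]), 4, 4, byrow = TRUE)
  lam <- max(eigen(k4, symmetric = TRUE)$values)
  sqrt(max(0, (sum(a^2) + sum(b^2) - 2 * lam) / nrow(a)))
}

# ---- fixture builders ------------------------------------------------------

# pocket with all coordinates scrambled uniformly in a box: contacts form
# and break at random, giving varied oracle instances
scrambled_pocket <- function(seed, box = 8) {
  pocket <- make_pocket()
  set.seed(seed)
  n <- nrow(pocket$atoms)
  coords <- matrix(runif(n * 3, -box, box), n, 3)
  list(topology = pocket, coords = coords)
}

# two rigid hexagonal rings (ligand benzene + protein PHE) in a random
# relative pose for the stacking oracle
ring_pair_fixture <- function(seed) {
  set.seed(seed)
  hexagon <- function(phase = 0) {
    k <- 0:5
    cbind(1.39 * cos(phase + k * pi / 3), 1.39 * sin(phase + k * pi / 3),
          0)
  }
  lig_xyz <- hexagon()
  rot <- trajpharm:::random_rotation()
  shift <- c(runif(2, -2.5, 2.5), runif(1, 0, 6.5))
  prot_xyz <- sweep(hexagon(runif(1, 0, pi / 3)) %*% rot, 2, shift, `+`)
  atoms <- rbind(
    tibble::tibble(name = paste0("C", 1:6), element = "C", resname = "LIG",
                   resnum = 1L, chain = "L",
                   x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
                   is_ligand = TRUE),
    tibble::tibble(name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                   element = "C", resname = "PHE", resnum = 20L, chain = "A",
                   x = prot_xyz[, 1], y = prot_xyz[, 2], z = prot_xyz[, 3],
                   is_ligand = FALSE))
  bonds <- tibble::tibble(i = 1:6, j = c(2:6, 1))
  list(topology = topology(atoms, bonds), lig_xyz = lig_xyz,
       prot_xyz = prot_xyz)
}

# random pose set for clustering oracles: n poses of a 5-atom ligand
# scattered so cluster structure varies
random_pose_set <- function(seed, n = 30) {
  set.seed(seed)
  atoms <- tibble::tibble(name = paste0("C", 1:5), element = "C",
                          resname = "LIG", resnum = 1L, chain = "L",
                          x = 0, y = 0, z = 0)
  base <- matrix(rnorm(15), 5, 3)
  coords <- array(0, dim = c(5, 3, n))
  for (k in seq_len(n)) {
    coords[, , k] <- base + matrix(rep(runif(3, -4, 4), each = 5), 5, 3) +
      matrix(rnorm(15, sd = 0.3), 5, 3)
  }
  pose_set(atoms, coords, labels = paste0("p", seq_len(n)))
}

# random matcher instance: small model (4 positions) and a point cloud
# built from a noisy subset of the centers plus scatter
random_match_instance <- function(seed) {
  set.seed(seed)
  centers <- matrix(runif(12, -4, 4), 4, 3)
  kinds <- sample(c("HBA", "HBD", "Aro", "Hyd"), 4, replace = TRUE)
  model <- pharmacophore_model(
    tibble::tibble(name = paste0("F", 1:4), kind = kinds,
                   x = centers[, 1], y = centers[, 2], z = centers[, 3],
                   radius = 1.0),
    min_match = 3)
  n_good <- sample(0:4, 1)
  good <- if (n_good > 0) sample(4, n_good) else integer()
  n_scatter <- sample(1:3, 1)
  pts_xyz <- rbind(
    centers[good, , drop = FALSE] +
      matrix(rnorm(n_good * 3, sd = 0.45), ncol = 3),
    matrix(runif(n_scatter * 3, -8, 8), ncol = 3))
  pts_kind <- c(kinds[good], sample(c("HBA", "HBD", "Aro", "Hyd"),
                                    n_scatter, replace = TRUE))
  # random rigid scramble (matching is invariant to it)
  rot <- trajpharm:::random_rotation()
  pts_xyz <- sweep(pts_xyz %*% rot, 2, runif(3, -3, 3), `+`)
  pts <- tibble::tibble(kind = pts_kind, x = pts_xyz[, 1], y = pts_xyz[, 2],
                        z = pts_xyz[, 3])
  conf <- conformer("probe",
                    tibble::tibble(element = "C", x = pts$x, y = pts$y,
                                   z = pts$z),
                    feature_points = pts)
  list(model = model, conf = conf, pts = pts)
}

expect_same_events <- function(a, b) {
  key <- function(e) {
    e <- e[order(e$itype, e$resnum, round(e$distance, 6)), ]
    paste(e$itype, e$resnum, round(e$distance, 6))
  }
  expect_identical(key(as.data.frame(a)), key(as.data.frame(b)))
}
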