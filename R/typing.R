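# Atom role perception. Protein atoms are typed from residue templates
# (PDB input usually lacks hydrogens and reliable CONECT records); ligand
# atoms are typed from their bond graph. Rings on the ligand side are
# cycles of the bond graph accepted as aromatic when planar within 0.3 A
# RMS of the best-fit plane.

.adjacency <- function(n, bonds) {
  adj <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$i[k]; j <- bonds$j[k]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# small-ring perception: for every edge, shortest alternative path between
# its endpoints; cycles of size 5 or 6 kept, deduplicated by atom set
.find_rings <- function(n, bonds, max_size = 6) {
  if (nrow(bonds) == 0) return(list())
  adj <- .adjacency(n, bonds)
  seen <- character()
  rings <- list()
  for (k in seq_len(nrow(bonds))) {
    u <- bonds$i[k]; v <- bonds$j[k]
    # BFS from u to v avoiding the direct edge
    prev <- rep(NA_integer_, n)
    dist <- rep(Inf, n)
    dist[u] <- 0
    queue <- u
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      if (dist[cur] >= max_size - 1) next
      for (nb in adj[[cur]]) {
        if (cur == u && nb == v) next
        if (is.infinite(dist[nb])) {
          dist[nb] <- dist[cur] + 1
          prev[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
    if (is.finite(dist[v])) {
      path <- v
      while (path[1] != u) path <- c(prev[path[1]], path)
      if (length(path) >= 5 && length(path) <= max_size) {
        key <- paste(sort(path), collapse = "-")
        if (!key %in% seen) {
          seen <- c(seen, key)
          rings[[length(rings) + 1]] <- path
        }
      }
    }
  }
  rings
}

#' Perceive donor/acceptor/apolar/aromatic/charged roles for all atoms
#'
#' Protein-side roles come from residue-name templates for the 20 standard
#' amino acids (backbone N donor, backbone O acceptor, plus side-chain
#' table); ligand-side roles come from the bond graph: N/O bearing an
#' explicit hydrogen are donors, non-quaternary N and all O are acceptors,
#' carbons bonded only to C/H are apolar, and planar 5/6-cycles are
#' aromatic rings. When the ligand carries no explicit hydrogens at all,
#' under-valent N/O are treated as (implicit-H) donors.
#'
#' @param topology a `topology`.
#' @param coords optional n x 3 matrix for ring-planarity checks (defaults
#'   to the topology's stored coordinates).
#' @return a list of roles, each an index vector or list: `donors`
#'   (integer), `donor_h` (list of H indices per donor), `acceptors`,
#'   `apolar`, `rings` (list of atom-index vectors), `charge_groups`
#'   (tibble: `sign`, `atoms` list-column, `chain`, `resnum`, `resname`).
#' @export
atom_roles <- function(topology, coords = NULL) {
  at <- topology$atoms
  n <- nrow(at)
  if (is.null(coords)) coords <- topology_coords(topology)
  adj <- .adjacency(n, topology$bonds)
  lig <- at$is_ligand
  has_bond <- lengths(adj) > 0

  donors <- integer()
  donor_h <- list()
  acceptors <- integer()
  apolar <- integer()

  # ligand side: graph rules
  lig_idx <- which(lig)
  lig_has_h <- any(at$element[lig_idx] == "H")
  for (i in lig_idx) {
    el <- at$element[i]
    nbrs <- adj[[i]]
    nbr_el <- at$element[nbrs]
    if (el %in% c("N", "O")) {
      hs <- as.integer(nbrs[nbr_el == "H"])
      is_donor <- length(hs) > 0
      if (!lig_has_h && !is_donor) {
        # implicit-hydrogen fallback: under-valent N/O can donate
        heavy_deg <- sum(nbr_el != "H")
        is_donor <- (el == "N" && heavy_deg < 3) || (el == "O" && heavy_deg < 2)
      }
      if (is_donor) {
        donors <- c(donors, i)
        donor_h[[length(donor_h) + 1]] <- hs
      }
      if (el == "O" || (el == "N" && length(nbrs) < 4)) {
        acceptors <- c(acceptors, i)
      }
    } else if (el == "C" && has_bond[i] &&
               all(nbr_el %in% c("C", "H"))) {
      apolar <- c(apolar, i)
    }
  }

  # protein side: templates
  prot <- which(!lig & at$element != "H")
  for (i in prot) {
    rn <- at$resname[i]
    nm <- at$name[i]
    if (!rn %in% .standard_residues) next
    if (nm == "N") { # backbone amide
      donors <- c(donors, i); donor_h[[length(donor_h) + 1]] <- integer()
    }
    if (nm %in% c("O", "OXT")) acceptors <- c(acceptors, i)
    if (nm %in% (.template_donors[[rn]] %||% character())) {
      donors <- c(donors, i); donor_h[[length(donor_h) + 1]] <- integer()
    }
    if (nm %in% (.template_acceptors[[rn]] %||% character())) {
      acceptors <- c(acceptors, i)
    }
    if (nm %in% (.template_apolar[[rn]] %||% character())) {
      apolar <- c(apolar, i)
    }
  }

  # rings: ligand from graph + planarity, protein from templates
  rings <- list()
  lig_bonds <- topology$bonds[lig[topology$bonds$i] & lig[topology$bonds$j], ]
  for (ring in .find_rings(n, lig_bonds)) {
    if (plane_rms(coords[ring, , drop = FALSE]) <= 0.3) {
      rings[[length(rings) + 1]] <- ring
    }
  }
  res_tab <- distinct(at[!lig, c("chain", "resnum", "resname")])
  if (nrow(res_tab) > 0) {
    for (r in seq_len(nrow(res_tab))) {
      tmpl <- .template_rings[[res_tab$resname[r]]]
      if (is.null(tmpl)) next
      in_res <- which(!lig & at$chain == res_tab$chain[r] &
                        at$resnum == res_tab$resnum[r])
      for (ring_names in tmpl) {
        idx <- in_res[match(ring_names, at$name[in_res])]
        if (!anyNA(idx)) rings[[length(rings) + 1]] <- idx
      }
    }
  }

  # charged groups
  cg <- list()
  if (nrow(res_tab) > 0) {
    for (r in seq_len(nrow(res_tab))) {
      tmpl <- .template_charges[[res_tab$resname[r]]]
      if (is.null(tmpl)) next
      in_res <- which(!lig & at$chain == res_tab$chain[r] &
                        at$resnum == res_tab$resnum[r])
      for (grp in tmpl) {
        idx <- in_res[match(grp$atoms, at$name[in_res])]
        idx <- idx[!is.na(idx)]
        if (length(idx) > 0) {
          cg[[length(cg) + 1]] <- tibble(
            sign = grp$sign, atoms = list(idx),
            chain = res_tab$chain[r], resnum = res_tab$resnum[r],
            resname = res_tab$resname[r])
        }
      }
    }
  }
  for (i in lig_idx[at$formal_charge[lig_idx] != 0L]) {
    cg[[length(cg) + 1]] <- tibble(
      sign = as.integer(sign(at$formal_charge[i])), atoms = list(i),
      chain = at$chain[i], resnum = at$resnum[i], resname = at$resname[i])
  }
  charge_groups <- if (length(cg) > 0) bind_rows(cg) else
    tibble(sign = integer(), atoms = list(), chain = character(),
           resnum = integer(), resname = character())

  list(donors = donors, donor_h = donor_h, acceptors = acceptors,
       apolar = apolar, rings = rings, charge_groups = charge_groups)
}
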