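# Trajectory-level analytics: occurrence profiles, backbone RMSD series,
# C-alpha RMSF, salt-bridge prevalence.

#' Dynamic noncovalent interaction profile of a trajectory
#'
#' Runs the frame detector on every frame and counts, for each (residue,
#' interaction type) pair, the number of frames showing at least one
#' qualifying event. Occurrence is defined over frames, not event
#' multiplicity: several hydrogen bonds to one residue in one frame count
#' that frame once.
#'
#' @param traj an `md_trajectory` with a non-empty ligand selection.
#' @param criteria an [interaction_criteria()].
#' @param include_pication also count cation-pi events.
#' @param keep_events retain the full event tibble (needed by
#'   [build_features()]).
#' @return object of class `interaction_profile`: a counts tibble
#'   (`chain`, `resnum`, `resname`, `itype`, `count`), `total_frames`,
#'   and optionally `events`.
#' @examples
#' traj <- make_trajectory(plant_spec(n_frames = 20, seed = 1))
#' profile_trajectory(traj)
#' @export
profile_trajectory <- function(traj, criteria = interaction_criteria(),
                               include_pication = FALSE,
                               keep_events = FALSE) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (length(ligand_indices(traj$topology)) == 0) {
    abort("trajectory topology has no ligand selection")
  }
  roles <- atom_roles(traj$topology)
  nf <- n_frames(traj)
  rows <- vector("list", nf)
  for (k in seq_len(nf)) {
    rows[[k]] <- .frame_rows(traj$topology, frame_coords(traj, k), criteria,
                             roles, frame = k,
                             include_pication = include_pication)
  }
  events <- .rows_to_events(unlist(rows, recursive = FALSE, use.names = FALSE))
  if (nrow(events) == 0) {
    counts <- tibble(chain = character(), resnum = integer(),
                     resname = character(), itype = character(),
                     count = integer())
  } else {
    counts <- events |>
      distinct(.data$frame, .data$chain, .data$resnum, .data$resname,
               .data$itype) |>
      dplyr::count(.data$chain, .data$resnum, .data$resname, .data$itype,
                   name = "count") |>
      arrange(desc(.data$count))
  }
  structure(list(counts = counts, total_frames = nf,
                 criteria = criteria,
                 events = if (keep_events) events else NULL),
            class = "interaction_profile")
}

#' @export
print.interaction_profile <- function(x, ...) {
  cat("<interaction_profile> ", nrow(x$counts), " (residue, type) cells over ",
      x$total_frames, " frames\n", sep = "")
  if (nrow(x$counts) > 0) print(tidy(x), n = 10)
  invisible(x)
}

#' Occurrence percentage of an interaction
#'
#' `100 * count / total_frames`, rounded half away from zero to two
#' decimals (the convention that reproduces printed occurrences such as
#' 3239/15000 = 21.59).
#'
#' @param count frames with the interaction present.
#' @param total_frames total frames analyzed.
#' @return percentage, 2 decimals.
#' @examples
#' occurrence_percent(14998, 15000) # 99.99
#' @export
occurrence_percent <- function(count, total_frames) {
  if (any(total_frames == 0)) abort("total_frames must be positive")
  if (any(count < 0 | count > total_frames)) {
    abort("count must lie in [0, total_frames]")
  }
  round_half_away(100 * count / total_frames, 2)
}

#' Interactions above the relevance threshold
#'
#' Cells of a profile whose occurrence is strictly greater than the
#' threshold (default 20% of simulation time), sorted by decreasing
#' occurrence. A cell at exactly the threshold is excluded.
#'
#' @param profile an `interaction_profile`.
#' @param threshold_percent relevance threshold, percent.
#' @return tibble (`chain`, `resnum`, `resname`, `itype`, `count`,
#'   `percent`).
#' @export
relevant_interactions <- function(profile, threshold_percent = 20) {
  stopifnot(inherits(profile, "interaction_profile"))
  out <- profile$counts |>
    mutate(exact = 100 * .data$count / profile$total_frames,
           percent = occurrence_percent(.data$count, profile$total_frames)) |>
    filter(.data$exact > threshold_percent) |>
    arrange(desc(.data$exact)) |>
    select(-"exact")
  out
}

# backbone atom indices per residue, with per-residue completeness check
.backbone_indices <- function(topology, require_all = TRUE) {
  at <- topology$atoms
  bb_names <- c("N", "CA", "C", "O")
  prot <- !at$is_ligand & at$resname %in% .standard_residues
  idx <- which(prot & at$name %in% bb_names)
  if (require_all) {
    chk <- at[prot, ] |>
      group_by(.data$chain, .data$resnum) |>
      summarise(ok = all(bb_names %in% .data$name), .groups = "drop")
    bad <- chk[!chk$ok, ]
    if (nrow(bad) > 0) {
      abort(paste0("missing backbone atoms in residue ",
                   bad$chain[1], ":", bad$resnum[1]))
    }
  }
  idx
}

#' Backbone RMSD series of a trajectory
#'
#' Each frame is optimally superposed (least-squares rigid fit) onto the
#' reference frame over protein backbone atoms (N, CA, C, O), then the
#' RMSD over those atoms is reported.
#'
#' @param traj an `md_trajectory`.
#' @param reference_frame frame index used as reference (default 1, the
#'   first production frame).
#' @param superpose set FALSE to skip the rigid fit (diagnostic).
#' @return a `series_result` with one value per frame (A).
#' @export
backbone_rmsd_series <- function(traj, reference_frame = 1,
                                 superpose = TRUE) {
  bb <- .backbone_indices(traj$topology)
  if (length(bb) == 0) abort("no backbone atoms found")
  ref <- frame_coords(traj, reference_frame)[bb, , drop = FALSE]
  vals <- map_dbl(seq_len(n_frames(traj)), function(k) {
    x <- frame_coords(traj, k)[bb, , drop = FALSE]
    if (superpose) kabsch_fit(x, ref)$rmsd else coord_rmsd(x, ref)
  })
  structure(list(values = vals, kind = "rmsd",
                 index = tibble(frame = seq_len(n_frames(traj))),
                 reference = paste0("frame ", reference_frame,
                                    if (!superpose) " (no superposition)")),
            class = "series_result")
}

#' Per-residue C-alpha RMSF of a trajectory
#'
#' Frames are superposed on the time-average structure over backbone
#' atoms (two refinement passes: align to the first frame, average,
#' re-align to the average, re-average), then the root-mean-square
#' fluctuation of each C-alpha about its mean position is reported.
#'
#' @param traj an `md_trajectory`.
#' @param superpose set FALSE to compute fluctuations in the raw frame
#'   (used by closed-form checks).
#' @return a `series_result` with one value per residue (A); the index
#'   tibble carries `chain`, `resnum`, `resname`.
#' @export
rmsf_per_residue <- function(traj, superpose = TRUE) {
  at <- traj$topology$atoms
  prot <- !at$is_ligand & at$resname %in% .standard_residues
  res_tab <- distinct(at[prot, c("chain", "resnum", "resname")])
  ca <- integer(nrow(res_tab))
  for (r in seq_len(nrow(res_tab))) {
    hit <- which(prot & at$chain == res_tab$chain[r] &
                   at$resnum == res_tab$resnum[r] & at$name == "CA")
    if (length(hit) != 1) {
      abort(paste0("missing CA in residue ", res_tab$chain[r], ":",
                   res_tab$resnum[r]))
    }
    ca[r] <- hit
  }
  nf <- n_frames(traj)
  aligned <- array(0, dim = dim(traj$coords))
  if (superpose) {
    bb <- .backbone_indices(traj$topology)
    ref <- frame_coords(traj, 1)[bb, , drop = FALSE]
    for (pass in 1:2) {
      for (k in seq_len(nf)) {
        x <- frame_coords(traj, k)
        fit <- kabsch_fit(x[bb, , drop = FALSE], ref)
        aligned[, , k] <- apply_transform(x, fit)
      }
      ref <- apply(aligned, c(1, 2), mean)[bb, , drop = FALSE]
    }
  } else {
    aligned <- traj$coords
  }
  mean_pos <- apply(aligned[ca, , , drop = FALSE], c(1, 2), mean)
  vals <- map_dbl(seq_along(ca), function(r) {
    dev <- sweep(t(aligned[ca[r], , ]), 2, mean_pos[r, ])
    sqrt(mean(rowSums(dev^2)))
  })
  structure(list(values = vals, kind = "rmsf", index = res_tab,
                 reference = paste0("time-average structure",
                                    if (!superpose) " (no superposition)")),
            class = "series_result")
}

#' @export
print.series_result <- function(x, ...) {
  cat("<series_result> ", x$kind, ", ", length(x$values),
      " values; reference: ", x$reference, "\n", sep = "")
  invisible(x)
}

#' Salt-bridge prevalence between two residues
#'
#' Percentage of frames in which the charged-group centroids of two
#' residues of opposite charge lie within the salt-bridge cutoff.
#'
#' @param traj an `md_trajectory`.
#' @param res_a,res_b residue selectors: list/vector with `chain` and
#'   `resnum` (e.g. `c(chain = "A", resnum = 38)`).
#' @param criteria an [interaction_criteria()].
#' @return prevalence percent (2 decimals).
#' @export
salt_bridge_prevalence <- function(traj, res_a, res_b,
                                   criteria = interaction_criteria()) {
  roles <- atom_roles(traj$topology)
  cg <- roles$charge_groups
  pick <- function(res) {
    hit <- which(cg$chain == as.character(res[["chain"]]) &
                   cg$resnum == as.integer(res[["resnum"]]))
    if (length(hit) == 0) {
      abort(paste0("residue ", res[["chain"]], ":", res[["resnum"]],
                   " not found among charged groups"))
    }
    hit[1]
  }
  a <- pick(res_a); b <- pick(res_b)
  if (cg$sign[a] * cg$sign[b] >= 0) {
    abort("residues do not carry opposite charges")
  }
  ia <- cg$atoms[[a]]; ib <- cg$atoms[[b]]
  nf <- n_frames(traj)
  hits <- 0L
  for (k in seq_len(nf)) {
    x <- frame_coords(traj, k)
    d <- sqrt(sum((colMeans(x[ia, , drop = FALSE]) -
                     colMeans(x[ib, , drop = FALSE]))^2))
    if (d < criteria$saltbridge_max) hits <- hits + 1L
  }
  occurrence_percent(hits, nf)
}

#' Combined occurrence table across systems
#'
#' Joins several profiles (e.g. one per ligand) into a residue-by-
#' (system, interaction type) occurrence table, keeping residues with any
#' cell strictly above the display threshold.
#'
#' @param profiles named list of `interaction_profile` objects.
#' @param min_occurrence display threshold, percent (default 20).
#' @return wide tibble: `chain`, `resnum`, `resname`, then one
#'   `system.itype` column per profile and type.
#' @export
profile_heatmap_export <- function(profiles, min_occurrence = 20) {
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    names(profiles) <- paste0("system", seq_along(profiles))
  }
  long <- bind_rows(imap(profiles, function(p, nm) {
    mutate(tidy(p), system = nm)
  }))
  if (nrow(long) == 0) {
    return(tibble(chain = character(), resnum = integer(),
                  resname = character()))
  }
  wide <- long |>
    mutate(col = paste(.data$system, .data$itype, sep = ".")) |>
    select("chain", "resnum", "resname", "col", "percent") |>
    tidyr::pivot_wider(names_from = "col", values_from = "percent",
                       values_fill = 0)
  val_cols <- setdiff(names(wide), c("chain", "resnum", "resname"))
  keep <- apply(as.matrix(wide[, val_cols]), 1,
                function(v) any(v > min_occurrence))
  arrange(wide[keep, ], .data$chain, .data$resnum)
}

#' Write an interaction profile to CSV
#'
#' @param profile an `interaction_profile`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(tidy(profile), path, row.names = FALSE)
  invisible(path)
}
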