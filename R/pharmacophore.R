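# Pharmacophore models: typed spheres (HBA/HBD/Aro/Hyd) with centers,
# radii and co-location groups, built from high-occurrence interactions
# of an MD trajectory or assembled from a declarative element list.

.feature_kinds <- c("HBA", "HBD", "Aro", "Hyd")

.empty_features <- function() {
  tibble(name = character(), kind = character(),
         x = double(), y = double(), z = double(),
         radius = double(), group = character(),
         provenance = character())
}

#' Construct a pharmacophore model
#'
#' @param features feature tibble: `name`, `kind` (HBA/HBD/Aro/Hyd), `x`,
#'   `y`, `z`, `radius`, optional `group` (co-location group id; members
#'   of one group share a center and count once toward the match
#'   minimum) and `provenance`.
#' @param min_match minimum number of positionally distinct elements a
#'   conformer must satisfy (default 6).
#' @return object of class `pharmacophore_model`.
#' @export
pharmacophore_model <- function(features, min_match = 6) {
  features <- as_tibble(features)
  if (nrow(features) > 0) {
    if (!"group" %in% names(features)) features$group <- NA_character_
    if (!"provenance" %in% names(features)) {
      features$provenance <- "manual"
    }
    if (!"radius" %in% names(features)) features$radius <- 1.0
    bad <- setdiff(unique(features$kind), .feature_kinds)
    if (length(bad) > 0) {
      abort(paste0("unknown feature kind(s): ", paste(bad, collapse = ", ")))
    }
    if (anyDuplicated(features$name)) abort("duplicate feature names")
    if (any(features$radius <= 0)) abort("feature radius must be positive")
    features$provenance[is.na(features$provenance)] <- "manual"
    # co-located members must share a center exactly
    grp <- features[!is.na(features$group), ]
    if (nrow(grp) > 0) {
      sp <- split(grp, grp$group)
      for (g in sp) {
        if (nrow(distinct(g[, c("x", "y", "z")])) != 1) {
          abort(paste0("co-location group ", g$group[1],
                       " has differing centers"))
        }
      }
    }
  } else {
    features <- .empty_features()
  }
  structure(list(features = features, min_match = as.integer(min_match)),
            class = "pharmacophore_model")
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  np <- n_positions(x)
  cat("<pharmacophore_model> ", nrow(x$features), " features at ", np,
      " distinct positions; min_match = ", x$min_match, "\n", sep = "")
  if (nrow(x$features) > 0) print(x$features, n = 12)
  invisible(x)
}

#' Number of positionally distinct elements of a model
#'
#' Co-located duals count once.
#'
#' @param model a `pharmacophore_model`.
#' @export
n_positions <- function(model) {
  f <- model$features
  if (nrow(f) == 0) return(0L)
  length(unique(ifelse(is.na(f$group), paste0("_f_", f$name), f$group)))
}

# positionally distinct element list: one entry per group/lone feature
.model_positions <- function(model) {
  f <- model$features
  if (nrow(f) == 0) return(list())
  key <- ifelse(is.na(f$group), paste0("_f_", f$name), f$group)
  map(unique(key), function(k) {
    rows <- f[key == k, ]
    list(id = if (startsWith(k, "_f_")) rows$name[1] else k,
         names = rows$name, kinds = unique(rows$kind),
         center = c(rows$x[1], rows$y[1], rows$z[1]),
         radius = rows$radius[1])
  })
}

#' Derive pharmacophore features from a trajectory's interaction profile
#'
#' Every relevant interaction (occurrence strictly above the threshold)
#' becomes a typed feature: ligand-acceptor hydrogen bonds map to HBA,
#' ligand-donor hydrogen bonds to HBD (each role thresholded on its own
#' occurrence), ring stacking to Aro, hydrophobic contacts to Hyd. The
#' feature center is the centroid over qualifying frames of the
#' ligand-side anchor (donor/acceptor atom, ring centroid, or closest
#' apolar carbon). Hydrophobic features whose anchors fall within the
#' merge radius collapse into one (single linkage, occurrence-weighted
#' centroid), mirroring how several residues' contacts with one ligand
#' region form a single hydrophobic element. Salt-bridge and cation-pi
#' cells have no feature mapping and are skipped.
#'
#' @param profile an `interaction_profile` built with
#'   `keep_events = TRUE` (otherwise pass `traj` to re-profile).
#' @param traj the source trajectory (only needed to recompute events).
#' @param threshold_percent relevance threshold (default 20).
#' @param radius feature sphere radius, A (default 1.0).
#' @param merge_radius hydrophobic anchor merge radius, A (default 1.5).
#' @return feature tibble (see [pharmacophore_model()]).
#' @export
build_features <- function(profile, traj = NULL, threshold_percent = 20,
                           radius = 1.0, merge_radius = 1.5) {
  stopifnot(inherits(profile, "interaction_profile"))
  if (is.null(profile$events)) {
    if (is.null(traj)) {
      abort("profile lacks events; rebuild with keep_events = TRUE or pass traj")
    }
    profile <- profile_trajectory(traj, profile$criteria, keep_events = TRUE)
  }
  ev <- profile$events
  total <- profile$total_frames
  rel <- relevant_interactions(profile, threshold_percent)
  if (nrow(rel) == 0) return(.empty_features())

  feats <- list()
  add_feat <- function(kind, center, prov, count) {
    feats[[length(feats) + 1]] <<- tibble(
      kind = kind, x = center[1], y = center[2], z = center[3],
      radius = radius, provenance = prov, count = count)
  }
  # per-frame mean anchor for a set of events
  anchor_centroid <- function(e) {
    per_frame <- e |>
      group_by(.data$frame) |>
      summarise(x = mean(.data$anchor_x), y = mean(.data$anchor_y),
                z = mean(.data$anchor_z), .groups = "drop")
    c(mean(per_frame$x), mean(per_frame$y), mean(per_frame$z))
  }

  for (r in seq_len(nrow(rel))) {
    cell <- ev |>
      filter(.data$chain == rel$chain[r], .data$resnum == rel$resnum[r],
             .data$itype == rel$itype[r])
    prov <- paste0(rel$chain[r], ":", rel$resnum[r], " ", rel$resname[r],
                   " ", rel$itype[r])
    if (rel$itype[r] == "hbond") {
      for (role in c("acceptor", "donor")) {
        sub <- filter(cell, .data$lig_role == role)
        n_fr <- dplyr::n_distinct(sub$frame)
        if (100 * n_fr / total > threshold_percent) {
          add_feat(if (role == "acceptor") "HBA" else "HBD",
                   anchor_centroid(sub),
                   paste0(prov, " (ligand ", role, ")"), n_fr)
        }
      }
    } else if (rel$itype[r] == "pi_stack") {
      add_feat("Aro", anchor_centroid(cell), prov, rel$count[r])
    } else if (rel$itype[r] == "hydrophobic") {
      add_feat("Hyd", anchor_centroid(cell), prov, rel$count[r])
    } # salt_bridge / pi_cation: no feature mapping
  }
  if (length(feats) == 0) return(.empty_features())
  ft <- bind_rows(feats)

  # single-linkage merge of hydrophobic anchors within merge_radius
  hyd <- which(ft$kind == "Hyd")
  if (length(hyd) > 1) {
    centers <- as.matrix(ft[hyd, c("x", "y", "z")])
    d <- as.matrix(stats::dist(centers))
    comp <- seq_along(hyd)
    repeat {
      changed <- FALSE
      for (a in seq_along(hyd)) {
        for (b in seq_along(hyd)) {
          if (d[a, b] <= merge_radius && comp[b] != comp[a]) {
            comp[comp == comp[b]] <- comp[a]
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    merged <- map(unique(comp), function(cmp) {
      rows <- ft[hyd[comp == cmp], ]
      w <- rows$count / sum(rows$count)
      tibble(kind = "Hyd",
             x = sum(rows$x * w), y = sum(rows$y * w), z = sum(rows$z * w),
             radius = radius,
             provenance = paste(rows$provenance, collapse = " + "),
             count = sum(rows$count))
    })
    ft <- bind_rows(ft[-hyd, ], bind_rows(merged))
  }

  # systematic names: kind + rank by descending occurrence within kind
  ft <- ft |>
    group_by(.data$kind) |>
    arrange(desc(.data$count), .by_group = TRUE) |>
    mutate(name = paste0(.data$kind, dplyr::row_number())) |>
    ungroup() |>
    select("name", "kind", "x", "y", "z", "radius", "provenance")
  ft$group <- NA_character_
  ft[, c("name", "kind", "x", "y", "z", "radius", "group", "provenance")]
}

#' Add a co-located dual feature
#'
#' Appends a feature of a new kind at the same center and radius as an
#' existing one and links the two into a co-location group: a conformer
#' may satisfy either member, and the pair counts once toward the match
#' minimum.
#'
#' @param model a `pharmacophore_model`.
#' @param feature_name existing feature to duplicate positionally.
#' @param new_kind kind of the added feature.
#' @param name optional name for the new feature (default: new kind plus
#'   the numeric suffix of `feature_name`).
#' @return the extended model.
#' @export
add_colocated <- function(model, feature_name, new_kind, name = NULL) {
  f <- model$features
  row <- which(f$name == feature_name)
  if (length(row) != 1) abort(paste0("unknown feature: ", feature_name))
  if (!new_kind %in% .feature_kinds) {
    abort(paste0("unknown feature kind: ", new_kind))
  }
  if (!is.na(f$group[row])) {
    abort(paste0("group already exists for feature ", feature_name))
  }
  if (is.null(name)) {
    suffix <- gsub("^[A-Za-z]+", "", feature_name)
    name <- paste0(new_kind, suffix)
    while (name %in% f$name) name <- paste0(name, "b")
  }
  gid <- paste0(feature_name, "/", name)
  f$group[row] <- gid
  new_row <- f[row, ]
  new_row$name <- name
  new_row$kind <- new_kind
  new_row$provenance <- paste0("co-located with ", feature_name)
  model$features <- bind_rows(f, new_row)
  pharmacophore_model(model$features, model$min_match)
}

#' Assemble a pharmacophore model from a declarative element list
#'
#' @param spec tibble/data.frame with columns `name`, `kind`, `x`, `y`,
#'   `z` and optionally `radius` (default 1.0) and `group`.
#' @param min_match minimum match count (default 6).
#' @return a `pharmacophore_model` with exactly the listed elements.
#' @export
assemble_reference_model <- function(spec, min_match = 6) {
  spec <- as_tibble(spec)
  if (nrow(spec) == 0) {
    return(pharmacophore_model(.empty_features(), min_match))
  }
  if (anyDuplicated(spec$name)) abort("duplicate feature names in spec")
  pharmacophore_model(spec, min_match)
}

#' The packaged reference pharmacophore (synthetic coordinates)
#'
#' Eight elements derived from the dynamic interaction profiles of five
#' kinase inhibitors: one hydrogen-bond acceptor and two donors anchored
#' at the hinge backbone, a stacking aromatic with a co-located
#' hydrophobic (Aro1/Hyd1), a buried hydrophobic with a co-located
#' aromatic (Hyd2/Aro2), and a third hydrophobic at an aliphatic side
#' chain. Element names, kinds and co-locations follow that model;
#' coordinates are synthetic stand-ins (the original model's geometry is
#' not published), laid out on its described triangular arrangement.
#'
#' @return a `pharmacophore_model` with 8 features, 6 distinct positions,
#'   `min_match = 6`.
#' @examples
#' ck1e_reference_model()
#' @export
ck1e_reference_model <- function() {
  read_model(system.file("extdata", "ck1e_elements_synthetic.json",
                         package = "trajpharm", mustWork = TRUE))
}

#' Drop features from a model
#'
#' Named features are removed; removing any member of a co-location
#' group removes the whole group (a dual element is one position).
#'
#' @param model a `pharmacophore_model`.
#' @param drop character vector of feature names.
#' @param min_match optional new minimum match count (default: keep).
#' @return the reduced model.
#' @export
submodel <- function(model, drop, min_match = NULL) {
  f <- model$features
  unknown <- setdiff(drop, f$name)
  if (length(unknown) > 0) {
    abort(paste0("unknown feature(s): ", paste(unknown, collapse = ", ")))
  }
  groups <- unique(f$group[f$name %in% drop & !is.na(f$group)])
  keep <- !(f$name %in% drop | (!is.na(f$group) & f$group %in% groups))
  pharmacophore_model(f[keep, ], min_match %||% model$min_match)
}

#' Write a pharmacophore model as JSON
#'
#' Pharmit-style points list: each feature becomes
#' `{name, kind, x, y, z, radius, enabled, group}`; `min_match` is kept
#' at the top level. [read_model()] inverts the mapping exactly.
#'
#' @param model a `pharmacophore_model`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  pts <- model$features
  out <- list(
    min_match = model$min_match,
    points = map(seq_len(nrow(pts)), function(i) {
      list(name = pts$name[i], kind = pts$kind[i],
           x = pts$x[i], y = pts$y[i], z = pts$z[i],
           radius = pts$radius[i], enabled = TRUE,
           group = pts$group[i], provenance = pts$provenance[i])
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a pharmacophore model from JSON
#'
#' @param path JSON file written by [write_model()] (or hand-authored in
#'   the same points-list layout).
#' @return a `pharmacophore_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$points)) abort("model JSON lacks a points list")
  pts <- bind_rows(map(obj$points, function(p) {
    if (is.null(p$kind) || !p$kind %in% .feature_kinds) {
      abort(paste0("unknown feature kind in model JSON: ",
                   p$kind %||% "<missing>"))
    }
    tibble(name = p$name, kind = p$kind,
           x = as.numeric(p$x), y = as.numeric(p$y), z = as.numeric(p$z),
           radius = as.numeric(p$radius %||% 1.0),
           group = p$group %||% NA_character_,
           provenance = p$provenance %||% "manual")
  }))
  enabled <- map_lgl(obj$points, ~ isTRUE(.x$enabled %||% TRUE))
  pharmacophore_model(pts[enabled, ], as.integer(obj$min_match %||% 6L))
}
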