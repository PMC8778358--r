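# Consensus analysis of docking poses: pairwise RMSD in the common
# receptor frame (no re-superposition), strict complete-linkage cutoff
# clustering, medoid representatives, largest-subcluster selection.

#' RMSD between two poses (no superposition)
#'
#' Root-mean-square deviation over heavy atoms of two coordinate sets
#' with identical atom ordering, evaluated in the shared receptor frame:
#' poses from one docking run are already placed, so no rigid refit is
#' applied.
#'
#' @param a,b n x 3 coordinate matrices in the same atom order.
#' @param elements optional element vector; hydrogens are excluded when
#'   it is given.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(a, b, elements = NULL) {
  if (!is.matrix(a)) a <- as.matrix(a)
  if (!is.matrix(b)) b <- as.matrix(b)
  if (nrow(a) != nrow(b)) abort("poses differ in atom count")
  if (!is.null(elements)) {
    keep <- toupper(elements) != "H"
    a <- a[keep, , drop = FALSE]
    b <- b[keep, , drop = FALSE]
  }
  coord_rmsd(a, b)
}

#' Pairwise RMSD matrix of a pose set
#'
#' @param poses a `pose_set`.
#' @return symmetric zero-diagonal matrix (A), labelled by pose.
#' @export
rmsd_matrix <- function(poses) {
  stopifnot(inherits(poses, "pose_set"))
  n <- n_poses(poses)
  if (n < 2) abort("need at least two poses")
  heavy <- toupper(poses$atoms$element) != "H"
  m <- matrix(0, n, n, dimnames = list(poses$labels, poses$labels))
  for (i in seq_len(n - 1)) {
    ci <- poses$coords[heavy, , i]
    for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- coord_rmsd(ci, poses$coords[heavy, , j])
    }
  }
  m
}

#' Cutoff clustering of a pose RMSD matrix (complete linkage)
#'
#' Agglomerates while the smallest complete-linkage distance between
#' clusters is below the cutoff, so every subcluster's diameter (largest
#' pairwise RMSD) is strictly below the cutoff. Merge ties break on the
#' smallest member index.
#'
#' @param matrix symmetric, zero-diagonal RMSD matrix.
#' @param cutoff diameter cutoff, A (default 2.0).
#' @param scores optional per-pose scores (lower = better), used for
#'   medoid tie-breaks.
#' @param linkage only `"complete"` is supported; the complete-linkage
#'   guarantee is what makes "all subcluster members mutually within the
#'   cutoff" true.
#' @return object of class `cluster_result`: the matrix, cutoff, member
#'   index sets sorted by decreasing size, and medoid representative per
#'   cluster.
#' @export
hierarchical_cluster <- function(matrix, cutoff = 2.0, scores = NULL,
                                 linkage = "complete") {
  linkage <- match.arg(linkage)
  n <- nrow(matrix)
  if (n != ncol(matrix)) abort("distance matrix must be square")
  if (max(abs(matrix - t(matrix))) > 1e-8) {
    abort("distance matrix must be symmetric")
  }
  if (any(diag(matrix) != 0)) abort("distance matrix diagonal must be zero")
  members <- as.list(seq_len(n))
  d <- matrix
  diag(d) <- Inf
  while (length(members) > 1) {
    min_d <- min(d)
    if (!(min_d < cutoff)) break
    idx <- which(d == min_d, arr.ind = TRUE)
    # deterministic tie-break: lexicographically smallest pair
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    a <- min(idx[1, ]); b <- max(idx[1, ])
    # Lance-Williams update for complete linkage
    new_row <- pmax(d[a, ], d[b, ])
    d[a, ] <- new_row; d[, a] <- new_row
    d[a, a] <- Inf
    d <- d[-b, -b, drop = FALSE]
    members[[a]] <- sort(c(members[[a]], members[[b]]))
    members[[b]] <- NULL
  }
  ord <- order(-lengths(members), map_int(members, min))
  members <- members[ord]
  reps <- map_int(members, representative, matrix = matrix, scores = scores)
  structure(list(rmsd_matrix = matrix, cutoff = cutoff,
                 clusters = members, representatives = reps,
                 scores = scores),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$clusters), " subclusters at cutoff ",
      x$cutoff, " A (sizes: ",
      paste(lengths(x$clusters), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Medoid representative of a cluster
#'
#' The member minimizing mean RMSD to the other members; ties break on
#' the better (lower) docking score, then the lowest index.
#'
#' @param cluster integer vector of pose indices.
#' @param matrix full RMSD matrix.
#' @param scores optional per-pose scores (lower = better).
#' @return pose index of the representative.
#' @export
representative <- function(cluster, matrix, scores = NULL) {
  if (length(cluster) == 0) abort("empty cluster")
  if (length(cluster) == 1) return(as.integer(cluster))
  sub <- matrix[cluster, cluster, drop = FALSE]
  mean_d <- rowSums(sub) / (length(cluster) - 1)
  sc <- if (is.null(scores)) rep(0, length(cluster)) else scores[cluster]
  sc[is.na(sc)] <- 0
  ord <- order(mean_d, sc, cluster)
  as.integer(cluster[ord[1]])
}

#' Consensus binding mode of a docking pose set
#'
#' Clusters all poses at the RMSD cutoff, selects the largest subcluster
#' (ties break on better mean score, then lowest member index), and
#' reports its medoid representative; when a reference pose is given, the
#' representative-to-reference RMSD is also reported.
#'
#' @param poses a `pose_set`.
#' @param cutoff subcluster diameter cutoff, A (default 2.0).
#' @param reference optional n x 3 reference coordinates (e.g. a
#'   crystallographic pose) in the same atom order and receptor frame.
#' @return object of class `consensus_report`: the `cluster_result`, the
#'   selected cluster index/members, representative pose index and label,
#'   and `reference_rmsd` (NA without a reference).
#' @examples
#' ps <- make_pose_set()
#' consensus_binding_mode(ps)
#' @export
consensus_binding_mode <- function(poses, cutoff = 2.0, reference = NULL) {
  m <- rmsd_matrix(poses)
  cl <- hierarchical_cluster(m, cutoff = cutoff, scores = poses$scores)
  sizes <- lengths(cl$clusters)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    mean_scores <- map_dbl(cl$clusters[best], function(ix) {
      s <- poses$scores[ix]
      if (all(is.na(s))) 0 else mean(s, na.rm = TRUE)
    })
    best <- best[order(mean_scores, map_int(cl$clusters[best], min))]
  }
  sel <- best[1]
  rep_idx <- cl$representatives[sel]
  ref_rmsd <- NA_real_
  if (!is.null(reference)) {
    ref_rmsd <- pose_rmsd(pose_coords(poses, rep_idx), as.matrix(reference),
                          elements = poses$atoms$element)
  }
  structure(list(clustering = cl, cluster_index = sel,
                 members = cl$clusters[[sel]],
                 representative = rep_idx,
                 representative_label = poses$labels[rep_idx],
                 reference_rmsd = ref_rmsd, poses = poses),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("<consensus_report> largest subcluster: ", length(x$members),
      " poses; representative ", x$representative_label, sep = "")
  if (!is.na(x$reference_rmsd)) {
    cat(sprintf("; RMSD to reference %.2f A", x$reference_rmsd))
  }
  cat("\n")
  invisible(x)
}
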