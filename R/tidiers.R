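# broom-style tidiers for the result objects.

#' @export
tidy.interaction_profile <- function(x, ...) {
  mutate(x$counts,
         total_frames = x$total_frames,
         percent = occurrence_percent(.data$count, x$total_frames))
}

#' @export
glance.interaction_profile <- function(x, ...) {
  td <- tidy(x)
  tibble(total_frames = x$total_frames,
         n_residues = dplyr::n_distinct(paste(td$chain, td$resnum)),
         n_cells = nrow(td),
         max_percent = if (nrow(td) > 0) max(td$percent) else NA_real_)
}

#' @export
tidy.series_result <- function(x, ...) {
  bind_cols(x$index, tibble(value = x$values))
}

#' @export
glance.series_result <- function(x, ...) {
  tibble(kind = x$kind, n = length(x$values),
         mean = mean(x$values), sd = stats::sd(x$values),
         max = max(x$values), reference = x$reference)
}

#' @export
tidy.cluster_result <- function(x, ...) {
  labels <- rownames(x$rmsd_matrix) %||% as.character(seq_len(nrow(x$rmsd_matrix)))
  bind_rows(imap(x$clusters, function(members, k) {
    tibble(cluster = k, pose = members, label = labels[members],
           is_representative = members == x$representatives[k])
  }))
}

#' @export
glance.cluster_result <- function(x, ...) {
  tibble(n_poses = nrow(x$rmsd_matrix), cutoff = x$cutoff,
         n_clusters = length(x$clusters),
         largest = max(lengths(x$clusters)))
}

#' @export
tidy.consensus_report <- function(x, ...) {
  mutate(tidy(x$clustering),
         in_consensus = .data$cluster == x$cluster_index,
         score = x$poses$scores[.data$pose])
}

#' @export
glance.consensus_report <- function(x, ...) {
  tibble(n_poses = n_poses(x$poses),
         n_clusters = length(x$clustering$clusters),
         consensus_size = length(x$members),
         representative = x$representative_label,
         reference_rmsd = x$reference_rmsd)
}

#' @export
tidy.pharmacophore_model <- function(x, ...) {
  x$features
}

#' @export
glance.pharmacophore_model <- function(x, ...) {
  tibble(n_features = nrow(x$features),
         n_positions = n_positions(x),
         min_match = x$min_match,
         kinds = paste(sort(unique(x$features$kind)), collapse = ","))
}

#' @export
tidy.screen_report <- function(x, ...) {
  x$results
}

#' @export
glance.screen_report <- function(x, ...) {
  tibble(n_conformers = nrow(x$results),
         n_compounds = nrow(x$compounds),
         n_hits = sum(x$compounds$verdict == "hit"),
         volume_max = x$params$volume_max,
         min_match = x$params$min_match)
}

#' @export
tidy.match_result <- function(x, ...) {
  x$assignment
}
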