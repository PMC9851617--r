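#' Jaccard similarity between two winner maps for one condition
#'
#' `|A ∩ B| / |A ∪ B|` over the two maps' winner vertex sets for the given
#' condition.  1 means identical non-empty maps, 0 disjoint maps.  When both
#' sets are empty the value is defined as 0 and flagged degenerate (the
#' 0/0 case is otherwise undefined).
#'
#' @param map_a,map_b `winner_map`s on the same ROI and mesh.
#' @param condition condition label.
#' @return numeric in `[0, 1]`, with attribute `degenerate` (logical).
#' @export
jaccard <- function(map_a, map_b, condition) {
  if (!identical(map_a$roi, map_b$roi))
    stop("winner maps cover different ROIs", call. = FALSE)
  a <- winner_vertices(map_a, condition)
  b <- winner_vertices(map_b, condition)
  u <- length(union(a, b))
  if (u == 0L) return(structure(0, degenerate = TRUE))
  structure(length(intersect(a, b)) / u, degenerate = FALSE)
}

#' Mean Jaccard similarity of one subject's map to a reference group
#'
#' Averages the per-condition Jaccard similarity of the target subject's
#' winner map against every reference subject's map.  For intra-group
#' comparisons the target is excluded from the reference set before
#' averaging (leave-self-out), so a subject is never compared to itself.
#'
#' @param target_id subject identifier of the target.
#' @param target_map the target's `winner_map`.
#' @param reference_maps named list (by subject id) of reference
#'   `winner_map`s.
#' @param condition condition label.
#' @param leave_self_out drop `target_id` from the references if present.
#' @return list with `mean_jaccard` and `n_references`.
#' @export
cross_group_similarity <- function(target_id, target_map, reference_maps,
                                   condition, leave_self_out = TRUE) {
  refs <- reference_maps
  if (leave_self_out) refs <- refs[setdiff(names(refs), target_id)]
  if (length(refs) == 0L)
    stop("reference group is empty after leave-self-out exclusion",
         call. = FALSE)
  vals <- vapply(refs, function(m) as.numeric(jaccard(target_map, m, condition)),
                 numeric(1))
  list(mean_jaccard = mean(vals), n_references = length(refs))
}

#' Long-format Jaccard similarity table for a set of winner maps
#'
#' Convenience wrapper producing the per-target, per-reference-group,
#' per-condition mean Jaccard table consumed by the group statistics.
#'
#' @param maps named list (by subject id) of `winner_map`s, one hemisphere.
#' @param groups named character vector: group label per subject id.
#' @param conditions condition labels (default the four face parts).
#' @param hemisphere label recorded in the output.
#' @return data frame: `target_subject`, `target_group`, `reference_group`,
#'   `hemisphere`, `condition`, `mean_jaccard`, `n_references`.
#' @export
jaccard_table <- function(maps, groups, conditions = FACE_CONDITIONS,
                          hemisphere = NA_character_) {
  stopifnot(all(names(maps) %in% names(groups)))
  rows <- list()
  for (tid in names(maps)) {
    for (rg in unique(groups)) {
      ref_ids <- names(maps)[groups[names(maps)] == rg]
      refs <- maps[ref_ids]
      for (cn in conditions) {
        res <- tryCatch(
          cross_group_similarity(tid, maps[[tid]], refs, cn,
                                 leave_self_out = TRUE),
          error = function(e) NULL)
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <- data.frame(
          target_subject = tid, target_group = groups[[tid]],
          reference_group = rg, hemisphere = hemisphere, condition = cn,
          mean_jaccard = res$mean_jaccard, n_references = res$n_references,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
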