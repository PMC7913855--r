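# Turning the cluster partition into a measurement plan: which DoF are
# independent (must always be recorded), which belong to coordination
# groups (record one candidate per group), and which clusters are too
# rare to keep.

#' Classify synergy clusters into independent DoF and coordination groups
#'
#' Applies loading-threshold rules to each cluster's averaged loading
#' vector (thresholds read on absolute values, since component sign is
#' arbitrary):
#'
#' * clusters present in fewer than `min_subject_fraction` of subjects
#'   are discarded as idiosyncratic;
#' * a cluster whose averaged loading has exactly one entry above
#'   `cc_high` and all others below `cc_low` represents the predominant
#'   motion of a single DoF; that DoF is *independent* — unless the same
#'   DoF also appears as a candidate (loading above `cc_candidate`) in a
#'   coordination cluster, in which case the single-DoF cluster is
#'   demoted into that coordination group;
#' * every other cluster represents coordinated motion: its candidates
#'   are the DoF with loading above `cc_candidate`, and coordination
#'   clusters whose candidate sets overlap are merged into one group
#'   (they describe the same coordination with different weights).
#'
#' @param partition A `synergy_partition` from [cluster_synergies()].
#' @param min_subject_fraction Minimum fraction of subjects a cluster
#'   must appear in to be retained (default 0.10).
#' @param cc_high,cc_low,cc_candidate Loading thresholds (defaults 0.8,
#'   0.3, 0.4).
#' @return A `dof_classification` object: list with `independent`
#'   (character vector of DoF), `groups` (list of coordination groups,
#'   each with `clusters` and `candidates` in canonical DoF order),
#'   `discarded` (tibble of discarded clusters) and `table` (tidy
#'   per-cluster classification).
#' @export
classify_clusters <- function(partition, min_subject_fraction = 0.10,
                              cc_high = 0.8, cc_low = 0.3,
                              cc_candidate = 0.4) {
  stopifnot(inherits(partition, "synergy_partition"))
  cl <- partition$clusters
  kept <- cl$subject_fraction >= min_subject_fraction
  discarded <- cl[!kept, c("cluster", "n_members", "subject_fraction")]
  cl <- cl[kept, , drop = FALSE]

  role <- character(nrow(cl))
  cand <- vector("list", nrow(cl))
  single_dof <- character(nrow(cl))
  for (i in seq_len(nrow(cl))) {
    v <- abs(cl$averaged_pc[[i]])
    hi <- which(v > cc_high)
    if (length(hi) == 1 && all(v[-hi] < cc_low)) {
      role[i] <- "single"
      single_dof[i] <- names(v)[hi]
      cand[[i]] <- names(v)[v > cc_candidate] # usually just the one DoF
    } else {
      role[i] <- "coordination"
      cand[[i]] <- names(v)[v > cc_candidate]
      if (length(cand[[i]]) == 0) {
        abort(sprintf(
          "cluster %d has no loading above the candidate threshold",
          cl$cluster[i]
        ))
      }
    }
  }

  # Demote single-DoF clusters whose DoF is a candidate of a coordination
  # cluster: they are part of that coordination, not independent.
  coord_cand <- unique(unlist(cand[role == "coordination"]))
  demoted <- role == "single" & single_dof %in% coord_cand
  role[demoted] <- "coordination"

  independent <- single_dof[role == "single"]

  # Merge coordination clusters with overlapping candidate sets
  # (union-find over clusters).
  coord_idx <- which(role == "coordination")
  parent <- seq_along(coord_idx)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_along(coord_idx)) {
    for (b in seq_len(a - 1L)) {
      if (length(intersect(cand[[coord_idx[a]]], cand[[coord_idx[b]]])) > 0) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_along(coord_idx), find, integer(1))
  groups <- lapply(unique(roots), function(r) {
    members <- coord_idx[roots == r]
    cands <- unique(unlist(cand[members]))
    list(
      clusters = cl$cluster[members],
      candidates = intersect(dof_labels(), cands) # canonical order
    )
  })
  # discovery order: by first contributing cluster id
  groups <- groups[order(vapply(groups, function(g) min(g$clusters), numeric(1)))]

  both <- intersect(independent, unlist(lapply(groups, `[[`, "candidates")))
  if (length(both) > 0) {
    abort(sprintf(
      "internal consistency error: DoF both independent and candidate: %s",
      paste(both, collapse = ", ")
    ))
  }

  table <- tibble::tibble(
    cluster = cl$cluster,
    role = role,
    subject_fraction = cl$subject_fraction,
    dof = ifelse(role == "single", single_dof, NA_character_),
    candidates = lapply(seq_len(nrow(cl)), function(i) {
      if (role[i] == "single") single_dof[i] else cand[[i]]
    })
  )

  structure(
    list(independent = intersect(dof_labels(), independent),
         groups = groups, discarded = discarded, table = table,
         thresholds = list(min_subject_fraction = min_subject_fraction,
                           cc_high = cc_high, cc_low = cc_low,
                           cc_candidate = cc_candidate)),
    class = "dof_classification"
  )
}

#' @export
print.dof_classification <- function(x, ...) {
  cat("<dof_classification>\n")
  cat("  independent:", paste(x$independent, collapse = ", "), "\n")
  for (i in seq_along(x$groups)) {
    cat(sprintf("  group %d candidates: %s\n", i,
                paste(x$groups[[i]]$candidates, collapse = ", ")))
  }
  if (nrow(x$discarded) > 0) {
    cat("  discarded clusters:", paste(x$discarded$cluster, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Enumerate representative-set combinations
#'
#' Forms every representative set obtainable by choosing exactly one
#' candidate DoF from each coordination group and combining it with all
#' independent DoF. Ordering is deterministic: groups in discovery
#' order, candidates within a group in canonical DoF order, the last
#' group varying fastest.
#'
#' @param classification A `dof_classification`.
#' @return Tibble with `set_id`, one `choice_<i>` column per group, and
#'   a `representative` list-column (character vector of recorded DoF,
#'   independent first).
#' @export
enumerate_combinations <- function(classification) {
  stopifnot(inherits(classification, "dof_classification"))
  groups <- classification$groups
  if (any(vapply(groups, function(g) length(g$candidates) == 0, logical(1)))) {
    abort("empty coordination group")
  }
  if (length(groups) == 0) {
    return(tibble::tibble(
      set_id = 1L,
      representative = list(classification$independent)
    ))
  }
  cands <- lapply(groups, `[[`, "candidates")
  grid <- rev(expand.grid(rev(cands), stringsAsFactors = FALSE))
  names(grid) <- paste0("choice_", seq_along(cands))
  out <- tibble::as_tibble(grid)
  out$set_id <- seq_len(nrow(out))
  out$representative <- lapply(seq_len(nrow(grid)), function(i) {
    c(classification$independent, unlist(grid[i, ], use.names = FALSE))
  })
  dplyr::relocate(out, "set_id")
}
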