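# Cross-subject clustering of pooled synergy loading vectors: the
# pairwise distance is the angle between components (sign-invariant),
# the hierarchy is complete linkage (farthest neighbor), and the
# partition is the coarsest one in which no cluster holds two synergies
# from the same subject.

#' Angle between two loading vectors
#'
#' The pairwise distance used to compare synergies:
#' `acos(|u . v| / (|u| |v|))` in degrees, in \[0, 90\]. The absolute
#' value makes the distance sign-invariant — a loading vector and its
#' negation describe the same coordination.
#'
#' @param u,v Numeric vectors of equal length (16 for hand synergies),
#'   not all zero.
#' @return Angle in degrees.
#' @examples
#' pc_angle(c(1, 0, 0), c(1, 1, 0)) # 45
#' pc_angle(c(1, 0), c(-1, 0))      # 0: sign-invariant
#' @export
pc_angle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("`u` and `v` must be nonzero vectors.")
  cosang <- min(1, abs(sum(u * v)) / (nu * nv))
  acos(cosang) * 180 / pi
}

# All pairwise pc_angle distances of a list of loading vectors.
pc_angle_matrix <- function(loadings) {
  m <- do.call(rbind, loadings)
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) abort("zero loading vector in pool")
  cosm <- abs(tcrossprod(m / norms))
  cosm[cosm > 1] <- 1
  d <- acos(cosm) * 180 / pi
  diag(d) <- 0
  d
}

#' Complete-linkage hierarchy of pooled synergies
#'
#' Agglomerative clustering where the distance between clusters is the
#' maximum pairwise angle between their members (farthest neighbor).
#'
#' @param pooled Tibble from [pool_synergies()] (needs `subject`,
#'   `component`, `loading` list-column), at least 2 rows.
#' @return An object of class `hclust` (merge heights in degrees), with
#'   the pooled tibble attached as attribute `"pooled"`.
#' @export
complete_linkage <- function(pooled) {
  if (nrow(pooled) < 2) abort("need at least 2 pooled synergies to cluster.")
  d <- pc_angle_matrix(pooled$loading)
  labs <- paste0(pooled$subject, ".", pooled$component)
  dimnames(d) <- list(labs, labs)
  tree <- hclust(as.dist(d), method = "complete")
  attr(tree, "pooled") <- pooled
  tree
}

#' Cut the hierarchy by the subject-uniqueness rule
#'
#' Scans partitions from coarsest (1 cluster) to finest and returns the
#' first — i.e. the minimum number of clusters — in which no cluster
#' contains more than one synergy from the same subject. Within-subject
#' synergies are orthogonal by construction of the rotation, so they are
#' far apart; a cluster holding two of them is merging distinct
#' coordinations and must be split.
#'
#' @param tree `hclust` object from [complete_linkage()].
#' @param pooled The pooled tibble the tree was built from (defaults to
#'   the copy attached to `tree`).
#' @return A `synergy_partition` object: list with `assignment` (tibble
#'   `subject`, `component`, `cluster`), `clusters` (per-cluster summary,
#'   see [summarize_cluster()]), `n_clusters`, `cut_distance` (degrees,
#'   rounded to 1; the smallest merge height undone by the cut), and
#'   `tree`.
#' @export
select_partition <- function(tree, pooled = attr(tree, "pooled")) {
  stopifnot(inherits(tree, "hclust"))
  n <- nrow(pooled)
  # Identical synergies from one subject can never be separated by any cut
  # below their (zero-height) merge; reject outright.
  d <- pc_angle_matrix(pooled$loading)
  same_subj <- outer(pooled$subject, pooled$subject, "==") & upper.tri(d)
  if (any(d[same_subj] < 1e-9)) {
    abort("unseparable members: a subject contributes two identical synergies",
          class = "handsyn_unseparable")
  }
  k_sel <- NA_integer_
  memb <- NULL
  for (k in seq_len(n)) {
    cl <- cutree(tree, k = k)
    if (all(table(pooled$subject, cl) <= 1)) {
      k_sel <- k
      memb <- cl
      break
    }
  }
  heights <- sort(tree$height)
  cut_distance <- if (k_sel >= 2) {
    # merges undone by a k-cluster cut are the top k-1; report the
    # smallest of them, rounded to whole degrees
    round(heights[n - k_sel + 1])
  } else {
    round(max(heights))
  }
  assignment <- tibble::tibble(
    subject = pooled$subject,
    component = pooled$component,
    cluster = as.integer(memb)
  )
  n_subjects <- dplyr::n_distinct(pooled$subject)
  clusters <- purrr::map_dfr(sort(unique(memb)), function(g) {
    summarize_cluster(pooled[memb == g, , drop = FALSE],
                      n_subjects = n_subjects) |>
      dplyr::mutate(cluster = g, .before = 1)
  })
  structure(
    list(assignment = assignment, clusters = clusters,
         n_clusters = k_sel, cut_distance = cut_distance, tree = tree,
         pooled = pooled, n_subjects = n_subjects),
    class = "synergy_partition"
  )
}

#' Summarize one cluster of synergies
#'
#' Members are sign-aligned to the member with the largest variance
#' explained (any member whose dot product with that anchor is negative
#' is flipped), then averaged element-wise to give the cluster's
#' representative loading vector.
#'
#' @param members Rows of a pooled tibble belonging to one cluster.
#' @param n_subjects Total number of subjects in the cohort (denominator
#'   of `subject_fraction`).
#' @return One-row tibble: `n_members`, `subject_fraction`,
#'   `mean_var_explained`, and `averaged_pc` (list-column holding the
#'   named 16-vector).
#' @export
summarize_cluster <- function(members, n_subjects) {
  stopifnot(nrow(members) >= 1)
  anchor <- members$loading[[which.max(members$var_explained)]]
  aligned <- lapply(members$loading, function(v) {
    if (sum(v * anchor) < 0) -v else v
  })
  avg <- Reduce(`+`, aligned) / length(aligned)
  tibble::tibble(
    n_members = nrow(members),
    subject_fraction = dplyr::n_distinct(members$subject) / n_subjects,
    mean_var_explained = mean(members$var_explained),
    averaged_pc = list(avg)
  )
}

#' Cluster a cohort's synergies end to end
#'
#' Pools all subjects' rotated components, builds the complete-linkage
#' hierarchy on inter-component angles, and selects the partition by the
#' subject-uniqueness rule.
#'
#' @param synergies A `hand_synergies` object from [extract_synergies()].
#' @return A `synergy_partition` object.
#' @export
cluster_synergies <- function(synergies) {
  pooled <- pool_synergies(synergies)
  select_partition(complete_linkage(pooled))
}

#' @export
print.synergy_partition <- function(x, ...) {
  cat(sprintf(
    "<synergy_partition> %d clusters of %d pooled synergies (cut ~%g deg)\n",
    x$n_clusters, nrow(x$assignment), x$cut_distance
  ))
  invisible(x)
}

#' @describeIn select_partition Per-cluster summary tibble with one row
#'   per cluster and the averaged loading unpacked into DoF columns.
#' @param x A `synergy_partition`.
#' @param ... Unused.
#' @method tidy synergy_partition
#' @export
tidy.synergy_partition <- function(x, ...) {
  wide <- do.call(rbind, x$clusters$averaged_pc)
  dplyr::bind_cols(
    dplyr::select(x$clusters, -"averaged_pc"),
    tibble::as_tibble(wide)
  )
}

#' @describeIn select_partition One-row summary: cluster count, cut
#'   distance, pooled synergy count.
#' @method glance synergy_partition
#' @export
glance.synergy_partition <- function(x, ...) {
  tibble::tibble(
    n_clusters = x$n_clusters,
    cut_distance = x$cut_distance,
    n_synergies = nrow(x$assignment),
    n_subjects = x$n_subjects
  )
}

#' Predominant DoF of a cluster
#'
#' DoF whose averaged loading exceeds `threshold` in absolute value,
#' sorted by decreasing magnitude — the style used to describe each
#' synergy in summary tables.
#'
#' @param partition A `synergy_partition`.
#' @param threshold Absolute-loading threshold (default 0.4).
#' @return Tibble `cluster`, `dof`, `loading`.
#' @export
predominant_dof <- function(partition, threshold = 0.4) {
  purrr::map_dfr(seq_len(nrow(partition$clusters)), function(i) {
    v <- partition$clusters$averaged_pc[[i]]
    keep <- which(abs(v) > threshold)
    keep <- keep[order(-abs(v[keep]))]
    tibble::tibble(cluster = partition$clusters$cluster[i],
                   dof = names(v)[keep], loading = unname(v[keep]))
  })
}
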