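# Rotate e1 by `deg` degrees towards e2 in 16-d space.
rotated_loading <- function(deg, from = 1, toward = 2) {
  v <- numeric(16)
  v[from] <- cos(deg * pi / 180)
  v[toward] <- sin(deg * pi / 180)
  setNames(v, dof_labels())
}

pooled_tbl <- function(loadings, subjects, var = NULL) {
  tibble::tibble(
    subject = subjects,
    component = stats::ave(seq_along(subjects), subjects, FUN = seq_along),
    var_explained = var %||% rep(0.1, length(subjects)),
    loading = loadings
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pc_angle is a sign-invariant semimetric bounded by 90 degrees", {
  u <- rotated_loading(0)
  expect_equal(pc_angle(u, u), 0)
  expect_equal(pc_angle(u, rotated_loading(90)), 90)
  expect_equal(pc_angle(u, -u), 0)
  expect_equal(pc_angle(c(1, 0, 0), c(1, 1, 0)), 45)
  expect_error(pc_angle(u, numeric(16)), "nonzero")

  set.seed(10)
  for (i in 1:50) {
    a <- rnorm(16); b <- rnorm(16)
    ang <- pc_angle(a, b)
    expect_gte(ang, 0)
    expect_lte(ang, 90)
    expect_equal(ang, pc_angle(b, a))                      # symmetric
    expect_equal(ang, pc_angle(-a, b))                     # sign-invariant
    expect_equal(pc_angle(a, 2.5 * a), 0, tolerance = 1e-5) # zero iff collinear
  }
})

test_that("complete linkage merges nearest pairs first, farthest last", {
  pcs <- pooled_tbl(
    list(rotated_loading(0), rotated_loading(5), rotated_loading(80)),
    subjects = c("A", "B", "C")
  )
  tree <- complete_linkage(pcs)
  expect_equal(sort(tree$height), c(5, 80), tolerance = 1e-6)

  # duplicates merge at height 0
  dup <- pooled_tbl(list(rotated_loading(10), rotated_loading(10)),
                    subjects = c("A", "B"))
  expect_equal(complete_linkage(dup)$height, 0, tolerance = 1e-9)
})

canonical_partition_from_sets <- function(sets, n) {
  memb <- integer(n)
  for (i in seq_along(sets)) memb[sets[[i]]] <- i
  canonical_partition(memb)
}

test_that("the linkage tree matches a brute-force reference", {
  set.seed(11)
  for (rep in 1:3) {
    n <- 10
    loadings <- lapply(1:n, function(i) setNames(rnorm(16), dof_labels()))
    pcs <- pooled_tbl(loadings, subjects = paste0("S", 1:n))
    tree <- complete_linkage(pcs)
    d <- outer(1:n, 1:n, Vectorize(function(i, j) {
      if (i == j) 0 else pc_angle(loadings[[i]], loadings[[j]])
    }))
    ref <- brute_complete_linkage(d)
    expect_equal(sort(tree$height), sort(ref$heights), tolerance = 1e-9)
    # partitions after each merge agree up to relabeling
    for (k in (n - 1):2) {
      got <- canonical_partition(cutree(tree, k = k))
      want <- canonical_partition_from_sets(ref$partitions[[n - k]], n)
      expect_equal(got, want)
    }
  }
})

test_that("the subject-uniqueness rule picks the coarsest valid partition", {
  # 2 subjects x 2 synergies: cross-subject pairs close (~10 deg),
  # within-subject pairs nearly orthogonal (~85 deg)
  pcs <- pooled_tbl(
    list(rotated_loading(0), rotated_loading(85),
         rotated_loading(10), rotated_loading(80)),
    subjects = c("A", "A", "B", "B")
  )
  part <- select_partition(complete_linkage(pcs))
  expect_equal(part$n_clusters, 2)
  tab <- table(part$assignment$subject, part$assignment$cluster)
  expect_true(all(tab == 1))
  # exhaustive check: no coarser valid partition exists (k = 1 pools a
  # subject's two synergies)
  expect_false(all(table(pcs$subject, rep(1, 4)) <= 1))

  # one synergy per subject, all mutually close: a single cluster
  close_pcs <- pooled_tbl(
    lapply(c(0, 2, 4), rotated_loading),
    subjects = c("A", "B", "C")
  )
  expect_equal(select_partition(complete_linkage(close_pcs))$n_clusters, 1)

  # identical synergies from one subject can never be separated
  stuck <- pooled_tbl(list(rotated_loading(5), rotated_loading(5)),
                      subjects = c("A", "A"))
  expect_error(select_partition(complete_linkage(stuck)),
               class = "handsyn_unseparable")
})

test_that("refining the cut never breaks an already-valid partition", {
  cohort <- default_cohort()
  pre <- preprocess_recordings(cohort$recordings, n_frames = 250)
  syn <- extract_synergies(pre)
  pooled <- pool_synergies(syn)
  tree <- complete_linkage(pooled)
  part <- select_partition(tree, pooled)
  # selected partition satisfies the constraint by construction
  expect_true(all(table(pooled$subject, cutree(tree, part$n_clusters)) <= 1))
  # and every finer partition does too
  for (k in part$n_clusters:min(part$n_clusters + 5, nrow(pooled))) {
    expect_true(all(table(pooled$subject, cutree(tree, k)) <= 1))
  }
})

test_that("cluster averaging sign-aligns members to the strongest one", {
  v <- unit_loading(c(PIP3F = 0.6, PIP4F = 0.8))
  n_subjects <- 4
  single <- summarize_cluster(
    pooled_tbl(list(v), "A"), n_subjects = n_subjects
  )
  expect_equal(single$averaged_pc[[1]], v)
  expect_equal(single$subject_fraction, 1 / n_subjects)

  flipped <- summarize_cluster(
    pooled_tbl(list(v, -v), c("A", "B"), var = c(0.3, 0.1)),
    n_subjects = n_subjects
  )
  expect_equal(flipped$averaged_pc[[1]], v)
  expect_equal(flipped$subject_fraction, 2 / n_subjects)
})

test_that("planted cohorts cluster into the planted coordinations", {
  cohort <- default_cohort() # jitter 5 deg < 15, noise 1 deg
  pre <- preprocess_recordings(cohort$recordings, n_frames = 250)
  part <- cluster_synergies(extract_synergies(pre))
  m <- ncol(cohort$ground_truth$loadings)
  p <- length(cohort$ground_truth$independent_dof)
  expect_equal(part$n_clusters, m + p)
  # every planted coordination matches one averaged cluster loading
  # (compared in correlation space, where a block's loading direction is
  # its normalized support)
  for (c in seq_len(m)) {
    target <- planted_cc_direction(cohort$ground_truth, c)
    angles <- vapply(part$clusters$averaged_pc, pc_angle,
                     numeric(1), v = target)
    expect_lte(min(angles), 20)
  }
})
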