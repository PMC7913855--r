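# Shared fixtures, built once per test run, and independent reference
# implementations used as oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  .fixture_cache[[name]]
}

toy_cohort <- function() cached_fixture("toy", make_toy_fixture())

# Noise- and jitter-free cohort: the exact-recovery regime.
noiseless_cohort <- function() {
  cached_fixture("noiseless", generate_cohort(synth_config(
    n_subjects = 4, n_tasks = 4, frames_per_task = 400,
    subject_loading_jitter = 0, noise_sd = 0, static_pad_s = 0, seed = 7L
  )))
}

# The generator's default study conditions (8 subjects, 6 tasks,
# jitter 5 deg, noise 1 deg, 0.5 s pads).
default_cohort <- function() {
  cached_fixture("default", generate_cohort(synth_config(seed = 11L)))
}

# Simple recordings tibble builder around a frames x 16 matrix.
recording_tbl <- function(m, subject = "S1", task = "T1") {
  colnames(m) <- dof_labels()
  dplyr::bind_cols(
    tibble::tibble(subject = subject, task = task, frame = seq_len(nrow(m))),
    tibble::as_tibble(as.data.frame(m))
  )
}

# Brute-force O(n^3) complete-linkage reference: returns merge heights
# (ascending) and the list of partitions (set of index sets) after each
# merge, for comparison with the hclust-based implementation.
brute_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_len(a - 1L)) {
        dd <- max(d[clusters[[a]], clusters[[b]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(b, a)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
    heights <- c(heights, best_d)
    partitions[[length(partitions) + 1]] <-
      lapply(clusters, function(x) sort(x))
  }
  list(heights = heights, partitions = partitions)
}

# Canonical form of a partition (for equality up to relabeling).
canonical_partition <- function(membership) {
  sets <- split(seq_along(membership), membership)
  sets <- lapply(sets, function(x) sort(unname(x)))
  unname(sets[order(vapply(sets, `[`, integer(1), 1))])
}

# Expected correlation-loading direction of a planted coordination: with
# a single activation driving a block, every block DoF correlates ~1 with
# the component (independently of the planted weight), so the CC vector
# points along the normalized support indicator.
planted_cc_direction <- function(ground_truth, c) {
  support <- ground_truth$loadings[, c] != 0
  v <- as.numeric(support)
  names(v) <- rownames(ground_truth$loadings)
  v / sqrt(sum(v^2))
}

# A unit 16-vector supported on the given DoF.
unit_loading <- function(weights) {
  v <- stats::setNames(numeric(16), dof_labels())
  v[names(weights)] <- weights
  v / sqrt(sum(v^2))
}

# Minimal synergy_partition stand-in for classification tests:
# averaged loading vectors plus subject fractions.
fake_partition <- function(avg_pcs, subject_fraction, mean_var = 0.1) {
  clusters <- tibble::tibble(
    cluster = seq_along(avg_pcs),
    n_members = 1L,
    subject_fraction = subject_fraction,
    mean_var_explained = mean_var,
    averaged_pc = avg_pcs
  )
  structure(
    list(clusters = clusters, n_clusters = length(avg_pcs),
         n_subjects = 10L),
    class = "synergy_partition"
  )
}
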