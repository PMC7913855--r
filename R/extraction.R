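# Per-subject kinematic synergy extraction: PCA on the standardized
# task ensemble, retention by cumulative variance, Varimax rotation, and
# expression of loadings as correlation coefficients (CC) between each
# rotated component and each joint angle.

#' Extract kinematic synergies for every subject
#'
#' For each subject, builds the standardized 16 x N task ensemble (via
#' [zscore_concat()]), performs PCA on its correlation structure, retains
#' the smallest number of leading components whose cumulative variance
#' reaches `var_threshold`, and Varimax-rotates the retained loadings to
#' obtain sparser, more interpretable synergies. Loadings are correlation
#' coefficients in \[-1, 1\]: eigenvectors scaled column-wise by the
#' square root of their eigenvalues, then rotated.
#'
#' The retained count k is fixed before rotation; rotation redistributes
#' variance among the retained components but preserves their total.
#' Component signs are arbitrary; reported loadings are sign-fixed so
#' each component's largest-magnitude loading is positive, and all
#' downstream consumers are sign-invariant.
#'
#' @param data Recordings tibble, preprocessed and resampled so every task
#'   has the same frame count (any number of subjects).
#' @param var_threshold Minimum cumulative fraction of total variance the
#'   retained components must explain, in (0, 1] (default 0.95).
#' @param fixed_k Optional integer: retain exactly this many components
#'   instead of applying the variance rule (useful to reproduce analyses
#'   that fixed the synergy count).
#' @return A `hand_synergies` object: a list with `loadings` (tibble
#'   `subject`, `component`, `dof`, `loading`), `variance` (tibble
#'   `subject`, `component`, `var_explained`), and `subjects`. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
extract_synergies <- function(data, var_threshold = 0.95, fixed_k = NULL) {
  data <- check_recordings(data)
  subjects <- unique(data$subject)
  per_subject <- lapply(subjects, function(s) {
    zc <- zscore_concat(dplyr::filter(data, .data$subject == s))
    ss <- extract_synergies_matrix(zc$z, var_threshold = var_threshold,
                                   fixed_k = fixed_k)
    list(subject = s, syn = ss)
  })
  loadings <- purrr::map_dfr(per_subject, function(p) {
    L <- p$syn$loadings
    tibble::tibble(
      subject = p$subject,
      component = rep(seq_len(ncol(L)), each = nrow(L)),
      dof = rep(dof_labels(), ncol(L)),
      loading = as.vector(L)
    )
  })
  variance <- purrr::map_dfr(per_subject, function(p) {
    tibble::tibble(
      subject = p$subject,
      component = seq_along(p$syn$var_explained),
      var_explained = p$syn$var_explained
    )
  })
  structure(
    list(loadings = loadings, variance = variance, subjects = subjects,
         var_threshold = var_threshold),
    class = "hand_synergies"
  )
}

#' Synergy extraction on a standardized matrix
#'
#' Matrix-level worker behind [extract_synergies()], exposed for direct
#' use: takes a 16 x N standardized matrix (rows mean 0, SD 1) and
#' returns the rotated correlation-coefficient loadings.
#'
#' @param z Standardized matrix, 16 rows in canonical DoF order.
#' @inheritParams extract_synergies
#' @return List with `loadings` (16 x k CC matrix), `var_explained`
#'   (per rotated component, fraction of total variance, decreasing),
#'   `total_var_explained`, and `k`.
#' @export
extract_synergies_matrix <- function(z, var_threshold = 0.95, fixed_k = NULL) {
  if (!is.numeric(var_threshold) || var_threshold <= 0 || var_threshold > 1) {
    abort("`var_threshold` must lie in (0, 1].")
  }
  if (nrow(z) != 16) abort("`z` must have 16 rows (canonical DoF order).")
  n <- ncol(z)
  if (n < 2) abort("`z` needs at least 2 columns.")
  # Correlation matrix of the DoF: rows are standardized, so the sample
  # covariance of the rows is the correlation matrix.
  R <- tcrossprod(z) / (n - 1)
  eig <- eigen(R, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  frac <- ev / sum(ev)
  cum <- cumsum(frac)
  if (is.null(fixed_k)) {
    if (max(cum) < var_threshold - 1e-9) {
      abort("threshold unreachable: cumulative variance never attains it",
            class = "handsyn_threshold_unreachable")
    }
    k <- which(cum >= var_threshold - 1e-12)[1]
  } else {
    k <- as.integer(fixed_k)
    if (k < 1 || k > 16) abort("`fixed_k` must be in 1..16.")
  }
  # Correlation loadings of the retained components, then Varimax
  # (Kaiser row-normalized) for sparsity.
  L <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  if (k > 1) {
    vm <- varimax(L, normalize = TRUE, eps = 1e-8)
    L <- L %*% vm$rotmat
  }
  ve <- colSums(L^2) / 16
  ord <- order(ve, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  ve <- ve[ord]
  # Sign fix: largest-magnitude loading positive in each column.
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- dof_labels()
  colnames(L) <- paste0("S", seq_len(k))
  list(loadings = L, var_explained = ve,
       total_var_explained = sum(ve), k = k)
}

#' @export
print.hand_synergies <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<hand_synergies> %d subject(s), %s components/subject, mean variance explained %.1f%%\n",
    length(x$subjects),
    paste(range(g$k), collapse = "-"),
    100 * mean(g$total_var_explained)
  ))
  invisible(x)
}

#' @describeIn extract_synergies Long tibble of loadings (one row per
#'   subject x component x DoF).
#' @param x A `hand_synergies` object.
#' @param ... Unused.
#' @method tidy hand_synergies
#' @export
tidy.hand_synergies <- function(x, ...) x$loadings

#' @describeIn extract_synergies One row per subject: retained component
#'   count `k` and `total_var_explained`.
#' @method glance hand_synergies
#' @export
glance.hand_synergies <- function(x, ...) {
  x$variance |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(k = dplyr::n(),
                     total_var_explained = sum(.data$var_explained),
                     .groups = "drop")
}

#' Pool all subjects' synergies for clustering
#'
#' Flattens a `hand_synergies` object into one row per extracted
#' component with its 16-element loading vector, the unit every
#' cross-subject analysis operates on.
#'
#' @param synergies A `hand_synergies` object.
#' @return Tibble with `subject`, `component`, `var_explained` and a
#'   `loading` list-column of named 16-vectors.
#' @export
pool_synergies <- function(synergies) {
  stopifnot(inherits(synergies, "hand_synergies"))
  wide <- synergies$loadings |>
    tidyr::pivot_wider(names_from = "dof", values_from = "loading") |>
    dplyr::left_join(synergies$variance, by = c("subject", "component"))
  m <- as.matrix(wide[dof_labels()])
  tibble::tibble(
    subject = wide$subject,
    component = wide$component,
    var_explained = wide$var_explained,
    loading = lapply(seq_len(nrow(m)), function(i) setNames(m[i, ], dof_labels()))
  )
}
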