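# Affine estimation of the non-recorded joint angles. For every
# estimated DoF j and frame i:
#
#   Angest_ji = intercept_j + sum_k Angrep_ki * x_j(k)
#
# with intercept and coefficients obtained by ordinary least squares
# over all pooled training frames (the closed-form solution of the
# sum-of-squared-differences objective).

#' Fit linear estimators for the non-representative DoF
#'
#' Pools all frames of all subjects and tasks (angles in raw degrees;
#' the affine model mixes angles directly, so no standardization) and
#' solves one OLS problem per estimated DoF against an intercept plus
#' the representative angles. The solve is QR-based; a design condition
#' number above `max_condition` signals collinear representative angles.
#'
#' @param data Recordings tibble of training frames (preprocessed).
#' @param representative Character vector of the recorded DoF labels.
#' @param max_condition Condition-number ceiling for the design matrix
#'   (default 1e10).
#' @return A `estimator_bank` object: list with `representative`,
#'   `estimated`, `coefficients` (tibble: `dof`, `intercept`, one column
#'   per representative label), `training` metadata. Supports [tidy()],
#'   [glance()], [autoplot()].
#' @export
fit_estimators <- function(data, representative, max_condition = 1e10) {
  data <- check_recordings(data)
  representative <- check_representative(representative)
  estimated <- setdiff(dof_labels(), representative)
  m <- angles_matrix(data)
  X <- cbind(`(Intercept)` = 1, m[, representative, drop = FALSE])
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > max_condition) {
    abort("degenerate design: representative angles are collinear",
          class = "handsyn_degenerate_design")
  }
  Y <- m[, estimated, drop = FALSE]
  fit <- stats::lm.fit(X, Y)
  B <- as.matrix(fit$coefficients) # (1 + n_rep) x n_est
  coefs <- tibble::tibble(dof = estimated, intercept = unname(B[1, ]))
  for (k in seq_along(representative)) {
    coefs[[representative[k]]] <- unname(B[k + 1, ])
  }
  res <- Y - X %*% B
  train_rmse <- sqrt(colMeans(res^2))
  structure(
    list(
      representative = representative,
      estimated = estimated,
      coefficients = coefs,
      training = list(
        n_frames = nrow(m),
        rmse = tibble::tibble(dof = estimated, rmse = unname(train_rmse))
      )
    ),
    class = "estimator_bank"
  )
}

check_representative <- function(representative) {
  if (anyDuplicated(representative) ||
      !all(representative %in% dof_labels()) ||
      length(representative) < 1 || length(representative) > 15) {
    abort("`representative` must be 1-15 distinct canonical DoF labels.")
  }
  intersect(dof_labels(), representative)
}

#' Apply an estimator bank to recorded representative angles
#'
#' @param bank An `estimator_bank` from [fit_estimators()].
#' @param data Recordings tibble (only the representative columns are
#'   read) or a numeric matrix whose columns are the representative
#'   angles in the bank's order.
#' @return If `data` is a tibble: a tibble `subject`, `task`, `frame`
#'   plus one estimated column per non-representative DoF. If a matrix:
#'   the frames x estimated matrix.
#' @export
estimate_angles <- function(bank, data) {
  stopifnot(inherits(bank, "estimator_bank"))
  B <- coef_matrix(bank)
  if (is.matrix(data)) {
    if (!identical(colnames(data), bank$representative)) {
      abort("matrix columns must match the bank's representative labels.")
    }
    return(cbind(1, data) %*% B)
  }
  data <- check_recordings(data)
  est <- cbind(1, angles_matrix(data)[, bank$representative, drop = FALSE]) %*% B
  dplyr::bind_cols(
    dplyr::select(data, dplyr::all_of(.id_cols)),
    tibble::as_tibble(as.data.frame(est))
  )
}

# (1 + n_rep) x n_est coefficient matrix, columns named by estimated DoF.
coef_matrix <- function(bank) {
  cf <- bank$coefficients
  B <- t(as.matrix(cf[, c("intercept", bank$representative)]))
  colnames(B) <- cf$dof
  B
}

#' Root-mean-square error between two angle traces
#'
#' @param est,rec Numeric vectors of equal positive length (degrees).
#' @return `sqrt(mean((est - rec)^2))`, in degrees.
#' @export
rmse <- function(est, rec) {
  if (length(est) != length(rec) || length(est) < 1) {
    abort("`est` and `rec` must have equal length >= 1.")
  }
  sqrt(mean((est - rec)^2))
}

#' Score representative-set combinations and select the best
#'
#' Fits an estimator bank for every enumerated representative set on the
#' pooled training frames, computes the training RMSE of each estimated
#' DoF, and selects the combination with the lowest RMSE averaged across
#' its estimated DoF (ties broken by enumeration order).
#'
#' @param data Recordings tibble of training frames.
#' @param combos Tibble from [enumerate_combinations()].
#' @return A `combination_scores` object: list with `scores` (tibble
#'   `set_id`, choices, `mean_rmse`, nested `per_dof`), `best_id`,
#'   `best` (representative labels) and `best_bank`.
#' @export
score_and_select <- function(data, combos) {
  data <- check_recordings(data)
  stopifnot(nrow(combos) >= 1)
  fits <- purrr::map(seq_len(nrow(combos)), function(i) {
    bank <- tryCatch(
      fit_estimators(data, combos$representative[[i]]),
      error = function(e) {
        abort(sprintf("combination %d failed to fit: %s",
                      combos$set_id[i], conditionMessage(e)))
      }
    )
    bank
  })
  per_dof <- purrr::map(fits, function(b) b$training$rmse)
  scores <- combos |>
    dplyr::select(-"representative") |>
    dplyr::mutate(
      mean_rmse = vapply(per_dof, function(t) mean(t$rmse), numeric(1)),
      per_dof = per_dof
    )
  best_i <- which.min(scores$mean_rmse) # which.min takes the first minimum
  structure(
    list(scores = scores, best_id = combos$set_id[best_i],
         best = combos$representative[[best_i]], best_bank = fits[[best_i]]),
    class = "combination_scores"
  )
}

#' @export
print.combination_scores <- function(x, ...) {
  cat(sprintf(
    "<combination_scores> %d combinations; best set #%d (mean RMSE %.2f deg): %s\n",
    nrow(x$scores), x$best_id,
    x$scores$mean_rmse[x$scores$set_id == x$best_id],
    paste(x$best, collapse = ", ")
  ))
  invisible(x)
}

#' @describeIn score_and_select Long tibble: one row per combination and
#'   estimated DoF with its training RMSE.
#' @param x A `combination_scores`.
#' @param ... Unused.
#' @method tidy combination_scores
#' @export
tidy.combination_scores <- function(x, ...) {
  x$scores |>
    dplyr::select("set_id", "per_dof") |>
    tidyr::unnest("per_dof")
}

#' @describeIn score_and_select One row per combination with its mean
#'   RMSE, best first.
#' @method glance combination_scores
#' @export
glance.combination_scores <- function(x, ...) {
  dplyr::arrange(dplyr::select(x$scores, -"per_dof"), .data$mean_rmse)
}

#' @describeIn fit_estimators Coefficient table: one row per estimated
#'   DoF, columns `intercept` plus the representative labels.
#' @param x An `estimator_bank`.
#' @param ... Unused.
#' @method tidy estimator_bank
#' @export
tidy.estimator_bank <- function(x, ...) x$coefficients

#' @describeIn fit_estimators One-row fit summary: representative count,
#'   training frames, mean training RMSE.
#' @method glance estimator_bank
#' @export
glance.estimator_bank <- function(x, ...) {
  tibble::tibble(
    n_representative = length(x$representative),
    n_estimated = length(x$estimated),
    n_frames = x$training$n_frames,
    mean_train_rmse = mean(x$training$rmse$rmse)
  )
}

#' @export
print.estimator_bank <- function(x, ...) {
  cat(sprintf(
    "<estimator_bank> %d estimated DoF from %d representative (fit on %d frames)\n",
    length(x$estimated), length(x$representative), x$training$n_frames
  ))
  invisible(x)
}
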