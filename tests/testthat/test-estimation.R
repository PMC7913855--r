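# Recordings whose non-representative angles are exact affine maps of
# the representative ones.
affine_recordings <- function(n = 300, seed = 20) {
  set.seed(seed)
  m <- matrix(rnorm(n * 16, 20, 5), n, 16)
  colnames(m) <- dof_labels()
  m[, "MCP3F"] <- 2 * m[, "CMC1F"] - m[, "CMC1A"] + 5
  m[, "PIP3F"] <- 12 # constant target
  recording_tbl(m)
}

test_that("OLS recovers exact affine structure and constants", {
  recs <- affine_recordings()
  rep_set <- setdiff(dof_labels(), c("MCP3F", "PIP3F"))
  bank <- fit_estimators(recs, rep_set)
  cf <- tidy(bank)

  row <- cf[cf$dof == "MCP3F", ]
  expect_equal(row$intercept, 5, tolerance = 1e-8)
  expect_equal(row$CMC1F, 2, tolerance = 1e-8)
  expect_equal(row$CMC1A, -1, tolerance = 1e-8)
  others <- setdiff(rep_set, c("CMC1F", "CMC1A"))
  expect_equal(max(abs(as.matrix(row[others]))), 0, tolerance = 1e-8)

  const <- cf[cf$dof == "PIP3F", ]
  expect_equal(const$intercept, 12, tolerance = 1e-8)
  expect_equal(max(abs(as.matrix(const[rep_set]))), 0, tolerance = 1e-8)

  expect_equal(bank$training$rmse$rmse, c(0, 0), tolerance = 1e-8)
})

test_that("fitted coefficients equal the normal-equations oracle", {
  set.seed(21)
  m <- matrix(rnorm(800 * 16, 15, 8), 800, 16)
  colnames(m) <- dof_labels()
  recs <- recording_tbl(m)
  rep_set <- c("CMC1F", "CMC1A", "MCP1F", "IP1F", "PIP2F", "PalmArch",
               "PIP4F", "MCP4F")
  bank <- fit_estimators(recs, rep_set)
  X <- cbind(1, m[, bank$representative])
  for (j in bank$estimated) {
    beta_oracle <- solve(crossprod(X), crossprod(X, m[, j]))
    row <- tidy(bank)[tidy(bank)$dof == j, ]
    got <- as.numeric(row[c("intercept", bank$representative)])
    expect_equal(got, as.numeric(beta_oracle), tolerance = 1e-8)
  }
})

test_that("the OLS solution is a local (and global) optimum", {
  set.seed(22)
  m <- matrix(rnorm(400 * 16, 10, 6), 400, 16)
  colnames(m) <- dof_labels()
  recs <- recording_tbl(m)
  rep_set <- c("CMC1F", "PIP4F", "MCP4F")
  bank <- fit_estimators(recs, rep_set)
  X <- cbind(1, m[, bank$representative])
  j <- "MCP2F"
  beta <- as.numeric(tidy(bank)[tidy(bank)$dof == j,
                                c("intercept", bank$representative)])
  sse <- function(b) sum((m[, j] - X %*% b)^2)
  base <- sse(beta)
  for (i in seq_along(beta)) {
    for (eps in c(-1e-3, 1e-3)) {
      pert <- beta
      pert[i] <- pert[i] + eps
      expect_gte(sse(pert), base)
    }
  }
  # and always at least as good as the intercept-only predictor
  for (j in bank$estimated) {
    rmse_fit <- bank$training$rmse$rmse[bank$training$rmse$dof == j]
    rmse_mean <- sqrt(mean((m[, j] - mean(m[, j]))^2))
    expect_lte(rmse_fit, rmse_mean + 1e-12)
  }
})

test_that("coefficients converge to truth as noise vanishes", {
  set.seed(23)
  n <- 10000
  m <- matrix(rnorm(n * 16, 20, 5), n, 16)
  colnames(m) <- dof_labels()
  truth_b <- c(1.5, -0.4, 0.25)
  rep_set <- c("CMC1F", "PIP4F", "MCP4F")
  m[, "MCP3F"] <- 3 + m[, rep_set] %*% truth_b + rnorm(n, 0, 1e-4)
  bank <- fit_estimators(recording_tbl(m), rep_set)
  row <- tidy(bank)[tidy(bank)$dof == "MCP3F", ]
  got <- as.numeric(row[c("intercept", rep_set)])
  expect_lt(max(abs(got - c(3, truth_b))), 1e-3)
})

test_that("collinear representative angles are rejected", {
  set.seed(24)
  m <- matrix(rnorm(200 * 16), 200, 16)
  colnames(m) <- dof_labels()
  m[, "CMC1A"] <- 2 * m[, "CMC1F"] # exact collinearity
  expect_error(fit_estimators(recording_tbl(m), c("CMC1F", "CMC1A", "MCP4F")),
               class = "handsyn_degenerate_design")
})

test_that("estimate_angles applies the affine map frame-wise", {
  recs <- affine_recordings(100)
  rep_set <- setdiff(dof_labels(), c("MCP3F", "PIP3F"))
  bank <- fit_estimators(recs, rep_set)

  est <- estimate_angles(bank, recs)
  expect_named(est, c("subject", "task", "frame", bank$estimated))
  # frame-by-frame scalar oracle
  cf <- tidy(bank)
  m <- as.matrix(recs[dof_labels()])
  for (j in bank$estimated) {
    row <- cf[cf$dof == j, ]
    manual <- vapply(seq_len(nrow(m)), function(i) {
      row$intercept + sum(as.numeric(row[rep_set]) * m[i, rep_set])
    }, numeric(1))
    expect_equal(est[[j]], manual, tolerance = 1e-9)
  }

  # zero-coefficient bank copies the intercept everywhere
  zero <- bank
  zero$coefficients[bank$representative] <- 0
  zero$coefficients$intercept <- 42
  est0 <- estimate_angles(zero, recs)
  expect_true(all(as.matrix(est0[bank$estimated]) == 42))

  # label mismatch on the matrix interface is a contract error
  bad <- as.matrix(recs[rev(rep_set)])
  expect_error(estimate_angles(bank, bad), "representative")
})

test_that("rmse matches its closed form", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(4, 5), c(1, 2)), 3)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt((9 + 16) / 2), tolerance = 1e-4)
  expect_error(rmse(numeric(0), numeric(0)), "length")
  expect_error(rmse(1:3, 1:2), "length")
})

test_that("combination scoring selects the lowest mean RMSE, ties by order", {
  recs <- affine_recordings(200)
  rep_all <- setdiff(dof_labels(), c("MCP3F", "PIP3F"))
  combos <- tibble::tibble(
    set_id = 1:3,
    representative = list(
      rep_all,                       # exact: mean RMSE 0
      setdiff(dof_labels(), c("MCP3F", "PIP3F", "MCP5F")),
      rep_all                        # duplicate of 1: tie
    )
  )
  sc <- score_and_select(recs, combos)
  expect_equal(sc$best_id, 1) # tie with 3 broken by enumeration order
  expect_equal(sc$scores$mean_rmse[1], 0, tolerance = 1e-8)
  expect_equal(sc$scores$mean_rmse[1], sc$scores$mean_rmse[3],
               tolerance = 1e-12)
  expect_gte(sc$scores$mean_rmse[2], sc$scores$mean_rmse[1])
  expect_s3_class(sc$best_bank, "estimator_bank")
})
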