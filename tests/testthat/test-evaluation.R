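test_that("range of motion pools extremes across datasets", {
  set.seed(29)
  m1 <- matrix(rnorm(50 * 16, 10, 1), 50, 16) # nonzero range everywhere
  m1[, 1] <- seq(0, 60, length.out = 50)
  one <- recording_tbl(m1)
  expect_equal(rom_table(one)$rom[1], 60)

  a <- recording_tbl(matrix(runif(50 * 16, 0, 40), 50, 16))
  b <- recording_tbl(matrix(runif(50 * 16, -10, 30), 50, 16), task = "T2")
  pooled <- rom_table(a, b)
  sep_max <- pmax(apply(as.matrix(a[dof_labels()]), 2, max),
                  apply(as.matrix(b[dof_labels()]), 2, max))
  sep_min <- pmin(apply(as.matrix(a[dof_labels()]), 2, min),
                  apply(as.matrix(b[dof_labels()]), 2, min))
  expect_equal(pooled$rom, unname(sep_max - sep_min))

  flat <- recording_tbl(matrix(5, 20, 16))
  expect_error(rom_table(flat), class = "handsyn_degenerate_rom")
})

eval_fixture <- function(n = 200, tasks = 2, noise = 0, seed = 30) {
  set.seed(seed)
  rep_set <- c("CMC1F", "CMC1A", "MCP1F", "IP1F", "PIP2F", "PalmArch",
               "PIP4F", "MCP4F")
  make <- function(task) {
    m <- matrix(rnorm(n * 16, 20, 6), n, 16)
    colnames(m) <- dof_labels()
    for (j in setdiff(dof_labels(), rep_set)) {
      m[, j] <- 4 + 0.8 * m[, "PIP4F"] - 0.3 * m[, "MCP4F"] +
        rnorm(n, 0, noise)
    }
    recording_tbl(m, task = paste0("T", task))
  }
  data <- dplyr::bind_rows(lapply(seq_len(tasks), make))
  bank <- fit_estimators(data, rep_set)
  list(data = data, bank = bank, rep_set = rep_set)
}

test_that("a dataset generated by the bank's affine map evaluates to zero error", {
  fx <- eval_fixture(noise = 0)
  rep <- evaluate_estimators(fx$bank, fx$data, rom_table(fx$data))
  expect_equal(rep$global$rmse, rep(0, nrow(rep$global)), tolerance = 1e-8)
  expect_equal(rep$per_activity$rmse, rep(0, nrow(rep$per_activity)),
               tolerance = 1e-8)
})

test_that("global RMSE^2 is the frame-weighted mean of per-activity RMSE^2", {
  fx <- eval_fixture(noise = 3, tasks = 3)
  # unequal activity lengths: drop frames from one task
  data <- dplyr::filter(fx$data, !(task == "T2" & frame > 120))
  rom <- rom_table(data)
  rep <- evaluate_estimators(fx$bank, data, rom)
  for (j in rep$global$dof) {
    pa <- rep$per_activity[rep$per_activity$dof == j, ]
    pooled <- sqrt(sum(pa$n_frames * pa$rmse^2) / sum(pa$n_frames))
    expect_equal(rep$global$rmse[rep$global$dof == j], pooled,
                 tolerance = 1e-9)
  }
  # %RoM bookkeeping
  expect_equal(rep$global$pct_rom,
               100 * rep$global$rmse /
                 rom$rom[match(rep$global$dof, rom$dof)],
               tolerance = 1e-9)
  # per-activity average across DoF (the AVG column)
  for (tk in rep$activity_avg$task) {
    expect_equal(
      rep$activity_avg$avg_pct_rom[rep$activity_avg$task == tk],
      mean(rep$per_activity$pct_rom[rep$per_activity$task == tk]),
      tolerance = 1e-12
    )
  }
})

test_that("%RoM is invariant to a shared constant offset", {
  fx <- eval_fixture(noise = 2)
  rom <- rom_table(fx$data)
  base <- evaluate_estimators(fx$bank, fx$data, rom)

  # shift one estimated DoF in both the data and the bank's intercept
  shift <- 25
  j <- fx$bank$estimated[1]
  data2 <- dplyr::mutate(fx$data, !!j := .data[[j]] + shift)
  bank2 <- fx$bank
  bank2$coefficients$intercept[bank2$coefficients$dof == j] <-
    bank2$coefficients$intercept[bank2$coefficients$dof == j] + shift
  rom2 <- rom_table(data2)
  shifted <- evaluate_estimators(bank2, data2, rom2)
  expect_equal(shifted$global$pct_rom, base$global$pct_rom, tolerance = 1e-9)
})

test_that("single-frame activities reduce to absolute error", {
  fx <- eval_fixture(noise = 2)
  one <- dplyr::filter(fx$data, task == "T1", frame == 1)
  rom <- rom_table(fx$data)
  rep <- evaluate_estimators(fx$bank, one, rom)
  est <- estimate_angles(fx$bank, one)
  for (j in fx$bank$estimated) {
    expect_equal(rep$per_activity$rmse[rep$per_activity$dof == j],
                 abs(est[[j]] - one[[j]]), tolerance = 1e-9)
  }
})

test_that("evaluation on the training frames reproduces training RMSE", {
  fx <- eval_fixture(noise = 2)
  rep <- evaluate_estimators(fx$bank, fx$data, rom_table(fx$data))
  expect_equal(
    rep$global$rmse[match(fx$bank$training$rmse$dof, rep$global$dof)],
    fx$bank$training$rmse$rmse, tolerance = 1e-9
  )
})

test_that("trace export is long, complete, and round-trips", {
  fx <- eval_fixture(noise = 1)
  one_rec <- dplyr::filter(fx$data, task == "T1")
  traces <- export_traces(fx$bank, one_rec)
  expect_equal(nrow(traces), nrow(one_rec) * length(fx$bank$estimated))
  expect_named(traces, c("subject", "task", "frame", "dof",
                         "recorded", "estimated"))

  # zero-coefficient bank gives a constant estimate
  zero <- fx$bank
  zero$coefficients[fx$bank$representative] <- 0
  tz <- export_traces(zero, one_rec)
  expect_equal(dplyr::n_distinct(tz$estimated), length(zero$estimated))

  path <- tempfile(fileext = ".csv")
  readr::write_csv(traces, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$recorded, traces$recorded, tolerance = 1e-6)
  expect_equal(back$estimated, traces$estimated, tolerance = 1e-6)
})
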