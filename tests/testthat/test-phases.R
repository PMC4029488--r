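# Hand-built piecewise trajectory with known event times: glycogen drop and
# HPr translocation at t = 1, operon expression above threshold at t = 2,
# sustained EIIA phosphorylation from t = 3, glucose exhaustion at t = 4.
piecewise_trajectory <- function(t_end = 5, stride = 0.05) {
  model <- build_ecoli_model()
  tt <- seq(0, t_end, by = stride)
  n <- length(tt)
  cols <- names(model$places)
  M <- matrix(0, nrow = n, ncol = length(cols),
              dimnames = list(NULL, cols))
  M[, "Glc_ext"] <- ifelse(tt < 4, 10, 0.001)
  M[, "glycogen"] <- ifelse(tt < 1, 2, 0.4)
  M[, "HPr_pole"] <- ifelse(tt < 1, 1, 0)
  M[, "HPr_cyt"] <- ifelse(tt < 1, 0, 1)
  M[, "expr_ptsHIcrr"] <- ifelse(tt < 2, 0.2, 2)
  M[, "expr_ptsG"] <- ifelse(tt < 2, 0.2, 2)
  M[, "EIIA"] <- ifelse(tt < 3, 1, 0)
  M[, "PEIIA"] <- ifelse(tt < 3, 0, 1)
  M[, "Cra"] <- 1
  M[, "CRP"] <- 1
  structure(list(times = tt, markings = M, dt = stride,
                 record_stride = stride, model = model),
            class = "hfpn_trajectory")
}

test_that("phase boundaries land on the constructed event times", {
  traj <- piecewise_trajectory()
  seg <- classify_phases(traj)
  expect_identical(seg$label,
                   c("early_lag", "late_lag", "early_log", "late_log",
                     "stationary"))
  expect_equal(seg$t_start[-1], 1:4, tolerance = 0.051)
  # contiguous, non-overlapping, covering [0, t_end]
  expect_identical(seg$t_start[1], 0)
  expect_identical(seg$t_end[5], 5)
  expect_identical(seg$t_end[-5], seg$t_start[-1])
})

test_that("classification errors name the missing boundary", {
  traj <- piecewise_trajectory()
  # truncate before glucose depletion
  keep <- traj$times < 3.5
  traj$times <- traj$times[keep]
  traj$markings <- traj$markings[keep, , drop = FALSE]
  expect_error(classify_phases(traj), "late_log -> stationary")
})

test_that("pearson_r matches hand-evaluated product-moment values", {
  x <- c(3, 1, 4, 1, 5)
  expect_identical(pearson_r(x, x), 1.0)
  expect_identical(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1.0)
  # direct formula: x = 1:4, y = (1,2,4,3) -> r = 4 / 5
  expect_equal(pearson_r(1:4, c(1, 2, 4, 3)), 0.8)
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(c(1, 2), c(2, 1)), "at least 3")
  expect_error(pearson_r(c(1, 1, 1), 1:3), "zero variance")
})

test_that("pearson_r is invariant under positive affine transforms", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(20)
    y <- rnorm(20)
    r0 <- pearson_r(x, y)
    expect_equal(pearson_r(2.7 * x + 5, y), r0, tolerance = 1e-12)
    expect_equal(pearson_r(x, 0.03 * y - 11), r0, tolerance = 1e-12)
  }
})

test_that("align_series interpolates linearly within the span", {
  mod <- decay_net(k = 0.2)
  traj <- hfpn_simulate(mod, t_end = 2, dt = 1e-2, record_stride = 0.1)
  at_grid <- align_series(traj, "A", traj$times[3:5])
  expect_identical(at_grid, unname(traj$markings[3:5, "A"]))
  mid <- align_series(traj, "A", 0.15)
  expect_equal(mid, mean(traj$markings[2:3, "A"]))
  expect_error(align_series(traj, "A", 3), "outside")
  expect_error(align_series(traj, "Z", 1), "not in trajectory")
  # refining the recording grid changes interpolants by at most the
  # curvature scale (max second difference of the coarse grid)
  fine <- hfpn_simulate(mod, t_end = 2, dt = 1e-2, record_stride = 0.01)
  probe <- seq(0.05, 1.95, by = 0.07)
  d <- abs(align_series(traj, "A", probe) - align_series(fine, "A", probe))
  second_diff <- max(abs(diff(traj$markings[, "A"], differences = 2)))
  expect_lte(max(d), second_diff)
})

test_that("an all-zero trajectory discretizes to the lowest bins", {
  traj <- piecewise_trajectory()
  traj$markings[] <- 0
  seg <- structure(
    data.frame(label = phase_labels(), t_start = 0:4, t_end = 1:5,
               stringsAsFactors = FALSE),
    class = c("phase_segmentation", "data.frame"))
  tab <- discretize_states(traj, seg)
  for (ph in phase_labels()) {
    expect_identical(table_cell(tab, "uptake", ph), "no")
    expect_identical(table_cell(tab, "composition", ph), "no")
    expect_identical(table_cell(tab, "decomposition", ph), "no")
    expect_identical(table_cell(tab, "FDP", ph), "low")
    expect_identical(table_cell(tab, "cAMP", ph), "low")
    expect_identical(table_cell(tab, "localization", ph), "cytosol")
  }
  # re-discretizing the same constant trajectory is idempotent
  expect_identical(tab, discretize_states(traj, seg))
})

test_that("batch-culture event ordering holds on the default simulation", {
  traj <- default_traj()
  rs <- regulatory_series(traj)
  # the glycogen trough (consumption turning into re-accumulation) precedes
  # glucose depletion; glycogen is consumed again after stationary onset,
  # so the first local minimum is the relevant event
  troughs <- which(diff(sign(diff(rs$glycogen))) > 0) + 1L
  t_gly_min <- rs$time[troughs[1]]
  t_glc_gone <- rs$time[which(rs$Glc_ext < 0.05)[1]]
  expect_lt(t_gly_min, t_glc_gone)
  # the first G6P surge comes after glycogen consumption has begun
  g6p <- traj$markings[, "G6P"]
  t_g6p_peak <- rs$time[which(diff(sign(diff(g6p))) < 0)[1] + 1L]
  t_gly_falling <- rs$time[which(rs$glycogen < 0.98 * rs$glycogen[1])[1]]
  expect_gt(t_g6p_peak, t_gly_falling)
})

test_that("segmentation of the default simulation covers the span", {
  seg <- default_segmentation()
  expect_identical(seg$t_start[1], 0)
  expect_equal(seg$t_end[5], max(default_traj()$times))
  expect_true(all(seg$t_end >= seg$t_start))
  expect_identical(seg$t_end[-5], seg$t_start[-1])
})
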