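test_that("enabling semantics follow arc kinds and thresholds", {
  mk <- function(kind, threshold) {
    hfpn_model(
      places = list(hfpn_place("A", marking = 0.5)),
      transitions = list(hfpn_continuous_transition("t", function(m, p) 1)),
      arcs = list(hfpn_arc("A", "t", "input", kind, weight = 1,
                           threshold = threshold)))
  }
  expect_false(is_enabled(mk("normal", 1.0), "t", c(A = 0.5)))
  expect_true(is_enabled(mk("normal", 1.0), "t", c(A = 1.0)))
  expect_true(is_enabled(mk("inhibitory", 1.0), "t", c(A = 0.5)))
  expect_false(is_enabled(mk("inhibitory", 1.0), "t", c(A = 1.5)))
  expect_true(is_enabled(mk("test", 0.2), "t", c(A = 0.5)))

  no_input <- hfpn_model(
    places = list(hfpn_place("A")),
    transitions = list(hfpn_continuous_transition("src", function(m, p) 1)),
    arcs = list(hfpn_arc("A", "src", "output")))
  expect_true(is_enabled(no_input, "src", c(A = 0)))
  expect_error(is_enabled(no_input, "nope", c(A = 0)), "unknown transition")
})

test_that("structural validation rejects malformed models and arcs", {
  expect_error(hfpn_arc("A", "t", "output", "test"), "input-only")
  expect_error(hfpn_arc("A", "t", "input", "inhibitory"),
               "explicit threshold")
  expect_error(hfpn_arc("A", "t", "input", weight = 0), "> 0")
  expect_error(hfpn_place("A", marking = -1), "non-negative")
  expect_error(
    hfpn_model(places = list(hfpn_place("A")),
               transitions = list(
                 hfpn_continuous_transition("t", function(m, p) 0)),
               arcs = list(hfpn_arc("B", "t", "input", threshold = 0))),
    "unknown place")
})

test_that("a zero-rate step leaves markings unchanged and dt is validated", {
  mod <- decay_net(k = 0)
  st <- hfpn_step(mod, initial_marking(mod), dt = 0.1)
  expect_identical(unname(st$marking[["A"]]), 1)
  expect_error(hfpn_step(mod, initial_marking(mod), dt = 0), "positive")
})

test_that("single-species decay matches the closed-form exponential", {
  mod <- decay_net(k = 0.1, A0 = 1)
  traj <- hfpn_simulate(mod, t_end = 10, dt = 1e-3, record_stride = 0.5)
  A10 <- traj$markings[nrow(traj$markings), "A"]
  expect_equal(unname(A10), exp(-1), tolerance = 1e-3)
})

test_that("halving dt roughly halves the error of the decay solution", {
  err <- function(dt) {
    mod <- decay_net(k = 0.5, A0 = 1)
    traj <- hfpn_simulate(mod, t_end = 4, dt = dt, record_stride = 1)
    abs(traj$markings[nrow(traj$markings), "A"] - exp(-2))
  }
  e1 <- err(2e-3)
  e2 <- err(1e-3)
  expect_gt(e1 / e2, 1.8)
  expect_lt(e1 / e2, 2.2)
})

test_that("closed cycles conserve mass along the whole trajectory", {
  mod <- cycle_net()
  traj <- hfpn_simulate(mod, t_end = 5, dt = 1e-3, record_stride = 0.1)
  tot <- rowSums(traj$markings)
  expect_lt(max(abs(tot - tot[1])), 1e-9)
})

test_that("simulation is deterministic and honours the record stride", {
  mod <- cycle_net()
  t1 <- hfpn_simulate(mod, t_end = 2, dt = 1e-3, record_stride = 0.1)
  t2 <- hfpn_simulate(mod, t_end = 2, dt = 1e-3, record_stride = 0.1)
  expect_identical(t1$markings, t2$markings)
  short <- hfpn_simulate(mod, t_end = 0.01, dt = 0.01, record_stride = 0.01)
  expect_length(short$times, 2L)
  expect_error(hfpn_simulate(mod, t_end = 1, dt = 1e-3,
                             record_stride = 0.0015),
               "multiple of dt")
})

test_that("no recorded marking is negative on random mass-action nets", {
  for (seed in 1:8) {
    mod <- random_ma_net(seed = seed)
    traj <- hfpn_simulate(mod, t_end = 3, dt = 2e-3, record_stride = 0.1)
    expect_gte(min(traj$markings), 0)
  }
})

test_that("the negative-marking guard preserves within-step stoichiometry", {
  # consumption far exceeding the available marking in one step: A -> 2B
  mod <- hfpn_model(
    places = list(hfpn_place("A", marking = 0.1),
                  hfpn_place("B", marking = 0)),
    transitions = list(hfpn_continuous_transition("t", function(m, p) 100)),
    arcs = list(hfpn_arc("A", "t", "input", "normal", 1, threshold = 0),
                hfpn_arc("B", "t", "output", weight = 2)))
  st <- hfpn_step(mod, initial_marking(mod), dt = 1)
  expect_equal(unname(st$marking[["A"]]), 0, tolerance = 1e-12)
  expect_equal(unname(st$marking[["B"]]), 0.2, tolerance = 1e-12)
})

test_that("test and inhibitory arcs never alter markings", {
  mod <- hfpn_model(
    places = list(hfpn_place("A", marking = 2), hfpn_place("B", marking = 3)),
    transitions = list(hfpn_continuous_transition("t", function(m, p) 1)),
    arcs = list(hfpn_arc("A", "t", "input", "test", threshold = 0.5),
                hfpn_arc("B", "t", "input", "inhibitory", threshold = 10)))
  traj <- hfpn_simulate(mod, t_end = 1, dt = 1e-2, record_stride = 0.1)
  expect_identical(unname(traj$markings[nrow(traj$markings), ]), c(2, 3))
})

test_that("discrete transitions fire after their enabling delay, in order", {
  mod <- hfpn_model(
    places = list(hfpn_place("A", "discrete", marking = 3),
                  hfpn_place("B", "discrete", marking = 0)),
    transitions = list(
      hfpn_discrete_transition("move", delay = 0.5, effects = c(A = -1,
                                                                B = 1))),
    arcs = list(hfpn_arc("A", "move", "input", "test", threshold = 1)))
  traj <- hfpn_simulate(mod, t_end = 1.8, dt = 0.01, record_stride = 0.1)
  final <- traj$markings[nrow(traj$markings), ]
  # fires at t = 0.5, 1.0, 1.5 -> three tokens moved
  expect_identical(unname(final), c(0, 3))
  expect_true(all(traj$markings == round(traj$markings)))
})

test_that("moiety_total sums weighted markings and flags unknown places", {
  expect_identical(moiety_total(c(A = 1), stats::setNames(numeric(0),
                                                          character(0))), 0)
  expect_equal(moiety_total(c(A = 0.3, B = 0.7), c(A = 1, B = 1)), 1.0)
  expect_equal(moiety_total(c(A = 0.5, B = 2), c(A = 2, B = 0.5)), 2.0)
  expect_error(moiety_total(c(A = 1), c(Z = 1)), "unknown places")
})

test_that("fixed-step engine matches adaptive reference on a smooth net", {
  mod <- cycle_net(kf = 1.2, kr = 0.4)
  traj <- hfpn_simulate(mod, t_end = 4, dt = 1e-3, record_stride = 0.2)
  ref <- deSolve::ode(y = initial_marking(mod), times = traj$times,
                      func = hfpn_ode_rhs(mod), parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  rel <- abs(traj$markings - ref[, colnames(traj$markings)]) /
    pmax(abs(ref[, colnames(traj$markings)]), 0.01)
  expect_lt(max(rel), 0.005)
})

test_that("integration blow-up reports the source and the time", {
  mod <- hfpn_model(
    places = list(hfpn_place("A", marking = 1)),
    transitions = list(
      hfpn_continuous_transition("exp", function(m, p) m[["A"]]^3 * 1e3)),
    arcs = list(hfpn_arc("A", "exp", "input", "test", threshold = 0),
                hfpn_arc("A", "exp", "output")))
  expect_error(hfpn_simulate(mod, t_end = 10, dt = 0.1, record_stride = 0.1),
               "at time .* 'exp'")
})
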