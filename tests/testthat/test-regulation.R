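test_that("gamma is the unique two-input three-level activation table", {
  expect_identical(gamma_lookup(0, 0), 0L)
  expect_identical(gamma_lookup(0, 1), 1L)
  expect_identical(gamma_lookup(1, 0), 1L)
  expect_identical(gamma_lookup(1, 1), 2L)
  expect_error(gamma_lookup(2, 0), "0 or 1")
  expect_error(gamma_lookup(0, -1), "0 or 1")
})

test_that("alpha follows Cra dynamics under FDP repression", {
  thr <- regulation_thresholds()
  p <- default_parameters()
  # FDP = 0 held: Cra converges to its maximal level, alpha stays 0
  cra <- 0.9
  for (i in 1:4000) cra <- alpha_state(0, cra, thr, p, dt = 1e-3)$Cra
  expect_equal(cra, p$v_cra / p$d_cra, tolerance = 1e-3)
  expect_identical(alpha_state(0, cra, thr, p)$alpha, 0L)

  # FDP >> FDP_high held: Cra decays below threshold -> alpha = 1
  cra <- 1
  crossed_at <- NA
  for (i in 1:6000) {
    st <- alpha_state(10, cra, thr, p, dt = 1e-3)
    cra <- st$Cra
    if (st$alpha == 1L && is.na(crossed_at)) crossed_at <- i * 1e-3
  }
  expect_identical(alpha_state(10, cra, thr, p)$alpha, 1L)
  # first-order decay to ~0: crossing time ~ log(1/thr)/d_cra
  expect_equal(crossed_at, log(1 / thr$cra_threshold) / p$d_cra,
               tolerance = 0.05)

  # step back to low FDP: alpha returns to 0 with the resynthesis lag
  for (i in 1:6000) cra <- alpha_state(0, cra, thr, p, dt = 1e-3)$Cra
  expect_identical(alpha_state(0, cra, thr, p)$alpha, 0L)
})

test_that("beta follows the PEIIA -> cAMP -> cAMP/CRP loop", {
  thr <- regulation_thresholds()
  p <- default_parameters()
  pools <- list(cAMP = 0.5, CRP = 0.5, cAMP_CRP = 0.5)
  # no phosphorylated EIIA: cAMP decays, complex dissolves, beta -> 0
  for (i in 1:8000) {
    st <- beta_state(0, pools, thr, p, dt = 1e-3)
    pools <- st[c("cAMP", "CRP", "cAMP_CRP")]
  }
  expect_identical(st$beta, 0L)
  expect_lt(pools$cAMP, 1e-2)
  # total CRP conserved by the loop
  expect_equal(pools$CRP + pools$cAMP_CRP, 1.0, tolerance = 1e-9)

  # high PEIIA held: beta = 1 at steady state
  for (i in 1:8000) {
    st <- beta_state(1, pools, thr, p, dt = 1e-3)
    pools <- st[c("cAMP", "CRP", "cAMP_CRP")]
  }
  expect_identical(st$beta, 1L)
})

test_that("pole fraction relaxes toward the flux/phosphorylation targets", {
  thr <- regulation_thresholds()
  # neither condition met: unchanged
  expect_identical(update_pole_fraction(0, 0, 0.4, dt = 0.01, thr), 0.4)
  # strong flux held long: -> 0
  pf <- 1
  for (i in 1:2000) pf <- update_pole_fraction(1, 0.1, pf, 1e-3, thr)
  expect_lt(pf, 1e-3)
  # idle flux + phosphorylated HPr held long: -> 1
  pf <- 0
  for (i in 1:2000) pf <- update_pole_fraction(0, 1, pf, 1e-3, thr)
  expect_gt(pf, 1 - 1e-3)
  expect_error(update_pole_fraction(0, 0, 0.5, dt = 0), "> 0")
})

test_that("GlgP complex speed ratio is exactly five under defaults", {
  gp <- glgp_params()
  expect_identical(gp$k_fast / gp$k_slow, 5)
  flux_u <- glycogen_decomposition_rate(1, 1, 0, 2, gp)
  flux_p <- glycogen_decomposition_rate(1, 0, 1, 2, gp)
  expect_identical(flux_u / flux_p, 5)
  # trivial gates
  expect_identical(glycogen_decomposition_rate(1, 1, 0, 0, gp), 0)
  expect_identical(glycogen_decomposition_rate(0, 1, 0, 2, gp), 0)
})

test_that("decomposition flux is linear in glycogen and bounded by the pure complexes", {
  gp <- glgp_params(k_fast = 10, GlgP_total = 0.15)
  set.seed(7)
  for (i in 1:25) {
    h <- runif(1, 0, 2)
    ph <- runif(1, 0, 2)
    gly <- runif(1, 0, 5)
    pf <- runif(1)
    fl <- glycogen_decomposition_rate(pf, h, ph, gly, gp)
    expect_gte(fl + 1e-12, gp$k_slow * gp$GlgP_total * gly * pf)
    expect_lte(fl - 1e-12, gp$k_fast * gp$GlgP_total * gly * pf)
    expect_equal(glycogen_decomposition_rate(pf, h, ph, 2 * gly, gp),
                 2 * fl, tolerance = 1e-12)
  }
})

test_that("PTS acceleration switches at the inclusive expression threshold", {
  thr <- regulation_thresholds()
  A <- 10
  expect_identical(pts_acceleration(0, 0, thr, A), 1)
  expect_identical(pts_acceleration(2 * thr$expr_PTS_threshold,
                                    2 * thr$expr_PTS_threshold, thr, A), A)
  expect_identical(pts_acceleration(thr$expr_PTS_threshold,
                                    thr$expr_PTS_threshold, thr, A), A)
  # both operons must be above threshold
  expect_identical(pts_acceleration(2 * thr$expr_PTS_threshold, 0, thr, A), 1)
})

test_that("glgCA synthesis is ordered in gamma and reaches its steady level", {
  tab <- list(slow = 0.5, fast = 5)
  r <- vapply(0:2, glgCA_synthesis_rate, numeric(1), rate_table = tab)
  expect_identical(r[[1]], 0)
  expect_true(r[[3]] > r[[2]] && r[[2]] > r[[1]])
  expect_error(glgCA_synthesis_rate(3), "0, 1 or 2")
  # held gamma = 1: first-order steady state = synthesis / decay
  p <- default_parameters()
  level <- 0
  syn <- glgCA_synthesis_rate(1, list(slow = p$glg_rate_slow,
                                      fast = p$glg_rate_fast))
  for (i in 1:20000) level <- level + 1e-3 * (syn - p$d_glg_expr * level)
  expect_equal(level, syn / p$d_glg_expr, tolerance = 1e-4)
})
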