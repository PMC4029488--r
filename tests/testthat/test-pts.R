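test_that("EI dimerization gate is a Hill function of PEP", {
  expect_identical(ei_dimer_active_fraction(0), 0)
  expect_equal(ei_dimer_active_fraction(1, K_dim = 1), 0.5)
  expect_equal(ei_dimer_active_fraction(0.5, K_dim = 0.5, n_dim = 3), 0.5)
  grid <- ei_dimer_active_fraction(seq(0, 10, by = 0.05), K_dim = 1,
                                   n_dim = 2)
  expect_true(all(diff(grid) >= 0))
  expect_true(all(grid >= 0 & grid <= 1))
  expect_error(ei_dimer_active_fraction(-0.1), ">= 0")
})

test_that("uptake requires glucose and phosphorylated EIICB", {
  m <- c(PEP = 1, PYR = 0, Glc_ext = 0, G6P = 0, EI = 0.1, PEI = 0.1,
         HPr_pole = 0, PHPr_pole = 0, HPr_cyt = 0.2, PHPr_cyt = 0.2,
         EIIA = 0.2, PEIIA = 0.2, EIICB = 0.1, PEIICB = 0.1)
  fl <- phospho_flux(m, default_parameters())
  expect_identical(unname(fl[["R5"]]), 0)
  m["Glc_ext"] <- 5
  expect_gt(phospho_flux(m, default_parameters())[["R5"]], 0)
})

test_that("phospho-flux is zero at the all-zero and detailed-balance points", {
  p <- default_parameters()
  zero <- stats::setNames(numeric(14),
                          c(pts_place_ids(), "PEP", "PYR", "Glc_ext", "G6P"))
  expect_true(all(phospho_flux(zero, p) == 0))
  # R2 detailed balance: PEI*HPr*k2f = EI*PHPr*k2r (k2f = k2r here)
  m <- zero
  m[c("PEI", "HPr_cyt", "EI", "PHPr_cyt")] <- c(0.2, 0.3, 0.3, 0.2)
  fl <- phospho_flux(m, p)
  expect_equal(unname(fl[["flux_EI_to_HPr"]]), 0, tolerance = 1e-12)
  expect_error(phospho_flux(c(PEP = 1), p), "missing PTS places")
})

test_that("phospho-flux matches a one-microstep finite difference", {
  mod <- pts_only_model(pep_source = 0,
                        init = list(PEP = 0.8, Glc_ext = 3, PEI = 0.1,
                                    PHPr_cyt = 0.15, PEIIA = 0.1,
                                    PEIICB = 0.05))
  m <- initial_marking(mod)
  fl <- phospho_flux(m, mod$parameters)
  dt <- 1e-6
  st <- hfpn_step(mod, m, dt)
  # net R1 flux = PYR production rate; net R5 = G6P production rate
  expect_equal(unname((st$marking[["PYR"]] - m[["PYR"]]) / dt),
               unname(fl[["R1"]]), tolerance = 1e-6)
  expect_equal(unname((st$marking[["G6P"]] - m[["G6P"]]) / dt),
               unname(fl[["R5"]]), tolerance = 1e-6)
})

test_that("phosphorylation fractions pool HPr and guard empty pools", {
  m <- c(EIIA = 0, PEIIA = 1, HPr_pole = 0.1, PHPr_pole = 0.2,
         HPr_cyt = 0.3, PHPr_cyt = 0.4, EI = 0.5, PEI = 0.5,
         EIICB = 0, PEIICB = 0)
  expect_identical(phosphorylation_fraction(m, "EIIA"), 1.0)
  expect_equal(phosphorylation_fraction(m, "HPr"), 0.6)
  expect_identical(phosphorylation_fraction(m, "EI"), 0.5)
  expect_error(phosphorylation_fraction(m, "EIICB"), "undefined")
})

test_that("moieties are conserved and k = 0 freezes the relay", {
  mod <- pts_only_model(init = list(Glc_ext = 2, PEP = 0.5, PEIIA = 0.1))
  traj <- hfpn_simulate(mod, t_end = 3, dt = 1e-3, record_stride = 0.1)
  for (pair in list(c(EI = 1, PEI = 1),
                    c(HPr_pole = 1, PHPr_pole = 1, HPr_cyt = 1,
                      PHPr_cyt = 1),
                    c(EIIA = 1, PEIIA = 1),
                    c(EIICB = 1, PEIICB = 1))) {
    tot <- moiety_total(traj, pair)
    expect_lt(max(abs(tot - tot[1])), 1e-9)
  }

  frozen <- pts_only_model(params = list(k_pts = 0), pep_source = 0,
                           init = list(Glc_ext = 2, PEP = 0.5, PEIIA = 0.1))
  tr2 <- hfpn_simulate(frozen, t_end = 1, dt = 1e-2, record_stride = 0.1)
  pts_cols <- pts_place_ids()
  expect_identical(tr2$markings[nrow(tr2$markings), pts_cols],
                   tr2$markings[1, pts_cols])
})

test_that("increasing PEP never decreases the instantaneous R1 flux", {
  p <- default_parameters()
  base <- stats::setNames(numeric(14),
                          c(pts_place_ids(), "PEP", "PYR", "Glc_ext", "G6P"))
  base[c("EI", "HPr_cyt", "EIIA", "EIICB")] <- 0.2
  r1 <- vapply(seq(0, 5, by = 0.1), function(pep) {
    m <- base
    m["PEP"] <- pep
    phospho_flux(m, p)[["R1"]]
  }, numeric(1))
  expect_true(all(diff(r1) >= -1e-12))
})

test_that("phosphate bookkeeping: PEP consumed equals PYR made plus pools", {
  mod <- pts_only_model(pep_source = 0,
                        init = list(PEP = 2, Glc_ext = 1))
  traj <- hfpn_simulate(mod, t_end = 4, dt = 1e-3, record_stride = 0.5)
  first <- traj$markings[1, ]
  last <- traj$markings[nrow(traj$markings), ]
  pep_used <- first[["PEP"]] - last[["PEP"]]
  pyr_made <- last[["PYR"]] - first[["PYR"]]
  expect_equal(pep_used, pyr_made, tolerance = 1e-9)
  # every phosphate from PEP is now on G6P or on a phospho-protein
  phos_pools <- c("PEI", "PHPr_pole", "PHPr_cyt", "PEIIA", "PEIICB")
  expect_equal(unname(pep_used),
               unname(last[["G6P"]] - first[["G6P"]] +
                        sum(last[phos_pools]) - sum(first[phos_pools])),
               tolerance = 1e-9)
})
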