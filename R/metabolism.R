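#' Metabolite species of the integrated model
#'
#' One continuous place per species, units mM.  `PG6`, `PG3`, `PG2` denote
#' 6-phosphogluconate, 3-phosphoglycerate and 2-phosphoglycerate (ids are
#' letter-led for interchange formats); `glycogen` is counted in mM
#' hexose-equivalents.
#'
#' @return Character vector of species ids.
#' @export
metabolite_pool <- function() {
  c("Glc_ext", "G6P", "F6P", "FDP", "DHAP", "GAP", "PGP", "PG3", "PG2",
    "PEP", "PYR", "PG6", "Ru5P", "R5P", "X5P", "E4P", "S7P",
    "G1P", "ADPG", "glycogen", "cAMP")
}

ma <- function(k) rate_law("mass_action", k = k)

#' Glycolysis and pentose phosphate reaction set
#'
#' The linear glycolytic chain G6P -> F6P -> FDP -> (DHAP + GAP),
#' DHAP <-> GAP, GAP -> PGP -> 3PG -> 2PG -> PEP -> PYR, the oxidative PP
#' branch G6P -> 6PG -> Ru5P with the Ru5P <-> R5P / Ru5P <-> X5P
#' isomerisations, and the transketolase/transaldolase exchanges
#' (R5P + X5P <-> S7P + GAP; S7P + GAP <-> E4P + F6P;
#' E4P + X5P <-> F6P + GAP).  All reactions default to general mass action;
#' PYR is a sink inside this set (drained only by dilution and PTS phosphate
#' regeneration), since TCA/acetate routes are outside the model.
#'
#' @param params Parameter list supplying one rate constant per reaction id
#'   (see [default_parameters()]).
#' @return List of 16 [reaction()] objects.
#' @export
build_glycolysis_pp <- function(params = default_parameters()) {
  need <- c("k_pgi", "k_pfk", "k_fba", "k_tpi_f", "k_tpi_r", "k_gapdh",
            "k_pgk", "k_gpm", "k_eno", "k_pyk", "k_zwf", "k_gnd",
            "k_rpi_f", "k_rpi_r", "k_rpe_f", "k_rpe_r", "k_tkt1_f",
            "k_tkt1_r", "k_tal_f", "k_tal_r", "k_tkt2_f", "k_tkt2_r")
  check_params(params, need, "glycolysis/PP")
  list(
    reaction("pgi", c(G6P = 1), c(F6P = 1), ma(params$k_pgi)),
    reaction("pfk", c(F6P = 1), c(FDP = 1), ma(params$k_pfk)),
    reaction("fba", c(FDP = 1), c(DHAP = 1, GAP = 1), ma(params$k_fba)),
    reaction("tpi", c(DHAP = 1), c(GAP = 1), ma(params$k_tpi_f),
             reverse_law = ma(params$k_tpi_r)),
    reaction("gapdh", c(GAP = 1), c(PGP = 1), ma(params$k_gapdh)),
    reaction("pgk", c(PGP = 1), c(PG3 = 1), ma(params$k_pgk)),
    reaction("gpm", c(PG3 = 1), c(PG2 = 1), ma(params$k_gpm)),
    reaction("eno", c(PG2 = 1), c(PEP = 1), ma(params$k_eno)),
    reaction("pyk", c(PEP = 1), c(PYR = 1), ma(params$k_pyk)),
    reaction("zwf", c(G6P = 1), c(PG6 = 1), ma(params$k_zwf)),
    reaction("gnd", c(PG6 = 1), c(Ru5P = 1), ma(params$k_gnd)),
    reaction("rpi", c(Ru5P = 1), c(R5P = 1), ma(params$k_rpi_f),
             reverse_law = ma(params$k_rpi_r)),
    reaction("rpe", c(Ru5P = 1), c(X5P = 1), ma(params$k_rpe_f),
             reverse_law = ma(params$k_rpe_r)),
    reaction("tkt1", c(R5P = 1, X5P = 1), c(S7P = 1, GAP = 1),
             ma(params$k_tkt1_f), reverse_law = ma(params$k_tkt1_r)),
    reaction("tal", c(S7P = 1, GAP = 1), c(E4P = 1, F6P = 1),
             ma(params$k_tal_f), reverse_law = ma(params$k_tal_r)),
    reaction("tkt2", c(E4P = 1, X5P = 1), c(F6P = 1, GAP = 1),
             ma(params$k_tkt2_f), reverse_law = ma(params$k_tkt2_r))
  )
}

check_params <- function(params, need, what) {
  miss <- need[!vapply(need, function(n) !is.null(params[[n]]), logical(1))]
  if (length(miss)) {
    stop("missing ", what, " parameters: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

# Effective glgC&glgA expression level: the expr_glgCA place when present in
# the marking, else a fixed parameter (standalone glycogen subsystems).
glgCA_level <- function(m, p) {
  if ("expr_glgCA" %in% names(m)) m[["expr_glgCA"]]
  else if (!is.null(p$fixed_glgCA_level)) p$fixed_glgCA_level
  else 1
}

# Pole composition of HPr from the marking, falling back to fixed parameters
# when the HPr pools are not part of the model.
pole_state <- function(m, p) {
  nm <- names(m)
  if (all(c("HPr_pole", "PHPr_pole", "HPr_cyt", "PHPr_cyt") %in% nm)) {
    tot <- m[["HPr_pole"]] + m[["PHPr_pole"]] + m[["HPr_cyt"]] +
      m[["PHPr_cyt"]]
    pf <- if (tot > 0) (m[["HPr_pole"]] + m[["PHPr_pole"]]) / tot else 0
    list(pole_fraction = pf, HPr_pole = m[["HPr_pole"]],
         PHPr_pole = m[["PHPr_pole"]])
  } else {
    list(pole_fraction = if (!is.null(p$fixed_pole_fraction))
           p$fixed_pole_fraction else 1,
         HPr_pole = if (!is.null(p$fixed_HPr_pole)) p$fixed_HPr_pole else 1,
         PHPr_pole = if (!is.null(p$fixed_PHPr_pole)) p$fixed_PHPr_pole
           else 0)
  }
}

model_glgp_params <- function(p) {
  glgp_params(k_fast = p$k_glgP_fast, k_slow = p$k_glgP_slow,
              GlgP_total = p$GlgP_total)
}

#' Glycogen metabolism reaction set
#'
#' Phosphoglucomutase G6P <-> G1P (mass action), GlgC-catalyzed G1P -> ADPG
#' and GlgA-catalyzed ADPG -> glycogen (both scaled multiplicatively by the
#' glgC&glgA expression level), and GlgP phosphorolysis glycogen -> G1P whose
#' rate is the HPr-phosphorylation- and localization-dependent
#' [glycogen_decomposition_rate()].  Glycogen is counted in hexose
#' equivalents, so the subsystem conserves hexose units exactly.
#'
#' @param params Parameter list (see [default_parameters()]).
#' @return List of [reaction()] objects.
#' @export
build_glycogen <- function(params = default_parameters()) {
  check_params(params, c("k_pgm_f", "k_pgm_r", "k_glgC", "k_glgA",
                         "k_glgP_fast", "k_glgP_slow", "GlgP_total"),
               "glycogen")
  expr_mod <- function(m, p) glgCA_level(m, p)
  glgP_speed <- function(m, p) {
    st <- pole_state(m, p)
    glycogen_decomposition_rate(st$pole_fraction, st$HPr_pole, st$PHPr_pole,
                                m[["glycogen"]], model_glgp_params(p))
  }
  list(
    reaction("pgm", c(G6P = 1), c(G1P = 1), ma(params$k_pgm_f),
             reverse_law = ma(params$k_pgm_r)),
    reaction("glgC", c(G1P = 1), c(ADPG = 1), ma(params$k_glgC),
             modifier = expr_mod),
    reaction("glgA", c(ADPG = 1), c(glycogen = 1), ma(params$k_glgA),
             modifier = expr_mod),
    reaction("glgP", c(glycogen = 1), c(G1P = 1), law = glgP_speed)
  )
}

#' Default model parameters
#'
#' The shipped constant set for the integrated model.  The study this model
#' emulates fitted its mass-action constants manually against batch-culture
#' measurements; the values here are re-derived by calibrating until the
#' default simulation reproduces the qualitative phase pattern (glycogen
#' consumed before extracellular glucose; glucose exhausted during log phase;
#' glycogen re-accumulating in late log; the five-phase regulator table) and
#' then frozen.  Units: rate constants per hour (first order) or per mM (or
#' au) per hour (second order); thresholds mM or au.
#'
#' @return Named list of parameters, including the nested `thresholds` block
#'   ([regulation_thresholds()]).
#' @export
default_parameters <- function() {
  list(
    # glycolysis
    k_pgi = 10, k_pfk = 8, k_fba = 0.8, k_tpi_f = 10, k_tpi_r = 1,
    k_gapdh = 10, k_pgk = 10, k_gpm = 10, k_eno = 10, k_pyk = 0.8,
    # pentose phosphate
    k_zwf = 0.8, k_gnd = 5, k_rpi_f = 5, k_rpi_r = 1, k_rpe_f = 5,
    k_rpe_r = 1, k_tkt1_f = 2, k_tkt1_r = 0.5, k_tal_f = 2, k_tal_r = 0.5,
    k_tkt2_f = 2, k_tkt2_r = 0.5,
    # glycogen module
    k_pgm_f = 2, k_pgm_r = 20, k_glgC = 4, k_glgA = 10,
    k_glgP_fast = 10, k_glgP_slow = 2, GlgP_total = 0.15,
    # PTS relay
    k_pts = 1, pts_accel = 10, pole_relay_scale = 0.1,
    k1f = 30, k1r = 0.2, k2f = 15, k2r = 15, k3f = 15, k3r = 15,
    k4f = 15, k4r = 15, k5 = 5, K_dim = 1, n_dim = 2,
    # gene expression and regulators
    v_cra = 1.5, d_cra = 1.5, n_fdp = 6,
    v_camp = 2, d_camp = 3, k_bind = 20, k_unbind = 4,
    v_pts_expr = 2, basal_pts_expr = 0.1, K_cra = 0.25, n_cra = 4,
    d_pts_expr = 0.5,
    glg_rate_slow = 0.5, glg_rate_fast = 5, d_glg_expr = 1,
    v_syn_EI = 0.03, v_syn_HPr = 0.025, v_syn_EIIA = 0.025, v_syn_EIICB = 0.006,
    d_prot = 0.05, d_met = 0.05,
    k_leak = 0.5,
    thresholds = regulation_thresholds()
  )
}

#' Default batch-culture initial marking
#'
#' Batch-culture start: extracellular glucose high, a moderate glycogen
#' store, glycolytic intermediates near zero, PTS proteins at low basal
#' levels with every relay component phosphorylated and HPr pole-located
#' (the lag phase opens with P~HPr), Cra at its unrepressed level, and the
#' cAMP/CRP loop in its high state.
#'
#' @return Named numeric vector over the places of the integrated model.
#' @export
default_initial_marking <- function() {
  c(Glc_ext = 10, G6P = 0, F6P = 0, FDP = 0, DHAP = 0, GAP = 0, PGP = 0,
    PG3 = 0, PG2 = 0, PEP = 0, PYR = 0, PG6 = 0, Ru5P = 0, R5P = 0,
    X5P = 0, E4P = 0, S7P = 0, G1P = 0, ADPG = 0, glycogen = 2,
    cAMP = 0.5,
    EI = 0.15, PEI = 0, HPr_pole = 0, PHPr_pole = 0.4, HPr_cyt = 0,
    PHPr_cyt = 0, EIIA = 0, PEIIA = 0.2, EIICB = 0, PEIICB = 0.05,
    Cra = 1, CRP = 0.5, cAMP_CRP = 0.5,
    expr_ptsHIcrr = 0.2, expr_ptsG = 0.2, expr_glgCA = 0)
}
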