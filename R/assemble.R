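#' Assemble the integrated carbohydrate-metabolism HFPN model
#'
#' Combines the glycolysis/pentose-phosphate network, the glycogen module,
#' the PTS phospho-relay, and the regulatory circuit (Cra, cAMP/CRP loop,
#' operon expression, PTS protein synthesis, HPr localization, dilution)
#' into one executable HFPN.
#'
#' @param params Parameter list, defaults to [default_parameters()];
#'   partial lists are merged onto the defaults.
#' @param init Named initial-marking overrides merged onto
#'   [default_initial_marking()].
#' @param include_expression Include PTS protein synthesis transitions
#'   (gene-expression inflow into the relay pools).
#' @param include_dilution Include first-order dilution of proteins and
#'   intracellular metabolites.
#' @return An [hfpn_model()].
#' @export
build_ecoli_model <- function(params = list(), init = NULL,
                              include_expression = TRUE,
                              include_dilution = TRUE) {
  p <- utils::modifyList(default_parameters(), params)
  m0 <- default_initial_marking()
  if (!is.null(init)) {
    bad <- setdiff(names(init), names(m0))
    if (length(bad)) {
      stop("unknown init species: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    m0[names(init)] <- unlist(init)
  }

  prot_unit <- function(id) {
    hfpn_place(id, "continuous", marking = m0[[id]], unit = "au")
  }
  places <- c(
    lapply(metabolite_pool(), function(s) {
      hfpn_place(s, "continuous", marking = m0[[s]],
                 unit = if (s == "cAMP") "au" else "mM")
    }),
    lapply(c(pts_place_ids(), "Cra", "CRP", "cAMP_CRP",
             "expr_ptsHIcrr", "expr_ptsG", "expr_glgCA"), prot_unit)
  )

  reactions <- c(build_glycolysis_pp(p), build_glycogen(p),
                 pts_reaction_set(p))
  rx <- reactions_to_hfpn(reactions)
  transitions <- rx$transitions
  arcs <- rx$arcs
  add <- function(id, speed, consume = character(0), produce = character(0)) {
    transitions[[length(transitions) + 1L]] <<-
      hfpn_continuous_transition(id, speed)
    for (s in consume) {
      arcs[[length(arcs) + 1L]] <<-
        hfpn_arc(s, id, "input", "normal", weight = 1, threshold = 0)
    }
    for (s in produce) {
      arcs[[length(arcs) + 1L]] <<-
        hfpn_arc(s, id, "output", "normal", weight = 1)
    }
  }

  thr <- p$thresholds

  # --- Cra / FDP feedback ------------------------------------------------
  add("cra_syn", function(m, p) cra_synthesis_rate(m[["FDP"]], p,
                                                   p$thresholds),
      produce = "Cra")
  add("cra_deg", function(m, p) p$d_cra * m[["Cra"]], consume = "Cra")

  # --- cAMP / CRP loop ---------------------------------------------------
  add("camp_syn", function(m, p) p$v_camp * m[["PEIIA"]], produce = "cAMP")
  add("camp_deg", function(m, p) p$d_camp * m[["cAMP"]], consume = "cAMP")
  add("crp_bind", function(m, p) p$k_bind * m[["cAMP"]] * m[["CRP"]],
      consume = c("cAMP", "CRP"), produce = "cAMP_CRP")
  add("crp_unbind", function(m, p) p$k_unbind * m[["cAMP_CRP"]],
      consume = "cAMP_CRP", produce = c("cAMP", "CRP"))

  # --- operon expression -------------------------------------------------
  pts_expr_syn <- function(m, p) {
    Kn <- p$K_cra^p$n_cra
    rep_term <- Kn / (Kn + m[["Cra"]]^p$n_cra)
    p$v_pts_expr * (p$basal_pts_expr + (1 - p$basal_pts_expr) * rep_term)
  }
  add("expr_ptsHIcrr_syn", pts_expr_syn, produce = "expr_ptsHIcrr")
  add("expr_ptsHIcrr_deg",
      function(m, p) p$d_pts_expr * m[["expr_ptsHIcrr"]],
      consume = "expr_ptsHIcrr")
  add("expr_ptsG_syn", pts_expr_syn, produce = "expr_ptsG")
  add("expr_ptsG_deg", function(m, p) p$d_pts_expr * m[["expr_ptsG"]],
      consume = "expr_ptsG")
  add("expr_glgCA_syn", function(m, p) {
    a <- as.integer(m[["Cra"]] < p$thresholds$cra_threshold)
    b <- as.integer(m[["cAMP_CRP"]] >= p$thresholds$cAMP_high)
    glgCA_synthesis_rate(gamma_lookup(a, b),
                         list(slow = p$glg_rate_slow, fast = p$glg_rate_fast))
  }, produce = "expr_glgCA")
  add("expr_glgCA_deg", function(m, p) p$d_glg_expr * m[["expr_glgCA"]],
      consume = "expr_glgCA")

  # --- PTS protein synthesis --------------------------------------------
  if (include_expression) {
    add("syn_EI", function(m, p) p$v_syn_EI * m[["expr_ptsHIcrr"]],
        produce = "EI")
    add("syn_HPr", function(m, p) p$v_syn_HPr * m[["expr_ptsHIcrr"]],
        produce = "HPr_cyt")
    add("syn_EIIA", function(m, p) p$v_syn_EIIA * m[["expr_ptsHIcrr"]],
        produce = "EIIA")
    add("syn_EIICB", function(m, p) p$v_syn_EIICB * m[["expr_ptsG"]],
        produce = "EIICB")
  }

  # --- HPr localization --------------------------------------------------
  # Translocation between the pole and cytosolic HPr pools, driven by the
  # net EI -> HPr phospho-flux; plus the slow dephosphorylation leak of pole
  # P~HPr that lets glycogenolysis start when glycolysis is idle.
  phpr_frac <- function(m) {
    tot <- m[["HPr_pole"]] + m[["PHPr_pole"]] + m[["HPr_cyt"]] +
      m[["PHPr_cyt"]]
    if (tot > 0) (m[["PHPr_pole"]] + m[["PHPr_cyt"]]) / tot else 0
  }
  # Outward translocation follows the EI -> HPr phosphorylation flux while
  # HPr is predominantly unphosphorylated (growth).  The return to the poles
  # requires predominantly phosphorylated HPr and an idle glucose-uptake step
  # (R5 flux per unit PTS speed, effectively a glucose-availability readout):
  # cytosolic HPr serves the PTS while uptake runs, and re-concentrates at
  # the glycogen-bearing poles once uptake has ceased.
  to_cyt_gate <- function(m, p) {
    fl <- pts_step_rates(m, p)
    net <- (fl$R2c_f - fl$R2c_r) + (fl$R2p_f - fl$R2p_r)
    net > p$thresholds$flux_loc_threshold &&
      phpr_frac(m) < p$thresholds$phpr_high
  }
  to_pole_gate <- function(m, p) {
    fl <- pts_step_rates(m, p)
    uptake_norm <- fl$R5 / pts_speed_factor(m, p)
    uptake_norm <= p$thresholds$flux_idle_threshold &&
      phpr_frac(m) >= p$thresholds$phpr_high
  }
  loc_speed <- function(pool, gate) {
    force(pool); force(gate)
    function(m, p) {
      if (gate(m, p)) p$thresholds$k_loc * m[[pool]] else 0
    }
  }
  add("loc_HPr_to_cyt", loc_speed("HPr_pole", to_cyt_gate),
      consume = "HPr_pole", produce = "HPr_cyt")
  add("loc_PHPr_to_cyt", loc_speed("PHPr_pole", to_cyt_gate),
      consume = "PHPr_pole", produce = "PHPr_cyt")
  add("loc_HPr_to_pole", loc_speed("HPr_cyt", to_pole_gate),
      consume = "HPr_cyt", produce = "HPr_pole")
  add("loc_PHPr_to_pole", loc_speed("PHPr_cyt", to_pole_gate),
      consume = "PHPr_cyt", produce = "PHPr_pole")
  add("leak_PHPr_pole", function(m, p) p$k_leak * m[["PHPr_pole"]],
      consume = "PHPr_pole", produce = "HPr_pole")

  # --- dilution ----------------------------------------------------------
  if (include_dilution) {
    mets <- setdiff(metabolite_pool(),
                    c("Glc_ext", "glycogen", "cAMP"))
    dil <- dilution_set(c(
      stats::setNames(rep(p$d_met, length(mets)), mets),
      stats::setNames(rep(p$d_prot, length(pts_place_ids())),
                      pts_place_ids())))
    transitions <- c(transitions, dil$transitions)
    arcs <- c(arcs, dil$arcs)
  }

  hfpn_model(places, transitions, arcs, parameters = p,
             reactions = reactions, name = "ecoli_carbohydrate")
}

#' Assemble the continuous reaction core of the integrated model
#'
#' The full reaction network (glycolysis/PP, glycogen module, PTS relay) as
#' a purely continuous, smooth kinetic system: no gene-expression, dilution
#' or localization transitions, glgC&glgA expression held at a fixed level
#' and the HPr pole state frozen at its initial composition.  This is the
#' part of the model that corresponds to a plain ODE system, used to
#' cross-check the fixed-step engine against adaptive reference integration.
#'
#' @param params Parameter overrides merged onto [default_parameters()].
#' @param init Initial-marking overrides merged onto
#'   [default_initial_marking()].
#' @return An [hfpn_model()] containing only continuous mass-action/Hill
#'   reaction transitions.
#' @export
build_continuous_core <- function(params = list(), init = NULL) {
  p <- utils::modifyList(default_parameters(), params)
  m0 <- default_initial_marking()
  if (!is.null(init)) m0[names(init)] <- unlist(init)
  # expression level is frozen (no expr_glgCA place in this model); the HPr
  # pole/cytosol split evolves only through the relay's phospho-exchange
  if (is.null(p$fixed_glgCA_level)) p$fixed_glgCA_level <- 1
  species <- c(setdiff(metabolite_pool(), "cAMP"), pts_place_ids())
  places <- lapply(species, function(s) {
    hfpn_place(s, "continuous", marking = m0[[s]],
               unit = if (s %in% metabolite_pool()) "mM" else "au")
  })
  rx <- c(build_glycolysis_pp(p), build_glycogen(p), pts_reaction_set(p))
  net <- reactions_to_hfpn(rx)
  hfpn_model(places, net$transitions, net$arcs, parameters = p,
             reactions = rx, name = "ecoli_continuous_core")
}
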