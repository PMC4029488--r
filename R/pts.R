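#' EI dimerization activity fraction
#'
#' High PEP stimulates EI dimerization, the limiting step gating phosphate
#' influx into the PTS relay.  Modelled as an instantaneous Hill activity
#' fraction of PEP rather than an explicit monomer/dimer species pair.
#'
#' @param PEP PEP concentration (mM), >= 0.
#' @param K_dim Half-saturation PEP level (mM).
#' @param n_dim Hill coefficient, >= 1.
#' @return Active fraction in [0,1], monotone non-decreasing in PEP.
#' @export
ei_dimer_active_fraction <- function(PEP, K_dim = 1, n_dim = 2) {
  if (any(PEP < 0)) stop("PEP must be >= 0", call. = FALSE)
  stopifnot(K_dim > 0, n_dim >= 1)
  PEP^n_dim / (K_dim^n_dim + PEP^n_dim)
}

# Places of the PTS phospho-relay.  HPr is split into a pole-located and a
# cytosolic pool; the relay acts on pole HPr at a reduced rate
# (pole_relay_scale), since pole HPr primarily serves glycogenolysis.
pts_place_ids <- function() {
  c("EI", "PEI", "HPr_pole", "PHPr_pole", "HPr_cyt", "PHPr_cyt",
    "EIIA", "PEIIA", "EIICB", "PEIICB")
}

# Global PTS speed factor: the parameter k times the expression-threshold
# acceleration when the operon-expression places are part of the marking.
pts_speed_factor <- function(m, p) {
  acc <- 1
  nm <- names(m)
  if ("expr_ptsHIcrr" %in% nm && "expr_ptsG" %in% nm) {
    thr <- if (!is.null(p$thresholds)) p$thresholds else regulation_thresholds()
    acc <- pts_acceleration(m[["expr_ptsHIcrr"]], m[["expr_ptsG"]],
                            thresholds = thr, A = p$pts_accel)
  }
  p$k_pts * acc
}

# Instantaneous directed rates of each relay step at marking m.  Returned as
# a list of forward/reverse rates; shared by the compiled reaction speeds and
# by phospho_flux so the two cannot drift apart.  Memoized on the marking:
# within one Euler step every relay speed and localization gate sees the same
# marking, so the rate list is computed once.
.pts_cache <- new.env(parent = emptyenv())

pts_step_rates <- function(m, p) {
  if (!is.null(.pts_cache$m) && identical(.pts_cache$m, m) &&
      identical(.pts_cache$p, p)) {
    return(.pts_cache$r)
  }
  r <- pts_step_rates_impl(m, p)
  .pts_cache$m <- m
  .pts_cache$p <- p
  .pts_cache$r <- r
  r
}

pts_step_rates_impl <- function(m, p) {
  fac <- pts_speed_factor(m, p)
  sc <- p$pole_relay_scale
  gate <- ei_dimer_active_fraction(m[["PEP"]], p$K_dim, p$n_dim)
  list(
    R1_f = fac * p$k1f * gate * m[["PEP"]] * m[["EI"]],
    R1_r = fac * p$k1r * m[["PYR"]] * m[["PEI"]],
    R2c_f = fac * p$k2f * m[["PEI"]] * m[["HPr_cyt"]],
    R2c_r = fac * p$k2r * m[["EI"]] * m[["PHPr_cyt"]],
    R2p_f = fac * sc * p$k2f * m[["PEI"]] * m[["HPr_pole"]],
    R2p_r = fac * sc * p$k2r * m[["EI"]] * m[["PHPr_pole"]],
    R3c_f = fac * p$k3f * m[["PHPr_cyt"]] * m[["EIIA"]],
    R3c_r = fac * p$k3r * m[["HPr_cyt"]] * m[["PEIIA"]],
    R3p_f = fac * sc * p$k3f * m[["PHPr_pole"]] * m[["EIIA"]],
    R3p_r = fac * sc * p$k3r * m[["HPr_pole"]] * m[["PEIIA"]],
    R4_f = fac * p$k4f * m[["PEIIA"]] * m[["EIICB"]],
    R4_r = fac * p$k4r * m[["EIIA"]] * m[["PEIICB"]],
    R5 = fac * p$k5 * m[["PEIICB"]] * m[["Glc_ext"]]
  )
}

#' PTS relay reaction set
#'
#' Elementary mass-balance reactions of the phospho-relay:
#' \itemize{
#'   \item R1: PEP + EI <-> PYR + P~EI, forward rate gated by
#'     [ei_dimer_active_fraction()];
#'   \item R2: P~EI + HPr <-> EI + P~HPr, acting on the cytosolic pool at
#'     full rate and the pole pool scaled by `pole_relay_scale`;
#'   \item R3: P~HPr + EIIA <-> HPr + P~EIIA (same pole scaling);
#'   \item R4: P~EIIA + EIICB <-> EIIA + P~EIICB;
#'   \item R5: P~EIICB + Glc_ext -> EIICB + G6P (irreversible uptake).
#' }
#' All steps are scaled by the global PTS speed parameter `k_pts` and, when
#' operon-expression places are present, by the expression-threshold
#' acceleration ([pts_acceleration()]).
#'
#' @param params Parameter list, see [default_parameters()].
#' @return List of [reaction()] objects.
#' @export
pts_reaction_set <- function(params = default_parameters()) {
  rt <- function(field) {
    force(field)
    function(m, p) pts_step_rates(m, p)[[field]]
  }
  list(
    reaction("R1", c(PEP = 1, EI = 1), c(PYR = 1, PEI = 1),
             law = rt("R1_f"), reverse_law = rt("R1_r")),
    reaction("R2_cyt", c(PEI = 1, HPr_cyt = 1), c(EI = 1, PHPr_cyt = 1),
             law = rt("R2c_f"), reverse_law = rt("R2c_r")),
    reaction("R2_pole", c(PEI = 1, HPr_pole = 1), c(EI = 1, PHPr_pole = 1),
             law = rt("R2p_f"), reverse_law = rt("R2p_r")),
    reaction("R3_cyt", c(PHPr_cyt = 1, EIIA = 1), c(HPr_cyt = 1, PEIIA = 1),
             law = rt("R3c_f"), reverse_law = rt("R3c_r")),
    reaction("R3_pole", c(PHPr_pole = 1, EIIA = 1), c(HPr_pole = 1, PEIIA = 1),
             law = rt("R3p_f"), reverse_law = rt("R3p_r")),
    reaction("R4", c(PEIIA = 1, EIICB = 1), c(EIIA = 1, PEIICB = 1),
             law = rt("R4_f"), reverse_law = rt("R4_r")),
    reaction("R5", c(PEIICB = 1, Glc_ext = 1), c(EIICB = 1, G6P = 1),
             law = rt("R5"))
  )
}

#' Instantaneous PTS phospho-flux report
#'
#' Net flux (forward minus reverse) through each relay step at a marking.
#' `flux_EI_to_HPr` is the net R2 flux summed over the cytosolic and pole
#' HPr pools; it drives the HPr localization switch.
#'
#' @param marking Named marking vector containing all PTS places plus PEP,
#'   PYR, Glc_ext.
#' @param params Parameter list, see [default_parameters()].
#' @return Named numeric vector with `R1` .. `R5` net fluxes (per hour) and
#'   `flux_EI_to_HPr`.
#' @export
phospho_flux <- function(marking, params = default_parameters()) {
  need <- c(pts_place_ids(), "PEP", "PYR", "Glc_ext")
  miss <- setdiff(need, names(marking))
  if (length(miss)) {
    stop("marking is missing PTS places: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  r <- pts_step_rates(marking, params)
  c(R1 = r$R1_f - r$R1_r,
    R2 = (r$R2c_f - r$R2c_r) + (r$R2p_f - r$R2p_r),
    R3 = (r$R3c_f - r$R3c_r) + (r$R3p_f - r$R3p_r),
    R4 = r$R4_f - r$R4_r,
    R5 = r$R5,
    flux_EI_to_HPr = (r$R2c_f - r$R2c_r) + (r$R2p_f - r$R2p_r))
}

#' Phosphorylated fraction of a PTS protein
#'
#' @param marking Named marking vector.
#' @param protein One of `"EI"`, `"HPr"`, `"EIIA"`, `"EIICB"`; HPr is pooled
#'   over its pole and cytosolic locations.
#' @return Fraction in [0,1].
#' @export
phosphorylation_fraction <- function(marking, protein = c("EI", "HPr", "EIIA",
                                                          "EIICB")) {
  protein <- match.arg(protein)
  pools <- switch(protein,
    EI = list(u = "EI", p = "PEI"),
    HPr = list(u = c("HPr_pole", "HPr_cyt"), p = c("PHPr_pole", "PHPr_cyt")),
    EIIA = list(u = "EIIA", p = "PEIIA"),
    EIICB = list(u = "EIICB", p = "PEIICB"))
  u <- sum(marking[pools$u])
  ph <- sum(marking[pools$p])
  tot <- u + ph
  if (!is.finite(tot) || tot <= 0) {
    stop("total ", protein, " pool is zero; phosphorylated fraction undefined",
         call. = FALSE)
  }
  ph / tot
}
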