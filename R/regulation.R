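#' Multi-valued glycogen-composition switch
#'
#' glgC/glgA transcription integrates two activation inputs: `alpha`, the
#' FDP/Cra route (high FDP represses Cra, releasing its inhibition of
#' glgC/glgA), and `beta`, the phosphorylated-EIIA/cAMP/CRP route.  Either
#' input alone drives slow glycogen composition, both together drive fast
#' composition:
#'
#' \tabular{ccc}{
#'   alpha \tab beta \tab gamma \cr
#'   0 \tab 0 \tab 0 \cr
#'   0 \tab 1 \tab 1 \cr
#'   1 \tab 0 \tab 1 \cr
#'   1 \tab 1 \tab 2
#' }
#'
#' @param alpha 0 or 1: FDP/Cra-driven glgC&glgA activation.
#' @param beta 0 or 1: cAMP/CRP-driven glgC&glgA activation.
#' @return Integer in \{0, 1, 2\}: glycogen composition speed level.
#' @export
gamma_lookup <- function(alpha, beta) {
  if (length(alpha) != 1L || length(beta) != 1L ||
      !(alpha %in% c(0, 1)) || !(beta %in% c(0, 1))) {
    stop("alpha and beta must each be 0 or 1", call. = FALSE)
  }
  as.integer(alpha + beta)
}

#' Default regulation thresholds
#'
#' Switching levels of the discrete regulatory readouts layered on the
#' continuous circuit.  Values are model units (mM for metabolites, au for
#' proteins/transcripts) and are calibrated jointly with
#' [default_parameters()].
#'
#' @return Named list:
#' \describe{
#'   \item{FDP_high}{FDP level (mM) above which sustained accumulation
#'     represses Cra.}
#'   \item{cra_threshold}{Cra level (au) below which `alpha = 1`.}
#'   \item{cAMP_high}{cAMP/CRP complex level (au) at or above which
#'     `beta = 1`.}
#'   \item{expr_PTS_threshold}{PTS operon expression level (au) at which the
#'     whole-PTS acceleration engages.}
#'   \item{flux_loc_threshold}{Net EI-to-HPr phospho-flux (au/h) above which
#'     HPr is translocated to the cytosol.}
#'   \item{flux_idle_threshold}{Glucose-uptake flux per unit PTS speed
#'     (mM/h) below which the PTS counts as idle, permitting the return of
#'     phosphorylated HPr to the poles.}
#'   \item{phpr_high}{HPr phosphorylated fraction above which, at idle
#'     phospho-flux, HPr re-concentrates at the poles.}
#'   \item{k_loc}{Localization relaxation rate (per hour).}
#' }
#' @export
regulation_thresholds <- function() {
  list(FDP_high = 0.45,
       cra_threshold = 0.5,
       cAMP_high = 0.3,
       expr_PTS_threshold = 1.0,
       flux_loc_threshold = 0.06,
       flux_idle_threshold = 0.07,
       phpr_high = 0.65,
       k_loc = 40)
}

#' FDP/Cra activation state (alpha)
#'
#' Cra is synthesized under decreasing-Hill repression by FDP and decays
#' first order; `alpha = 1` once Cra has fallen below its de-repression
#' threshold.  One Euler update of the Cra level is returned alongside the
#' discrete readout.
#'
#' @param FDP FDP concentration (mM), >= 0.
#' @param Cra_level Current Cra level (au).
#' @param thresholds [regulation_thresholds()] list (uses `FDP_high`,
#'   `cra_threshold`).
#' @param params Parameter list with `v_cra`, `d_cra`, `n_fdp`.
#' @param dt Step (hours); `dt = 0` returns the readout without advancing Cra.
#' @return List with `alpha` (0/1) and `Cra` (updated level).
#' @export
alpha_state <- function(FDP, Cra_level, thresholds = regulation_thresholds(),
                        params = default_parameters(), dt = 0) {
  if (FDP < 0) stop("FDP must be >= 0", call. = FALSE)
  syn <- cra_synthesis_rate(FDP, params, thresholds)
  Cra <- Cra_level + dt * (syn - params$d_cra * Cra_level)
  Cra <- max(Cra, 0)
  list(alpha = as.integer(Cra < thresholds$cra_threshold), Cra = Cra)
}

cra_synthesis_rate <- function(FDP, params, thresholds) {
  Kn <- thresholds$FDP_high^params$n_fdp
  params$v_cra * Kn / (Kn + FDP^params$n_fdp)
}

#' PEIIA/cAMP/CRP activation state (beta)
#'
#' Phosphorylated EIIA stimulates adenylate cyclase, so cAMP synthesis is
#' proportional to the P~EIIA level; cAMP binds CRP reversibly in a local
#' feedback loop, and `beta = 1` once the cAMP/CRP complex reaches its
#' activation level.  One Euler update of the loop is returned with the
#' readout.
#'
#' @param PEIIA Phosphorylated-EIIA level (au), >= 0.
#' @param pools Named vector/list with `cAMP`, `CRP`, `cAMP_CRP` levels.
#' @param thresholds [regulation_thresholds()] list (uses `cAMP_high`).
#' @param params Parameter list with `v_camp`, `d_camp`, `k_bind`,
#'   `k_unbind`.
#' @param dt Step (hours); `dt = 0` returns the readout without advancing.
#' @return List with `beta` (0/1) and updated `cAMP`, `CRP`, `cAMP_CRP`.
#' @export
beta_state <- function(PEIIA, pools, thresholds = regulation_thresholds(),
                       params = default_parameters(), dt = 0) {
  if (PEIIA < 0 || any(unlist(pools[c("cAMP", "CRP", "cAMP_CRP")]) < 0)) {
    stop("pools must be non-negative", call. = FALSE)
  }
  cAMP <- pools[["cAMP"]]; CRP <- pools[["CRP"]]; cpx <- pools[["cAMP_CRP"]]
  bind <- params$k_bind * cAMP * CRP
  unbind <- params$k_unbind * cpx
  cAMP2 <- max(cAMP + dt * (params$v_camp * PEIIA - params$d_camp * cAMP -
                              bind + unbind), 0)
  CRP2 <- max(CRP + dt * (unbind - bind), 0)
  cpx2 <- max(cpx + dt * (bind - unbind), 0)
  list(beta = as.integer(cpx2 >= thresholds$cAMP_high),
       cAMP = cAMP2, CRP = CRP2, cAMP_CRP = cpx2)
}

#' HPr pole-fraction relaxation
#'
#' While phosphate flows from P~EI onto HPr, HPr is translocated from the
#' poles to the cytosol (pole fraction relaxes toward 0); when that flux is
#' idle and HPr is predominantly phosphorylated, HPr re-concentrates at the
#' poles where glycogen is located (relaxes toward 1); otherwise the fraction
#' is held.
#'
#' @param flux_EI_to_HPr Net EI-to-HPr phospho-flux (au/h).
#' @param phpr_fraction Phosphorylated fraction of total HPr, in [0,1].
#' @param pole_fraction Current pole fraction, in [0,1].
#' @param dt Step in hours, > 0.
#' @param thresholds [regulation_thresholds()] list (uses
#'   `flux_loc_threshold`, `phpr_high`, `k_loc`).
#' @return Updated pole fraction, clamped to [0,1].
#' @export
update_pole_fraction <- function(flux_EI_to_HPr, phpr_fraction, pole_fraction,
                                 dt, thresholds = regulation_thresholds()) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  k <- thresholds$k_loc
  target <- NULL
  if (flux_EI_to_HPr > thresholds$flux_loc_threshold) {
    target <- 0
  } else if (flux_EI_to_HPr <= thresholds$flux_loc_threshold &&
             phpr_fraction >= thresholds$phpr_high) {
    target <- 1
  }
  if (is.null(target)) return(min(max(pole_fraction, 0), 1))
  pf <- pole_fraction + dt * k * (target - pole_fraction)
  min(max(pf, 0), 1)
}

#' GlgP complex parameters
#'
#' GlgP (glycogen phosphorylase) is taken to be always bound in a complex
#' with HPr; the unphosphorylated HPr::GlgP complex catalyzes glycogen
#' phosphorolysis about five times faster than P~HPr::GlgP, which is the
#' default `k_fast = 5 * k_slow` ratio.
#'
#' @param k_fast HPr::GlgP catalytic constant (per au GlgP per mM glycogen
#'   per hour).
#' @param k_slow P~HPr::GlgP catalytic constant; default `k_fast / 5`.
#' @param GlgP_total Total GlgP level (au).
#' @return Named list of class `glgp_params`.
#' @export
glgp_params <- function(k_fast = 10, k_slow = k_fast / 5, GlgP_total = 0.1) {
  stopifnot(k_fast >= 0, k_slow >= 0, GlgP_total >= 0)
  structure(list(k_fast = k_fast, k_slow = k_slow, GlgP_total = GlgP_total),
            class = "glgp_params")
}

#' Glycogen phosphorolysis flux
#'
#' GlgP is partitioned between HPr-bound and P~HPr-bound complexes in
#' proportion to the pole-located HPr and P~HPr amounts; only pole-located
#' HPr serves glycogenolysis, so the flux is additionally scaled by the pole
#' fraction of total HPr.  The flux is linear in glycogen and bounded between
#' the all-phosphorylated (slow) and all-unphosphorylated (fast) complex
#' rates.
#'
#' @param pole_fraction Fraction of total HPr located at the poles, [0,1].
#' @param HPr_pole Unphosphorylated pole HPr (au).
#' @param PHPr_pole Phosphorylated pole HPr (au).
#' @param glycogen Glycogen level (mM hexose equivalents).
#' @param complex GlgP complex parameters, a [glgp_params()].
#' @return Glycogen decomposition flux (mM/h), >= 0.
#' @export
glycogen_decomposition_rate <- function(pole_fraction, HPr_pole, PHPr_pole,
                                        glycogen,
                                        complex = glgp_params()) {
  stopifnot(pole_fraction >= 0, pole_fraction <= 1, HPr_pole >= 0,
            PHPr_pole >= 0, glycogen >= 0)
  tot <- HPr_pole + PHPr_pole
  if (tot <= 0 || glycogen <= 0 || pole_fraction <= 0) return(0)
  kcat <- (complex$k_fast * HPr_pole + complex$k_slow * PHPr_pole) / tot
  kcat * complex$GlgP_total * glycogen * pole_fraction
}

#' PTS whole-system acceleration multiplier
#'
#' Once both PTS operons (ptsHIcrr and ptsG) are expressed at or above the
#' expression threshold, the whole PTS reaction speed is strongly
#' accelerated; below threshold the multiplier is 1.  The threshold is
#' inclusive.
#'
#' @param expr_ptsHIcrr ptsHIcrr expression level (au), >= 0.
#' @param expr_ptsG ptsG expression level (au), >= 0.
#' @param thresholds [regulation_thresholds()] list (uses
#'   `expr_PTS_threshold`).
#' @param A Acceleration factor (> 1; default 10).
#' @return Multiplier, 1 or `A`.
#' @export
pts_acceleration <- function(expr_ptsHIcrr, expr_ptsG,
                             thresholds = regulation_thresholds(), A = 10) {
  stopifnot(expr_ptsHIcrr >= 0, expr_ptsG >= 0, A >= 1)
  if (min(expr_ptsHIcrr, expr_ptsG) >= thresholds$expr_PTS_threshold) A else 1
}

#' glgC&glgA synthesis rate from the composition level
#'
#' Maps the three-level composition switch to transcription rates: level 0
#' gives no synthesis, level 1 (either activation route) a slow rate, level 2
#' (both routes) a fast rate, with `fast > slow > 0`.  The expressed level
#' decays by its dilution transition, so enzyme decline after switch-off
#' takes time.
#'
#' @param gamma Composition level in \{0, 1, 2\} (see [gamma_lookup()]).
#' @param rate_table Named list/vector with `slow` and `fast` rates (au/h).
#' @return Synthesis rate (au/h).
#' @export
glgCA_synthesis_rate <- function(gamma, rate_table = list(slow = 0.5,
                                                          fast = 5)) {
  if (!(length(gamma) == 1L && gamma %in% 0:2)) {
    stop("gamma must be 0, 1 or 2", call. = FALSE)
  }
  if (rate_table$fast <= rate_table$slow || rate_table$slow <= 0) {
    stop("rate table must satisfy fast > slow > 0", call. = FALSE)
  }
  c(0, rate_table$slow, rate_table$fast)[gamma + 1L]
}
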