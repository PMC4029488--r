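#' Per-timepoint regulatory state series
#'
#' Derives the regulatory layer from a recorded trajectory of the integrated
#' model: pole fraction, phosphorylation fractions, the alpha/beta/gamma
#' switches, the PTS acceleration multiplier, and the uptake, decomposition
#' and composition fluxes.
#'
#' @param trajectory An `hfpn_trajectory` of the integrated model (see
#'   [build_ecoli_model()]).
#' @return Data frame, one row per recorded timepoint.
#' @export
regulatory_series <- function(trajectory) {
  M <- trajectory$markings
  p <- trajectory$model$parameters
  thr <- p$thresholds
  need <- c("Glc_ext", "glycogen", "FDP", "Cra", "cAMP", "cAMP_CRP",
            "expr_ptsHIcrr", "expr_ptsG", "expr_glgCA", "ADPG", "G1P",
            pts_place_ids())
  miss <- setdiff(need, colnames(M))
  if (length(miss)) {
    stop("trajectory lacks regulatory columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(M)
  out <- data.frame(
    time = trajectory$times,
    Glc_ext = M[, "Glc_ext"], glycogen = M[, "glycogen"],
    FDP = M[, "FDP"], PEP = M[, "PEP"], Cra = M[, "Cra"],
    cAMP = M[, "cAMP"], cAMP_CRP = M[, "cAMP_CRP"],
    expr_glgCA = M[, "expr_glgCA"]
  )
  hpr_tot <- M[, "HPr_pole"] + M[, "PHPr_pole"] + M[, "HPr_cyt"] +
    M[, "PHPr_cyt"]
  pole <- (M[, "HPr_pole"] + M[, "PHPr_pole"]) / pmax(hpr_tot, 1e-12)
  out$pole_fraction <- ifelse(hpr_tot > 0, pole, 0)
  out$phos_HPr <- (M[, "PHPr_pole"] + M[, "PHPr_cyt"]) / pmax(hpr_tot, 1e-12)
  out$phos_EIIA <- M[, "PEIIA"] / pmax(M[, "EIIA"] + M[, "PEIIA"], 1e-12)
  out$phos_EI <- M[, "PEI"] / pmax(M[, "EI"] + M[, "PEI"], 1e-12)
  out$phos_EIICB <- M[, "PEIICB"] / pmax(M[, "EIICB"] + M[, "PEIICB"], 1e-12)
  out$alpha <- as.integer(M[, "Cra"] < thr$cra_threshold)
  out$beta <- as.integer(M[, "cAMP_CRP"] >= thr$cAMP_high)
  out$gamma <- out$alpha + out$beta
  out$acceleration <- ifelse(
    pmin(M[, "expr_ptsHIcrr"], M[, "expr_ptsG"]) >= thr$expr_PTS_threshold,
    p$pts_accel, 1)
  gp <- model_glgp_params(p)
  kcat_mix <- (gp$k_fast * M[, "HPr_pole"] + gp$k_slow * M[, "PHPr_pole"]) /
    pmax(M[, "HPr_pole"] + M[, "PHPr_pole"], 1e-12)
  kcat_mix[M[, "HPr_pole"] + M[, "PHPr_pole"] <= 0] <- 0
  out$decomposition_kcat <- kcat_mix
  out$decomposition_flux <- kcat_mix * gp$GlgP_total * M[, "glycogen"] *
    out$pole_fraction
  out$composition_flux <- p$k_glgA * M[, "expr_glgCA"] * M[, "ADPG"]
  uptake <- numeric(n)
  flux_ei <- numeric(n)
  for (i in seq_len(n)) {
    r <- pts_step_rates(M[i, ], p)
    uptake[i] <- r$R5
    flux_ei[i] <- (r$R2c_f - r$R2c_r) + (r$R2p_f - r$R2p_r)
  }
  out$uptake_flux <- uptake
  out$flux_EI_to_HPr <- flux_ei
  out
}

#' Phase-boundary detection thresholds
#'
#' @return Named list: `glycogen_frac` (fraction of initial glycogen below
#'   which, together with cytosolic HPr, the late lag starts), `pole_cut`
#'   (pole-fraction discretization boundary), `eiia_cut` (EIIA
#'   phosphorylated-fraction boundary), `glc_eps` (mM level at which
#'   extracellular glucose counts as exhausted) and `sustain` (hours an
#'   EIIA crossing must persist to count as a phase boundary, screening out
#'   the brief relay re-equilibration at the lag/log transition).
#' @export
phase_thresholds <- function() {
  list(glycogen_frac = 0.5, pole_cut = 0.5, eiia_cut = 0.5, glc_eps = 0.05,
       sustain = 1)
}

phase_labels <- function() {
  c("early_lag", "late_lag", "early_log", "late_log", "stationary")
}

#' Classify a batch-culture trajectory into growth phases
#'
#' Segments the trajectory into the five canonical batch-culture phases by
#' ordered event detection:
#' \itemize{
#'   \item early lag -> late lag: glycogen falls below `glycogen_frac` of its
#'     initial level while the HPr pole fraction has dropped below
#'     `pole_cut` (glycogen consumed, HPr moved to the cytosol);
#'   \item late lag -> early log: the PTS acceleration multiplier engages
#'     (PTS operons above their expression threshold);
#'   \item early log -> late log: the EIIA phosphorylated fraction crosses
#'     `eiia_cut` upward;
#'   \item late log -> stationary: extracellular glucose falls below
#'     `glc_eps`.
#' }
#'
#' @param trajectory An `hfpn_trajectory` of the integrated model.
#' @param thresholds [phase_thresholds()] list.
#' @return A `phase_segmentation`: data frame with columns `label`,
#'   `t_start`, `t_end`, contiguous and covering the full span.
#' @export
classify_phases <- function(trajectory, thresholds = phase_thresholds()) {
  rs <- regulatory_series(trajectory)
  tt <- rs$time
  gly0 <- rs$glycogen[1L]
  find_after <- function(cond, from_idx, what) {
    idx <- which(cond & seq_along(cond) >= from_idx)
    if (length(idx) == 0L) {
      stop("phase classification failed: boundary '", what,
           "' never occurs in the trajectory", call. = FALSE)
    }
    idx[1L]
  }
  b1 <- find_after(rs$glycogen < thresholds$glycogen_frac * gly0 &
                     rs$pole_fraction < thresholds$pole_cut, 2L,
                   "early_lag -> late_lag")
  b2 <- find_after(rs$acceleration > 1, b1, "late_lag -> early_log")
  n <- length(rs$phos_EIIA)
  up <- c(FALSE, rs$phos_EIIA[-1L] >= thresholds$eiia_cut &
            rs$phos_EIIA[-n] < thresholds$eiia_cut)
  # a crossing counts only if the fraction stays above the cut for the
  # sustain window (transient relay re-equilibration is not a phase change)
  stride <- if (n > 1L) tt[2L] - tt[1L] else 1
  k_sus <- max(1L, ceiling(thresholds$sustain / stride))
  sustained <- vapply(seq_len(n), function(i) {
    if (!up[i]) return(FALSE)
    j <- seq.int(i, min(n, i + k_sus))
    all(rs$phos_EIIA[j] >= thresholds$eiia_cut)
  }, logical(1))
  b3 <- find_after(sustained, b2, "early_log -> late_log")
  b4 <- find_after(rs$Glc_ext < thresholds$glc_eps, b3,
                   "late_log -> stationary")
  bounds <- c(tt[1L], tt[c(b1, b2, b3, b4)], tt[length(tt)])
  seg <- data.frame(label = phase_labels(),
                    t_start = bounds[1:5], t_end = bounds[2:6],
                    stringsAsFactors = FALSE)
  structure(seg, class = c("phase_segmentation", "data.frame"))
}

#' Qualitative class boundaries for the regulator-state table
#'
#' Numeric cut points mapping continuous per-phase summaries onto the verbal
#' classes of the regulator table.  Calibrated once against the default
#' simulation and frozen; all values are model units.
#'
#' @return Named list of cuts: `uptake` (no / very slow / slow / fast /
#'   very fast flux bins, mM/h), `decomposition_eps` / `composition_eps`
#'   (fluxes below which decomposition / composition count as "no"),
#'   `composition_fast` (mM/h),
#'   `decomposition_kcat_mid` (per-complex catalytic speed separating slow
#'   from fast), `fdp_high` (mM), `camp_high` (au) and the 0.5 cuts for
#'   phosphorylation and localization.
#' @export
class_thresholds <- function() {
  list(uptake = c(no = 0.02, very_slow = 0.35, slow = 1.2, fast = 4),
       decomposition_eps = 0.1,
       composition_eps = 0.02,
       composition_fast = 1.0,
       decomposition_kcat_mid = 6,
       fdp_high = 0.8,
       camp_high = 0.3,
       phos_cut = 0.5,
       pole_cut = 0.5)
}

classify_value <- function(quantity, value, cuts) {
  switch(quantity,
    uptake = {
      cs <- cuts$uptake
      if (value < cs[["no"]]) "no"
      else if (value < cs[["very_slow"]]) "very slow"
      else if (value < cs[["slow"]]) "slow"
      else if (value < cs[["fast"]]) "fast"
      else "very fast"
    },
    FDP = if (value >= cuts$fdp_high) "high" else "low",
    alpha = , beta = if (value >= 0.5) "on" else "off",
    phos_EIIA = , phos_HPr = if (value >= cuts$phos_cut) "yes" else "no",
    cAMP = if (value >= cuts$camp_high) "high" else "low",
    composition = {
      if (value[["flux"]] < cuts$composition_eps) "no"
      else if (value[["flux"]] < cuts$composition_fast) "slow"
      else "fast"
    },
    decomposition = {
      if (value[["flux"]] < cuts$decomposition_eps) "no"
      else if (value[["kcat"]] < cuts$decomposition_kcat_mid) "slow"
      else "fast"
    },
    localization = if (value >= cuts$pole_cut) "pole" else "cytosol",
    stop("unknown quantity '", quantity, "'", call. = FALSE))
}

# Windowed start/end summaries of a series within [t0, t1]: medians of the
# first and last `frac` of the phase, robust against boundary blips.
phase_window <- function(tt, t0, t1, frac = 0.15) {
  inside <- which(tt >= t0 - 1e-9 & tt <= t1 + 1e-9)
  k <- max(1L, ceiling(length(inside) * frac))
  list(start = inside[seq_len(k)],
       end = inside[seq.int(length(inside) - k + 1L, length(inside))],
       all = inside)
}

#' Discretize regulator behavior per phase
#'
#' Renders the machine-readable analogue of the qualitative regulator table:
#' per phase and regulator a discrete class, with a transition written
#' `"x→y"` when the class at the phase start differs from the phase end
#' (start/end values are medians over the first/last 15% of the phase).
#' The composition class is derived from the realized glycogen synthesis
#' flux (so it reads "no" when substrate is exhausted regardless of the
#' gamma level); the decomposition class combines pole availability with
#' the per-complex catalytic speed mix.  `alpha`, `beta` and `gamma` rows
#' are reported directly from the threshold readouts.
#'
#' @param trajectory An `hfpn_trajectory` of the integrated model.
#' @param segmentation A [classify_phases()] result.
#' @param thresholds [class_thresholds()] list.
#' @return A `qualitative_state_table`: data frame `regulator` x phase
#'   columns.
#' @export
discretize_states <- function(trajectory, segmentation,
                              thresholds = class_thresholds()) {
  rs <- regulatory_series(trajectory)
  tt <- rs$time
  cell <- function(quantity, phase_row, value_fn) {
    w <- phase_window(tt, segmentation$t_start[phase_row],
                      segmentation$t_end[phase_row])
    a <- classify_value(quantity, value_fn(w$start), thresholds)
    b <- classify_value(quantity, value_fn(w$end), thresholds)
    if (identical(a, b)) a else paste0(a, "→", b)
  }
  med <- function(col) function(idx) stats::median(rs[[col]][idx])
  flux_kcat <- function(fcol, kcol) function(idx) {
    c(flux = stats::median(rs[[fcol]][idx]),
      kcat = stats::median(rs[[kcol]][idx]))
  }
  comp_val <- function(idx) c(flux = stats::median(rs$composition_flux[idx]))
  rows <- list(
    uptake = function(i) cell("uptake", i, med("uptake_flux")),
    FDP = function(i) cell("FDP", i, med("FDP")),
    alpha = function(i) cell("alpha", i, med("alpha")),
    phos_EIIA = function(i) cell("phos_EIIA", i, med("phos_EIIA")),
    cAMP = function(i) cell("cAMP", i, med("cAMP_CRP")),
    beta = function(i) cell("beta", i, med("beta")),
    composition = function(i) cell("composition", i, comp_val),
    decomposition = function(i) cell("decomposition", i,
                                     flux_kcat("decomposition_flux",
                                               "decomposition_kcat")),
    phos_HPr = function(i) cell("phos_HPr", i, med("phos_HPr")),
    localization = function(i) cell("localization", i,
                                    med("pole_fraction")),
    gamma = function(i) {
      w <- phase_window(tt, segmentation$t_start[i], segmentation$t_end[i])
      a <- stats::median(rs$gamma[w$start])
      b <- stats::median(rs$gamma[w$end])
      if (a == b) as.character(a) else paste0(a, "→", b)
    })
  tab <- data.frame(regulator = names(rows), stringsAsFactors = FALSE)
  for (ph in seq_len(nrow(segmentation))) {
    tab[[segmentation$label[ph]]] <-
      vapply(rows, function(f) f(ph), character(1))
  }
  structure(tab, class = c("qualitative_state_table", "data.frame"))
}

#' Pearson product-moment correlation
#'
#' @param sim_values,obs_values Equal-length numeric series, n >= 3, each
#'   with nonzero variance.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(sim_values, obs_values) {
  if (length(sim_values) != length(obs_values)) {
    stop("series must have equal length", call. = FALSE)
  }
  if (length(sim_values) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(sim_values) == 0 || stats::sd(obs_values) == 0) {
    stop("correlation undefined: a series has zero variance", call. = FALSE)
  }
  stats::cor(sim_values, obs_values, method = "pearson")
}

#' Interpolate a trajectory at observation times
#'
#' Linear interpolation of a recorded species onto arbitrary times within
#' the trajectory span.
#'
#' @param trajectory An `hfpn_trajectory`.
#' @param species Place id.
#' @param observation_times Numeric times within `[0, max(times)]`.
#' @return Numeric vector of interpolated values.
#' @export
align_series <- function(trajectory, species, observation_times) {
  if (!(species %in% colnames(trajectory$markings))) {
    stop("species '", species, "' not in trajectory", call. = FALSE)
  }
  tt <- trajectory$times
  if (any(observation_times < tt[1L] - 1e-9) ||
      any(observation_times > tt[length(tt)] + 1e-9)) {
    stop("observation times outside the trajectory span", call. = FALSE)
  }
  stats::approx(tt, trajectory$markings[, species],
                xout = observation_times, rule = 1)$y
}

#' Compare a simulation to an observation set
#'
#' Pearson r per species between the trajectory (interpolated at the
#' observation times) and the observed values.
#'
#' @param trajectory An `hfpn_trajectory`.
#' @param observations An [observation_set] (see [generate_observations()])
#'   or a long data frame with columns `time`, `species`, `value`.
#' @return Data frame with columns `species`, `r`, `n`.
#' @export
compare_observations <- function(trajectory, observations) {
  df <- if (inherits(observations, "observation_set")) observations$data
        else observations
  sp <- unique(df$species)
  res <- lapply(sp, function(s) {
    d <- df[df$species == s, ]
    sim <- align_series(trajectory, s, d$time)
    data.frame(species = s, r = pearson_r(sim, d$value), n = nrow(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
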