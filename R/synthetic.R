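#' Observation noise model
#'
#' Multiplicative lognormal noise (relative measurement error) plus a small
#' additive floor, emulating sparse batch-culture assays.
#'
#' @param sigma_mult Standard deviation of the log-scale multiplicative
#'   component (default 0.1, i.e. ~10% relative error).
#' @param sigma_add Standard deviation of the additive floor, in species
#'   units (default 1e-3).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sigma_mult = 0.1, sigma_add = 1e-3) {
  stopifnot(sigma_mult >= 0, sigma_add >= 0)
  structure(list(sigma_mult = sigma_mult, sigma_add = sigma_add),
            class = "noise_model")
}

#' Generate a synthetic observation set
#'
#' Forward-simulates the model, samples the requested species at the
#' observation times by linear interpolation, and applies
#' `value * exp(N(0, sigma_mult)) + N(0, sigma_add)` clamped at zero.
#' Reproducible for a given seed.
#'
#' @param model An [hfpn_model()].
#' @param species Character vector of observed species; the default mirrors
#'   the evaluated batch-culture metabolites.
#' @param times Observation times (hours); default 15 points uniform over
#'   `[0, t_end]`.
#' @param noise A [noise_model()].
#' @param seed Integer RNG seed.
#' @param t_end,dt,record_stride Simulation settings passed to
#'   [hfpn_simulate()].
#' @param trajectory Optional pre-computed trajectory of `model` (skips the
#'   forward simulation).
#' @return An `observation_set`: list with `data` (long data frame `time`,
#'   `species`, `value`), `species`, `times`, `truth` (the generating
#'   parameter record), `noise` and `seed`.
#' @export
generate_observations <- function(model,
                                  species = c("Glc_ext", "glycogen", "G6P",
                                              "F6P", "FDP", "PEP", "PYR"),
                                  times = NULL, noise = noise_model(),
                                  seed = 1L, t_end = 12, dt = 1e-3,
                                  record_stride = 10 * dt,
                                  trajectory = NULL) {
  bad <- setdiff(species, names(model$places))
  if (length(bad)) {
    stop("species not in model: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(trajectory)) {
    trajectory <- hfpn_simulate(model, t_end = t_end, dt = dt,
                                record_stride = record_stride)
  }
  if (is.null(times)) {
    times <- seq(0, max(trajectory$times), length.out = 15)
  }
  set.seed(as.integer(seed))
  rows <- lapply(species, function(s) {
    v <- align_series(trajectory, s, times)
    noisy <- v * exp(stats::rnorm(length(v), 0, noise$sigma_mult)) +
      stats::rnorm(length(v), 0, noise$sigma_add)
    data.frame(time = times, species = s, value = pmax(noisy, 0),
               stringsAsFactors = FALSE)
  })
  structure(list(data = do.call(rbind, rows), species = species,
                 times = times, truth = model$parameters, noise = noise,
                 seed = as.integer(seed)),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat("Observation set:", length(x$species), "species x", length(x$times),
      "timepoints (seed", x$seed, ")\n")
  invisible(x)
}

#' Fit model parameters to observations
#'
#' Levenberg-Marquardt least squares on log-scale residuals
#' `log(sim + eps) - log(obs + eps)` between the simulated and observed
#' series, over a named set of free parameters (optimized in log space, so
#' positivity is structural).  Log residuals keep species spanning orders of
#' magnitude (mM glucose vs au signals) on a common footing.
#'
#' @param model Model whose parameters (other than the free ones) are held
#'   fixed; the model is rebuilt per evaluation via `rebuild`.
#' @param observations An `observation_set` or long data frame
#'   (`time`, `species`, `value`).
#' @param free Character vector of free parameter names.
#' @param lower,upper Named bounds on the free parameters (positive).
#' @param init_guess Named starting values; defaults to the model's current
#'   values.
#' @param t_end,dt Simulation settings for the objective (coarser `dt` than
#'   the display default keeps fitting desk-scale).
#' @param rebuild Function `function(params) -> hfpn_model` used to
#'   reassemble the model at trial parameters; defaults to
#'   [build_ecoli_model()].
#' @param eps Log-offset guarding zero values.
#' @return A `fit_result`: list with `par` (fitted values), `rss`,
#'   `converged`, `info` and the `nls.lm` object.
#' @export
fit_parameters <- function(model, observations, free,
                           lower = NULL, upper = NULL, init_guess = NULL,
                           t_end = NULL, dt = 0.01,
                           rebuild = function(params)
                             build_ecoli_model(params = params),
                           eps = 1e-3) {
  df <- if (inherits(observations, "observation_set")) observations$data
        else observations
  df <- df[order(df$species, df$time), ]
  p0 <- model$parameters
  miss <- setdiff(free, names(p0))
  if (length(miss)) {
    stop("free parameters not in model: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(init_guess)) init_guess <- unlist(p0[free])
  init_guess <- init_guess[free]
  if (any(init_guess <= 0)) {
    stop("free parameters must be positive", call. = FALSE)
  }
  if (is.null(t_end)) t_end <- max(df$time)
  log_lower <- if (is.null(lower)) rep(-Inf, length(free)) else log(lower[free])
  log_upper <- if (is.null(upper)) rep(Inf, length(free)) else log(upper[free])

  resid_fn <- function(log_theta) {
    theta <- exp(log_theta)
    names(theta) <- free
    pars <- utils::modifyList(p0, as.list(theta))
    mod <- rebuild(pars)
    traj <- tryCatch(
      hfpn_simulate(mod, t_end = t_end, dt = dt, record_stride = dt),
      error = function(e) NULL)
    if (is.null(traj)) return(rep(1e3, nrow(df)))
    res <- numeric(nrow(df))
    i <- 1L
    for (s in unique(df$species)) {
      d <- df[df$species == s, ]
      sim <- align_series(traj, s, d$time)
      res[i:(i + nrow(d) - 1L)] <- log(sim + eps) - log(d$value + eps)
      i <- i + nrow(d)
    }
    res
  }
  fit <- minpack.lm::nls.lm(par = log(init_guess), fn = resid_fn,
                            lower = log_lower, upper = log_upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-10, ptol = 1e-10))
  par <- exp(fit$par)
  names(par) <- free
  structure(list(par = par, rss = fit$deviance,
                 converged = fit$info %in% 1:4, info = fit$info,
                 fit = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Parameter fit (", if (x$converged) "converged" else "NOT converged",
      "), RSS = ", format(x$rss, digits = 6), "\n", sep = "")
  print(x$par)
  invisible(x)
}

#' Parameter-recovery report
#'
#' Relative error of fitted parameters against known generating values.
#'
#' @param fit_result A [fit_parameters()] result (or named vector of fitted
#'   values).
#' @param truth Named vector/list of true values.
#' @return Data frame with `parameter`, `fitted`, `truth`, `rel_error`
#'   (`|fitted - true| / true`; absolute error with `absolute = TRUE` flag
#'   when the true value is zero).
#' @export
recovery_report <- function(fit_result, truth) {
  fitted <- if (inherits(fit_result, "fit_result")) fit_result$par
            else fit_result
  truth <- unlist(truth)[names(fitted)]
  if (anyNA(truth)) stop("truth must cover all fitted parameters",
                         call. = FALSE)
  abs0 <- truth == 0
  err <- ifelse(abs0, abs(fitted - truth), abs(fitted - truth) / abs(truth))
  data.frame(parameter = names(fitted), fitted = unname(fitted),
             truth = unname(truth), rel_error = unname(err),
             absolute = unname(abs0), stringsAsFactors = FALSE)
}

#' Write / read observation sets as delimited text
#'
#' Long CSV with header `time,species,value`.
#'
#' @param observations An `observation_set` or long data frame.
#' @param path File path.
#' @return `write_observations` invisibly returns `path`;
#'   `read_observations` returns a long data frame.
#' @export
write_observations <- function(observations, path) {
  df <- if (inherits(observations, "observation_set")) observations$data
        else observations
  utils::write.csv(df[, c("time", "species", "value")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "species", "value")
  if (!all(need %in% names(df))) {
    stop("observation file must have columns time, species, value",
         call. = FALSE)
  }
  df[, need]
}
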