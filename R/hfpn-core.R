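#' Hybrid functional Petri net engine
#'
#' A hybrid functional Petri net (HFPN) couples continuous places (non-negative
#' real markings, e.g. metabolite concentrations) and discrete places (integer
#' token counts) through transitions: continuous transitions fire at a
#' marking-dependent speed (amount per hour), discrete transitions fire a token
#' effect after being continuously enabled for a fixed delay.  Arcs connect
#' places to transitions; `test` arcs read a marking without consuming it and
#' `inhibitory` arcs disable a transition once a marking reaches a threshold.
#'
#' @name hfpn
NULL

#' Create a place
#'
#' @param id Unique place name.
#' @param kind `"continuous"` (real-valued marking) or `"discrete"`
#'   (integer tokens).
#' @param marking Initial marking, non-negative (integer for discrete places).
#' @param unit Free-text unit tag; conventionally `"mM"` for metabolites and
#'   `"au"` for proteins and transcripts.
#' @return An object of class `hfpn_place`.
#' @export
hfpn_place <- function(id, kind = c("continuous", "discrete"), marking = 0,
                       unit = "mM") {
  kind <- match.arg(kind)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(marking) || length(marking) != 1L || is.na(marking) ||
      marking < 0) {
    stop("marking of place '", id, "' must be a single non-negative number",
         call. = FALSE)
  }
  if (kind == "discrete" && marking != round(marking)) {
    stop("discrete place '", id, "' needs an integer marking", call. = FALSE)
  }
  structure(list(id = id, kind = kind, marking = as.numeric(marking),
                 unit = unit),
            class = "hfpn_place")
}

#' Create a continuous transition
#'
#' @param id Unique transition name.
#' @param speed Function `function(m, p)` of the named marking vector `m` and
#'   the model parameter list `p`, returning a non-negative firing speed
#'   (amount per hour).
#' @return An object of class `hfpn_transition`.
#' @export
hfpn_continuous_transition <- function(id, speed) {
  stopifnot(is.character(id), length(id) == 1L, is.function(speed))
  structure(list(id = id, type = "continuous", speed = speed),
            class = "hfpn_transition")
}

#' Create a discrete transition
#'
#' Fires once its input-arc conditions have held continuously for `delay`
#' hours; firing applies `effects` (named token increments, negative values
#' consume) and restarts the delay clock.
#'
#' @param id Unique transition name.
#' @param delay Positive enabling delay in hours.
#' @param effects Named numeric vector of token changes applied per firing.
#' @return An object of class `hfpn_transition`.
#' @export
hfpn_discrete_transition <- function(id, delay, effects) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!is.numeric(delay) || length(delay) != 1L || delay <= 0) {
    stop("delay of discrete transition '", id, "' must be > 0", call. = FALSE)
  }
  stopifnot(is.numeric(effects), !is.null(names(effects)))
  structure(list(id = id, type = "discrete", delay = as.numeric(delay),
                 effects = effects),
            class = "hfpn_transition")
}

#' Create an arc
#'
#' Normal input arcs consume `weight` per unit firing; output arcs produce it.
#' Test and inhibitory arcs are read-only and input-only.  The enabling
#' threshold of a normal or test arc defaults to its weight (the classical
#' Petri-net convention); inhibitory arcs must state their threshold.
#'
#' @param place Place id.
#' @param transition Transition id.
#' @param direction `"input"` or `"output"`.
#' @param kind `"normal"`, `"test"` or `"inhibitory"`.
#' @param weight Positive stoichiometric weight.
#' @param threshold Enabling level; defaults to `weight` for normal/test arcs.
#' @return An object of class `hfpn_arc`.
#' @export
hfpn_arc <- function(place, transition, direction = c("input", "output"),
                     kind = c("normal", "test", "inhibitory"), weight = 1,
                     threshold = NULL) {
  direction <- match.arg(direction)
  kind <- match.arg(kind)
  stopifnot(is.character(place), is.character(transition))
  if (!is.numeric(weight) || weight <= 0) {
    stop("arc weight must be > 0 (", place, " - ", transition, ")",
         call. = FALSE)
  }
  if (kind != "normal" && direction != "input") {
    stop(kind, " arcs are input-only (", place, " - ", transition, ")",
         call. = FALSE)
  }
  if (is.null(threshold)) {
    if (kind == "inhibitory") {
      stop("inhibitory arc needs an explicit threshold (", place, " - ",
           transition, ")", call. = FALSE)
    }
    threshold <- weight
  }
  if (threshold < 0) stop("arc threshold must be >= 0", call. = FALSE)
  structure(list(place = place, transition = transition, direction = direction,
                 kind = kind, weight = as.numeric(weight),
                 threshold = as.numeric(threshold)),
            class = "hfpn_arc")
}

#' Assemble an HFPN model
#'
#' Validates structural integrity (unique ids, arc endpoints exist, arc-kind
#' constraints) and pre-compiles per-transition index tables used by the
#' stepper.
#'
#' @param places List of [hfpn_place()] objects.
#' @param transitions List of transition objects.
#' @param arcs List of [hfpn_arc()] objects.
#' @param parameters Named list of global parameters visible to speed
#'   functions.
#' @param reactions Optional list of [reaction()] objects the model was
#'   compiled from; retained for SBML export.
#' @param name Model name.
#' @return An object of class `hfpn_model`.
#' @export
hfpn_model <- function(places, transitions, arcs, parameters = list(),
                       reactions = NULL, name = "hfpn") {
  pid <- vapply(places, function(x) x$id, character(1))
  tid <- vapply(transitions, function(x) x$id, character(1))
  if (anyDuplicated(pid)) {
    stop("duplicate place ids: ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tid)) {
    stop("duplicate transition ids: ",
         paste(unique(tid[duplicated(tid)]), collapse = ", "), call. = FALSE)
  }
  for (a in arcs) {
    if (!(a$place %in% pid)) {
      stop("arc references unknown place '", a$place, "'", call. = FALSE)
    }
    if (!(a$transition %in% tid)) {
      stop("arc references unknown transition '", a$transition, "'",
           call. = FALSE)
    }
  }
  names(places) <- pid
  names(transitions) <- tid
  model <- structure(list(places = places, transitions = transitions,
                          arcs = arcs, parameters = parameters,
                          reactions = reactions, name = name),
                     class = "hfpn_model")
  model$compiled <- compile_hfpn(model)
  model
}

# Pre-compile index tables: per transition the enabling conditions and the
# consumption/production weights as integer indices into the marking vector.
compile_hfpn <- function(model) {
  pid <- names(model$places)
  np <- length(pid)
  tid <- names(model$transitions)
  nt <- length(tid)
  comp <- vector("list", nt)
  names(comp) <- tid
  S <- matrix(0, nrow = np, ncol = nt, dimnames = list(pid, tid))
  C <- matrix(0, nrow = np, ncol = nt, dimnames = list(pid, tid))
  for (j in seq_len(nt)) {
    comp[[j]] <- list(enab_idx = integer(0), enab_thr = numeric(0),
                      enab_inh = logical(0))
  }
  for (a in model$arcs) {
    i <- match(a$place, pid)
    j <- match(a$transition, tid)
    if (a$direction == "input") {
      comp[[j]]$enab_idx <- c(comp[[j]]$enab_idx, i)
      comp[[j]]$enab_thr <- c(comp[[j]]$enab_thr, a$threshold)
      comp[[j]]$enab_inh <- c(comp[[j]]$enab_inh, a$kind == "inhibitory")
      if (a$kind == "normal") {
        S[i, j] <- S[i, j] - a$weight
        C[i, j] <- C[i, j] + a$weight
      }
    } else {
      S[i, j] <- S[i, j] + a$weight
    }
  }
  is_cont <- vapply(model$transitions, function(x) x$type == "continuous",
                    logical(1))
  list(S = S, C = C, comp = comp, is_cont = is_cont,
       cont_idx = which(is_cont),
       disc_idx = which(!is_cont)[order(tid[!is_cont])])
}

#' Initial marking of a model
#'
#' @param model An [hfpn_model()].
#' @return Named numeric vector of initial markings.
#' @export
initial_marking <- function(model) {
  vapply(model$places, function(p) p$marking, numeric(1))
}

#' Transition enabling test
#'
#' A transition is enabled when every normal/test input arc sees a marking at
#' or above its threshold and every inhibitory arc sees a marking strictly
#' below its threshold.  A transition with no input arcs is vacuously enabled.
#'
#' @param model An [hfpn_model()].
#' @param transition Transition id.
#' @param marking Named marking vector for `model`.
#' @return Logical scalar.
#' @export
is_enabled <- function(model, transition, marking) {
  j <- match(transition, names(model$transitions))
  if (is.na(j)) stop("unknown transition '", transition, "'", call. = FALSE)
  if (!all(names(model$places) %in% names(marking))) {
    stop("marking does not cover all places of the model", call. = FALSE)
  }
  marking <- marking[names(model$places)]
  cmp <- model$compiled$comp[[j]]
  enabled_one(cmp, marking)
}

enabled_one <- function(cmp, m) {
  if (length(cmp$enab_idx) == 0L) return(TRUE)
  # normal/test arcs need marking >= threshold, inhibitory arcs < threshold
  all((m[cmp$enab_idx] >= cmp$enab_thr) != cmp$enab_inh)
}

# Vector of enabling states for all transitions at marking m.
enabled_all <- function(model, m) {
  vapply(model$compiled$comp, enabled_one, logical(1), m = m)
}

#' Advance an HFPN one Euler step
#'
#' Continuous transitions fire an amount `speed * dt` (evaluated at the
#' start-of-step marking); if a firing would drive a place negative the
#' offending transitions' amounts are scaled so the limiting place lands
#' exactly at zero, preserving within-step stoichiometry.  Discrete delay
#' clocks accrue while their transition is enabled and token effects are
#' applied on expiry, in id-sorted order.
#'
#' @param model An [hfpn_model()].
#' @param marking Named marking vector.
#' @param dt Step size in hours, > 0.
#' @param clocks Named numeric vector of discrete-transition clocks (internal
#'   state); defaults to all-zero.
#' @return List with elements `marking` and `clocks`.
#' @export
hfpn_step <- function(model, marking, dt, clocks = NULL) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a single positive number", call. = FALSE)
  }
  cp <- model$compiled
  m <- marking[rownames(cp$S)]
  p <- model$parameters
  nt <- ncol(cp$S)
  amount <- numeric(nt)
  for (j in cp$cont_idx) {
    if (enabled_one(cp$comp[[j]], m)) {
      sp <- model$transitions[[j]]$speed(m, p)
      if (!is.finite(sp)) {
        stop("non-finite speed from transition '",
             names(model$transitions)[j], "'", call. = FALSE)
      }
      if (sp < 0) {
        stop("negative speed from transition '",
             names(model$transitions)[j], "'", call. = FALSE)
      }
      amount[j] <- sp * dt
    }
  }
  # Negative-marking guard: scale offending transitions so the limiting place
  # reaches exactly 0.  Production is credited before scaling, so coupled
  # produce/consume chains are not over-throttled.
  for (iter in 1:50) {
    newm <- m + drop(cp$S %*% amount)
    neg <- which(newm < -1e-12)
    if (length(neg) == 0L) break
    i <- neg[which.min(newm[neg])]
    cons <- drop(cp$C[i, ] * amount)
    tot_cons <- sum(cons)
    prod <- m[i] + sum(pmax(drop(cp$S[i, ] * amount), 0))
    f <- if (tot_cons > 0) max(prod, 0) / tot_cons else 0
    amount[cons > 0] <- amount[cons > 0] * min(f, 1)
  }
  newm <- pmax(m + drop(cp$S %*% amount), 0)

  # discrete layer
  if (is.null(clocks)) {
    clocks <- stats::setNames(numeric(length(cp$disc_idx)),
                              names(model$transitions)[cp$disc_idx])
  }
  for (j in cp$disc_idx) {
    id <- names(model$transitions)[j]
    if (enabled_one(cp$comp[[j]], newm)) {
      clocks[[id]] <- clocks[[id]] + dt
      tr <- model$transitions[[j]]
      if (clocks[[id]] >= tr$delay) {
        eff <- tr$effects
        tgt <- newm[names(eff)] + eff
        if (any(tgt < 0)) {
          stop("discrete transition '", id, "' would drive a place negative",
               call. = FALSE)
        }
        newm[names(eff)] <- tgt
        clocks[[id]] <- 0
      }
    } else {
      clocks[[id]] <- 0
    }
  }
  list(marking = newm, clocks = clocks)
}

#' Simulate an HFPN model
#'
#' Fixed-step explicit-Euler hybrid simulation from the model's initial
#' marking.  Deterministic for given arguments.
#'
#' @param model An [hfpn_model()].
#' @param t_end End time in hours, > 0.
#' @param dt Step size in hours (default `1e-3`).
#' @param record_stride Recording interval, a positive multiple of `dt`
#'   (default `10 * dt`).
#' @param init Optional named marking vector overriding the model's initial
#'   markings.
#' @return An `hfpn_trajectory`: list with `times`, `markings`
#'   (time-by-place matrix), `dt`, `record_stride` and the `model`.
#' @export
hfpn_simulate <- function(model, t_end, dt = 1e-3, record_stride = 10 * dt,
                          init = NULL) {
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  k <- record_stride / dt
  if (abs(k - round(k)) > 1e-8 || k < 1) {
    stop("record_stride must be a positive multiple of dt", call. = FALSE)
  }
  k <- as.integer(round(k))
  n_steps <- as.integer(ceiling(t_end / dt - 1e-9))
  m <- initial_marking(model)
  if (!is.null(init)) {
    bad <- setdiff(names(init), names(m))
    if (length(bad)) {
      stop("init names not in model: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    m[names(init)] <- init
  }
  n_rec <- n_steps %/% k + 1L
  out <- matrix(NA_real_, nrow = n_rec + 1L, ncol = length(m),
                dimnames = list(NULL, names(m)))
  times <- numeric(n_rec + 1L)
  out[1L, ] <- m
  times[1L] <- 0
  clocks <- NULL
  r <- 1L
  for (s in seq_len(n_steps)) {
    st <- tryCatch(
      hfpn_step(model, m, dt, clocks),
      error = function(e) {
        stop("simulation failed at time ", format(s * dt), " h: ",
             conditionMessage(e), call. = FALSE)
      })
    m <- st$marking
    clocks <- st$clocks
    if (!all(is.finite(m))) {
      bad <- names(m)[!is.finite(m)][1L]
      stop("non-finite marking at place '", bad, "', time ",
           format(s * dt), " h (integration blow-up; reduce dt)",
           call. = FALSE)
    }
    if (s %% k == 0L) {
      r <- r + 1L
      out[r, ] <- m
      times[r] <- s * dt
    }
  }
  if (times[r] < t_end - 1e-9) {
    r <- r + 1L
    out[r, ] <- m
    times[r] <- n_steps * dt
  }
  structure(list(times = times[seq_len(r)],
                 markings = out[seq_len(r), , drop = FALSE],
                 dt = dt, record_stride = record_stride, model = model),
            class = "hfpn_trajectory")
}

#' @export
print.hfpn_trajectory <- function(x, ...) {
  cat("HFPN trajectory:", length(x$times), "timepoints x",
      ncol(x$markings), "places, t in [0,",
      format(max(x$times)), "] h, dt =", format(x$dt), "h\n")
  invisible(x)
}

#' @export
print.hfpn_model <- function(x, ...) {
  cat("HFPN model '", x$name, "': ", length(x$places), " places, ",
      length(x$transitions), " transitions, ", length(x$arcs), " arcs\n",
      sep = "")
  invisible(x)
}

#' Tidy data frame of a trajectory
#'
#' @param x An `hfpn_trajectory`.
#' @param ... Unused.
#' @return Data frame with columns `time`, `place`, `value`.
#' @export
as.data.frame.hfpn_trajectory <- function(x, ...) {
  data.frame(time = rep(x$times, times = ncol(x$markings)),
             place = rep(colnames(x$markings), each = length(x$times)),
             value = as.vector(x$markings),
             stringsAsFactors = FALSE)
}

#' Weighted moiety total
#'
#' Sum of `weight * marking` over a set of places; used for conservation
#' checks such as phospho-protein pools.
#'
#' @param marking Named marking vector, or an `hfpn_trajectory` (then a series
#'   over time is returned).
#' @param weighted_places Named numeric vector: place id -> weight.
#' @return Numeric scalar (or vector over time for a trajectory).
#' @export
moiety_total <- function(marking, weighted_places) {
  if (length(weighted_places) == 0L) {
    return(if (inherits(marking, "hfpn_trajectory"))
      numeric(length(marking$times)) else 0)
  }
  nm <- names(weighted_places)
  if (inherits(marking, "hfpn_trajectory")) {
    miss <- setdiff(nm, colnames(marking$markings))
    if (length(miss)) {
      stop("unknown places: ", paste(miss, collapse = ", "), call. = FALSE)
    }
    return(drop(marking$markings[, nm, drop = FALSE] %*% weighted_places))
  }
  miss <- setdiff(nm, names(marking))
  if (length(miss)) {
    stop("unknown places: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  sum(marking[nm] * weighted_places)
}

#' Right-hand side function for reference ODE integration
#'
#' Expresses the continuous part of an HFPN model as the derivative function
#' `dm/dt = S %*% speed(m)` in the signature expected by `deSolve`
#' integrators, for cross-checking the fixed-step engine against an adaptive
#' reference on purely continuous models.
#'
#' @param model An [hfpn_model()] without discrete transitions.
#' @return `function(t, y, parms)` returning `list(dy)`.
#' @export
hfpn_ode_rhs <- function(model) {
  cp <- model$compiled
  if (length(cp$disc_idx) > 0L) {
    stop("ODE form is only defined for purely continuous models",
         call. = FALSE)
  }
  trans <- model$transitions
  p <- model$parameters
  function(t, y, parms) {
    m <- pmax(y, 0)
    names(m) <- rownames(cp$S)
    rates <- numeric(ncol(cp$S))
    for (j in cp$cont_idx) {
      if (enabled_one(cp$comp[[j]], m)) rates[j] <- trans[[j]]$speed(m, p)
    }
    list(drop(cp$S %*% rates))
  }
}
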