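#' Kinetic rate laws
#'
#' Three rate-law families cover the model: general mass action (the default
#' for the integrated model), Michaelis-Menten (available for users wiring in
#' saturable kinetics), and Hill (used for the PEP-driven EI dimerization gate
#' and regulatory switches).
#'
#' @param form `"mass_action"`, `"michaelis_menten"` or `"hill"`.
#' @param ... Form-specific parameters:
#'   \describe{
#'     \item{mass_action}{`k` (rate constant); optional `orders`, a named
#'       vector of per-reactant kinetic orders (default 1 per substrate).}
#'     \item{michaelis_menten}{`Vmax`; `Km`, a named vector of per-substrate
#'       half-saturation constants.}
#'     \item{hill}{`Vmax`; `K_half`; `n` (Hill coefficient).}
#'   }
#' @return An object of class `rate_law`.
#' @export
rate_law <- function(form = c("mass_action", "michaelis_menten", "hill"),
                     ...) {
  form <- match.arg(form)
  pars <- list(...)
  if (form == "mass_action" && is.null(pars$k)) {
    stop("mass_action rate law needs 'k'", call. = FALSE)
  }
  if (form == "michaelis_menten" &&
      (is.null(pars$Vmax) || is.null(pars$Km))) {
    stop("michaelis_menten rate law needs 'Vmax' and 'Km'", call. = FALSE)
  }
  if (form == "hill" &&
      (is.null(pars$Vmax) || is.null(pars$K_half) || is.null(pars$n))) {
    stop("hill rate law needs 'Vmax', 'K_half' and 'n'", call. = FALSE)
  }
  structure(list(form = form, pars = pars), class = "rate_law")
}

#' Evaluate a rate law
#'
#' @param law A [rate_law()].
#' @param concentrations Named non-negative concentration vector covering the
#'   substrates the law references.
#' @param substrates Character vector of substrate names (with multiplicity
#'   for mass action, i.e. a coefficient-2 substrate appears squared).
#' @return Non-negative flux.
#' @export
evaluate_rate <- function(law, concentrations, substrates = names(concentrations)) {
  if (any(concentrations < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  pars <- law$pars
  switch(law$form,
    mass_action = {
      ord <- pars$orders
      if (is.null(ord)) {
        ord <- table(substrates)
        ord <- stats::setNames(as.numeric(ord), names(ord))
      }
      f <- pars$k
      for (s in names(ord)) f <- f * concentrations[[s]]^ord[[s]]
      unname(f)
    },
    michaelis_menten = {
      f <- pars$Vmax
      for (s in names(pars$Km)) {
        cs <- concentrations[[s]]
        f <- f * cs / (pars$Km[[s]] + cs)
      }
      unname(f)
    },
    hill = {
      cs <- concentrations[[substrates[1L]]]
      if (cs == 0 && pars$n > 0) return(0)
      unname(pars$Vmax * cs^pars$n / (pars$K_half^pars$n + cs^pars$n))
    })
}

#' Define a reaction
#'
#' A reaction is compiled into one (irreversible) or two (reversible) HFPN
#' continuous transitions by [reactions_to_hfpn()].
#'
#' @param id Reaction id; compiled transition ids are `id` (forward) and
#'   `id_r` (reverse).
#' @param substrates Named numeric vector: species -> stoichiometric
#'   coefficient (all positive).
#' @param products Named numeric vector, as `substrates`.
#' @param law Forward [rate_law()], or a function `function(m, p)` for
#'   arbitrary kinetics.
#' @param reverse_law Reverse rate law (or function); implies reversible.
#' @param modifier Optional function `function(m, p)` multiplying the forward
#'   (and reverse) flux; used for expression-level gating and the PTS global
#'   speed factor.
#' @return An object of class `reaction`.
#' @export
reaction <- function(id, substrates, products, law, reverse_law = NULL,
                     modifier = NULL) {
  chk <- function(v, what) {
    if (length(v) && (is.null(names(v)) || any(v <= 0))) {
      stop("reaction '", id, "': ", what,
           " must be a named vector of positive coefficients", call. = FALSE)
    }
  }
  chk(substrates, "substrates")
  chk(products, "products")
  structure(list(id = id, substrates = substrates, products = products,
                 law = law, reverse_law = reverse_law, modifier = modifier),
            class = "reaction")
}

# Expand a substrate stoichiometry vector into a name-with-multiplicity
# character vector for mass-action order defaults.
expand_substrates <- function(substrates) {
  rep(names(substrates), times = round(substrates))
}

law_speed_fn <- function(law, substrates, modifier) {
  if (is.function(law)) {
    if (is.null(modifier)) return(law)
    return(function(m, p) law(m, p) * modifier(m, p))
  }
  subs <- expand_substrates(substrates)
  snames <- unique(subs)
  function(m, p) {
    f <- evaluate_rate(law, m[snames], subs)
    if (!is.null(modifier)) f <- f * modifier(m, p)
    f
  }
}

#' Compile reactions into HFPN components
#'
#' Each reaction becomes a continuous transition with normal input arcs from
#' its substrates (threshold 0: kinetic laws already vanish at zero substrate)
#' and output arcs to its products; reversible reactions are expanded into a
#' forward/reverse transition pair.
#'
#' @param reactions List of [reaction()] objects.
#' @return List with `transitions` and `arcs` suitable for [hfpn_model()].
#' @export
reactions_to_hfpn <- function(reactions) {
  transitions <- list()
  arcs <- list()
  add_dir <- function(id, substrates, products, law, modifier) {
    transitions[[length(transitions) + 1L]] <<-
      hfpn_continuous_transition(id, law_speed_fn(law, substrates, modifier))
    for (s in names(substrates)) {
      arcs[[length(arcs) + 1L]] <<-
        hfpn_arc(s, id, "input", "normal", weight = substrates[[s]],
                 threshold = 0)
    }
    for (s in names(products)) {
      arcs[[length(arcs) + 1L]] <<-
        hfpn_arc(s, id, "output", "normal", weight = products[[s]])
    }
  }
  for (r in reactions) {
    add_dir(r$id, r$substrates, r$products, r$law, r$modifier)
    if (!is.null(r$reverse_law)) {
      add_dir(paste0(r$id, "_r"), r$products, r$substrates, r$reverse_law,
              r$modifier)
    }
  }
  list(transitions = transitions, arcs = arcs)
}

#' First-order dilution/degradation transitions
#'
#' @param decay Named numeric vector: place id -> first-order decay constant
#'   (per hour).
#' @param prefix Transition id prefix (default `"D_"`), matching the
#'   degradation transitions of the network diagram convention.
#' @return List with `transitions` and `arcs`.
#' @export
dilution_set <- function(decay, prefix = "D_") {
  stopifnot(all(decay >= 0))
  transitions <- list()
  arcs <- list()
  for (s in names(decay)) {
    kd <- decay[[s]]
    id <- paste0(prefix, s)
    f <- local({
      s0 <- s; k0 <- kd
      function(m, p) k0 * m[[s0]]
    })
    transitions[[length(transitions) + 1L]] <-
      hfpn_continuous_transition(id, f)
    arcs[[length(arcs) + 1L]] <-
      hfpn_arc(s, id, "input", "normal", weight = 1, threshold = 0)
  }
  list(transitions = transitions, arcs = arcs)
}
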