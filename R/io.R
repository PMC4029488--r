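#' Load a run configuration
#'
#' Reads a YAML configuration, validates its schema (unknown keys are
#' rejected, settings must be positive) and assembles the model.  Two model
#' sources are supported: `model: ecoli` assembles the integrated
#' carbohydrate-metabolism model ([build_ecoli_model()]) with optional
#' `parameters`, `thresholds` and `initial` overrides; `model: custom`
#' builds a network from inline `places`, `transitions` (speed expressions
#' in place/parameter names) and `arcs` blocks.
#'
#' @param path Path to a YAML file.
#' @param params_path Optional second YAML file whose `parameters` /
#'   `thresholds` blocks are merged on top (a `--params` override file).
#' @return List with `config` (validated settings incl. `simulation`,
#'   `seed`) and `model` (an [hfpn_model()]).
#' @export
load_config <- function(path, params_path = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  allowed <- c("model", "parameters", "thresholds", "initial", "simulation",
               "seed", "output_dir", "places", "transitions", "arcs")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(params_path)) {
    ov <- yaml::read_yaml(params_path)
    bad <- setdiff(names(ov), c("parameters", "thresholds"))
    if (length(bad)) {
      stop("override file may only contain parameters/thresholds, got: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    cfg$parameters <- utils::modifyList(cfg$parameters %||% list(),
                                        ov$parameters %||% list())
    cfg$thresholds <- utils::modifyList(cfg$thresholds %||% list(),
                                        ov$thresholds %||% list())
  }
  sim <- utils::modifyList(list(t_end = 12, dt = 1e-3, record_stride = 0.01),
                           cfg$simulation %||% list())
  for (k in c("t_end", "dt", "record_stride")) {
    if (!is.numeric(sim[[k]]) || sim[[k]] <= 0) {
      stop("simulation.", k, " must be positive", call. = FALSE)
    }
  }
  cfg$simulation <- sim
  kind <- cfg$model %||% "ecoli"
  if (identical(kind, "ecoli")) {
    pars <- cfg$parameters %||% list()
    if (!is.null(cfg$thresholds)) {
      pars$thresholds <- utils::modifyList(regulation_thresholds(),
                                           cfg$thresholds)
    }
    model <- build_ecoli_model(params = pars, init = cfg$initial)
  } else if (identical(kind, "custom")) {
    model <- custom_model_from_config(cfg)
  } else {
    stop("configuration key 'model' must be 'ecoli' or 'custom'",
         call. = FALSE)
  }
  list(config = cfg, model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

custom_model_from_config <- function(cfg) {
  for (blk in c("places", "transitions", "arcs")) {
    if (is.null(cfg[[blk]])) {
      stop("custom model needs a '", blk, "' block", call. = FALSE)
    }
  }
  places <- lapply(cfg$places, function(pl) {
    hfpn_place(pl$id, pl$kind %||% "continuous", pl$marking %||% 0,
               pl$unit %||% "mM")
  })
  params <- cfg$parameters %||% list()
  transitions <- lapply(cfg$transitions, function(tr) {
    if (is.null(tr$speed)) {
      stop("transition '", tr$id, "' has no speed expression", call. = FALSE)
    }
    ex <- parse(text = tr$speed)[[1]]
    vars <- all.vars(ex)
    known <- c(vapply(cfg$places, function(x) x$id, character(1)),
               names(params))
    bad <- setdiff(vars, known)
    if (length(bad)) {
      stop("speed of '", tr$id, "' references undeclared names: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    local({
      ex0 <- ex
      hfpn_continuous_transition(tr$id, function(m, p) {
        eval(ex0, envir = c(as.list(m), p))
      })
    })
  })
  arcs <- lapply(cfg$arcs, function(a) {
    hfpn_arc(a$place, a$transition, a$direction %||% "input",
             a$kind %||% "normal", a$weight %||% 1,
             a$threshold)
  })
  hfpn_model(places, transitions, arcs, parameters = params,
             name = "custom")
}

#' Export a trajectory as tidy CSV
#'
#' Columns `time,place,value` (RFC-4180), values at 17 significant digits so
#' a read-back reproduces the stored matrix bit-exactly.
#'
#' @param trajectory An `hfpn_trajectory`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time,place,value", con)
  writeLines(paste(sprintf("%.17g", df$time), df$place,
                   sprintf("%.17g", df$value), sep = ","), con)
  invisible(path)
}

#' Read a trajectory CSV back into a time-by-place matrix
#'
#' @param path File written by [export_trajectory()].
#' @return List with `times` and `markings` matrix.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("time", "place", "value"))) {
    stop("not a trajectory file (expect header time,place,value)",
         call. = FALSE)
  }
  places <- unique(df$place)
  times <- unique(df$time)
  M <- matrix(df$value, nrow = length(times), ncol = length(places),
              dimnames = list(NULL, places))
  list(times = times, markings = M)
}

#' Export the reaction network as SBML Level 3
#'
#' Writes species (continuous places), global numeric parameters and the
#' model's reaction set with kinetic laws: mass-action laws are emitted as
#' MathML (`k * S1 * ...`); reactions with programmatic rate functions
#' (regulation-dependent kinetics) carry an explanatory annotation instead
#' of executable math.  Regulatory threshold logic is annotation-only and
#' marked non-executable.
#'
#' @param model An [hfpn_model()] carrying a reaction registry (e.g. from
#'   [build_ecoli_model()]).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
export_sbml <- function(model, path) {
  if (is.null(model$reactions)) {
    stop("model carries no reaction registry; only reaction-based models ",
         "can be exported", call. = FALSE)
  }
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = model$name)
  cmp <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(cmp, "compartment", id = "cell", constant = "true",
                      spatialDimensions = "3", size = "1")
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (pl in model$places) {
    if (pl$kind != "continuous") next
    xml2::xml_add_child(los, "species", id = pl$id, compartment = "cell",
                        initialConcentration = format(pl$marking),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  for (pn in names(model$parameters)) {
    v <- model$parameters[[pn]]
    if (is.numeric(v) && length(v) == 1L) {
      xml2::xml_add_child(lop, "parameter", id = pn, value = format(v),
                          constant = "true")
    }
  }
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  add_species_refs <- function(parent, tag, stoich) {
    if (length(stoich) == 0L) return(invisible())
    lst <- xml2::xml_add_child(parent, tag)
    ref <- if (tag == "listOfModifiers") "modifierSpeciesReference"
           else "speciesReference"
    for (s in names(stoich)) {
      if (ref == "speciesReference") {
        xml2::xml_add_child(lst, ref, species = s,
                            stoichiometry = format(stoich[[s]]),
                            constant = "true")
      } else {
        xml2::xml_add_child(lst, ref, species = s)
      }
    }
  }
  one_reaction <- function(id, substrates, products, law) {
    rxn <- xml2::xml_add_child(lor, "reaction", id = id,
                               reversible = "false")
    add_species_refs(rxn, "listOfReactants", substrates)
    add_species_refs(rxn, "listOfProducts", products)
    kl <- xml2::xml_add_child(rxn, "kineticLaw")
    if (inherits(law, "rate_law") && law$form == "mass_action") {
      math <- xml2::xml_add_child(
        kl, "math", xmlns = "http://www.w3.org/1998/Math/MathML")
      ap <- xml2::xml_add_child(math, "apply")
      xml2::xml_add_child(ap, "times")
      cn <- xml2::xml_add_child(ap, "cn")
      xml2::xml_text(cn) <- format(law$pars$k)
      for (s in expand_substrates(substrates)) {
        ci <- xml2::xml_add_child(ap, "ci")
        xml2::xml_text(ci) <- s
      }
    } else {
      ann <- xml2::xml_add_child(kl, "annotation")
      note <- xml2::xml_add_child(ann, "nonExecutableRate")
      xml2::xml_text(note) <-
        paste0("rate of '", id, "' is regulation-dependent and defined ",
               "programmatically; not executable from this document")
    }
  }
  for (r in model$reactions) {
    one_reaction(r$id, r$substrates, r$products, r$law)
    if (!is.null(r$reverse_law)) {
      one_reaction(paste0(r$id, "_r"), r$products, r$substrates,
                   r$reverse_law)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
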