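# Shared fixtures: small nets built in code, and a memoized default
# batch-culture simulation (expensive; computed once per test run).

.fixtures <- new.env(parent = emptyenv())

# Single-species first-order decay net A -> (sink), dA/dt = -k A.
decay_net <- function(k = 0.1, A0 = 1) {
  hfpn_model(
    places = list(hfpn_place("A", marking = A0)),
    transitions = list(
      hfpn_continuous_transition("dec", function(m, p) p$k * m[["A"]])),
    arcs = list(hfpn_arc("A", "dec", "input", "normal", 1, threshold = 0)),
    parameters = list(k = k))
}

# Closed two-place mass-action cycle A <-> B.
cycle_net <- function(kf = 0.7, kr = 0.3, A0 = 1, B0 = 0.5) {
  hfpn_model(
    places = list(hfpn_place("A", marking = A0),
                  hfpn_place("B", marking = B0)),
    transitions = list(
      hfpn_continuous_transition("f", function(m, p) p$kf * m[["A"]]),
      hfpn_continuous_transition("r", function(m, p) p$kr * m[["B"]])),
    arcs = list(
      hfpn_arc("A", "f", "input", "normal", 1, threshold = 0),
      hfpn_arc("B", "f", "output"),
      hfpn_arc("B", "r", "input", "normal", 1, threshold = 0),
      hfpn_arc("A", "r", "output")),
    parameters = list(kf = kf, kr = kr))
}

# PTS-only relay model: the relay reactions plus a constant PEP source;
# glucose and the phospho-state of the pools are set by `init`.  PYR
# accumulates freely (its backpressure on R1 is part of the model).
pts_only_model <- function(params = list(), init = list(),
                           pep_source = 1, pyr_drain = 0) {
  p <- utils::modifyList(default_parameters(), params)
  m0 <- c(PEP = 0.2, PYR = 0, Glc_ext = 0, G6P = 0,
          EI = 0.15, PEI = 0, HPr_pole = 0, PHPr_pole = 0,
          HPr_cyt = 0.4, PHPr_cyt = 0, EIIA = 0.25, PEIIA = 0,
          EIICB = 0.05, PEIICB = 0)
  m0[names(init)] <- unlist(init)
  places <- lapply(names(m0), function(s) {
    hfpn_place(s, "continuous", marking = m0[[s]])
  })
  net <- reactions_to_hfpn(pts_reaction_set(p))
  if (pep_source > 0) {
    net$transitions <- c(net$transitions, list(
      hfpn_continuous_transition("pep_src", function(m, p) p$pep_source)))
    net$arcs <- c(net$arcs, list(hfpn_arc("PEP", "pep_src", "output")))
  }
  if (pyr_drain > 0) {
    net$transitions <- c(net$transitions, list(
      hfpn_continuous_transition("pyr_out",
                                 function(m, p) p$pyr_drain * m[["PYR"]])))
    net$arcs <- c(net$arcs, list(
      hfpn_arc("PYR", "pyr_out", "input", "normal", 1, threshold = 0)))
  }
  p$pep_source <- pep_source
  p$pyr_drain <- pyr_drain
  hfpn_model(places, net$transitions, net$arcs, parameters = p,
             name = "pts_only")
}

# Random small purely-continuous mass-action nets for property tests.
random_ma_net <- function(n_places = 4, n_trans = 5, seed = 1) {
  set.seed(seed)
  ids <- paste0("P", seq_len(n_places))
  places <- lapply(ids, function(s) {
    hfpn_place(s, marking = round(stats::runif(1, 0, 2), 3))
  })
  transitions <- list()
  arcs <- list()
  for (j in seq_len(n_trans)) {
    tid <- paste0("t", j)
    sub <- sample(ids, sample(1:2, 1))
    prod <- sample(setdiff(ids, sub), sample(0:2, 1))
    k <- round(stats::runif(1, 0.1, 2), 3)
    transitions[[j]] <- local({
      sub0 <- sub; k0 <- k
      hfpn_continuous_transition(tid, function(m, p) {
        k0 * prod(m[sub0])
      })
    })
    for (s in sub) {
      arcs[[length(arcs) + 1L]] <- hfpn_arc(s, tid, "input", "normal", 1,
                                            threshold = 0)
    }
    for (s in prod) {
      arcs[[length(arcs) + 1L]] <- hfpn_arc(s, tid, "output")
    }
  }
  hfpn_model(places, transitions, arcs)
}

# Default batch-culture simulation, memoized (used by phase, acceptance and
# Pearson-r tests).
default_traj <- function() {
  if (is.null(.fixtures$traj)) {
    model <- build_ecoli_model()
    .fixtures$traj <- hfpn_simulate(model, t_end = 13.5, dt = 1e-3,
                                    record_stride = 0.02)
  }
  .fixtures$traj
}

default_segmentation <- function() {
  if (is.null(.fixtures$seg)) {
    .fixtures$seg <- classify_phases(default_traj())
  }
  .fixtures$seg
}

table_cell <- function(tab, regulator, phase) {
  tab[[phase]][tab$regulator == regulator]
}
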