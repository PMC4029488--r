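---
title: "Modelling glucose and glycogen utilization in E. coli with a hybrid functional Petri net"
author: "glycoHFPN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glucose and glycogen utilization in E. coli with a hybrid functional Petri net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4.5)
library(glycoHFPN)
```

## The biological question

During the lag phase of a batch culture, *Escherichia coli* has two sugar
sources: extracellular glucose and its internal glycogen store. Which one
is used, and when, is decided by a compact regulatory circuit centred on
two phosphotransferase-system (PTS) proteins, HPr and EIIA^Glc. This
package implements a kinetic model of that circuit as a hybrid functional
Petri net (HFPN): continuous places carry metabolite concentrations (mM)
and protein or transcript levels (arbitrary units, au), continuous
transitions fire at marking-dependent speeds, and a small discrete layer is
available for delayed token events.

The model couples four parts:

* **Glycolysis and the pentose phosphate pathway** — a general mass-action
  network from glucose 6-phosphate (G6P) down to pyruvate (PYR), with the
  oxidative PP branch and the transketolase/transaldolase exchanges.
  Cofactors (ATP/ADP, NAD(P)H, P~i~) are not state variables; their effect
  is absorbed into the rate constants. PYR is a sink: TCA, acetate overflow
  and gluconeogenesis are outside the model's scope.
* **The PTS phospho-relay** — elementary reversible phosphotransfer steps
  PEP + EI ⇌ PYR + P\~EI (R1), P\~EI + HPr ⇌ EI + P\~HPr (R2),
  P\~HPr + EIIA ⇌ HPr + P\~EIIA (R3), P\~EIIA + EIICB ⇌ EIIA + P\~EIICB
  (R4) and the irreversible uptake step P\~EIICB + Glc~ext~ → EIICB + G6P
  (R5). R1 is gated by a Hill function of PEP standing in for
  PEP-stimulated EI dimerization, the limiting step of phosphate influx.
  A global speed parameter `k_pts` scales the whole relay.
* **Glycogen metabolism** — phosphoglucomutase G6P ⇌ G1P, GlgC/GlgA
  synthesis G1P → ADPG → glycogen (scaled by the glgC&glgA expression
  level), and GlgP phosphorolysis glycogen → G1P. GlgP is taken to be
  always complexed with HPr; the unphosphorylated HPr::GlgP complex
  catalyzes phosphorolysis five times faster than P\~HPr::GlgP
  (`k_glgP_fast = 5 * k_glgP_slow`), and only pole-located HPr serves
  glycogenolysis.
* **The regulatory circuit** — two activation inputs for glgC&glgA
  transcription: `alpha` (high FDP represses Cra, releasing its
  inhibition) and `beta` (phosphorylated EIIA stimulates adenylate
  cyclase; the cAMP/CRP complex activates transcription). Their
  combination sets the three-level composition speed
  `gamma = gamma_lookup(alpha, beta)`: 0 (off), 1 (slow, either input),
  2 (fast, both). PTS operon expression (ptsHIcrr, ptsG) is released when
  Cra falls; once both operons pass an expression threshold the whole PTS
  speed is multiplied by an acceleration factor (default 10). HPr
  localization is a pole/cytosol split of the HPr pools, driven outward by
  the EI→HPr phospho-flux and back to the poles when uptake is idle and
  HPr is predominantly phosphorylated.

## Numerical engine

Simulation is explicit Euler with a fixed step (default `dt = 1e-3` h),
matching the fixed-step semantics of the graphical HFPN tools this model
family is normally built in. Two engine details matter:

* **Non-negativity.** If a step would drive a place negative, the firing
  amounts of the transitions consuming that place are scaled so it lands
  exactly at zero; scaling the amount (rather than clamping the result)
  preserves within-step stoichiometry, so conservation checks hold to
  rounding error.
* **Accuracy.** The engine is first order. Against adaptive reference
  integration (`deSolve::lsoda`, rtol 1e-8) of the identical rate
  equations on the purely continuous reaction core, the worst-case
  relative error (with a 0.01-unit floor on the denominator) converges
  linearly: about 1.06% at `dt = 1e-3`, 0.53% at `5e-4` and 0.27% at
  `2.5e-4`. The engine-accuracy check in the test suite therefore runs at
  `dt = 2.5e-4`; the default `1e-3` is accurate to about one percent,
  which is far below the scale of the qualitative phase behaviour the
  integrated model is used for. Relay exchange constants are kept at
  15 au^-1^h^-1^ so that even under the tenfold PTS acceleration the
  stiffest local rates stay inside the explicit-Euler stability region at
  the default step.

## Default parameters and what they were calibrated against

The model's mass-action constants are not taken from a database; they are
calibrated, once, against the qualitative behaviour the circuit is known
to produce in a batch culture, and then frozen (the harness is
`tools/calibrate_defaults.R`):

1. glycogen is consumed quickly during the lag phase, before extracellular
   glucose is touched appreciably;
2. glucose is exhausted during the log phase;
3. glycogen re-accumulates in late log under fast (gamma = 2) synthesis;
4. the five batch-culture phases classify in canonical order, and the
   discretized regulator table shows the expected pattern — decomposition
   slow→fast in early lag, silent while HPr is cytosolic, slow again in
   stationary phase; localization pole → cytosol → … → pole; EIIA and HPr
   re-phosphorylated from late log onward.

Units are hours, mM for metabolites and au for proteins/transcripts. The
initial marking is a batch-culture start: 10 mM glucose, 2 mM
hexose-equivalents of glycogen, intermediates at zero, PTS proteins at low
basal levels with HPr, EIIA and EIICB phosphorylated and HPr pole-located,
Cra at its unrepressed level and the cAMP/CRP loop in its high state.

A run of the default configuration takes a couple of minutes:

```{r simulate, eval = FALSE}
model <- build_ecoli_model()
traj <- hfpn_simulate(model, t_end = 13.5, dt = 1e-3, record_stride = 0.02)
seg <- classify_phases(traj)
seg
discretize_states(traj, seg)
```

```{r plot, eval = FALSE}
rs <- regulatory_series(traj)
matplot(rs$time, cbind(rs$Glc_ext, rs$glycogen, rs$FDP), type = "l",
        lty = 1, xlab = "time (h)", ylab = "mM",
        col = c("black", "forestgreen", "orange"))
legend("topright", c("Glc_ext", "glycogen", "FDP"), lty = 1,
       col = c("black", "forestgreen", "orange"))
```

## Phase classification and the qualitative table

`classify_phases()` segments a trajectory by ordered event detection:

* early lag → late lag when glycogen has fallen below half its initial
  level *and* the HPr pole fraction has dropped below 0.5;
* late lag → early log when the PTS acceleration engages;
* early log → late log when the EIIA phosphorylated fraction crosses 0.5
  upward **and stays above it for at least `sustain` hours (default 1)** —
  right after HPr floods into the cytosol the relay re-equilibrates and
  can transiently exceed 0.5, which is a re-distribution of existing
  phosphate, not a phase change;
* late log → stationary when extracellular glucose falls below
  `glc_eps = 0.05` mM.

`discretize_states()` renders the machine-readable analogue of the
qualitative regulator table: per phase, medians over the first and last
15% of the phase are mapped through frozen class boundaries
(`class_thresholds()`), and a cell reads `"x→y"` when the start and end
classes differ. Two rendering choices are worth spelling out:

* the **composition** class is derived from the realized glycogen
  synthesis flux (ADPG → glycogen), not from `gamma` alone — in stationary
  phase `beta` is on but there is no substrate, so composition correctly
  reads from the flux; `alpha`, `beta` and `gamma` are reported as their
  own rows;
* the **decomposition** class combines pole availability (flux below
  `decomposition_eps` reads "no") with the per-complex catalytic speed mix
  (`k_fast`/`k_slow` weighted by the pole HPr phosphorylation state) for
  the slow/fast distinction, which is what the slow/fast language of the
  regulator table refers to.

The rendered table is close to, but not identical with, the idealized
qualitative description: continuous dynamics put transitions where the
verbal table has plateaus (for instance `alpha` switches on shortly before
the early-lag boundary rather than exactly at it, and the uptake-speed row
compresses because the simulated uptake flux spans a narrower range than
the verbal five-level scale). The acceptance tests assert the cells that
carry the regulatory story: the decomposition and localization rows, the
late-lag composition, and the stationary-phase phosphorylation states.

## Localization gates in the integrated model

The standalone `update_pole_fraction()` follows the plain rule: outward
relaxation while the EI→HPr flux exceeds a threshold, pole-ward relaxation
when the flux is idle and HPr is predominantly phosphorylated. Wiring that
rule naively into the integrated model locks HPr out of the poles in
stationary phase: the slow dephosphorylation leak of pole P\~HPr (the
default 0.5 h^-1^ first-order leak that lets glycogenolysis start when
glycolysis is idle) is immediately re-phosphorylated at the pole, and that
re-phosphorylation is itself an EI→HPr flux. The integrated model's gates
therefore differ in two respects: outward translocation additionally
requires HPr to be predominantly unphosphorylated (a growth signature),
and the return condition reads the uptake step R5 per unit PTS speed — a
glucose-availability readout — rather than the exchange flux. Both gates
relax the pole pools at `k_loc = 40` h^-1^.

## Synthetic observations and parameter recovery

The study conditions this package emulates include sparse batch-culture
measurements of glycogen and glycolytic intermediates. The
`generate_observations()` generator stands in for them: 15 timepoints
uniformly over the simulated span, multiplicative lognormal noise with
sigma 0.1 (about 10% relative error) plus a 1e-3 additive floor, clamped
at zero. It emulates sparse sampling and proportional assay error; it does
**not** emulate systematic calibration offsets, autocorrelated drift, or
biological replicate variation — so a passing recovery experiment shows
the fitting machinery is sound, not that real measurements of this system
would constrain the constants equally well.

`fit_parameters()` minimizes log-scale residuals (`log(sim + 1e-3) −
log(obs + 1e-3)`) with Levenberg–Marquardt in log-parameter space; the log
scale keeps mM-range glucose from dominating au-range signals, and log
parameters make positivity structural. The recovery experiment frees the
three glycogen-module constants `k_glgP_fast` (with `k_glgP_slow` tied at
one fifth), `k_glgC` and `k_pgm_r`, observes glycogen, G1P, ADPG and G6P
over the glycogen-active first 2.5 h, and starts from a guess at twice the
truth. Each free constant directly drives one observed pool, which is what
makes the problem well conditioned; a superficially similar set that frees
both phosphoglucomutase directions instead leaves one direction almost
flat in the objective. Observations are generated at the same step size
the objective simulates with, so the noiseless truth is an exact fixed
point. Noiseless recovery is exact to optimizer tolerance; at 10% noise
the per-parameter error stays below about 7% across seeds.

## Problem sizes

The shipped analyses are sized for a desk machine: the default batch
simulation covers 13.5 h of culture time at `dt = 1e-3` (13,500 steps, 676
recorded points); the engine-accuracy check integrates the continuous core
for 6 h at `dt = 2.5e-4`; the recovery experiment runs six
Levenberg–Marquardt fits of a 2.5 h window at `dt = 5e-3`. A full test-suite
run performs each of these once.

## Known limitations

* Absolute concentrations and times are calibrated to a qualitative
  target, not fitted to measurements; only the *pattern* of the phase
  table, the five-to-one GlgP complex ratio, the multi-valued composition
  switch and the relay's phosphorylation logic should be read as the
  model's claims.
* PYR accumulates (no TCA/acetate outlet), so late-time absolute levels of
  lower glycolysis are not meaningful.
* The pole P\~HPr dephosphorylation leak is a stand-in for an unexplained
  slow dephosphorylation that the circuit needs in early lag; its rate
  (0.5 h^-1^) is a modelling choice exposed in the configuration.
* SgrS/SgrT small-RNA mechanics are collapsed into a direct Cra→ptsG
  repression release; ppGpp and CsrA regulation are absent.
* The verbal five-level uptake-speed scale is rendered from one continuous
  flux with frozen cuts; two of its five cells disagree with the idealized
  table (see above), which the package reports honestly rather than
  forcing.
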