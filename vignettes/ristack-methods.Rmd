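---
title: "Retention-index prediction across stationary phases: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retention-index prediction across stationary phases: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ristack)
```

## The problem

The Kovats retention index (RI) normalizes an analyte's gas-chromatographic
retention against the n-alkane series, making it transferable across
instruments: `RI = 100 * (n + (log k_x - log k_n) / (log k_{n+1} - log k_n))`,
with `k` the retention factor and `n` the bracketing alkane carbon number.
Predicted RI values are useful as a soft constraint in GC-MS library search
and for selecting a stationary phase (SP) for a separation. Abundant
reference data exist for non-polar phases (DB-1, DB-5, squalane), much less
for polar polyethylene-glycol phases (DB-WAX), and very little for mid-polar
phases (DB-624, OV-17, DB-210, DB-1701). `ristack` implements a multi-level
strategy for exactly this data imbalance:

1. **Base neural regressors** (an MLP over molecular descriptors and a 1D
   CNN over SMILES characters), trained on data-rich non-polar phases, each
   conditioned on a stationary-phase encoding.
2. **Transfer learning**: the polar-phase models are initialized with the
   base models' final weights and fine-tuned on the smaller polar corpus.
3. **Second-level stacking** for mid-polar phases: an epsilon-SVR consumes
   the RI values predicted by all four networks for every registry phase
   (114 features, each divided by 1000) plus 327 molecular descriptors —
   441 inputs — and maps them to RI on the data-poor target phase. The same
   pipeline applies to second-dimension GCxGC retention times.
4. **Few-parameter linear phase combinations** where even a stacking set is
   unavailable: RI on a target phase as an intercept-free linear combination
   of RI on at most five well-covered phases, built greedily.

A linear functional-group-contribution baseline (84 counters, ordinary
least squares) is included as the classical comparison model.

## Phase encoding and registries

All four networks share one 38-slot phase-encoding array, so transfer
learning is a pure weight copy. Non-polar models one-hot 36 non-polar phase
types; polar models one-hot 21 slots (20 named polyethylene-glycol-class
phases plus a catch-all "Other polar"); remaining slots stay zero. The
registry ships as a versioned CSV (`phase_registry_v1.csv`). Phase names in
the registry are common commercial column designations; the catalog is a
package artifact, chosen once, and the non-polar catalog is closed (an
unknown non-polar phase is an error), while unknown polar phases fall back
to "Other polar".

## Descriptors

The descriptor manifest (`descriptor_manifest_v1.csv`) pins 327 features:
243 general descriptors — OpenBabel physicochemical properties (logP, molar
refractivity, TPSA, hydrogen-bond counts, molecular weight), element
counts, graph indices (Wiener, Zagreb, Randic, walk counts, spectral
radius, eccentricity statistics), topological-distance atom-pair counts
(element pairs C/N/O/S/halogen at bond distances 1–9) and 65
atom-environment SMARTS counts — plus 84 functional-group counters defined
by a shipped SMARTS table. Counters are integers before scaling; every
descriptor is affinely scaled by a center and scale **frozen in the
manifest** (computed once from a fixed-seed 2,000-analyte reference library
and never refit on any training set), mirroring the fixed-scaling-factor
protocol of deployed QSRR pipelines. Descriptors are computed from the
canonical SMILES, so they are invariant to the input rendering of a
molecule.

The exact descriptor list of any particular legacy software cannot be
reproduced from the literature; the manifest is therefore this package's
own versioned definition with the same block sizes (243 + 84 = 327), and
tests pin those sizes.

## Network architectures and training protocol

Both networks regress RI/1000 with mean-absolute-error loss, Adam
(learning rate 1e-3), mini-batches of 256, and compound-based validation:
10% of training *compounds* are isolated before training; validation MAE is
recorded every 500 iterations and the best checkpoint's weights are used
for prediction, while the final-iteration weights seed transfer learning.
Full-scale protocols are 50,000 base iterations and 10,000 transfer
iterations; one "iteration" is one mini-batch update.

The MLP consumes the 327 descriptors concatenated with the 38-slot phase
encoding through an input layer and residual dense blocks
(`relu(h + W2 relu(W1 h + b1) + b2)`). The CNN embeds SMILES tokens
(two-character elements `Cl`, `Br`, `Si` are single tokens), applies two
convolutional layers (kernel 5) with a stride-2 max pool between them,
global max+mean pooling over positions, concatenates the phase encoding,
and finishes with a dense head. Padding positions are masked out of
convolutions and pooling; the mean pool divides by the true token length.

Layer sizes are artifact choices of this package; the QSRR literature
does not converge on a standard configuration. The constructors default to a 512-wide MLP
with three residual blocks and a 32/64-channel CNN. The **desk-scale
configuration** used by `fit_ri_models()` and by the package's own
end-to-end study is deliberately smaller — MLP width 160 with three
residual blocks; CNN embedding 8, channels 12/24, dense head 48, maximum
token length 44 — with 5,000 base and 2,000 transfer iterations, sized so
the whole multi-stage study runs on a single CPU core in minutes while
still leaving the base models clearly better than trivial baselines. All
of it is configurable through `net_spec()` and `train_protocol()`.

Gradients are exact (unit tests check backpropagation against central
differences at 1e-10 level), training is deterministic given a protocol
seed, and transfer initialization is shape-checked so it can never silently
change the architecture.

## The second-level SVR

The stacker is epsilon-SVR with the exponential (Laplacian) kernel
`k(x,y) = exp(-||x-y||/sigma)`, `sigma = 31`, box constraint `C = 31000`,
trained on labels divided by 1000 and multiplied back at prediction. The
441-feature layout is fixed: positions 1–114 are the predicted-RI block
(CNN then MLP over the 36 non-polar types, then CNNPolar and MLPPolar over
the 21 polar types), positions 115–441 the descriptors.

Two constants of this working point, `epsilon = 0.82` and
`tolerance = 2.7`, are ambiguous in unit. Applied verbatim to labels/1000
(whose whole range is roughly 0.3–4.0), a 0.82 tube would make the loss
blind to nearly all structure and the fit would degenerate towards a flat
function — a regime in which no useful mid-polar predictor can be obtained
at all, so these magnitudes cannot be meant on that scale. Read in *index
units* and scaled together with the labels, they become 8.2e-4 and 2.7e-3 —
the latter exactly the magnitude of a typical SMO convergence tolerance.
`ristack` therefore defaults to `epsilon_units = "index"`; the literal
scaled reading remains available (`epsilon_units = "scaled"`) and a
regression test demonstrates its degeneracy. This is a deliberate design
resolution of a genuinely ambiguous convention, made on the dimensional
argument above.

Degenerate inputs are handled explicitly: if all scaled targets fit inside
one tube, the exact optimum is a flat function and `train_stack()` returns
a bias-only model (midrange bias) rather than calling the solver.
`kkt_check()` verifies dual feasibility (`|alpha| <= C`), that points
strictly inside the tube carry zero dual coefficient, and that bound
support vectors sit on or outside the tube, with slack tied to the solver
tolerance.

## Greedy linear phase combinations

If retention obeys a five-parameter linear solvation equation
(`log k = c + eE + sS + aA + bB + lL`), then `log k` on any liquid phase is
a linear combination of `log k` on at most five others, and under an
isothermal alkane ladder RI is affine in `log k` — so RI on a target phase
is an intercept-free linear combination of RI on donor phases. The builder
starts from the single most-correlated phase (largest absolute Pearson
correlation, then an intercept-free least-squares refit — "most
correlated" admits several readings; this is the package's),
adds at each step the candidate with the largest MAE gain (ties resolve to
the lowest registry index), refits all coefficients, and stops below a
gain threshold (default 4 index units, the customary 3–5 range) or at five
terms. An optional exclusion table keeps phases of near-identical polarity
from entering together; it is off by default because the underlying rule
is qualitative. The two published fixed equations for DB-1701 and DB-210
ship verbatim in `builtin_combo_equations()`.

## The simulator

`generate_library()` + `build_corpus()` emulate a curated retention corpus
without any proprietary download. Analytes from 21 compound classes get
Abraham solute parameters `(E, S, A, B, L)` linked to structure: `L` grows
with heavy-atom count (homolog ordering), `A` counts hydrogen-bond donors
and is exactly zero for donor-free classes, `S` and `B` reflect polar
functionality, plus small seeded jitter so class members are not
degenerate. Phases carry `(c, e, s, a, b, l)` vectors: five non-polar
columns (small `s`, `a`), four polar (large `s`, `a`) and one mid-polar —
values chosen to be plausible for isothermal GC, not calibrated to
measured solvation data. Retention is `log k = c + eE + sS + aA + bB + lL`;
RI comes from Kovats bracketing against an alkane ladder with `L` affine in
carbon number (C4–C40); records add Gaussian noise (default sd 10 index
units, a realistic inter-source replicate spread) per (analyte, phase).

Because the alkane `L` is affine in carbon number, the simulated RI is
*exactly* affine in `log k` inside the ladder — this is what makes the
noiseless greedy-recovery test sharp: for a phase built as
`sum(w_i * phase_i)`, the RI-space combination coefficients are
`w_i * l_i / l_mix`, and the greedy builder must recover them to 1e-6.

What the simulator does *not* emulate: temperature dependence, non-linear
ladder effects, systematic inter-laboratory bias, conformer-dependent
retention, and the chemical diversity of a real 9,000-compound database.
Tests passing on this corpus therefore demonstrate the correctness and the
qualitative behavior of the pipeline (transfer helps when polar data are
scarce; stacking beats any single base-model feature), not the absolute
accuracies attainable on curated experimental data.

## The desk-scale study and what it shows

The end-to-end study (shared by the acceptance tests and
`scripts/acceptance.R`) simulates 2,000 analytes over the ten default
phases, removes n-alkanes and whitelist violators, holds 500 mid-polar
compounds out of all network training (400 to train the stacker, 100 to
test it), trains the four networks (5,000/2,000 iterations), and compares
the stacker's test MAE against the strongest single base-model prediction
column (selected on the stacking training set). The transfer-learning
comparison fine-tunes versus retrains from scratch on a 10x-reduced polar
corpus at a matched 2,000-iteration budget with shared seeds, median over
three seeds. Problem sizes are the package's chosen desk-scale study
conditions; each stage accepts larger corpora and budgets unchanged.

## Known limitations

- The descriptor manifest and phase registry are package-defined artifacts;
  models trained against one manifest/registry version refuse inputs from
  another.
- Molecules are limited to the element whitelist
  {C, H, O, N, S, P, F, Cl, Br, I, Si}, 100 heavy atoms and (for the CNN)
  the configured token alphabet and maximum length; single-heavy-atom
  molecules are outside the supported domain (the admission filters remove
  them in practice).
- The SVR inherits kernlab's SMO behavior; with near-zero epsilon and very
  large C it interpolates and can be sensitive to duplicated conflicting
  records (a warning is raised).
- RI temperature dependence and GCxGC modulation physics are out of scope;
  second-dimension times are modeled by the same stacking pipeline with a
  unit tag only.
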