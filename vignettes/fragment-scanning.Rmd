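---
title: "Fragment-based scanning of coiled-coil folding potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based scanning of coiled-coil folding potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilscan)
```

## The problem

Coiled coils are bundles of two or more α-helices winding around a shared
axis, burying a hydrophobic core through knobs-into-holes (KIH) packing:
a core residue (the knob) of one helix inserts into a cavity formed by
four residues (the hole) of an adjacent helix. The canonical sequence
signature is the heptad repeat, seven residues labelled *a*–*g* with the
core at *a* and *d*. Long fibrous coiled coils — myosin stalks, endosomal
tethers, viral fusion stalks — are difficult targets for structure
predictors: full-length models are often spuriously bent, and
non-canonical (e.g. hendecad) bundles come back with poor confidence and
absent core packing.

The fragment-scanning approach sidesteps the full-length prediction:
divide the sequence into short overlapping windows, predict each window
as an isolated homo-oligomer, and map the per-fragment models and their
confidence scores back onto full-length coordinates. Local properties —
where the sequence supports a confident parallel dimer, where it prefers
an antiparallel arrangement, where no packing is encoded at all — become
visible per residue, even when the full-length model hides them.

`coilscan` implements the bookkeeping around that idea: the divider, the
feature extractors, and the integrator. It deliberately runs no predictor
itself; any program that emits PDB models (pLDDT in the B-factor column)
and optionally PAE JSON can sit in the middle of the pipeline.

## The specification N_L_O and the windowing rule

A *specification* is the string `N_L_O`: model `L`-residue windows with
`O` residues of overlap between consecutive windows, as an `N`-chain
homo-oligomer (`2_30_15`: 30-residue windows, 15-residue overlap,
dimers). Validity requires `N ≥ 1`, `L ≥ 1`, and `0 ≤ O ≤ L − 1`, so the
window step `s = L − O` is at least one residue.

Windows start at 0, s, 2s, … (0-based half-open internally; the
`constructs.csv` on disk reports 1-based inclusive ranges, the convention
human readers expect of residue numbering). When the final regular window
would run past the C-terminus, the window *length* is given priority: the
last window is anchored at the C-terminus instead, so its overlap with
its predecessor grows beyond `O` and every emitted window has exactly `L`
residues. A sequence shorter than `L` yields a single full-sequence
window with a warning rather than an error — erroring would make short
proteins unscannable for no benefit.

With `O = L/2`, every residue further than `L/2` from both termini is
covered by exactly two windows, which is the regime in which integrated
feature values are two-model averages.

An optional *flank* (an adaptor sequence such as a GCN4-derived helix) is
attached to both termini of every window before prediction, to promote
folding of fragments too short to fold alone. Flanks are stripped —
coordinates, pLDDT, and PAE rows/columns alike — before any feature is
computed, so they never contribute to scores.

## Features

Four per-residue features are extracted from each fragment model:

* **pLDDT** (0–100): read from the CA B-factor column, averaged over the
  N chain copies of each position.
* **PAE** (Å): for position *i*, the mean of all PAE entries in the rows
  and columns of every chain copy of residue *i* (diagonal included).
  A whole-matrix average would blur per-residue structure, and the
  scanning view is inherently per-residue, so the row∪column slice is
  used. For oligomers this mean is dominated by inter-chain blocks, which
  is what makes it informative about the robustness of the assembly.
* **Orientation**: for each unordered chain pair, the mean CA–CA distance
  between equivalent residue indices (`d_fwd`) is compared with the same
  mean after reversing the residue index of one chain (`d_rev`); the pair
  is antiparallel iff the reversal reduces the mean distance. For `N > 2`
  the model-level call is the majority over all pairs (1 parallel, 0
  antiparallel, 0.5 on an exact tie, which needs ≥ 4 chains). A pair with
  `d_rev == d_fwd` exactly is called parallel: the tie-break must be
  deterministic, and the event has measure zero on real coordinates.
* **KIH participation**: an internal SOCKET-style detector. Residue *r*
  is a knob when at least four side-chain centers of residues on one
  single other chain lie within the packing cutoff (default 7.0 Å, the
  SOCKET convention, exposed as a parameter) of *r*'s side-chain center;
  the four nearest form the hole. The per-position feature is binary
  participation — knob or hole member on any chain — so integrated
  values read as the fraction of covering models in which the residue
  takes part in a coiled-coil interface. Side-chain centers are centroids
  of non-backbone heavy atoms, with CB and then CA as fallbacks; no
  register (*a*–*g*) or SOCKET type assignment is attempted, and no
  helicity prefilter is applied — an unpacked residue simply yields no
  KIH.

## Integration

Each fragment contributes its feature vector at the positions its window
covers; overlapping contributions are flattened with a reducer, by
default the arithmetic mean (min, max, and median are available — the
flattening is a named strategy, not a hard-wired formula). The flattened
orientation is therefore interpretable directly: 0.5 at a position means
half the covering models were parallel and half antiparallel, i.e. the
local sequence does not encode a topology. A `coverage` column counts the
covering models. Fragments whose model file is absent are skipped with a
warning and reduce coverage; a fragment missing only one feature (no PAE
file, or a monomer's undefined orientation) is excluded from that
feature's mean but still counts toward coverage. The C-terminal
priority window is weighted like any other window.

## The synthetic generator

Testing the integrator requires models with known ground truth, so the
package fabricates them from the Crick parameterization: the backbone of
a coiled coil as a minor helix of radius `R1` wound around a superhelical
axis of radius `R0`. Defaults are standard idealized values — `R1` =
2.26 Å, minor-helix frequency `ω1` = 720/7 ≈ 102.86°/residue (two turns
per heptad), rise 1.51 Å/residue, superhelical frequency `ω0` =
−3.6°/residue (left-handed heptad supercoil), `R0` = 4.9 Å for dimers
and 6.3 Å for tetramers. These produce CA–CA spacings of 3.77–3.78 Å and,
with the default minor-helix phase `φ1 = 0`, inward-facing core residues
at positions 2 and 5 (0-based) modulo 7 — the two heptad core slots.
Pseudo side-chain centers are placed 1.5 Å radially outward from the
local minor-helix axis, sufficient because the KIH detector consumes only
side-chain centers.

Chains are spaced 360/N° around the axis. An antiparallel chain is built
by a proper 180° rotation about an in-plane axis, which preserves
handedness while reversing the chain's direction along the bundle axis;
the stored residue order is deliberately *not* reversed afterwards, since
that second inversion would recreate a parallel arrangement.

`build_fake_run()` assembles a complete desk-scale "prediction run" from
a ground-truth region layout (parallel / antiparallel / unstructured
segments): it designs a sequence, divides it, and writes one synthetic
model per fragment according to the majority label of its window —
a parallel bundle, an antiparallel bundle, or extended chains 100 Å
apart. Coiled-coil regions get pLDDT 90 and PAE 3 Å, unstructured regions
pLDDT 40 and PAE 20 Å — values typical of confident oligomer predictions
versus disordered-segment output. All coordinate noise (0.2 Å by
default, a mild perturbation well below any decision margin) flows from
one seed recorded in the run's parameters file, so runs are byte-identical
given the seed.

What the generator does *not* emulate: real side-chain rotamers, bent or
partially folded fragments, confidence scores correlated with geometry
quality, oligomer-state ambiguity, or sequence-dependent folding. Tests
passing on these fixtures demonstrate that the bookkeeping — windowing,
flank handling, feature extraction, mapping, flattening — is correct, not
that any predictor's models are accurate.

## Worked example

```{r example}
layout <- region_layout(c("parallel", "antiparallel", "unstructured"),
                        c(100, 100, 100))
rundir <- file.path(tempdir(), "demo_run")
run <- build_fake_run(layout, parse_spec("2_50_25"), rundir, seed = 13)
tbl <- integrate_run(rundir)
tbl[c(50, 125, 150, 250), ]
```

Region interiors recover their ground truth (orientation 1 / 0, the
injected pLDDT), boundary-straddling coverage mixes the calls toward 0.5,
and KIH participation tracks the packed regions:

```{r summary}
sapply(split(tbl$orientation, cut(tbl$position, c(0, 100, 200, 300))),
       mean)
```

```{r plot, eval = FALSE}
plot_summary(tbl, "scan.png")
```

## Numerical choices and problem sizes

* Orientation tie `d_rev == d_fwd` → parallel; pair-majority tie → 0.5.
* Ambiguous region label of a boundary-straddling window → the label
  covering most of the window, first-listed region on an exact tie.
* Degenerate inputs: monomer orientation and missing PAE are reported
  missing (`NULL`/`NA`), never zero; a monomer's KIH annotation is
  all-false; empty models and non-amino-acid sequences are errors that
  name the offending positions.
* PDB fixed-width precision bounds round-trips at 1e-3 Å (coordinates)
  and 1e-2 (pLDDT); CSV round-trips are exact to 1e-6.
* The test suite exercises windowing on 1,200 random (length, L, O)
  triples against an independent enumerator, orientation recovery on a
  216-model noisy generator sweep (dimers to tetramers, both
  orientations, R0 4.5–7.5 Å, lengths 21–70), KIH register on dimers up
  to 70 residues, and a 300-residue three-region end-to-end run — sizes
  chosen so the whole suite completes in well under a minute while
  covering every decision boundary.

## Limitations

* Orientation is a global per-model call; a fragment that is genuinely
  mixed (e.g. a helical hairpin) gets one label.
* The KIH detector reports participation only — no register assignment,
  no SOCKET packing types, no distinction between true coiled-coil cores
  and incidental side-chain proximity at the cutoff.
* One model per fragment: ranking or ensembling a predictor's multiple
  models is the caller's concern.
* Insertion codes, multi-model PDB files, and heteromeric fragments are
  unsupported; fragments are homo-oligomers by construction.
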