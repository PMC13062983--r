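---
title: "Models and methods in embryoTrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in embryoTrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoTrace)
```

embryoTrace works on lineage-resolved cell-tracking tables of the
*C. elegans* embryo: one row per (cell, timepoint), with a Sulston name,
a 3D nuclear position and optional reporter intensities. This vignette
explains the models behind the package's three quantitative steps —
rigid-body orientation, depth correction and time alignment — the
conventions and tunable parameters, what the synthetic-data generator
does and does not emulate, and the numerical choices that were genuinely
open.

## The data model

An `EmbryoTable` holds the long-format table plus three flags: coordinate
units (`pixel` straight from the tracker, or `micron` after
`applyMetadata`), time units (`ordinal` frame index, elapsed `minutes`,
or a signed `aligned` axis after event alignment) and the names of the
expression columns (conventionally `blot`). Validity enforces unique
(cell, time) pairs, finite positions, and whole positive ordinals.
Missing expression is stored as `NA`, never 0 — zero is a legitimate
measurement.

Sulston names are parsed as the longest founder prefix (P0–P4, AB, EMS,
MS, E, C, D, Z2, Z3) plus a suffix over the division letters a/p, l/r,
d/v; `EMS` is the founder EMS, never E + "ms". Anything else ("polar
body", `Nuc101`) is a literal label: kept in tables and plots, excluded
from lineage algebra (queries answer "unknown" via `NA`/warnings, not
errors). Patterns add a single-letter wildcard `x` (`Cxp` = Cap, Cpp);
`x` deliberately never spans variable depth, which keeps expansions
finite and matches how such selections are written in practice.
`selectCells` operates on *observed* names (matches plus, optionally,
their observed descendants); landmark groups instead use ancestry
membership — a cell belongs to the `Cxp` group if it *or any ancestor*
matches — so a group stays usable after its cells divide.

## Rigid-body orientation

Embryos are imaged in arbitrary poses. At a user-chosen reference time
the fitter:

1. centres the nuclear positions and takes the first principal axis as
   the anterior–posterior (AP) axis — the embryo is a prolate ellipsoid,
   so PCA identifies its long axis. If the two leading eigenvalues agree
   to within 1e-6 (relative) the long axis is ambiguous and fitting
   stops with an error rather than guessing;
2. fixes the axis sign so the anterior landmark centroid projects
   positive (equivalently the posterior centroid negative);
3. rotates that axis onto +x, then resolves the remaining roll from the
   dorsal/ventral/left/right landmark groups. Each group's centroid
   direction in the y–z plane yields one candidate roll angle that would
   put it on its target half-axis; the final roll is the average of the
   candidates.

Conventions chosen here (the field fixes none): anterior = +x,
left = +y, dorsal = +z, a right-handed frame. Downstream figures depend
on this and it is stated on the transform and in the plots. Default
landmarks are posterior `Cxp`, dorsal `Cxaa`, right `MSap`, left `MSpp`;
ventral/right groups enter as dorsal/left candidates rotated by π. The
centring uses **all** cells, not only landmarks, and only the reference
timepoint (no temporal pooling).

**Roll averaging.** With a single roll group the result is exact: that
group lands on its half-axis to machine precision. With several,
mutually inconsistent groups no roll satisfies all of them and the fit
is a compromise. "Average" is implemented as the circular mean refined
by the mean wrapped deviation, which is the exact minimiser of the
summed squared wrapped angular deviation whenever the candidates lie
within π of the result. The refinement matters near 30° spreads, where
the plain circular mean can drift ~0.01 rad off the least-squares
optimum; the refined mean agrees with brute-force grid minimisation to
grid resolution, and reduces to the plain mean for consistent groups.

The resulting `RigidTransform` (`p ↦ R (p − c)`, det R = +1, orthogonal
to 1e-9) can be applied to the reference time only or to all timepoints,
is an exact isometry, and serialises to a small text file. Mirror-image
(chirality) correction is out of scope: the transform is always a proper
rotation.

## Depth correction

Fluorescence from deeper nuclei is attenuated. Following the standard
lineage-expression pipelines, embryoTrace models the decay as
exponential in imaging depth and learns it across replicate embryos:

\[ \log E_{ij} = a_i - k\, z_{ij} + \varepsilon_{ij} \]

fitted by ordinary least squares over all rows with positive expression,
with one slope \(k\) (per micron) shared across embryos and one
intercept \(a_i\) per embryo absorbing brightness differences between
recordings. Pointwise fitting (no z-binning) and a plain quadratic loss
are the simplest choices consistent with that precedent. Rows with
\(E \le 0\) are excluded from fitting (log undefined) but still
corrected at apply time, where the factor
\(\exp(k\,(z - z_\mathrm{ref}))\) is defined for any value. Only \(k\)
and \(z_\mathrm{ref}\) are used at apply time — per-embryo intercepts
cannot exist for unseen embryos — so a model learned on one cohort
transfers to embryos acquired with equivalent imaging. The default
reference depth is 0 µm (top of the stack): for \(k > 0\) correction
only boosts, keeping corrected values comparable to shallow-cell raw
values. Corrected values replace the expression column; the original is
preserved under a `_raw` suffix.

Two caveats are part of the contract: fit **before** rotating to the
canonical frame (z must still mean optical depth), and expect bias if
expression level is itself correlated with depth in every replicate —
the model is meant for ubiquitously expressed or replicate-randomised
signals. Spatially varying attenuation and photobleaching over time are
out of scope.

## Time alignment and trajectories

Embryos are staged by a shared developmental event: the birth (first
appearance) or last observation of a named cell. Each table's time axis
is shifted so the event sits at 0 — times before it become negative, and
ordinal axes become signed numeric, which a cross-embryo comparison plot
needs. Alignment to t = 0 (rather than the cohort mean event time) keeps
offsets interpretable per embryo and makes re-alignment idempotent.
Events are name-based, not geometry-based, because only names and times
are guaranteed in the data model.

`lineageTrajectory` then averages (mean, matching the "averaged across
cells" convention; never the median) the expression of the selected
cells present at each timepoint, per embryo. Timepoints with no selected
cell are omitted — gaps are shown as gaps, never interpolated. Both
per-embryo rows and condition labels are emitted so callers can overlay
per-embryo curves or aggregate per condition; aggregation is left to the
plot layer.

## Rendering

Lineage trees put time downward, one vertical branch per cell spanning
[birth, last seen], branching at divisions, with leaves at uniform x in
canonical sibling order (a<p, d<v, l<r) and parents at daughter
midpoints; branch x position encodes ordering only. Each (cell, time)
observation becomes one coloured sub-segment, with a perceptually
uniform sequential palette (viridis), clamping to a user colour range,
and grey for missing values. Trees are written directly as SVG — plain,
well-formed vector elements — and 3D views are orthographic projections
(equal aspect, units in the axis labels) rendered with ggplot2 and
exported to PNG/SVG/PDF. The interactive-viewer side of the legacy
tools is explicitly not reproduced; figures are the deliverable.

## The simulator: a stated world

`simulateEmbryo` exists so every module can be tested with known ground
truth and no external data. Its defaults are fixture constants, not
biological claims:

* a stereotyped division schedule to roughly the 100-cell stage
  (founder-specific cadences of 3–5 frames over 26 ordinal frames),
  with division letters cycling a/p, l/r, d/v per generation so the
  conventional landmark names (MSap, MSpp, Cap, Cpp, Caaa, Cpaa) exist;
* positions inside a 50 × 30 × 30 µm ellipsoid; daughters displaced
  along the axis implied by their last division letter with shrinking
  magnitude, 1 µm isotropic placement jitter, and explicit nudges
  placing the default landmark lineages on their anatomical half-axes;
* the canonical frame is then *canonicalised*: the simulator runs the
  orientation fitter once on itself, so stored ground-truth positions
  are an exact fixed point of `fitOrientation` and pose-recovery tests
  compare against a well-defined target;
* an acquisition pose (random proper rotation + translation, shifted so
  all coordinates are positive like a real stack);
* expression: lineage rules (default MS at level 500 from frame 8, E at
  800 from frame 9, baseline 20) attenuated by \(e^{-k z}\) with
  k = 0.04 µm⁻¹ in the emitted frame, times lognormal noise with
  σ = 0.1. These are the conditions the depth-correction recovery tests
  state; depth-model checks use a uniform-expression variant because a
  depth model is learned on ubiquitously expressed signals in practice.

What it does **not** emulate: cell movement between divisions, tracking
errors and identity swaps, division-time variability, anisotropic PSF
effects, background fluorescence structure. A green test therefore
establishes algorithmic correctness on idealised tracks, not robustness
to curation errors — the latter is AceTree's domain and out of scope.

## Numerical choices and limitations

* Degenerate-PCA guard at 1e-6 relative eigenvalue gap; rotation
  validity at 1e-9; isometry and inverse round-trips asserted at 1e-9.
* Transform and depth-model files store numbers at 17 significant
  digits, so save → load → save is byte-identical; TIME files likewise.
  CD files store 15 significant digits (≥ 6 contractually, compared at
  1e-6 in round-trip tests).
* CD headers are matched case-insensitively with whitespace stripped —
  files come from several legacy exporters. Re-applying micron
  conversion is an error, never a silent re-scale.
* The StarryNite zip dialect (field order within nuclei records) is not
  standardised in print; the reader documents the supported layout and
  rejects others loudly, and should be confirmed against local archives
  before batch use.
* The depth model assumes a single global decay rate; embryos acquired
  with different optics need their own model.
* With both dorsal/ventral and left/right landmarks provided, neither
  pair ends exactly on its axis (the linked-axes compromise described
  above); the fit minimises the total squared angular deviation.
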