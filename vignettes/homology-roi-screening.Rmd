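---
title: "Homology-based ROI screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based ROI screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bettiscreen)
```

## The screening model

The screen rests on one histological observation: colonic lesions change
the *contact degree* of nuclei. Normal mucosa holds its nuclei apart, in
single-file rings around gland lumina; neoplastic epithelium enlarges and
pseudo-stratifies them until they touch and fuse into fenestrated sheets.
Contact has an exact topological readout. A binary image is read as a
full cubical complex — each foreground pixel contributes a filled unit
square with its four edges and four vertices, shared cells counted once —
and its Betti numbers are

* `b0`: connected foreground components under 8-connectivity (diagonal
  pixels share a complex vertex, so they are one component);
* `b1`: windows, i.e. 4-connected components of the background that do
  not reach the image border.

The complement connectivity is forced by planar duality: with foreground
8-connectivity and background 4-connectivity the Euler identity
`b0 − b1 = V − E + F` holds exactly, and the package uses it (plus an
independent pure-R flood-fill implementation, plus igraph components in
the test suite) to verify the compiled engine:

```{r chi}
ring <- matrix(TRUE, 3, 3); ring[2, 2] <- FALSE
betti_numbers(ring)
cell_counts(ring)
```

Fusing isolated nuclei into a fenestrated sheet converts `b0` into `b1`,
so segments with many windows per unit of tissue mark high-contact
regions — ROI candidates.

## Pipeline and parameters

| parameter | default | meaning |
|---|---|---|
| `blank_level` | 220 | a pixel is bare glass iff `min(R,G,B) ≥ 220` (8-bit intensities). Scanner white points vary, so this is exposed. Lowering it can only shrink the blank set, so the non-blank ratio is monotone in it. |
| grid | 14 × 14 | segments per tile; boundaries at `round(j·width/cols)` so any tile size tiles exactly. |
| `threshold` | 30 | a segment is flagged iff normalized `b1` strictly exceeds it. |
| `min_tissue` | 0.05 | minimum non-blank ratio for a segment to be scored at all. |
| `normalize` | `TRUE` | score is `b1 / nonblank_ratio` rather than raw `b1`. |

Binarization is parameter-free per image: darkness is the Rec.601
luminance complement `d = 255 − round(0.299R + 0.587G + 0.114B)`, and the
threshold maximizes the between-class variance of `d` restricted to
non-blank pixels (Otsu's criterion, computed over the full 0–255
histogram). Foreground is the strictly darker class, which on H&E is the
hematoxylin-stained chromatin. Restricting the histogram to non-blank
pixels matters: glass dominates sparse tiles and would otherwise drag the
threshold into the background mode.

Normalizing by the tissue fraction makes scores comparable between full
and partly blank segments, but diverges as the fraction goes to zero: a
speck of debris with one enclosed window and 3 % tissue scores ~33. That
failure mode is real (detached mucus rings on the glass do exactly this),
so the `min_tissue` guard reports such segments as `insufficient_tissue`
with their raw `b0`/`b1` retained and a reported score of 0. Setting
`min_tissue = 0` disables the guard and reproduces the artifact, which
the tests exercise in both directions.

## Numerical choices

* **Threshold tie-breaks.** The between-class-variance sweep can plateau
  (e.g. a two-level histogram); the smallest maximizing cut is taken, so
  on a two-population image the whole darker population is foreground.
* **Degenerate histograms.** If all non-blank pixels share one darkness,
  every split has zero between-class variance; the threshold falls back
  to the median darkness, and the strict `d > t` rule then yields an
  empty foreground. An all-blank image short-circuits to an empty mask.
* **Flagging comparisons are strict** (`> 30`, not `≥`), matching the
  screening rule's statement; a segment scoring exactly the threshold is
  not flagged.
* **Grid rounding** is half-up (`floor(x + 0.5)`), not banker's, so
  boundaries are platform-stable.
* **Metric rounding** for display is half-up to one decimal (the
  convention the reference tables use); unrounded values are always
  returned alongside.
* **Holes are counted per segment**: a window cut by a segment boundary
  is a window of neither segment. This keeps segment records purely
  local — editing pixels outside a segment can never change its record.

## Open design points, and how they were settled

* The published description of the screen does not state the automatic
  binarization rule. The luminance-complement + Otsu contract above was
  chosen because it is parameter-free per image and lands the foreground
  on the hematoxylin-dark class; no claim of bit-identity with any other
  implementation is made.
* "14 × 14 segments" is read as a 14-by-14 *grid* (196 segments per
  tile), consistent with an overlay dot lattice; both grid dimensions are
  configurable in case fixed-size segments are wanted instead.
* Whether the flagging threshold applies to raw or normalized `b1` is
  ambiguous; normalized was chosen because the normalization exists
  precisely to make segment scores comparable, and `normalize = FALSE`
  restores the raw reading.
* The overlay's exact color ramp is not recoverable from prose; the
  default is a blue → amber → red ramp over `[0, threshold]` with green
  reserved exclusively for flagged segments — the one visual invariant
  stated in words — and the whole scale is configurable.

## What the synthetic tissue emulates

`generate_tile()` draws, at roughly 1 µm/pixel, the morphology the screen
actually measures, with all randomness flowing from one explicit seed
(the caller's RNG state is saved and restored):

* **normal_mucosa** — ~70 glands on a jittered non-overlapping grid;
  each is a near-white lumen (radius 7–12 px) ringed by elliptical nuclei
  (radius 2.5–3.5 px) spaced 1.6 nuclear diameters apart: low contact,
  `b1 ≈ 0` per segment.
* **adenocarcinoma** — a sheet covering ~85 % of the tile of nuclei on a
  jittered hexagonal lattice at 0.965 diameters spacing (`contact_prob
  = 0.9`): neighbours overlap, interstices become windows, interior
  segments score ~40–50.
* **inflammation** — 2–4 aggregates (radius 13–26 px) of small round
  cells (radius 2–2.8 px) touching their neighbours, plus scattered
  infiltrate: a deliberate benign-but-ROI phenotype that flags
  intermittently, reproducing the lymphocyte-concentration false-positive
  mechanism.
* **blank_margin** — bare glass with a thin normal-like tissue strip and
  five detached debris rings (outer radius 4.5 px) whose segments hold
  ~3 % tissue and one window each: guarded, they are reported
  `insufficient_tissue`; unguarded, they flag spuriously.
* **folded_artifact** — normal mucosa plus an elliptical fold where both
  layers' nuclei project into one plane (a crowded sheet) on stroma
  darkened to 0.8×: the fold's segments flag, as folded sections do.

Stain colors default to nucleus (64,32,128), stroma (230,170,190),
background (250,250,250), with per-nucleus color jitter and Gaussian
pixel noise (sd 3) — separable by the default blank level and the
automatic threshold, as real H&E usually is.

What it does **not** emulate: stain variation across scanners, chromatin
texture, nuclear polarity, out-of-focus blur, mucin pools, the full
morphological range of the benign ROI categories, or compression
artifacts. Passing the synthetic discrimination tests therefore shows the
*pipeline* behaves as designed on the morphology it targets — it is not a
clinical validation, and thresholds tuned here should be re-examined on
real slides.

## Problem sizes used by the tests

The homology engine is checked against its oracles on all 512 3×3 masks
and 1000+ random 64×64 masks; pattern generators are verified over 25
seeds per kind; pipeline discrimination uses 20 seeded 560×560 tiles per
phenotype at default parameters; the acceptance script repeats the
discrimination run and verifies the engine on 400 random masks. These
sizes keep a full run in a few minutes on one core while leaving the
statistical conclusions (positive rates, one-sided rank shift) stable
across base seeds.

## Known limitations

* `b1` alone carries the flag decision; `b0` is computed and reported but
  unused by the default rule, so lesions that raise nuclear density
  without closing loops (e.g. discohesive, undifferentiated growth) are
  invisible to the screen — a false-negative mode inherent to the method.
* Scores are grid-aligned: a high-contact focus straddling four segment
  corners dilutes into all four. A sliding or multi-resolution window is
  out of scope.
* The screen is deliberately sensitive rather than specific: benign
  high-contact tissue (inflammation, lymphoid aggregates, regeneration)
  flags by design, which is acceptable for ROI triage but not for
  diagnosis.
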