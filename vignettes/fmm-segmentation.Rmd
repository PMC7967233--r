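---
title: "Region-based fast marching segmentation of lung nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based fast marching segmentation of lung nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmmseg)
```

## The model

Segmentation is framed as front propagation. A front moving with positive
speed $F(x, y)$ has an arrival-time surface $T(x, y)$ that satisfies the
Eikonal equation

$$|\nabla T|\, F = 1,$$

so the front is slow exactly where the speed is small. Choosing
$F = e^{\tau |\nabla I|}$ with $\tau < 0$ (and renormalizing so
$\max F = 1$) makes the front race through homogeneous tissue and stall at
intensity boundaries. The fast marching method solves this equation in a
single pass: a min-heap holds the narrow band of trial pixels, the smallest
trial time is frozen at each step, and frozen neighbors feed the first-order
Godunov update

$$\text{if } |a - b| \ge h/F: \; T = \min(a, b) + h/F, \qquad
  \text{else solve } (T-a)^2 + (T-b)^2 = (h/F)^2,$$

where $a$ and $b$ are the smaller known arrival times on the horizontal and
vertical axes. We run the solver **multi-label**: every seed starts its own
front with $T = 0$, a pixel freezes with the label of the first front to
reach it, and the crop is partitioned into one region per seed — the
"stained glass" partition. The marching loop is compiled (Rcpp) with lazy
heap deletion and raster-order tie-breaking, so the partition is fully
deterministic; the seed insertion order is irrelevant except at exact time
ties.

Regions are far smaller than anatomical structures, so the mask is assembled
in a second stage. Region seeds are grouped by k-means on their (row, col)
coordinates alone — seeds pack densely in uniform areas, so spatial
proximity is the right grouping signal, and intensity is deliberately *not*
a clustering feature because it is the merging criterion. The initial
centroids come from the same gradient-filtered lattice as the seed grid
(pitch = `cluster_density`) instead of random starts, which makes the
clustering repeatable. The start cluster maximizes
$\bar{I}_c / (d_c + 1)$, mean intensity over centroid distance to the image
center (+1 px guards the centroid-at-center singularity); this picks bright
ring tissue rather than the dark cavity in cavitary nodules. Merging is a
breadth-first growth over the cluster adjacency graph: a neighbor $j$
discovered from accepted cluster $i$ is accepted iff
$|\bar{I}_i - \bar{I}_j| < t$. The criterion is *pairwise*, not a running
blob mean, so a gentle intensity gradient can be traversed step by step; the
trade-off is documented transitivity (a chain 0.8–0.7–0.6 merges fully at
$t = 0.15$ although the ends differ by 0.2).

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `sigma` | 1 | px | Gaussian scale before the gradient |
| `tau` | -2 | — | speed exponent, $F = e^{\tau G}$ |
| `alpha`, `beta` | 1, 2 | — | seed keep/shift/delete thresholds |
| `seed_distance` | 3 | px | seed lattice pitch (densest non-overlapping 3×3 areas) |
| `cluster_density` | 7 | px | centroid lattice pitch; lower = finer clusters |
| `mean_threshold` | 0.15 | intensity | pairwise merge criterion |
| diffusion `kappa`, `iters`, `dt` | 0.05, 10, 0.15 | — | Perona–Malik denoising |

The first five are fixed values of the method; the last two are the tunable
ones. The diffusion settings are our own choice (no canonical values exist):
`kappa = 0.05` in normalized-intensity units treats gradients above ~5% of
the dynamic range as edges, and 10 explicit steps at `dt = 0.15` (stable for
the 4-neighbor scheme, which requires `dt` ≤ 0.25) remove phantom-level
noise without measurably moving step edges (verified in the test suite).

Seed-rule details the equations leave open, fixed here for determinism: the
local gradient mean uses the in-domain 3×3 patch including the pixel itself;
the three rules partition the line as `local > beta*total` (delete),
`alpha*total <= local <= beta*total` (shift), `local < alpha*total` (keep) —
at the default `alpha = 1` this coincides with either printed reading of the
keep rule; a shifted seed moves to the 3×3 candidate (diagonals included)
with the smallest local mean, the seed itself winning ties, remaining ties
resolved in raster order. On a constant image the shift band degenerates to
$0 \le 0 \le 0$ and every seed wins its own tie, so the full lattice
survives — the correct limiting behavior.

## Preprocessing

CT slices are resampled to 0.5 mm/px in-plane (cubic splines), lungs are
segmented by thresholding at −320 HU, keeping the two largest interior
air components, closing with a 5 px disc and taking a per-lung convex hull
(so wall-attached nodules stay inside the lung field), intensities are
windowed linearly from −1000 to +400 HU into [0, 1], and a square crop of
side 2× the annotated diameter is taken around the centroid (round-half-up,
zero-padded at slice edges, recorded in the crop provenance). Before the
gradient is computed the crop is *pleura-padded*: every pixel outside the
lung mask takes the value of its nearest inside pixel (grassfire fill), so
the artificial step at the mask boundary contributes no gradient and
juxtapleural nodules are not fenced in by a spurious speed barrier.
Coordinates are 1-based (row, col) with pixel centers at integer positions,
the native R convention.

## The phantom generator

`make_phantom_case()` renders nodule crops with known ground truth from an
analytic boundary $r(\theta) = r_0 (1 + \sum_k a_k \sin(k\theta + \phi_k))$,
$k = 3..8$, $|a_k| \le 0.15$ (zero amplitudes for solid-round). Intensity
levels mirror the −1000..+400 HU window: aerated lung 0.15, soft-tissue
nodule 0.65, chest wall 0.9. The rim is blurred (σ = 0.8 px) to imitate
partial-volume smudging. Category alterations: sub-solid drops the contrast
to 0.15 with smooth multiplicative texture; cavitary inserts a concentric
background-level cavity (ground truth = ring only; default ring thickness
35% of the diameter); juxtapleural adds a wall slab tangent to the nodule,
excluded from the lung mask; juxtavascular adds a 2–4 px soft-tissue vessel
tangent to the nodule, excluded from the ground truth. Noise is additive
Gaussian with $\sigma = 0.05\sqrt{197/\text{mA}}$ — quantum-noise scaling
anchored at the cleanest study current (197 mA), spanning ≈ 0.05–0.13 over
30–197 mA. Everything is seeded: the same configuration always renders the
same case.

What the generator does *not* emulate: reconstruction-kernel noise texture
(real CT noise is correlated; ours is white), streak artifacts, vessels that
curve or branch, pleural curvature, and neighboring structures of
intermediate density. Passing tests on these phantoms therefore demonstrate
the machinery is correct under controlled conditions, not clinical-grade
accuracy on patient data.

```{r example}
cs <- make_phantom_case(synth_config("solid-round", "isolated",
                                     diameter_mm = 10, tube_current_mA = 197,
                                     seed = 7))
sg <- segment(cs$image)
sg
dice(sg$mask, cs$ground_truth)
```

## Numerical choices and degenerate inputs

* Exact heap ties pop in raster order, and a trial pixel inherits the label
  of its lowest-time known axis neighbor (ties: lower row, then column);
  this makes masks byte-identical across runs and platforms.
* Speed is normalized by max-division (not affine rescale): homogeneous
  regions then sit at speed ≈ 1 and boundaries near 0, as the model intends.
  `total_grad_mean` is computed over lung-mask pixels when a mask is
  present.
* In-domain pixels isolated by the lung mask are unreachable by any front;
  they keep a sentinel label (with a warning) rather than being invented.
* Empty lung masks, zero surviving seeds, non-positive speeds, cavity rings
  of non-positive thickness and empty masks passed to the diameter code all
  raise immediate, specific errors.
* The short axis is the longest chord perpendicular to the long axis,
  discretized as the maximum perpendicular extent over pixel pairs within
  half a pixel of each other along the long axis; a one-pixel-wide line has
  short axis 0. Border distances are center-to-center with no +1 px pixel
  extent, which shifts diameters by about half a pixel relative to
  conventions that include it. Diameters are reported to the nearest whole
  millimeter (the manual measurement convention) and errors are computed on
  the rounded values; unrounded values are kept internally. Diameters are
  measured on the largest connected component, matching manual practice.
* Dice of two empty masks is defined as 1. Cavitary Dice is computed on the
  masks as-is — the cavity is excluded from both ground truth and (when the
  method finds it) the prediction, so a missed cavity costs overlap.

## Known behavior and limitations

The first-order scheme overshoots at a source's immediate diagonal
($T = 1 + 1/\sqrt{2}$ at unit speed versus the true $\sqrt{2}$); this
deviation decays with distance but the maximum absolute error of a
point-source field grows slowly with grid size (≈ 0.82 grid steps on a
21×21 grid, ≈ 1.17 on 64×64 — values that SimpleITK's
`FastMarchingImageFilter` reproduces to machine precision on the same
inputs). Accuracy comparisons against graph shortest paths are therefore
made outside the two pixel rings nearest each seed, where the asymptotic
regime holds; the near-seed stencil is pinned exactly by closed-form tests.

Sub-solid phantoms are generated at contrast 0.15 — exactly the default
merge threshold — so cluster mean differences across the boundary fall just
below the criterion and the method over-segments; this is the documented
failure mode of mean-intensity merging on ground-glass lesions and we leave
it visible rather than tuning the generator around it. Cavitary nodules
with thin rings under-segment when ring clusters average toward background.
The pipeline is 2D and single-slice; there is no nodule detection, no
parameter optimization, and marching is spacing-agnostic (crops are
isotropic by construction).

Test and benchmark problem sizes were chosen to keep the whole suite fast:
oracle comparisons run on 32×32 grids (where Dijkstra on the 8-connected
graph is exact and cheap), convergence checks on 64–128 px grids, and the
benchmark sweep uses the full 108-case reference layout at 5–20 mm
(20–80 px crops), which completes in seconds thanks to the compiled core.
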