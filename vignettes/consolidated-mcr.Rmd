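---
title: "Consolidated MCR analysis of multi-sample ToF-SIMS images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consolidated MCR analysis of multi-sample ToF-SIMS images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcrsims)
```

## The problem

Time-of-flight secondary ion mass spectrometry (ToF-SIMS) produces a
full mass spectrum at every pixel of a rastered surface. After peak
integration against a curated peak list, each acquisition is a
hyperspectral cube: `height x width` pixels by several hundred m/z
channels. High-throughput surface screens — polymer microarrays in
particular — generate many such cubes per slide, and the chemistries of
interest (a shared substrate coating, monomer-specific fragments,
contamination overlayers) recur *across* samples. Analysing cubes one
at a time forfeits that shared structure; `mcrsims` instead row-stacks
the unfolded cubes into a single matrix and resolves all samples
jointly.

## The model

Multivariate curve resolution (MCR) assumes the bilinear mixture model

$$ D = C\,S + E, \qquad C \ge 0,\; S \ge 0, $$

where $D$ is the consolidated pixels-by-channels matrix, each row of
$S$ ($k \times \text{channels}$) is a pure-component spectrum, each
column of $C$ ($\text{pixels} \times k$) is that component's
concentration image across all samples, and $E$ is the residual. Both
factors are non-negative because ion counts and concentrations are.
Fit quality is summarised by the lack of fit,
$100\,\lVert E\rVert_F / \lVert D\rVert_F$ (percent).

The factors are estimated by alternating least squares (ALS): fixing
$S$, every pixel row of $C$ is an independent non-negative
least-squares (NNLS) problem; fixing $C$, every channel column of $S$
is one. Each subproblem is solved *exactly* under the constraint with
an active-set method (block principal pivoting over the small Gram
matrix, batched across pixels; a Lawson–Hanson solver backstops rows
that fail to settle). Solving exactly — rather than clipping an
unconstrained solution — is what makes the lack of fit provably
non-increasing across iterations, a property the test suite asserts
with tolerance $10^{-10}$ on every fit.

Two identifiability conventions resolve the bilinear ambiguities:
loading rows are rescaled to unit Euclidean norm after every loadings
update (the scale moving into the scores), and solutions are compared
only up to component permutation (`match_components()`).

## Choosing the number of components

A PCA scree of $D$ bounds the component count before any MCR run. In
keeping with the no-pre-treatment policy the decomposition is of the
*uncentred* cross-product by default (`centred = TRUE` is an explicit
flag), computed on the channels-by-channels Gram matrix since channels
are few relative to pixels. Scree curves of SIMS image data rarely have
a sharp elbow, so the output is a range, not a point: the elbow index
is the smallest $i$ with $\lambda_i/\lambda_{i+1} < 1.5$ (eigenvalues
below $10^{-10}\lambda_1$ count as a numerical-zero plateau), and the
advisory range is $(\text{elbow}-2,\ \text{elbow}+3)$, clipped to the
valid interval. The factor 1.5 and the $-2/+3$ bracket are package
choices; the suggestion is never applied automatically.

The definitive choice comes from `scan_components()`: the full
consensus pipeline is run for each candidate $k$ and each solution is
examined for over-fitting — several components describing the same
spatially located feature with the same associated ions. A pair is
flagged when the cosine between its score columns **and** the cosine
between its loading rows both reach 0.9 (both thresholds are
arguments). The recommended $k$ is the largest candidate with zero
flagged pairs, per-cluster stability at least 0.9 and per-cluster
repeat coverage at least 80% — reported alongside the full scan table
so a human can overrule it.

## The consensus protocol

Converged ALS solutions depend on their random starting point. The
pipeline therefore:

1. runs `n_repeats = 10` fits from independent random initialisations
   (strictly positive uniform entries; repeat $i$'s seed is derived
   deterministically from the master seed, so repeats may execute
   concurrently and still reproduce the sequential results bit for
   bit);
2. pools the $10 \times k$ unit-norm loading vectors and k-means
   clusters them into $k$ groups (Euclidean distance on unit vectors,
   monotonically related to cosine; 10 restarts, seeded). Degenerate
   repeats are excluded; merely unconverged ones still contribute;
3. re-normalises the cluster means and uses them as the initial
   loadings of one final ALS round with fresh random scores. Because
   the first scores update solves the scores from those loadings, the
   consensus information seeds the final solution; the final model is
   the headline result.

Per-cluster dispersion (mean cosine of members to their centroid) and
repeat coverage (how many distinct repeats populate each cluster) are
reported as stability diagnostics. No constraint forces one loading per
repeat per cluster; coverage makes violations visible instead.

## Defaults and tunables

| Parameter | Default | Meaning |
|---|---|---|
| `tol` | `1e-6` | relative lack-of-fit change declaring convergence |
| `max_iter` | 500 | ALS iteration cap per fit |
| `n_repeats` | 10 | random starts per component count |
| `score_thresh`, `loading_thresh` | 0.9 | over-fit flag thresholds (cosine) |
| `stability_thresh` | 0.9 | minimum per-cluster mean cosine in scans |
| `coverage_thresh` | 0.8 | minimum per-cluster repeat-coverage fraction |

A fit also stops when the lack of fit falls below $10^{-8}$ percent —
on noiseless data the residual keeps shrinking proportionally and the
relative test alone would never fire.

Degenerate components (a loading row or score column collapsing to
zero mid-iteration) are re-initialised once from the dominant
non-negative direction of the residual; a second collapse returns the
model flagged `degenerate` with `converged = FALSE`.

## The synthetic scene

No public instrument data accompany this workflow, so validation rests
on a phantom generator with exact ground truth. The default scene
mirrors a microarray screen at test scale: 8 samples of 64 × 64 pixels
over 500 × 500 µm fields, 30 channels, and five components — one
substrate background present everywhere, three spot chemistries printed
on the sample subsets {1, 2, 4, 8}, {3, 7} and {5, 6}, and one
contamination overlayer on sample 4. `preset = "full_scale"` switches
to 256 × 256 pixels and 461 channels, the shape of a full
positive-ion acquisition.

Choices worth knowing about:

* **Spots are raised-cosine discs**, not hard circles, with a mild
  within-spot intensity gradient: printed spots are not uniform, and
  smooth edges exercise the factorisation more realistically than
  binary masks.
* **Pure spectra are sparse** (six dominant channels each, two of them
  reserved per component). Real fragment spectra over a curated peak
  list are sparse, and every surface chemistry in practice shows some
  uniquely characteristic ions; the reserved channels give the scene
  that property, which is also what makes exact recovery of the pure
  spectra well-posed.
* **Occlusion is complete at the core.** Static SIMS samples only the
  outermost nanometres, so the substrate contributes nothing under the
  spot core and the contamination overlayer fully masks the spot
  beneath its own core, adding its spectrum while multiplicatively
  attenuating the spot's concentration map. Amplitudes default to
  100–150 mean counts, so Poisson noise at realistic count rates is
  available via `noise = "poisson"` (additive truncated Gaussian noise
  is also provided).
* Noiseless cubes equal the bilinear product of the true factors
  exactly, so the unfolded matrix has numerical rank equal to the
  number of components — the property the scree and recovery tests
  lean on.

What the phantom does **not** emulate: fragmentation physics and
matrix effects, m/z-dependent detector response, topography and
charging artefacts, or inter-sample dose drift. Passing tests
demonstrate that the algorithmic chain recovers known bilinear
structure under counting noise; they do not certify performance on
data violating the bilinear model.

## Numerical behaviour and known limitations

* **Saddle plateaus.** A minority of random starts (roughly a third on
  the Poisson-noise reference scene) settle on an ALS plateau whose
  lack of fit is well above the attainable optimum, with sustained
  relative change near $10^{-9}$ for thousands of iterations before
  eventual escape. No practical tolerance distinguishes such a plateau
  from convergence, and iterating through it costs more than it
  returns. This is precisely the failure mode the consensus protocol
  absorbs — majority cluster structure carries the correct spectra and
  the final round recovers them — but it can depress the per-cluster
  repeat coverage below the nominal 10.
* **Non-uniqueness.** When the scene lacks pure pixels or
  characteristic channels, non-negativity constrains but does not pin
  the factors; recovered spectra can then differ from ground truth by
  a rotation within the feasible cone even at a near-zero lack of fit.
* **Memory.** The consolidated matrix is dense; eight full-scale cubes
  with 461 channels occupy about 1.9 GB as doubles. The factorisation
  itself never forms a pixels-by-pixels object.

## Problem sizes used in the checks

Routine tests run on 2–4-sample scenes of 8–16 pixels square; the
integration checks use the full 8-sample, 64 × 64, 30-channel scene
(32 768 pixels), with the 10-repeat consensus at $k = 5$ and a
component scan over $k = 3\ldots8$. These sizes keep the whole suite
in the minutes range while preserving every structural feature of the
full-scale analysis; the 256 × 256 × 461 preset is exercised only for
shape bookkeeping.

## A worked example

```{r example, eval = FALSE}
library(mcrsims)

truth <- generate_phantom(phantom_spec(seed = 42))
cm <- consolidate(truth$cubes, truth$peaklist)

pca_scree(cm)$suggested_range

res <- run_consensus(cm, k = 5, n_repeats = 10, master_seed = 42)
res$final_model

rec <- match_components(res$final_model$loadings, truth$true_loadings)
rec$cosines

render_report(res, cm, out_dir = "mcr_out")
```
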