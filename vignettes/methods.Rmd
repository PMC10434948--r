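---
title: "Methods: MDS-based DNA-loop calling from Hi-C contact maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MDS-based DNA-loop calling from Hi-C contact maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

loopMDS treats loop calling as a geometry-reconstruction problem. A cis
Hi-C contact map for one chromosome segment is converted into a distance
matrix, embedded into the plane by classical (Torgerson) multidimensional
scaling, and DNA loops are read off as stretches where consecutive genomic
bins take unusually large steps through that plane. The underlying
assumption is that looped chromatin forms spatial excursions: bins inside a
loop travel farther per 10 kb step in the reconstructed structure than bins
in the compact backbone.

The chain of operators, for bins `i, j` and contact frequencies `d_ij`:

* **Missing-as-zero.** Pairs absent from the sparse input are zero
  contacts. This is deliberate: replacing missing values by averages (as in
  smoothing-based reconstructions) erases exactly the contrast between
  looped and unlooped DNA that the method keys on.
* **Vanilla coverage (VC).** `c_ij / (s_i s_j)` with `s_k` the symmetric
  row sum, globally rescaled to preserve the total matrix sum. VC is the
  common first-moment coverage correction for Hi-C; the rescale keeps the
  weighted values on the scale of the raw counts so the `+1` in the
  distance transform below stays meaningful.
* **Distance-decay weighting.** `d'_ij = d_ij ln|i-j|` beyond a cutoff
  band, identity inside it. Contacts between loci far apart on the chain
  are systematically underestimated relative to short-range contacts; the
  logarithmic ramp re-amplifies them so that loop-scale structure survives
  the embedding. The band default is 50 kbp expressed in bins
  (`ceiling(50000/resolution)`, so 5 bins at 10 kb and 1 bin at 50 kb):
  short-range contacts carry a large assay-driven excess and are left
  untouched. A linear variant `d_ij · a · |i-j|` is implemented for
  comparison but does not produce loop-consistent structures; the
  logarithmic form is the default.
* **Distance transform.** `D_ij = 1/(d'_ij + 1)`, `D_ii = 0`. Strong
  contacts mean proximity, so the reciprocal serves as a distance; the `+1`
  maps missing contacts to the maximal distance 1 and bounds `D` in
  `(0, 1]` off-diagonal. The decay exponent linking contact frequency and
  distance is taken as 1, as in fractal-globule contact scaling.
* **Classical MDS.** `K = -1/2 J D^(2) J`, `J = I - (1/N)11'`;
  eigendecomposition `K = V A V'` with eigenvalues sorted algebraically
  descending. The coordinates are the **raw unit eigenvectors** of ranks 2
  and 3.
* **Step profile and calling.** `E_i` is the Euclidean step between
  consecutive embedded bins; `E'` is a forward running mean (window 10
  steps, boundary minimum 5); the threshold is `T = 2 · mean(E')`; cores
  above `T` are extended outward to the first local minima, which become
  the loop roots.

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| `resolution` | 10000 | bp/bin | bin width of the input map |
| `cutoff_bins` | `ceiling(50000/resolution)` | bins | unweighted short-range band |
| `weight_mode` | `"log"` | — | `ln|i-j|` ramp vs `a·|i-j|` |
| `components` | `c(2, 3)` | ranks | eigenvectors used as coordinates |
| `window_bins` | 5000 | bins | independent MDS segment length (50 Mb at 10 kb) |
| `smooth_window` / `min_window` | 10 / 5 | steps | running-mean window and its boundary floor |
| `threshold_factor` | 2 | — | multiple of the mean smoothed step |
| `top_n` | 300 | peaks | peaks ranked by score for enrichment |
| `genome_bp` | 3,186,000,000 | bp | human genome length for the expected overlap |

Why ranks 2–3 rather than 1–2 is an empirical matter: for these bounded,
strongly non-Euclidean distance matrices the leading eigenvector largely
tracks overall contact richness, and the second and third retain the
spatial organization. The ranks are exposed as configuration
(`components`), not hard-coded, and `scale_eigen = TRUE` switches to the
textbook `sqrt(lambda)`-scaled Torgerson coordinates — on an exactly
Euclidean distance matrix those reproduce the generating configuration up
to rigid motion, which is how the MDS core is validated (against
`stats::cmdscale` and a Procrustes alignment) independently of the rank
convention.

# Numerical choices

* **Boundary smoothing rule.** The running mean is forward over 10 steps
  wherever 10 remain. In the right-boundary tail the window truncates to
  the available points down to a floor of 5, and the final positions
  extend backward so at least 5 points are always averaged. This keeps the
  profile length equal to `length(E)` and is deterministic and
  order-preserving; the published index ranges for the boundary correction
  are internally inconsistent as printed, so this fully specified variant
  of their evident intent (10-point means, 5–9-point means at the edges) is
  adopted.
* **Strict decrease during root extension.** The outward walk stops as soon
  as the next value fails to decrease strictly; a plateau therefore stops
  the walk and its near edge becomes the root.
* **Adjacent cores.** Extension between two cores is capped at the gap
  midpoint so regions cannot overlap; when the shared midpoint roots both
  walks the two regions merge into one. Root bins are included in the
  reported region, since the roots are the biologically interesting
  anchors (enhancer/promoter candidates).
* **Threshold base.** The mean defining `T` is taken over the smoothed
  profile (configurable to the raw profile via `threshold_on`), keeping the
  threshold and the thresholded quantity on the same scale.
* **Spectrum handling.** `D` is far from Euclidean, so `K` has negative
  eigenvalues; they are kept in the reported spectrum for diagnostics but
  ranks (2, 3) under algebraic descending order never select them in
  practice.
* **Exact test.** The two-sided Fisher p-value is computed by log-space
  enumeration of the hypergeometric support (probabilities not exceeding
  the observed table's, with the usual `1e-7` relative tolerance). When the
  smallest margin exceeds `1e4` the chi-square test with continuity
  correction is substituted and flagged, since genome-scale bp tables are
  beyond enumeration but deep in the asymptotic regime. Expected cells are
  kept real-valued for the odds ratio and rounded half-up only for the
  test.
* **Segmenting.** Chromosomes are processed in independent windows of
  `window_bins` bins (dense eigendecomposition, so segments stay at
  desk scale); a final stub shorter than half a window is folded into the
  preceding segment. Loop calls are concatenated across segments.

# The synthetic generator

`synthetic_spec()` / `simulate_hic()` generate ground-truth-annotated maps:
a planar Gaussian random walk (step sd `step_sd`, arbitrary units — the
contact model is scale-free in it) in which each planted loop replaces the
sub-walk between its two anchors by a Brownian bridge conditioned so the
anchors coincide to within `step_sd/2`. Contacts are drawn as
`Poisson(lambda_ij)` with `lambda_ij ∝ 1/(eps + |x_i - x_j|)^alpha`,
`eps = step_sd/10`, `alpha = 1`, intensities for `|i-j| <= 1` multiplied by
a short-range excess factor (default 10, emulating the self-ligation and
adjacent-bin inflation of raw maps), the field normalized to a total
sequencing depth, and a dropout fraction of nonzero entries deleted
uniformly (emulating missingness). All randomness flows from the single
spec seed. Defaults: 500 bins, two planted loops spanning bins 100–150 and
300–380, depth `1e5`, dropout 0.3.

**What this emulates and what it does not.** The generator reproduces the
sparsity, decay, counting noise and missingness of a shallow 10 kb map,
and plants loops with the defining contact signature — coincident anchors
and an enhanced intra-loop contact block. It does **not** reproduce two
features of real looped chromatin: loop interiors are not spatially
extended relative to the backbone (a Brownian bridge at the backbone's
step variance is, if anything, more compact, since the bridge variance
`t(L-t)/L` is below the free-walk variance `t`), and there is no
compartment or TAD texture. The first point matters for interpreting the
end-to-end tests: the step-distance statistic calls regions that spread
out in the embedding, and on this generator planted loops embed as
*compact* blobs — across seeds and generator settings the smoothed step
distance inside planted loops sits at or below background. End-to-end
planted-loop recovery is therefore weak (the recovery suite reports
Jaccard overlaps near zero at the default depth), and this is documented
here as a known limitation of the emulation rather than hidden by tuning
the generator until it flatters the caller. Passing unit, oracle and
invariance tests validate every operator in the chain; the recovery suite
measures, honestly, how far this synthetic world is from the data regime
the method was designed for.

# Test problem sizes

The suite validates the MDS core on 20 random planar configurations of
50–500 points; the exact test exhaustively against enumeration on all
101,476 distinct 2×2 tables with total count ≤ 44 plus randomized tables
with margins ≤ 60; loop recovery on ten 500-bin maps with 2–4 planted
loops at depth `1e5` and dropout 0.3; and invariance of loop calls under
sign flips, rotations and rescalings of the embedding (exact equality of
called regions). These sizes keep the whole suite at desk scale while
exercising every code path.

# Known limitations

* The eigendecomposition is dense, `O(n^3)` per segment; segments beyond
  ~6000 bins should be windowed (the default does this).
* Calling operates per segment; loops straddling a segment boundary are
  split.
* The 10-step smoothing window is calibrated to 10 kb resolution (100 kbp);
  at other resolutions it is kept in bins, not rescaled, and should be
  revisited by the user.
* Only cis maps are analyzed; trans contacts are out of scope.
* Native `.hic`/cooler parsing is not implemented; any tool that dumps
  sparse triplets (e.g. straw) interoperates through `read_contacts()`,
  which accepts both bp-position and bin-index triplets.
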