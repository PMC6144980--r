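---
title: "Colour vision models in a unified n-dimensional chromaticity space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colour vision models in a unified n-dimensional chromaticity space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaspace)
```

## The model family

Chromatic (hue and saturation) vision in animals is generally explained by
opponency: the outputs of the $i$ photoreceptor classes are compared
against each other, so only *differences* between receptor outputs carry
chromatic information. The widely used colour vision models — the colour
hexagon, the Endler–Mielke colour space, and the linear and log-linear
receptor-noise-limited (RNL) models — share one skeleton, and chromaspace
implements that skeleton once:

1. **Quantum catch.** For receptor $i$ with spectral sensitivity
   $S_i(\lambda)$, stimulus reflectance $R(\lambda)$ and illuminant
   $I(\lambda)$,
   $$Q_i = \int R(\lambda)\, I(\lambda)\, S_i(\lambda)\, d\lambda .$$
2. **von Kries adaptation.** Catches are normalised by the catch of the
   adapting background, $q_i = Q_i / Q_{B,i}$, emulating receptor
   adaptation to the light environment; the background itself maps to
   $q = 1$ in every channel.
3. **Receptor transform.** $E_i = f(q_i)$ with $f$ the identity (linear
   RNL), $\ln$ (the Fechner–Weber law; Endler–Mielke and log RNL),
   the saturating hyperbolic $q/(q+1)$ (colour hexagon), or any
   user-supplied function for generic models.
4. **Opponent projection.** Outputs are projected through a matrix $V$
   of $i$ equidistant vectors spanning an $n = i-1$ dimensional
   chromaticity diagram, $x = V p$; the chromatic distance between two
   stimuli is the Euclidean distance between their loci
   ($\Delta S$), with the background at the origin.

Because the columns of $V$ sum to zero, adding a constant to all outputs
does not move a locus: the models are sensitive only to differences
between receptor outputs, which is the opponency assumption made
explicit. All receptor classes are weighted equally and opposed against
each other, which matches the observation that exact opponent wiring
rarely needs to be known for useful predictions.

## Building the equidistant basis

For any $i \ge 2$ the package constructs $i$ unit vectors in
$\mathbb{R}^{i-1}$ with pairwise angle $\theta = \arccos(-1/n)$ —
the vertices of a regular simplex. The construction is recursive: the
dichromat solution is $(+1, -1)$; each larger set embeds the previous
one scaled by $\sin\theta$ with an added shared coordinate
$\cos\theta$, plus a final "pole" vector. The seed of this recursion is
the all-negative generic unit vector whose last component is
$\cos\theta$ and whose remaining components follow
$v_{n-k} = -\tfrac{1}{n-k}\sqrt{1 - \sum_{m>n-k} v_m^2}$
(`generic_unit_vector()`). Three invariants are verified at construction
time to $10^{-10}$: equal column lengths, pairwise dot products
$-L^2/n$, and zero column sum. The orientation is one fixed choice
among infinitely many; any rotation of $V$ yields identical distances,
so published diagrams may differ from ours by a rotation only.

Two scalings are exposed, because extending a model to a different
receptor count forces a choice:

* **fixed vector length** — the named models' convention (length 1 for
  the hexagon, 0.75 for the sum-to-one space);
* **fixed vertex distance** — hold the edge between diagram vertices
  constant across dimensionalities, at the cost of a changing
  centre-to-vertex length: with the edge held at $\sqrt{2}$ the
  centre-to-vertex distance is $\sqrt{(i-1)/i}$, i.e. $0.816$ for a
  trichromat and $0.866$ for a tetrachromat.

On that last point the literature sometimes phrases the same trade-off
as "an edge length of 2" while printing exactly the $0.816/0.866$ pair;
those printed values correspond to edge $\sqrt{2}$ (squared edge 2).
chromaspace leaves the edge length a free parameter and documents the
$\sqrt{2}$ reading rather than silently resolving the discrepancy.

## The named models

* **Colour hexagon (CH):** hyperbolic transform, unit vectors. Since
  $0 \le q/(q+1) < 1$, every locus lies strictly inside the unit
  circumradius.
* **Endler–Mielke (EM):** $\ln$ transform and *relative* outputs
  $e_i = E_i / \sum_j E_j$ (sum-to-one), vectors scaled to 0.75. The
  farthest a stimulus can legitimately sit from the background is a
  simplex corner, at distance exactly 0.75. The tetrachromatic original
  fixes 0.75; chromaspace applies the same constant at other receptor
  counts, which affects only a global scale.
* **Linear / log RNL:** identity or $\ln$ transform, per-receptor Weber
  noise $e_i$. Distances are measured in noise units (just-noticeable
  differences) and are independent of the diagram geometry.

### Receptor-noise distances and the noise-space transform

For 2–4 receptors the classical closed forms weight output differences
$\Delta f_i$ by the Weber fractions (e.g. for a dichromat
$\Delta S = |\Delta f_1 - \Delta f_2| / \sqrt{e_1^2 + e_2^2}$).
chromaspace additionally provides the general route valid for any $i$:
with $R = \mathrm{diag}(e_i^2)$ the covariance of receptor outputs and
$V$ the unit basis,
$$ s = \left[(V R V^T)^{1/2}\right]^{-1} x $$
rescales loci so that *Euclidean distance in $s$-space equals
$\Delta S$ itself* (the square root is what turns squared distances
into distances; it is computed as the symmetric positive-definite
square root via eigendecomposition). Equivalence with the closed forms
on randomized inputs, to $10^{-9}$, is the module's core test, and the
same route extends the RNL models to pentachromats and beyond.

When Weber fractions have not been measured they may be derived from
relative receptor abundances as $e_i = \nu/\sqrt{\eta_i}$
(`noise_from_abundance()`); this is an optional convenience following
the receptor-noise literature, off unless called explicitly.

## Spurious regimes are data, not bugs

Two failure modes of these models matter in practice, and the package
deliberately reproduces rather than sanitises them, flagging affected
rows in the result table (`near_singular`, `negative_output`):

* When the stimulus catch falls below the background catch
  ($q_i < 1$), $\ln q_i$ is negative. In sum-to-one models the
  denominator $\sum_j E_j$ can then approach zero and relative outputs
  blow up far beyond the simplex: distances exceed the model's own
  defined maximum by orders of magnitude. A row is flagged
  near-singular when $|\sum E| < 0.1 \sum |E|$ — a scale-relative
  criterion, because the outputs themselves can be arbitrarily large
  near the cancellation; the threshold 0.1 flags exactly the regime
  where relative outputs leave the simplex by a large margin, and a sum
  of exactly zero is an error.
* Against a chromatic (e.g. leaf-like) background, achromatic stimuli
  do not sit at the diagram centre. The log-RNL distance is then the
  same at every reflectance level (ln differences are level-free),
  while the linear-RNL distance grows linearly with level and the
  bounded models *decrease* with level — qualitatively different
  predictions for the same physical series.

Both behaviours are exercised by the packaged simulation harnesses.

## Simulation harnesses and their defaults

`midpoint_sweep()` runs a model over sigmoid reflectance stimuli with
midpoints 300–700 nm in 5-nm steps (81 stimuli), lower/upper asymptotes
0.10/0.60, slope 0.05 nm⁻¹ (a transition roughly 100 nm wide), against
a 7% flat background under CIE D65. The slope is not uniquely fixed by
the transition widths reported for such stimuli; 0.05 is the package
default and is configurable. `shift = -10` subtracts ten percentage
points from every stimulus, pushing catches below the background and
triggering the spurious regime above.

`achromatic_sweep()` runs flat stimuli from 5% to 95% reflectance in
10-point steps against an arbitrary background;
`synthetic_leaf_background()` provides a smooth vegetation-like
chromatic background (low UV, green bump at 550 nm, beginning of the
far-red rise). It is synthetic: any measured background spectrum can be
supplied instead.

`screen_receptor_sets()` enumerates every combination of candidate
$\lambda_{max}$ values (default 330–630 nm in 30-nm steps, sizes 2–5,
i.e. $\sum_k \binom{11}{k} = 1012$ combinations), builds unit-peak
Gaussian sensitivities (width 40 nm), and selects the combination with
the maximum mean $\Delta S$ over the stimulus set; ties are broken
lexicographically by peak wavelength so rankings are deterministic.
`compare_models()` reports Spearman rank correlations (average ranks
for ties, two-sided p-values) between models' $\Delta S$ columns, since
model outputs live on different non-linearly related scales.

### What the synthetic generators do and do not emulate

The packaged receptor set (`synthetic_bee_receptors()`) places Gaussian
curves at the honeybee $\lambda_{max}$ values 344/436/556 nm with the
measured honeybee Weber fractions 0.13/0.06/0.12, and
`synthetic_flower_spectra()` mixes random sigmoid edges and Gaussian
bumps to mimic petal reflectance. These reproduce the *structure* of
real inputs — trichromatic UV/blue/green spacing, step- and bump-shaped
stimuli — but not measured curve shapes (no β-band, no measurement
noise, no correlated spectral detail). Tests built on them therefore
validate model mechanics and qualitative behaviour classes (bell-shaped
distance profiles, spurious EM maxima in the mid-wavelength window,
log-RNL level invariance), not quantitative predictions for any real
species; quantitative work should load measured sensitivities and
spectra via `read_spectra()`.

## Numerical choices

* Interpolation is linear, onto the 300–700 nm, 1-nm default grid;
  values at original nodes are preserved and extrapolation is always an
  error.
* Integration is trapezoidal on the working grid — exact for the
  piecewise-linear representation the resampler produces.
* Negative reflectance values (spectrometer noise) are clamped to zero,
  with the count reported.
* $\ln$ of a zero relative catch is an error naming the receptor, not
  $-\infty$: downstream geometry cannot consume non-finite values.
* Basis invariants are enforced to $10^{-10}$, unit seed vectors to
  $10^{-12}$; the noise-space square root refuses near-singular
  $V R V^T$.
* Test problem sizes are kept small (tens of stimuli, the 81-stimulus
  sweeps, the 1012-combination screen), chosen so the full suite
  documents every behaviour class while remaining quick on a laptop.

## Limitations

These are models of the chromatic component only: no achromatic or
brightness channel, no psychometric mapping from $\Delta S$ to
probability of discrimination (thresholds vary with background and
species, and the relationship is not linear far above threshold), no
ocular-media or oil-droplet filtering, no shot-noise corrections for
dim light, and no higher-order cognition. Distances should be read as
chromatic dissimilarity under the calibrating assumptions, with
$\Delta S = 1$ JND meaningful for RNL models only near threshold and
under bright-light conditions.
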