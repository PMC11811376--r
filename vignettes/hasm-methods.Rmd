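---
title: "Correcting lumbar-spine landmarks with a heatmap-based active shape model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting lumbar-spine landmarks with a heatmap-based active shape model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hasm)
```

## The problem

Keypoint-regression networks locate anatomical landmarks on radiographs by
producing one response map ("heatmap") per landmark and taking its argmax.
On lateral lumbar X-rays the targets are 22 points — the four corners of
each vertebral body L1–L5 plus the two endpoints of the sacral (S1) upper
endplate — and occasional channels fail badly: film artifacts, overlapping
organs, or ambiguous anatomy can pull a single argmax tens of pixels away
from the true corner. Such outliers barely move the *mean* landmark error
but dominate the *maximum* error per image, which is what matters when the
landmarks feed downstream measurements such as slip assessment in
spondylolisthesis.

This package implements a correction stage that runs after detection. It
combines two sources of information that are individually insufficient:

* the **heatmaps** themselves, which encode where the detector saw
  plausible corners, and
* a **statistical shape model** of the 22-point configuration, which
  encodes how lumbar spines are actually shaped.

## The shape model

Each configuration is flattened to a 44-vector
$\mathbf{x} = (x_1,\dots,x_{22},\,y_1,\dots,y_{22})$. Training
configurations are brought into a common frame by generalized Procrustes
analysis (GPA) using similarity transforms only — translation, rotation and
positive scale; reflections are excluded because lateral views have a fixed
chirality. The mean shape $\bar{\mathbf{x}}$ is centered at the origin and
scaled to unit Euclidean norm (the standard normalization for point
distribution models; no normalization is canonical, so this one is declared
and used consistently).

Aligned shapes are then projected into the *tangent plane* of the unit
shape sphere at the mean, $\mathbf{y}' = \mathbf{y} / (\mathbf{y} \cdot
\bar{\mathbf{x}})$, which linearizes the shape statistics, and principal
component analysis of the projected shapes about the mean yields
eigenvectors $\mathbf{P}$ and eigenvalues $\lambda_k$. The projection step
matters in practice, not just in principle: it makes the mode deviations
orthogonal to the mean, so a shape constructed as
$\bar{\mathbf{x}} + \mathbf{P}\mathbf{b}$ is recovered *exactly* by the
constraint iteration below. Without it the iteration's fixed point is
biased by the component of $\mathbf{P}\mathbf{b}$ along $\bar{\mathbf{x}}$,
an error of order $10^{-3}$ on realistic shapes.

All modes with positive eigenvalue are retained in the fitted object (at
most 43); how many are *used* is decided at correction time by `n_P`.
Eigenvector signs follow a deterministic convention (largest-magnitude
component positive), so fits are reproducible across platforms.

### Slip augmentation

Spondylolisthesis — the anterior/posterior slip of a vertebra relative to
the one below — is underrepresented in typical training sets, and a model
fitted to mostly-normal spines will "correct" genuinely slipped landmarks
toward normality. To de-bias the model, artificial slip configurations are
generated from normal ones: a consecutive block of vertebral elements
`v_start..v_end` (1–5 = L1–L5, 6 = the S1 endplate pair) is rigidly
translated by
$$\mathbf{d} = \alpha\,\beta\,(\mathbf{UR}^* - \mathbf{UL}^*),$$
where $(\mathbf{UL}^*, \mathbf{UR}^*)$ are the upper-endplate corners of
the first moved element, $\alpha \in \{-1,+1\}$ sets the slip direction and
$\beta \in [0, 0.3]$ its magnitude as a fraction of the endplate width. The
translation direction is a convention: in a lateral view the upper-endplate
vector approximates the anterior–posterior axis along which real slips
occur; a global-x alternative is available
(`augment_spondylolisthesis(..., direction = "image_x")`). Sampling is
uniform over the stated ranges (only the ranges are prescribed); whether
the block always extends to the sacrum is configurable (`fix_v_end`),
since real slips virtually always involve the lumbosacral junction but the
general form does not require it. These configurations are coordinate-level
only — no images are synthesized — and they are not claimed to be medically
faithful; they widen the shape prior where it would otherwise be biased.

`balance_training_set()` appends augmented copies of randomly chosen normal
configurations until a target spondylolisthesis fraction is reached.

## The correction loop

Starting from the per-channel argmax detections $\mathbf{CL}$, two steps
alternate for up to `max_iterations` rounds:

**1. Heatmap-gradient update.** Each channel's gradient field is computed
once with a $3\times3$ Sobel operator and sampled at the current landmark
position, giving a magnitude $m_h$ and orientation $o_h$. The landmark
moves *up* the response surface:
$$\mathbf{UL}_i = \mathbf{CL}_i + \mu\, m_h (\cos o_h, \sin o_h) / s_i ,$$
with $s_i$ the channel scale (channel pixels per image pixel) so that $\mu$
is resolution-independent. The proportional-step rule is the minimal law
consistent with using both the gradient's distance and direction
information; the sensitivity $\mu$ is a user parameter (reference value
0.02, selected by grid search — see below). A landmark that falls outside
its channel window receives no heatmap update that round but still
participates in the shape step, which is how landmarks with unusable
channels get re-estimated from the rest of the configuration.

**2. Shape reorganization.** The updated configuration $\mathbf{Y}$ is
projected onto the model subspace by the classical constraint iteration:
starting from $\mathbf{b} = \mathbf{0}$, repeat

1. $\mathbf{x} = \bar{\mathbf{x}} + \mathbf{P}_{1..n_P}\mathbf{b}$;
2. fit the similarity transform $T$ minimizing $\|T(\mathbf{x}) -
   \mathbf{Y}\|^2$ (closed form via complex least squares);
3. $\mathbf{y} = T^{-1}(\mathbf{Y})$, tangent projection
   $\mathbf{y}' = \mathbf{y}/(\mathbf{y}\cdot\bar{\mathbf{x}})$;
4. $\mathbf{b} = \mathbf{P}_{1..n_P}^{\top}(\mathbf{y}' - \bar{\mathbf{x}})$,
   optionally clamped to $|b_k| \le c\sqrt{\lambda_k}$;

until $\|\Delta\mathbf{b}\| < 10^{-6}$ or 50 iterations. The result
$\mathbf{X} = T(\bar{\mathbf{x}} + \mathbf{P}\mathbf{b})$ replaces
$\mathbf{CL}$. Clamping defaults to $c = 3$ (the usual three-standard-
deviation box of the ASM literature) and can be disabled; whether the
original method clamps at all is not documented, so it is a switch rather
than a guess. A degenerate tangent projection
($\mathbf{y}\cdot\bar{\mathbf{x}} = 0$) is detected and raised as an error;
it cannot occur for configurations anywhere near the mean.

The outer loop stops early when the maximum per-landmark displacement of a
full round falls below `position_tol` (default 0.1 px — the reference
method defers this threshold to supplementary material, so it is exposed as
configuration; the maximum rather than the mean displacement is used, the
stricter of the two readings). With the reference parameters the loop is a
contraction in practice and typically stops after a handful of rounds.

Two sanity properties pin the design down. With $\mu = 0$, all modes, and
no clamping, the loop is *inert*: the constraint step reproduces any
configuration (complete basis), so the initial detection passes through
unchanged — there is no hidden force. And the whole pipeline is equivariant
to translating the channel windows: geometry lives entirely in the affine
channel-to-image maps.

### Reference parameters

`n_P` (modes used) and `mu` were selected in the reference study by grid
search on validation data; the designated pair is $(n_P, \mu) = (20,
0.02)$, which `grid_search()` reproduces as the default-grid winner on
fixtures with a correctable corruption. Iteration count 30 is the reference
budget. The defaults of `hasm_config()` are exactly these values.

### Snap-back post-processing

The shape step moves *every* landmark slightly, so the mean error rises a
little while the maximum error falls a lot. When mean-error fidelity
matters, a final pass moves a corrected landmark back to its channel's
global argmax whenever the two are closer than $\gamma \tilde{E}_a$, where
$\tilde{E}_a$ is the allowable error computed *from the corrected
(detected) landmarks themselves* — no ground truth is needed at inference.
$\tilde{E}_a$ is computed once before any snapping (order independence),
and the criterion is a strict inequality, so $\gamma = 0$ disables
snapping entirely. Snapped sets are nested and non-decreasing in $\gamma$.

## Evaluation metrics

For $N$ images with detected positions $\hat{p}_{ij}$ and truth $p_{ij}$:
$E_{ij} = \|\hat{p}_{ij} - p_{ij}\|$; per image the maximum
$E_{max,i}$ and mean $E_{mean,i}$ over the 22 landmarks; averaged over
images, $AE_{max}$ and $AE_{mean}$. The *allowable error* $E_{a,i}$ is 20%
of the mean length of the 21 vertebral edges (four edges per lumbar body
plus the S1 endplate edge); normalized indices $NE_{max}$, $NE_{mean}$
average $E_{max,i}/E_{a,i}$ and $E_{mean,i}/E_{a,i}$ and are invariant to
image scale and to px/mm units. An interval histogram bins images by
$E_{max,i}$ in multiples of their own $E_{a,i}$, with inclusive upper bin
edges (an image at exactly $E_{a,i}$ counts as within tolerance). Paired
comparisons between two detectors use a two-sided paired t-test on the
per-image indices, with explicit flags for the degenerate cases (identical
vectors; constant nonzero difference). Errors are reported in millimeters
when a pixel spacing is available, else in pixels, and the report says
which.

## The synthetic test bed

The generator stands in for both the radiographs and the detector, because
the correction method consumes only coordinates and heatmaps.

**Geometry.** Five vertebral bodies plus the S1 endplate are stacked along
a bowed (lordotic) curve. Defaults, in working-resolution pixels: body
width 60, height 42, disc gap 12, with coefficients of variation 8%, 8%
and 20%; per-spine bow amplitude drawn around 15 px; per-vertebra tilt
spread 0.04 rad about the curve tangent; sacral endplate inclined a further
0.3 rad; isotropic 1 px corner jitter for endplate irregularity. Vertebral
dimensions share a subject-level factor (within-subject correlation 0.85),
reflecting the high correlation of lumbar vertebral dimensions within an
individual reported in morphometric studies; this is what concentrates the
generator's variance in a few interpretable modes (size/aspect, curvature,
slip) rather than a flat spectrum. A fraction (default 15%) of spines
receives an artificial slip with $\beta \in [0.1, 0.3]$ at L4 or L5. The
recorded pixel spacing defaults to 0.17 mm/px, the center of the spacing
range of the public lumbar dataset the landmark scheme comes from; the
generator's pixel geometry is a working-resolution abstraction and does not
claim absolute anatomical sizes.

**Heatmaps.** Each landmark gets a 128×128 channel window with an
integer-valued origin offset recorded in the stack's sidecar (so channel
nodes coincide with integer image pixels), holding a unit-peak Gaussian of
width $\sigma = 5$ px centered on the true point. Corruptions are applied
independently per channel with configurable probabilities: a displaced
primary peak, a spurious secondary peak of sub-unit amplitude, attenuation
of the primary peak, and additive clipped Gaussian pixel noise. These
abstract, at the heatmap level where the correction operates, the failure
causes seen in practice (artifact lines, organ interference, ambiguous
shapes). What the generator does *not* emulate: image appearance, spatially
correlated multi-channel failures, anisotropic response shapes, and
detector-specific bias. Passing tests therefore demonstrate the mechanics
and the corrective behavior of the method under controlled corruption, not
its clinical performance on real radiographs.

## Numerical choices

* **Sobel scaling 1/8** makes the operator an unbiased derivative estimate
  (exact on affine surfaces), so $\mu$ has consistent meaning across
  resolutions. Border handling is replicate padding, which avoids spurious
  boundary gradients. Per-channel max-normalization before the Sobel step
  is on by default so that $\mu$ is comparable across images regardless of
  detector confidence.
* **Orientation accuracy.** The discrete Sobel orientation on a sampled
  isotropic Gaussian deviates from the analytic gradient direction by
  $O(\sigma^{-2})$: about $2\times10^{-2}$ rad at $\sigma = 5$ and
  $5\times10^{-4}$ at $\sigma = 24$ (over points with non-negligible
  magnitude). Oracle tests of orientation therefore use a well-resolved
  Gaussian; at the working $\sigma = 5$ the orientation is accurate to a
  degree or so, which is ample for gradient ascent.
* **Subpixel sampling** interpolates the Cartesian gradient components
  bilinearly and re-derives magnitude and angle; angles are never
  interpolated directly (ill-defined across $\pm\pi$).
* **Argmax ties** are broken by the smallest row-major index —
  deterministic and documented, though ties essentially never occur on
  real-valued responses.
* **Coordinates** are 0-based with pixel centers at integer coordinates,
  x rightward (columns), y downward (rows), everywhere, including all file
  formats.
* **Problem sizes.** The bundled simulation experiment uses 200 training
  spines and 100 validation stacks, each with exactly one channel's peak
  displaced by 20 px; this is large enough that the benchmark's outcome
  fractions are stable across seeds while the whole suite runs in seconds.

## Known limitations

* A single shape model covers both normal and slipped spines; strongly
  atypical anatomy (e.g. transitional vertebrae) is outside the prior and
  will be pulled toward it.
* The update law treats channels independently and isotropically; no
  per-landmark weighting in the shape step (a natural extension).
* The correction trades a small mean-error increase for a large
  maximum-error decrease; the snap-back stage exposes that trade-off but
  cannot eliminate it.
* Pose is a global similarity transform; perspective and non-rigid
  imaging effects are not modeled.

## A worked run

```{r}
set.seed(1)
train <- generate_dataset(spine_template_params(), n = 120)
model <- shape_model(train)
model

truth <- generate_spine(spine_template_params())
stack <- simulate_heatmaps(truth,
                           heatmap_noise_params(shift_prob = 1,
                                                shift_range = c(20, 20)),
                           landmarks_affected = 7)
res <- hasm_correct(stack, model)
res

rep <- error_report(res$landmarks, truth, baseline = res$initial)
rep
```
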