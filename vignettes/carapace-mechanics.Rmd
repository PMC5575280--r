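---
title: "Carapace mechanics: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carapace mechanics: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daphniarmor)
```

`daphniarmor` dissects how two inducible defences of daphniids — altered
body shape (neckteeth, head crests) and a reorganized carapace cuticle —
contribute to mechanical resistance against predator attack. This vignette
explains the models behind each stage, the parameters that matter, and the
choices made where the design was genuinely open.

## The laminate procuticle model

The arthropod procuticle is a Bouligand composite: sheets of parallel chitin
fibres whose orientation rotates continuously through the thickness. In STEM
cross-sections each bright–dark band (one counted "layer") spans a 180°
rotation. A continuous rotation cannot be meshed directly, so the package
follows a stepwise idealization: stacked cylinders, each representing a 120°
rotation. From an observation of total thickness $T$ and layer count $L$,

$$T_{360} = \frac{T}{L}\times 2, \qquad T_{120} = \frac{T_{360}}{3},$$

and the cylinder count that meets the observed thickness is
$\lfloor T / T_{120}\rfloor$. For the published median observations
(0.843 µm / 9 layers; 1.358 µm / 11; 0.919 µm / 6) this gives 13, 16 and 9
cylinders — `cylinders_for_thickness()` uses the floor because it reproduces
exactly these counts from the printed medians (13.5, 16.5 and 9.0 before
truncation).

Each cylinder (default diameter 1.5 µm) is subdivided into parallel strips of
alternating material: chitin fibre (E = 17 GPa, ν = 0.3) and protein matrix
(E = 0.2 GPa, ν = 0.3), with the strip direction rotated 120° per cylinder.
The strip count (default 8 across the diameter, even so the phases alternate)
is not dictated by any measurement; the homogeneous-limit property — equal
fibre and matrix moduli must make the response independent of the rotation
step — guards the implementation independently of this choice. Support and
load conditions follow the standard one-direction-of-interest convention:
the bottom edge ring is blocked in z, one edge node on the y-axis
additionally in x, the opposite edge node in all directions, and 3 mN is
shared by the five nodes nearest the top-face centre (a cross pattern; the
original node pattern is not recorded anywhere, so the nearest-five rule is
a documented choice).

Per-cylinder thickness, mesh density (default 12 elements across the
diameter, 2 element layers per cylinder) and materials are configurable in
`cylinder_stack_spec()`. These densities were chosen so that the solver
oracles (patch, beam, plate tests) pass at interactive runtimes; the
simulation series for one morphotype (n = 1…6 cylinders) runs in roughly ten
seconds on one core.

**What the absolute numbers mean.** A point-loaded linear model has a
mesh-dependent displacement at the load singularity, and commercial-code
element formulations differ from ours; absolute deformations in metres are
therefore solver-specific and are *not* comparison targets. What carries
over — and what the tests assert — are orderings between morphotypes, the
strict decrease of deformation with lamination, the power-law exponent
(observed ≈ −2.8, consistent with the plate-bending t³ law softened by local
indentation), and the downstream fit/extrapolation arithmetic, which
operates on the published per-cylinder series shipped with the package.

## Power-law fit and extrapolation

Deformation versus cylinder count is fitted as $f(x) = a\,x^b$ by ordinary
least squares on $(\ln x, \ln y)$, with $R^2$ computed in log space. Whether
the original spreadsheet fit used log or linear space is not recorded;
log-space OLS reproduces the published coefficients and $R^2$ values from
the 3-decimal table data (e.g. model i: fitted 0.974·x^−2.828, R² 0.9884
versus the printed 0.9679·x^−2.822, R² 0.9887) and is adopted.
Extrapolations are reported at 4 decimal places in nm, matching the
published table. No confidence intervals are attached — none were reported,
and the series has six points.

## Hertz inversion of indentation curves

Two tip geometries are supported. The AFM probe is a four-sided pyramid
(face angle α, default 35°, typical of the silicon-nitride probes used for
soft biological samples):

$$F = \frac{\tan\alpha}{\sqrt{2}}\,\frac{E}{1-\vartheta^2}\,\delta^2 .$$

The microindenter tip is parabolic with radius r (default 12.37 µm):

$$F = \frac{4}{3}\,\sqrt{r}\,\frac{E}{1-\vartheta^2}\,\delta^{3/2} .$$

Both are the standard Hertz/Bilodeau contact forms; E enters linearly, so
the inverse problem is a closed-form projection once the contact point and
depth are known. Sample Poisson's ratio defaults: 0.5 for AFM (incompressible
soft hydrated cuticle convention) and 0.15 for the microindenter (matching
the shell models); both configurable, since instrument-software settings are
not recorded in the source data.

Contact detection first finds where force exceeds the pre-contact baseline
mean + 5 SD for at least 5 consecutive samples. Because a smooth
$\delta^2$ or $\delta^{3/2}$ onset crosses any noise threshold well after
true contact, the crossing is then refined by a one-dimensional
least-squares search over candidate contact samples (baseline offset
re-estimated per candidate, modulus projected in closed form). On synthetic
curves with 1% baseline noise this localizes contact within ±1–3 samples;
with no noise it is exact, which is what makes the noiseless
generate-then-fit round trip recover E to 1e−6 relative. When a cantilever
spring constant k is present in the curve metadata, the sample indentation is
corrected by the cantilever deflection, $\delta = z - F/k$. AFM fits are
windowed at the instrument limits (10 nN maximal force, 50 nm maximal
depth).

The critical force — the maximum force the carapace bears before lethal
collapse — is detected as the first sample-to-sample force drop exceeding a
fraction (default 0.15) of the running maximum; the reported force is the
local maximum immediately preceding the drop.

## The finite-element engine

Solids are 8-node trilinear hexahedra with 2×2×2 Gauss quadrature,
augmented by Wilson–Taylor incompatible bending modes (nine internal
degrees of freedom, statically condensed, with the centroid-Jacobian
correction so the constant-strain patch test passes exactly on distorted
meshes). The enhancement matters: the plain trilinear element shear-locks
and misses the slender-cantilever closed form by ~10% even at moderate
refinement, while the enhanced element is within 1%; the plain formulation
remains available (`incompatible_modes = FALSE`) and is used in the test
suite to demonstrate monotone convergence from below. Stress is reported as
von Mises at element centroids and "maximum stress" as the maximum over
elements, the simplest scalar consistent with a single reported Pa value.

Shells are flat three-node facets superposing a constant-strain membrane
with the discrete-Kirchhoff (DKT) plate-bending triangle; each node carries
six degrees of freedom, the in-plane drilling rotation receiving a small
artificial stiffness (1e−6 of the element diagonal) so assemblies of
coplanar facets stay non-singular. The facet shell reproduces the
simply-supported Kirchhoff plate series solution within 2% at a 16×16 grid
and obeys the t³ thickness law within 10%.

Both element types assemble into one sparse symmetric system solved by
direct factorization (`Matrix`); an equilibrium-residual check converts a
silently singular factorization into an explicit "under-constrained" error.
External work and strain energy agree to 1e−8 relative on every solve the
suite runs, and reaction forces balance the applied loads by construction
of the residual.

Internally everything is SI (m, Pa, N); µm/nm/mN/kPa appear only at I/O
boundaries — the data mix five different unit scales, and a single internal
system avoids silent mixed-unit errors.

## The shape pipeline

Carapace shape is described by the species outline schemes (33 ordered
landmarks/semi-landmarks for *D. pulex*, 31 for *D. longicephala*; shipped
as a machine-readable table via `landmark_scheme()`), a 310-point surface
grid (31 horizontal × 10 vertical lines over one body hemisphere), one
cleft semi-landmark per horizontal line marking the free ventral margin,
and three anatomical reference points (rostrum tip, carapace–spine
transition, fifth dorsal thorn). Alignment uses the least-squares similarity
transform on exactly these three anchors — not a full Procrustes over all
landmarks — because three designated reference points are the anchoring
protocol for these data. Averaging is the pointwise mean of aligned
configurations.

The shell model triangulates the grid (two facets per quad, plus cleft fans
along the ventral margin: 600 facets, 341 nodes), takes its wall thickness
from the STEM observation and its modulus from the AFM measurement
(ν = 0.15), constrains all body-outline nodes except the ventral margin,
and spreads 1 mN over the five free nodes of the grid column reaching the
greatest lateral depth, directed toward the sagittal plane. How many nodes
carried the load originally is not recorded; the count is exposed in
`build_shell_model()`. The grid triangulation itself is likewise a
documented choice — the original surface meshing procedure is not described
at element level.

The swap experiment crosses shape (uninduced/induced) with structure
(uninduced/induced thickness + modulus). Because real CLSM coordinates are
unavailable, the pipeline runs on parametric synthetic shapes, and
acceptance for this stage is ordinal and scaling-based: the induced
structure must stiffen under either shape, the four cells must reproduce
the qualitative published ordering (uninduced-shape/induced-structure
smallest, induced-shape/uninduced-structure largest), deformation must
scale exactly as 1/E and linearly with load, and the deformation maximum
must fall on the free ventral margin. Absolute µm/kPa values are not
comparable for the same reasons as in the laminate models, compounded here
by synthetic geometry.

## Synthetic data: what it emulates, and what it does not

The generators produce study-shaped data with recorded ground truth: Hertz
force curves with a flat pre-contact baseline, multiplicative loading noise
(default 5%), baseline noise (default 1% of maximal force) and optional
collapse drops; log-normal procuticle thickness samples (positive by
construction) and shifted-binomial layer counts whose large-sample medians
converge to the published medians; parametric hemisphere carapaces with a
truncated-Gaussian head-crest term (strictly local to the head region) or
dorsal neckteeth bumps, species-correct outline schemes and controlled
inter-individual jitter; and hierarchical AFM-style measurement sets
(individuals → repeated indentations) for the nested ANOVA. The induced
*D. pulex* template is larger than the uninduced one, so the induced shape
is the more compliant under equal structure — the geometric relationship the
swap experiment probes.

These stand-ins deliberately do not model imaging physics, real landmark
digitization error structure, adhesion or drift in force curves, or any
correlation between shape and cuticle parameters. Passing tests therefore
demonstrate that the *analysis machinery* is correct (round-trip recovery,
invariances, orderings), not that the biological effect sizes would be
recovered from real instruments.

## Statistics

`mann_whitney_u()` reports U = min(U₁, U₂) with midrank ties; the p-value is
the exact two-sided tail of the null U distribution for groups of up to 20
without ties (the exhaustive-enumeration oracle in the test suite checks it
for n ≤ 8), otherwise a tie-corrected, continuity-corrected normal
approximation. `students_t()` is the pooled-variance two-sample t.
`nested_anova()` partitions SS_total = SS_treatment + SS_individual +
SS_residual exactly (the nested decomposition holds for unbalanced data
too) and tests treatment against the among-individual mean square with
individuals-minus-treatments denominator degrees of freedom — the design
that controls for inter-individual differences in hierarchical AFM data.
For unbalanced designs this F test is the unweighted-means approximation
and the output says so; which unbalanced flavour the original commercial
software used is not recorded, so the approximation is flagged rather than
hidden. Significance stars follow the reporting convention (* ≤ 0.05,
** ≤ 0.01, *** ≤ 0.005). Two-sided p-values are used throughout.

## Numerical choices and degenerate inputs

* Direct sparse Cholesky, no iterative-solver tuning: all systems here are
  desk-scale (≤ ~10⁴ degrees of freedom).
* Equilibrium residual above 1e−6 of the load scale raises an error rather
  than returning a silently wrong solution.
* Degenerate (zero-area) shell facets, inverted hexahedra, collinear
  reference points, non-positive power-law inputs, zero pooled variance and
  all-constant nested designs all raise explicit errors naming the offending
  entity.
* "Maximum deformation" is the displacement magnitude by default; the signed
  z-component is available (`component = "z"`), since the original direction
  convention is not recorded.
* Tie-breaks: the five loaded nodes are chosen by distance rank from the
  face centre (stack) or by depth rank within the widest column (shell);
  ties beyond the count fall to the lower node index via `order()`.

## Problem sizes

The shipped defaults — 12 elements across the cylinder diameter with two
element layers per cylinder, a 31×10 shell grid, 500-curve Monte-Carlo
recovery batches and 2000-replicate null calibrations — were chosen as the
sizes at which each check stabilizes well inside its tolerance on a single
core; larger sizes change the reported quantities only in digits the
tolerances ignore.

## Known limitations

* Linear static analysis only: no contact, buckling or large-deformation
  kinematics. At mN loads on µm-thick shells the real response is
  geometrically nonlinear, which is one reason absolute deformations are
  treated as non-comparable.
* The stepwise 120° laminate cannot represent the truly continuous Bouligand
  rotation; cuticle chemistry (crosslinking, mineralization) is outside
  scope.
* Synthetic carapace geometry is an ellipsoid-hemisphere idealization; no
  thin-plate-spline warping onto real outlines is attempted.
* The Mann-Whitney normal approximation is used whenever ties occur, even
  in small samples.
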