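# daphniarmor

Biomechanics of predator-induced carapace defences in the water flea
*Daphnia*.

Daphniids respond to predator chemical cues with inducible defences:
*D. pulex* grows dorsal "neckteeth" against *Chaoborus* larvae, and
*D. longicephala* an enlarged head crest against the backswimmer
*Notonecta*. Alongside these visible shape changes, the carapace cuticle
itself is reorganized — the chitinous procuticle becomes more finely
laminated (more Bouligand layers) and stiffer. `daphniarmor` implements the
quantitative machinery needed to separate the contributions of **shape** and
**cuticle structure** to the carapace's mechanical resistance:

* a small linear-elasticity finite-element engine — 8-node hexahedra with
  incompatible bending modes for solid laminate models, and flat facet shells
  (constant-strain membrane + discrete-Kirchhoff bending triangle) for the
  carapace surface;
* construction of laminate **cylinder-stack models** of the procuticle: each
  cylinder represents a 120° rotation of chitin fibre orientation with
  thickness T₁₂₀ = T₃₆₀ / 3, where T₃₆₀ = thickness / layers × 2, subdivided
  into alternating fibre (E = 17 GPa) and matrix (E = 0.2 GPa) strips;
* **power-law fitting** of simulated deformation vs. cylinder count,
  f(x) = a·xᵇ by OLS on (ln x, ln y), and extrapolation to the cylinder
  count ⌊thickness / T₁₂₀⌋ that meets the observed procuticle;
* **Hertz-model inversion** of indentation force–distance curves — the
  four-sided pyramidal form F = tan α/√2 · E/(1−ϑ²) · δ² for AFM
  nanoindentation of the procuticle and the parabolic form
  F = 4/3·√r · E/(1−ϑ²) · δ^{3/2} for microindentation of the whole
  carapace — plus detection of the critical (collapse) force from rapid
  force drops;
* a **landmark shape pipeline**: species outline schemes (33 / 31 points),
  a 310-point surface semi-landmark grid, 3-reference-point similarity
  alignment, shape averaging, loaded shell models (1 mN at the carapace's
  widest point, outline constrained except the free ventral margin), and the
  2×2 **shape × structure swap experiment**;
* the matching statistics (Mann–Whitney U with exact small-sample p, pooled
  t, two-level nested ANOVA testing treatment against among-individual
  variance) and synthetic-data generators with known ground truth for every
  stage.

## Worked example

Fit the power law to the reference per-cylinder deformation series of the
three laminate models and extrapolate to the observed procuticle
thicknesses:

```r
library(daphniarmor)
extrapolation_table()
#>       model         a         b r_squared n_extrapolation deformation_nm
#> 1   model_i 0.9735992 -2.827655 0.9883787              13         0.0007
#> 2  model_ii 0.5775140 -2.767769 0.9903722              16         0.0003
#> 3 model_iii 0.3654687 -2.659291 0.9935205               9         0.0011
```

Model i is the shared laminate of uninduced *D. pulex* and induced
*D. longicephala*, model ii the induced *D. pulex* procuticle, model iii the
uninduced *D. longicephala* procuticle. The exponents near −2.7 reflect the
plate-bending t³ stiffening with increasing lamination; the last column is
the deformation (nm) expected at the full observed procuticle thickness
(13, 16 and 9 cylinders). The uninduced *D. pulex* procuticle deforms about
2.4× more than the induced one (0.0007 vs 0.0003 nm), the uninduced
*D. longicephala* about 1.6× more than the induced (0.0011 vs 0.0007 nm).

Derive a laminate model from a microscopy observation and recover a modulus
from a noisy synthetic AFM curve:

```r
procuticle_observation(0.843, 9, "D. pulex uninduced")
#> <procuticle_observation> D. pulex uninduced: 0.843 um, 9 layer(s); T120 = 0.0624 um -> 13 cylinder(s)

afm <- indenter_spec("pyramidal")
cv  <- gen_force_curve(2.93e6, afm, "afm", baseline_sd_frac = 0.01,
                       multiplicative_sd = 0.05, seed = 7)
fit_young_modulus(cv, afm)
#> <hertz_fit> E = 2.847e+06 Pa (contact at sample 51, 128 samples, RMS residual 1.29e-10 N)
```

The fitted 2.85 MPa recovers the generating 2.93 MPa within the 5% noise
level. Reporting utilities reproduce the derived group comparisons, e.g.
`percent_change(142.38, 262.84)` → `85` (% increase in structural modulus of
induced *D. pulex*) and `percent_reduction(95.2, 34.4)` → `64` (% reduced
shell deformation of the induced shape simulation).

The full synthetic study — generation, laminate simulation series,
fits/extrapolations, indentation batch fitting, shape-swap shell
simulations and group statistics — runs end-to-end with
`run_pipeline(run_config())`, writing tidy CSVs plus a stage manifest.

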