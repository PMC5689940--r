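# fffqa

Independent planar dose calculation for photon-beam IMRT quality
assurance, with a head model that works for both flattened (FF) and
flattening-filter-free (FFF) beams.

Patient-specific IMRT QA compares a delivered dose plane (typically a
2D diode array under solid water) against a calculation.  A second,
independent calculation engine — simpler than the treatment planning
system but physically honest about the machine head and the MLC — is a
valuable cross-check.  This package provides that engine for medical
physicists: a fast analytical model commissionable from standard
water-tank data, plus the gamma analysis used to score agreement.

## The model

* **Source**: a primary point source plus an extra-focal source
  f(x,y) = Σᵢ Aᵢ/(2π σₓᵢ σᵧᵢ) · exp(−x²/2σₓᵢ² − y²/2σᵧᵢ²),
  a sum of bivariate Gaussians on a plane below the target whose x/y
  anisotropy implicitly carries the collimator-exchange effect.  Fitted
  parameter sets for 6/10 MV FF/FFF ship with the package
  (`beam_model_library()`).
* **In-air output factors**: Sc = (1 + I(field)) / (1 + I(10×10)), where
  I integrates the source over the rectangle visible through the
  back-projected collimator edges — closed-form error functions, no
  quadrature.
* **Fluence**: per-ray MLC transmission (rounded leaf tips
  L(d) = exp(−d^α/β), bulk, interleaf and tongue-and-groove strips,
  jaw shadow) plus the extra-focal integral over the open leaf rows,
  times a fourth-degree off-axis-ratio polynomial R(r) for FFF beams.
* **Dose**: 2D convolution with a triple-Gaussian kernel
  k(x,y) = Σᵢ Aᵢ/(2πσᵢ²)·e^(−r²/2σᵢ²) on a 1 mm grid.
* **Commissioning**: four staged bounded least-squares fits (source from
  Sc; OAR from large-field profiles; kernel from in-plane profiles; leaf
  end from cross-plane profiles), each compared after convolution with a
  Gaussian detector response that emulates chamber volume averaging.
* **Scoring**: 2D gamma index with local/global dose criterion, DTA and
  low-dose threshold, verified against a brute-force search oracle.

See `vignettes/fffqa-methods.Rmd` for assumptions, parameter meanings,
numerical choices and limitations.

## Worked example

```r
library(fffqa)

ff  <- beam_model_library("6FF")
fff <- beam_model_library("6FFF")

central_intensity(ff$source)                     # 0.009 cm^-2
central_intensity(fff$source)                    # 0.019 cm^-2
half_max_radius(ff$source)                       # 1.27 cm
half_max_radius(fff$source)                      # 0.75 cm
head_scatter_reduction(ff$source, fff$source)    # 34.6 %

compute_sc(fff, rect_field(5, 5))                # 0.9913
compute_sc(fff, rect_field(30, 30))              # 1.0124

# a synthetic QA session: random 10-segment plan, pseudo-measurement on
# a staggered diode array, gamma comparison at 2%/2 mm local, 10% threshold
spec <- fixture_spec(n_segments = 10, seed = 42)
beam <- make_imrt_plan(spec)
dose <- calc_dose_plane(fff, beam)
meas <- make_measurement(fff, beam, spec, dose = dose)
gamma_index(meas, dose, gamma_criteria(2, 0.2, 10, "local"))
#> <gamma_result> 2%/2 mm (local), 10% threshold
#>   passing rate: 100.0% of 211 evaluated points (1194 below threshold)
```

Removing the flattening filter shrinks the extra-focal source (1.27 →
0.75 cm half-max radius), concentrates it (0.009 → 0.019 cm⁻²
centrally), and cuts its total contribution by a third — which is why
FFF beams need less head-scatter modelling headroom.  The Sc values
bracket 1 because output is normalized to the 10×10 cm² reference.  The
gamma result scores the calculated plane against the noisy
pseudo-measurement at every diode above 10% of the maximum dose.

A thin command-line wrapper over the same functions ships in
`inst/cli/fffqa.R` with subcommands `sc`, `calc-plane`, `gamma`,
`simulate` and `commission`.

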