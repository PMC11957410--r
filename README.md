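# glwave

Small-angle scattering (SANS/SAXS) from lamellar phases — surfactant
stacks, lipid membranes, block copolymers — is routinely fitted with
ideal-lamellar models that assume uninterrupted layers. Real samples are
crumpled and threaded by dislocation lines, and the diffuse scattering
between and around the quasi-Bragg peaks carries that information.
`glwave` is an R toolkit for scattering practitioners who want to
extract it. It implements the generalized leveled-wave (GLW)
representation of distorted lamellar and sponge phases, a
Kolmogorov–Arnold-network (KAN) surrogate that inverts measured curves
to structural parameters, and a winding-number analysis that locates,
classifies and tracks the topological defect lines of the reconstructed
structures.

## The model in brief

Density fluctuations are a superposition of random plane waves,

    S(r) = sqrt(2/n) * sum_m exp[i (k_m . r + phi_m)],

with wave vectors drawn from a factorized anisotropic distribution:
magnitude |k| ~ N(k0, sigma_k k0) with k0 = 2*pi/d (spacing disorder),
polar angle from the Fisher density ∝ exp(Gamma cos(theta)) about the
layer normal (orientational order), azimuth and phases uniform. Clipping
Re S at its upper alpha-quantile yields a binary scattering-length
density whose volume fraction is alpha; an FFT and radial average give
the dimensionless spectrum I(Qd/2pi). Three parameters — sigma_k, Gamma,
alpha — therefore span ideal stacks, distorted lamellae and isotropic
sponges. A two-stage KAN (spline edge functions, widths [3,7,3] and
[4,9,1,1]) learns (sigma_k, ln Gamma, alpha, Q) -> I and is fitted to
reduced 1-D curves by bounded least squares with scale and background
nuisances. Defect lines are traced as phase singularities of S: the
cumulative wrapped phase difference around each pixel's 8-neighbor loop
is an exact multiple of 2*pi, nonzero exactly on dislocation lines
(screw when within 45 degrees of the layer normal, else edge).

## Worked example

```r
library(glwave)

m <- glw_model(sigma_k = 0.05, gamma = 128, alpha = 0.3, d = 40,
               grid_n = 64, seed = 1)
m
#> GLW model: sigma_k = 0.05, gamma = 128, alpha = 0.3, d = 40
#>   1000 waves, box 8 x d, grid 64^3, seed 1

sp <- ensemble_spectrum(m, n_real = 4)
correlation_peaks(sp)
#>   q     height prominence nearest_order offset_bins
#> 1 1  1.3759426   1.138031             1           0
#> 2 2 -0.1167164   0.527931             2           0
```

The spectrum of this well-ordered stack (Gamma = 128) shows correlation
peaks on the bin centers at Qd/2pi = 1 and 2 (heights are log10 of the
dimensionless intensity; at alpha = 0.3 the second order is already
partially suppressed — it vanishes entirely at alpha = 0.5, and a third
order emerges at alpha near 0).

```r
f   <- plane_wave_field(m)
rho <- clip_to_sld(f)
rho
#> SLD field: 64^3 voxels, membrane fraction 0.2882 (target 0.3000)

defect_statistics(trace_defect_lines(winding_map(f)), m$box_edge)
#> Defect lines: 45 (10 screw, 35 edge), line density 0.0002035 / vol
```

The realized membrane fraction tracks the clipping level (single
realizations of strongly aligned fields fluctuate by a few percent; the
ensemble mean is exact). Dropping the orientational order to a
sponge-like Gamma = 0.5 multiplies the defect line density by ~17:

```r
ms <- glw_model(0.05, 0.5, 0.3, d = 40, grid_n = 64, seed = 1)
defect_statistics(trace_defect_lines(winding_map(plane_wave_field(ms))),
                  ms$box_edge)
#> Defect lines: 1419 (373 screw, 1046 edge), line density 0.003417 / vol
```

Fitting a measured (or synthetic) reduced curve:

```r
lib <- make_library(200, grid_n = 64, n_real = 8, seed = 1)  # ~7 min
mod <- kan_train(kan_surrogate(seed = 1), lib, seed = 1)     # ~4 min
spec <- read_spectrum("reduced_curve.dat")        # Q [1/A], I, dI
fit  <- fit_spectrum(spec, mod)           # d from the first peak
fit$sigma_k; fit$ln_gamma; fit$alpha
render_structure(fit, grid_n = 64, seed = 1)  # 3-D reconstruction
```

A thin command-line wrapper (`inst/cli/glwave.R`) exposes the same
pipeline as subcommands `simulate`, `spectrum`, `train`, `fit`,
`defects`, `track`, `onion` and `synth`, each writing a provenance JSON
beside its outputs.

See the methods vignette (`vignettes/glwave-methods.Rmd`) for the model
assumptions, training recipe, identifiability analysis and numerical
conventions.

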