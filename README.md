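# ballisticwave

Reaction–diffusion modelling and microscopy kinetics analysis of invasion
fronts in arrested biomolecular condensates.

Solid-like ("arrested") condensates can be invaded by short
oligonucleotides that bind complementary barcode domains of the
condensate-forming polymers. This molecular recognition, coupled to an
arrested-to-dynamic transition of the invaded material, produces a
transport mode unlike classical diffusion: an ultrasharp invasion front
that moves at constant velocity and carries a high-intensity accumulation
of invader at its tip ("ballistic wave diffusion"). This package is for
biophysicists who want to simulate that mechanism, explore its regime
diagram, and quantify invasion-front, FRAP and FLIM recordings with the
matching estimators.

## The model

Per material volume element: free invader $u$ (diffusivity $D_0$ in
arrested material, $D_1 \gg D_0$ in swollen material), free barcode $m$,
and the bound complex in arrested ($M_{\mathrm{arr}}$) or swollen
($M_{\mathrm{sw}}$) state,

$$\partial_t u = \nabla\!\cdot\!\big(D(\varphi)\nabla u\big) - k_{\mathrm{bind}}\, u\, m,\qquad
\partial_t m = -k_{\mathrm{bind}}\, u\, m,$$

$$\partial_t M_{\mathrm{arr}} = k_{\mathrm{bind}}\, u\, m - k_{\mathrm{swell}} M_{\mathrm{arr}},\qquad
\partial_t M_{\mathrm{sw}} = k_{\mathrm{swell}} M_{\mathrm{arr}},$$

with $D(\varphi) = D_1$ once the swollen fraction $\varphi =
M_{\mathrm{sw}}/(m + M_{\mathrm{arr}} + M_{\mathrm{sw}})$ exceeds a
threshold $\theta$ (else $D_0$), and local material expansion $w = w_0[1
+ (f_{\mathrm{swell}} - 1)\varphi]$ (volumetric swelling factor
$f_{\mathrm{swell}} \approx 4$). Binding is irreversible
(diffusion-controlled, strong duplex). Depending on $D_1/D_0$ and
$k_{\mathrm{swell}}$ the model produces ballistic wave diffusion
($\Delta X \propto t$ with a peak), ballistic front diffusion (linear,
peakless) or Fickian diffusion ($\Delta X \propto \sqrt t$).

The analysis side implements the standard quantifications: kymograph
front tracking (position, width, velocity, $I_p/I_0$ peak ratio, scaling
exponent, regime classification), FRAP double normalization
$I_{\mathrm{norm}}(t) = \frac{I_{\mathrm{ROI}}(t)}{I_{\mathrm{ROI}}(t_0)}
\cdot \frac{I_{\mathrm{ref}}(t_0)}{I_{\mathrm{ref}}(t)}$ with
half-recovery times (arrested convention $t_{1/2} = 6000$ s),
point-bleach diffusivity from $\sigma^2(t) = \sigma_0^2 + 2Dt$, and the
FLIM phasor transform $g = \int I\cos(n\omega t)\,dt / \int I\,dt$,
$s = \int I\sin(n\omega t)\,dt / \int I\,dt$ with mono-exponential
readout $\tau = s/(g\,n\,\omega)$. A synthetic-data module generates all
inputs with known ground truth.

## Worked example

Simulate the canonical ballistic-wave condition (defaults: 1 mM barcode,
1 uM invader reservoir, $D_1/D_0 = 10^4$, $k_{\mathrm{swell}} = 10^{-3}$
/s, fourfold swelling, 7.5 um slab) and quantify the front:

```r
library(ballisticwave)

sim <- simulate_invasion(canonical_params("ballistic_wave"))
front_analysis(sim$kymograph)
#> <front_fit> regime = ballistic_wave
#>   v = 0.0001109 +/- 2.8e-08 um/s, alpha = 1.003 +/- 0.000
#>   median I_p/I_0 = 3.035, median W = 0.01709 um, window [16350, 120300] s
```

The front moves at constant velocity (displacement exponent `alpha`
$\approx 1$, not the Fickian 0.5), and the invader peak at the tip is
about 3x brighter than the invaded plateau behind it — the fingerprint of
the wave regime. Swapping in `canonical_params("fickian")` (no
diffusivity contrast) yields `alpha = 0.48` and a `fickian` label;
`canonical_params("ballistic_front")` (thousandfold faster swelling)
keeps the linear front but flattens the peak to $I_p/I_0 = 1.06$.

Closed-loop estimator checks run the same way on synthetic data, e.g.

```r
g <- gen_pointbleach_stack(D = 1, noise = list(type = "gaussian", sigma_rel = 0.01))
fit_diffusion_coefficient(g$series)$D
#> [1] 0.9939181
```

(ground truth `D = 1`, recovered within 1%; the generator records its
ground truth and seed alongside every dataset).

A thin command-line dispatcher over the same functions lives at
`inst/cli/bwd.R` (`simulate`, `scan`, `front`, `frap`, `pointbleach`,
`phasor`, `generate`), reading and writing the delimited formats
documented there.

## Documentation

The methods vignette (`vignettes/ballistic-wave-diffusion.Rmd`) describes
the model and its assumptions, the numerical scheme and why it is
implicit with binding coupled into the transport solve, the front-width
and fit-window conventions, what the synthetic generators do and do not
emulate, and known limitations.
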