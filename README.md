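# coanafor

Reconstruction of crowded NMR spectra from truncated (or non-uniformly
sampled) time-domain data, for solution-NMR spectroscopists who need
**accurate peak-height ratios** — e.g. transferred cross-saturation (TCS),
relaxation, or titration readouts — from short measurements of dilute,
unstable samples.

## The problem and the method

The indirect dimension of a 2D experiment is sampled point by point, so its
maximum evolution time is paid for in wall-clock time. Recording only the
first `M` of `N` increments (truncated uniform sampling, "sampling coverage"
`M/N`) and spending the saved time on more scans per increment raises the
signal-to-noise ratio of the recorded points by `sqrt(N/M)` — if the missing
points can be inserted without biasing peak heights.

Most biomolecular measurements are preceded by a quick, sensitive reference
spectrum (¹H–¹⁵N HSQC or TROSY) whose peak positions — the *guide-FID*
frequencies — are in principle identical to those of the expensive
experiment. Each interferogram is modelled as a sum of exponentially damped
complex sinusoids at those known frequencies ν_j with a uniform decay rate R:

    y(t_k) ≈ Σ_j a_j · exp(i 2π ν_j t_k − R t_k)

The complex amplitudes are estimated from the recorded points by
Tikhonov-regularized (ridge) least squares,

    â = argmin_a ‖Φa − y‖² + λ‖a‖²,   λ = 0.01 · mean(diag(ΦᴴΦ)),

and the model is evaluated **only at the unrecorded positions**; every
experimentally recorded point is conserved bit-identically (hence
*conservation* ANAFOR, Co-ANAFOR). Conservation bounds the damage done by
*misinformation* (guide frequencies slightly off the truth), and the ridge
term tames the least-squares instabilities that plague the original
full-replacement ANAFOR in crowded spectra.

The package also implements the standard comparison methods — zero-filling,
forward linear prediction with root reflection, SIFT (iterative
frequency-domain support projection, 54 Hz bright regions, 50 iterations),
and compressed sensing by iterative soft thresholding (400 iterations) with
sinusoidal-weighted Poisson-gap schedule generation — plus square-sine
apodization/FT processing, a synthetic HSQC-like interferogram generator,
and the Monte-Carlo RMSΔ(h₍ii₎/h₍i₎) evaluation of peak-height-ratio
accuracy.

## Worked example

```r
library(coanafor)

set.seed(1)
grid  <- time_grid(128, dwell = 1/2000)            # 2000 Hz spectral width
truth <- synthesize(c(-200, -134), 23, c(1, 0.8) + 0i, grid)
noisy <- truth + complex(real = rnorm(128, 0, 0.01),
                         imaginary = rnorm(128, 0, 0.01))
fid   <- truncate_fid(interferogram(noisy, grid), 0.25)
fid
#> <interferogram> 128 points (32 recorded, coverage 25.0%), sw 2000 Hz

rec  <- coanafor_extend(fid, c(-200, -134), reconstruction_config(target_n_points = 128))
spec <- to_spectrum(rec)                           # square-sine 90°, zero-fill
peak_height(spec, -200)
#> $height
#> [1] 45.59772
#> $freq_hz
#> [1] -199.2188
```

The first 32 points of `rec` are the measured values, untouched; the
remaining 96 are model-calculated. The peak height is the local maximum of
the real part within ±27 Hz of the nominal position.

Accuracy evaluation (here at reduced scale, 50 repetitions):

```r
res <- run_coverage_sweep(synthetic_scenario(), c("zerofill", "coanafor"),
                          c(0.25, 0.75), n_reps = 50, seed = 1)
res$table
#>     method coverage rmsdelta n_reps n_invalid reference_ratio
#> 1 zerofill     0.25   0.0720     50         0           0.995
#> 2 zerofill     0.75   0.0123     50         0           0.995
#> 3 coanafor     0.25   0.0132     50         0           0.995
#> 4 coanafor     0.75   0.0113     50         0           0.995
```

RMSΔ is the root-mean-square deviation of reconstructed peak-height ratios
from the reference ratio of fully sampled, unreconstructed data: at 25 %
coverage, zero-filling distorts the ratio about 5× more than Co-ANAFOR.

## Command line

```sh
Rscript inst/exec/coanafor reconstruct --in fid.tsv --out rec.tsv \
    --method coanafor --peaks guide.tsv --target-points 128
Rscript inst/exec/coanafor make-schedule --out a.sched --n 128 --coverage 0.25 --seed 1
Rscript inst/exec/coanafor evaluate --sweep coverage --reps 50 --seed 1 --out sweep.tsv
```

## Practical defaults

Regularization factor 0.01; direct-dimension selection window ±0.02 ppm;
uniform R = 1/(maximum evolution time after insertion); square-sine 90°
window. Recommended operating point: maximum evolution time after insertion
≈ 120 % of the average transverse relaxation time at ≈ 30 % sampling
coverage.
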