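# icgemd

Delineation of impedance cardiography (ICG) signals with empirical mode
decomposition, and the hemodynamic parameters that follow from it.

The ICG waveform dZ/dt — the first derivative of thoracic impedance —
carries three landmarks per cardiac cycle: **B** (aortic valve opening,
onset of the systolic upstroke), **C** (the cycle maximum, the largest
rate of impedance change) and **X** (aortic valve closing, the
post-systolic trough). Their positions determine the left-ventricular
ejection time (LVET = X − B), dZ/dt<sub>max</sub> (the amplitude at C),
and through the Kubicek formula the stroke volume

> SV = ρ · L² / Z₀² · dZ/dt<sub>max</sub> · LVET  [mL],

with ρ the blood resistivity (Ω·cm), L the inter-electrode thoracic
length (cm) and Z₀ the base impedance (Ω); heart rate comes from the
C-to-C intervals and cardiac output is SV × HR / 1000 (L/min).

`icgemd` locates B, C and X using only the dZ/dt channel — no
simultaneous ECG:

* **C** from the plain EMD of the signal: the detection function
  cf1 = |(IMF₁+IMF₂+IMF₃+IMF₄) · IMF₁·IMF₂·IMF₃| is scanned with an
  adaptive two-level threshold, a 200 ms refractory period and a
  search-back stage, then each detection is snapped onto the waveform
  maximum.
* **B** from the ensemble EMD (EEMD): the local maximum of the first
  derivative of ensemble mode 4 nearest before each C.
* **X** from the EEMD: the first local minimum of
  cf2 = IMF₃ + 2·IMF₄ + 4·IMF₅ within [C, C + 0.15·CC̄], where CC̄ is
  the mean beat interval.

The package also provides the preprocessing chain (zero-phase
downsampling, Savitzky–Golay smoothing), a synthetic dZ/dt generator
with analytic ground-truth annotations, a tolerance-based annotation
matcher, and a command-line interface (`exec/icgemd`) with `simulate`,
`decompose`, `detect`, `hemo` and `evaluate` subcommands. All sample
indices are 1-based, in the API and in annotation files.

## Worked example

```r
library(icgemd)

# two minutes of synthetic dZ/dt at 250 Hz, 75 +/- 3 bpm, 20 dB SNR
gen <- synth_signal(synth_spec(duration_s = 120, snr_db = 20, seed = 1))
sig <- savgol_smooth(gen$signal)          # standard preprocessing

fid <- detect_fiducials(sig, ensemble = ensemble_config(seed = 1))
fid
#> <icg_fiducials> 150 beats @ 250 Hz (B present: 150, X present: 150)
#>    beat    b    c    x
#> 1     1   87  100  129
#> 2     2  286  300  328
#> ...

evaluate_fiducials(fid, gen$annotations)
#> <fiducial_evaluation> tolerance 7 samples (28 ms)
#>   B: 100.00% (150/150)
#>   C: 100.00% (150/150)
#>   X: 100.00% (150/150)

beat_metrics(fid, sig, subject_constants(rho = 150, length_cm = 30,
                                         z0 = 25))
#> <beat_metrics> 150 beats (150 with full B/C/X)
#>   HR 75.0 bpm | mean SV 53.0 mL | CO 3.98 L/min
```

The evaluation block reads: every ground-truth B, C and X point was
matched by a detection within 7 samples (28 ms). The metrics line gives
the record-level heart rate, the mean Kubicek stroke volume over beats
with complete B/C/X, and the resulting cardiac output.

A single worked stroke volume:

```r
stroke_volume(subject_constants(rho = 150, length_cm = 30, z0 = 25),
              dzdt_max = 1.5, lvet_s = 0.3)
#> [1] 97.2
```

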