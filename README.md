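# slicelogp

Reference-free determination of the *n*-octanol/water partition
coefficient (log *P*) by slice-selective ¹⁹F NMR, as a desk-scale R
toolkit: plan the spatial-encoding geometry, simulate partitioned
two-phase samples as pseudo-2D NMR datasets, and process them to a
log *P* value with an uncertainty propagated from signal-to-noise.

## The method

log *P* = log₁₀(C_oct/C_aq) is the standard lipophilicity descriptor of
drug discovery. The classical shake-flask measurement needs each phase
sampled and assayed separately; the slice-selective NMR variant instead
acquires both phases *in situ* from a single partitioned NMR tube. A
frequency-selective pulse applied during a z pulsed-field gradient
excites only a thin axial slab: the slab thickness is

    Δz = BW / (γ̄ · G)

and its position relative to the solvent interface (placed at the coil
centre) is set by the pulse offset Ω,

    d = Ω / (γ̄ · G),

with BW the pulse bandwidth (Hz), G the gradient amplitude (G/cm) and
γ̄ = γ/2π the gyromagnetic constant (MHz/T; 40.06 for ¹⁹F). With a
6 kHz bandwidth under an 8.8 G/cm gradient this gives 1.7 mm slices,
positioned at ±6.4 mm for offsets of ±60 ppm at 9.4 T. Each slice gives
a clean 1D ¹⁹F spectrum of one phase — no solvent background, no
reference compound — and because the slice volumes are identical,

    log P = log₁₀(I_oct / I_aq)

for identically scaled integrals *I* over a 1 ppm window centred on each
signal. The measurement uncertainty is propagated from the
signal-to-noise ratios as σ = √(SNR_oct⁻² + SNR_aq⁻²)/ln 10, and summed-
vs. separate-spectrum integration is selected by a 10:1 SNR rule.
Quantitative integrals require a relaxation delay d1 ≥ 5 × T₁ and an
echo delay short against T₂; the simulator models both, so the erosion
of accuracy at short d1 is reproducible.

## Worked example

```r
library(slicelogp)

plan <- plan_slices(nucleus("19F"), proton_freq = 400.13,
                    gradient = gradient_spec(16), bandwidth = 6000, omega = 60)
plan
#> <slice plan>
#>   nucleus          : 19F at 376.50 MHz (1H 400.13 MHz)
#>   gradient         : 16% of 55 G/cm = 8.8 G/cm
#>   pulse bandwidth  : 6000 Hz
#>   slice thickness  : 1.70 mm
#>   offsets          : +22589.9 / -22589.9 Hz
#>   slice positions  : +6.41 mm (octanol) / -6.41 mm (aqueous)
#>   valid            : yes

a <- builtin_analytes("4-fluorophenol")
samp <- partition_sample(a, logp_true = 1.77, n_total = 0.027)  # mmol in 270+270 uL
params <- acq_params(o1p = -123.5, seed = 42)
params$noise_sigma <- noise_sigma_for_snr(samp, plan, params, snr_target = 35)

res <- run_pipeline(simulate_pseudo2d(samp, plan, params))
res
#> <log P result>
#>   log P      : 1.7725 +/- 0.0123  (summed mode)
#>   integrals  : oct 0.804258 / aq 0.0135791
#>   SNR        : oct 1470.33 / aq 35.42
#>   both modes : summed 1.7725 / separate 1.7706
#>   truth      : 1.7700 (simulated)
```

The plan reports the slice geometry and flags invalid configurations
(slices straddling the interface or leaving the coil's active region)
instead of erroring. The result carries the two identically scaled
integrals, their SNRs, the integration mode chosen by the 10:1 rule,
log *P* with its propagated uncertainty, and both the summed-mode and
separate-mode values for cross-checking; here the simulated truth of
1.77 is recovered within the reported uncertainty.

The same workflow is scriptable from a shell via the `slicelogp`
executable (`exec/slicelogp`):

```sh
slicelogp plan --proton-freq 400.13                      # geometry table
slicelogp simulate --analyte 4-fluorophenol --out ds --seed 42 --snr 35
slicelogp process --in ds --out result.json
slicelogp report --results result.json
```

Datasets are written either as a Bruker-style directory (binary `ser` +
`acqus` key-value text) or as a portable `*.slogp.json` fixture with a
float64 payload; both round-trip losslessly through `read_dataset()`.

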