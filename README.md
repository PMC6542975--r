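# eisdry

Equivalent-circuit modelling of electrical impedance spectra and
impedance-based moisture estimation for drying plant tissue (onion bulbs and
similar vegetables).

## The problem

During unrefrigerated storage a bulb loses water, and its complex electrical
impedance `Z(ω) = Re(Z) − j·X` rises as the electrolyte-filled tissue dries
out. Electrical impedance spectroscopy (EIS) — scanning a small AC signal
over a set of spot frequencies — is a nondestructive way to follow that
process. Two analyses are standard, and this package implements both:

1. **Equivalent-circuit modelling.** The measured spectrum is fitted with a
   small series/parallel network of resistors (extra- and intracellular
   fluid), capacitors (cell membranes) and constant phase elements (CPEs,
   impedance `1/(P·(jω)^n)`, which model distributed, "depressed-arc"
   membrane capacitance). The package ships the classical plant-tissue
   circuits — Hayden `Re|((Rm|Cm)-Ri)`, simplified Hayden `Re|(Ri-Cm)`,
   CPE-modified `Re|(Ri-CPE)`, double-shell `R1|(C1-(R2|(C2-R3)))` — plus a
   two-relaxation series model `R1-(R2|CPE1)-(R3|C1)`, and fits any of them
   (or any user-written circuit expression) by complex nonlinear least
   squares using Nelder–Mead simplex. Fit quality is reported as mean
   absolute and root-mean-squared *percentage* errors of the real and
   imaginary parts.
2. **Moisture calibration.** Moisture content relative to solid content,
   `M = (m_t − s·m_o)/(s·m_o)` (g water per g solids, solids fraction
   `s = 0.13` by default), is regressed on the impedance magnitude at a spot
   frequency — or on impedance per unit weight, `Zpu = |Z|/(m/1000)` in
   Ω/kg — by ordinary least-squares polynomials, reporting SSE, R² and RMSE.

Because published drying studies rarely release their raw spectra, the
package also contains a synthetic drying-experiment generator
(`simulate_drying()`) that emulates the standard study design (10 samples,
21 days, 27 spot frequencies between 0.5 and 10 kHz) with a documented
moisture→parameter power-law map, so every stage can be exercised and tested
end to end.

## Worked example

```r
library(eisdry)

cfg <- drying_sim_config(seed = 42)   # 10 samples x 21 days, CPE-modified truth
ds  <- simulate_drying(cfg)
ds
#> drying dataset: 10 samples x 21 days = 210 records, 27-point spectra
#> (cpe_modified truth circuit, seed 42)

sp  <- ds$spectra[[record_key("S01", 18)]]   # sample 1, day 18
fit <- fit_model("proposed", sp, fit_options(seed = 1))
fit
#> fit of 'proposed' (modulus weighting): objective 4.82432e-06, converged after 34440 iterations
#>           R1           R2       CPE1.P       CPE1.n           R3           C1
#> 1.996514e+03 7.233061e+03 1.920034e-06 7.867628e-01 2.264852e+03 3.072047e-06
#>   MAE%: real 0.03377 imag 0.04444 | RMSE%: real 0.04177 imag 0.05512
```

The fitted parameters are the circuit elements in SI units (Ω, F, and the
CPE pair `P` in S·s^n with dimensionless exponent `n`); the percentage
errors say the model spectrum tracks the measured real and imaginary parts
to well under 0.1% on this synthetic spectrum with 0.05% measurement noise.

Moisture calibrations at the four conventional analysis frequencies:

```r
cals <- calibration_sweep(ds, c(500, 1100, 5000, 10000))
calibration_table(cals)
#>   frequency_hz degree     slope intercept     sse r_squared    rmse   n
#> 1        10000      1 -0.003317     12.30 0.08631    0.9970 0.02027 210
#> 2         5000      1 -0.003358     12.47 0.08949    0.9969 0.02064 210
#> 3         1100      1 -0.003774     14.02 0.11316    0.9960 0.02321 210
#> 4          500      1 -0.004695     17.52 0.16458    0.9942 0.02799 210
```

Every slope is negative (impedance rises as moisture falls) and the
correlation strengthens toward high frequency, where the current penetrates
the cells — the expected β-dispersion behaviour.

A command-line wrapper with `simulate`, `fit`, `compare`, `calibrate` and
`predict` subcommands is installed at `inst/scripts/eisdry`; see
`?eisdry_cli`.

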