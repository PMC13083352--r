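# silentsub

Silent substitution stimulus design for multiprimary visual stimulators.

Photoreceptor-directed stimulation — modulating one photoreceptor class
(L-, M-, S-cones, rods or melanopsin-expressing ipRGCs) while keeping the
excitation of the others constant — is the workhorse of modern flicker
electroretinography and photoreceptor psychophysics. Computing such stimuli
requires combining calibrated primary emission spectra with photoreceptor
fundamentals and inverting the resulting excitation matrix; silentsub does
this for full-field stimulators with 3–5 spectrally distinct primaries
modulated sinusoidally around a mean setting, and additionally answers the
validation question: *how silent is the stimulus really*, for the classes
the device cannot control and for observers whose pre-receptoral filtering
or photopigments deviate from the standard observer.

## The core computation

With area-normalized primary spectra scaled to mean luminances $L_j$, the
excitation of photoreceptor $p$ by primary $j$ is
$a_{pj} = \sum_\lambda R_p(\lambda)\Phi_j(\lambda)\Delta\lambda$. For
sinusoidal modulation with per-primary Michelson contrasts $c_j$, the
photoreceptor excitation contrasts are exactly linear:

$$C = W c, \qquad w_{pj} = a_{pj} \Big/ \sum\nolimits_k a_{pk},$$

so the primary contrasts realizing a requested contrast vector $C$ over
the controlled classes (L, M, S; + rod with 4 primaries; + melanopsin
with 5) are $c = W^{-1} C$. A silent substitution request simply sets
$C_p = 0$ for the silenced classes. Solutions can be rescaled so one
primary reaches 100% contrast (`maximize`), are checked against the
device's luminance ranges, and are forward-evaluated through the full
five-row matrix of a possibly modified observer (macular pigment density,
lens age via the Pokorny–Smith–Lutze model, L/M λ-max shifts) to report
residual contrasts.

## Worked example: rod-isolating stimulus on a 4-primary stimulator

```r
library(silentsub)

dev <- synthetic_device()     # blue/green/amber/red at 4/40/100/80 cd/m2
obs <- synthetic_observer()   # five Gaussian fundamentals, MPOD 0.3, age 40

sol <- silent_substitution(dev, c(L = 0, M = 0, S = 0, rod = 0.2), obs,
                           maximize = TRUE)
summary(sol)
#> <ss_solution> feasible (scale applied 0.8357)
#>  primary Contrast MinLuminance MaxLuminance feasible
#>     blue  -19.51%     3.219610      4.78039     TRUE
#>    green  +67.43%    13.027380     66.97262     TRUE
#>    amber -100.00%     0.000000    200.00000     TRUE
#>      red  +98.60%     1.121792    158.87821     TRUE
#> achieved photoreceptor contrasts (all classes):
#>        L        M        S      rod      mel
#>  -0.000%  +0.000%  -0.000% +16.714% +17.203%
#> not controlled by this device: mel
```

Reading: after maximization the amber primary is the limiting channel at
100% contrast (so raising its mean luminance would buy more rod contrast);
the rod contrast achievable with this device and these settings is 16.7%
Michelson, cones are silenced to numerical precision, and melanopsin — not
controllable with four primaries — rides along at 17.2%. Validation
against a modified observer quantifies how individual differences break
the silence:

```r
val <- achieved_contrasts(dev, sol$contrasts,
                          modify_observer(obs, mpod = 0.6, lens_age = 60))
print(val)
#> <ss_validation> achieved photoreceptor contrasts
#>   observer: MPOD 0.6, lens age 60 y, L +0 nm, M +0 nm
#>   L    -0.3667%
#>   M    -1.2743%
#>   S   +11.1990%
#>   rod +20.0941%
#>   mel +26.1487%  (not controlled by 4-primary device)
```

A dense macula plus an older lens leave an 11% S-cone residual in this
nominally S-silent stimulus — the kind of error the validation panel is
meant to expose.

Spectra import (`read_spectra()`, CSV/xlsx with a wavelength column plus
3–5 named primary columns), JSON/CSV solution export
(`export_solution()`), device bookmarking (`save_device_config()`) and a
command-line interface (`inst/cli/silentsub.R` with `solve`, `validate`,
`spectra` and `demo` subcommands; exit code 0 feasible, 2 infeasible,
1 error) round out the tool. See the vignette
`vignettes/silent-substitution-design.Rmd` for the model, the observer
modifications and all numerical conventions.

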