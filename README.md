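# symmsel

Symmetry-based model selection for age-incidence curves.

## What problem this solves, and for whom

Cancer incidence rises steeply with age, and two mechanistic models
compete to explain it. The **power law model** (PLM), from multistage
carcinogenesis theory,

$$R(t) = A\,t^{\gamma},$$

attributes the rise to the accumulation of $\gamma + 1$ driver
mutations. The **immunological model** (IM) attributes it to
immunosenescence: cancerous clones arise at a constant rate, grow as a
birth–death process, and progress only if they cross an immune escape
threshold that decays with T-cell output
($\alpha = 0.044\ \mathrm{yr}^{-1}$, halving every ~16 years), giving

$$R(t) = \frac{A}{\exp\!\big(e^{-\alpha (t-\tau)}\big) - C}.$$

Both families fit typical registry incidence series almost equally
well, so choosing between them by residuals (even with complexity
penalties) is unreliable — and the choice matters, because it is a
claim about the biological mechanism. This package, aimed at
mathematical-biology and cancer-epidemiology modellers, implements an
alternative criterion based on **Lie symmetries**: each model admits a
one-parameter transformation group $\Gamma_\epsilon$ that maps its own
solution curves onto one another (an age-scaling
$t \mapsto t e^\epsilon$ for the PLM; a parameter-dependent age map
equivalent to shifting $C$ for the IM). The data are transformed by a
candidate's symmetry, the candidate is refitted (only the
symmetry-moved parameter), the fit is pulled back, and its orthogonal
distance RMS against the original data is recorded as a profile
$\mathrm{RMS}(\epsilon)$. *Select the model whose profile stays flat*:
its structural properties, not just its curve shape, are manifest in
the data. A flat-nowhere outcome rejects all candidates — useful
negative information no residual criterion can give.

The package provides the models (including their mechanistic
birth–death parameterization and absorption probability), the four
symmetries with numeric verifiers (group laws, linearized symmetry
condition, reduced characteristic, generator exponentiation),
orthogonal distance regression with compiled foot-point projection, the
selection loop, a synthetic-data generator for in-silico benchmarking,
plotting/`tidy()`/`glance()` methods, and a CLI
(`inst/cli/symmsel`).

## Worked example

Generate a colon-cancer-like series from the power law (reference
parameters $A = 5.78\times 10^{-7}$, $\gamma = 4.60$; rates per
100,000; Gaussian noise on both coordinates), fit both candidates, and
profile each under its own symmetry:

```r
library(symmsel)

d <- generate_incidence_like("colon-plm", seed = 1)
fit_plm <- fit_full(d, "plm")
fit_im  <- fit_full(d, "im")
glance(fit_plm)
#>   model label         m    SS   RMS   eps converged n_starts
#> 1 plm   colon-plm    74  11.6 0.397     0 TRUE             1
tidy(fit_plm)
#>   term     estimate free
#> 1 A     0.000000521 TRUE
#> 2 gamma 4.63        TRUE

profs <- list(symmetry_profile(d, "plm", baseline = fit_plm),
              symmetry_profile(d, "im",  baseline = fit_im))
select_model(profs)
#>   model symmetry    label      rms0 rms_max verdict
#> 1 plm   plm-scaling colon-plm 0.397   0.397 invariant
#> 2 im    im          colon-plm 0.502   0.549 invariant
```

Reading the output: the orthogonal-distance fit recovers the generating
exponent ($\hat\gamma = 4.63$ vs 4.60) with baseline
$\mathrm{RMS}(0) = 0.397$. The PLM's profile is flat to three decimals
across age-doubling transformations — its scaling symmetry is manifest
in the data. The IM profile rises (0.502 → 0.549); on noisy synthetic
data this metric distortion is modest, so always inspect
`autoplot(profs[[2]])` and the raw profile (`tidy()`), not only the
thresholded verdict. The transformation scales that make profiles
comparable are available directly, e.g. the IM parameter that doubles
age 85 under the myeloma-fit pivot age:

```r
transformation_scale("im", im_params(109.54, 76.78, -0.49), n = 2, t = 85)
#> [1] 0.7673906   # ~0.77
```

The same pipeline runs from the shell:

```sh
inst/cli/symmsel simulate --type colon-plm --seed 1 --out data.csv
inst/cli/symmsel select data.csv --models plm,im --min-age 12
```

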