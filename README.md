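# indivobs

Individual colorimetric observer modelling in R: physiologically
parameterised cone fundamentals, Monte Carlo observer populations, and
simulation of metameric colour matches and Rayleigh (anomaloscope) matches.

## Why

Colour-normal people do not share one set of colour matching functions.
Two stimuli that match for one observer can visibly mismatch for another
(observer metamerism), which matters wherever colours are reproduced across
media — display calibration, soft proofing, colour grading.  Average
observers (CIE 1931, CIE 1964, the CIE 2006 physiological observer) predict
a single match; this package predicts the *range* of matches across a
population.

## The model

An individual observer's cone fundamentals are

```
lms = f(a, v, d_lens, d_macula, d_L, d_M, d_S, s_L, s_M, s_S)
```

where `a` (age, years) and `v` (field size, degrees) fix the baseline
average observer, and eight deviation parameters perturb its physiological
components:

| parameter | meaning | unit | population SD (adopted) |
|---|---|---|---|
| `d_lens` | ocular-media (lens) optical density | % | 18.7 |
| `d_macula` | macular pigment peak optical density | % | 36.5 |
| `d_L`, `d_M`, `d_S` | photopigment peak optical densities | % | 9.0, 9.0, 7.4 |
| `s_L`, `s_M`, `s_S` | photopigment lambda-max shifts | nm | 2.0, 1.5, 1.3 |

Percentage deviations act multiplicatively on the corresponding density,
shifts translate the absorbance spectra; the cone absorptances
`1 - 10^(-D_max A_j(lambda - s_j))` are filtered by
`10^(-D_macula - D_ocul)`, converted to energy units, and peak-normalised.
With all deviations zero the model reduces exactly to the average observer.
Sampling the deviations from independent normals with the SDs above
generates CMF populations.  The SDs themselves are derived in two stages:
variance pooling of a literature survey (`pool_sds()`, `derive_step1()`),
then a two-scalar fit against colour-matching variability
(`optimize_scalars()`).

**Note on reference data:** the fixed basis tables (ocular-media
components, macular density spectrum, photopigment absorbances, standard
observer) are shipped as clearly labelled *synthetic stand-ins* generated
from published analytic templates (`synthetic_basis_tables()`).
`load_basis_tables()` accepts a directory of replacement CSVs for users
holding the archival tabulations.  See the vignette for what this does and
does not affect.

## Worked example

```r
library(indivobs)

# one observer: 45 years, 2-degree field, a dense lens, L-cones shifted +2 nm
cf <- cone_fundamentals(observer_spec(age = 45, field_size = 2,
                                      d_lens = 20, s_L = 2))
round(cf$lms[cf$wavelength_nm %in% c(450, 550, 650), ], 4)
#>           l      m      s
#> [1,] 0.0209 0.0396 0.9284
#> [2,] 0.9058 1.0000 0.0029
#> [3,] 0.2028 0.0219 0.0000

# a population of 500 observers, ages 20-60, at the adopted SDs
specs <- sample_observers(500, age_source(range = c(20, 60)),
                          field_size = 8.5, sd_table("step2"), seed = 42)
pop <- generate_population(specs)

# simulate the packaged five-match protocol and summarise observer spread
res <- simulate_matches(pop, generate_fixture_stimuli("five_matches"))
print(res$summary, digits = 3)
#>    label   sd_a  sd_b  sd_ab
#> 1 match1  0.849 1.414  1.132
#> 2 match2  0.877 1.222  1.050
#> 3 match3 14.930 6.167 10.549
#> 4 match4  0.570 0.463  0.516
#> 5 match5  0.771 1.053  0.912

# Rayleigh matches (700/550 nm mixture against 589 nm)
fr <- vapply(pop, rayleigh_match, numeric(1))
signif(sd(fr), 3)
#> [1] 0.00102
```

`sd_ab` is the inter-observer standard deviation of each simulated match in
CIELAB (mean of the a\* and b\* SDs): the neutral broadband matches
(1, 2, 5) spread by about one CIELAB unit, while the saturated cyan
(match 3), far outside the display-like primaries' gamut, is an order of
magnitude more observer-dependent.  The Rayleigh red fraction is on a [0, 1]
radiance scale; its SD quantifies normal L/M variation.

A command-line surface over the same functions is installed at
`inst/cli/indivobs.R` (subcommands `generate`, `population`, `match`,
`rayleigh`, `derive`, `validate`, `fixtures`).

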