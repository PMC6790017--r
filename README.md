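# archfatigue

Fatigue analysis of the medial longitudinal foot arch under cyclic axial
loading.

Adult acquired flatfoot deformity is a progressive collapse of the medial
arch, and high body mass is one of its main risk factors. Cadaveric loading
rigs probe this directly: a foot is fixed under a material testing machine,
loaded from 0 N to a peak of 500 N (normal body weight) or 1000 N (class
I–II obesity, with or without an arch-support insole) once per second for
10,000 cycles — about 20,000 steps — while a marker on the navicular
tuberosity is tracked optically and the posterior tibial tendon is towed
with a 32 N servo once axial load passes 150 N. `archfatigue` is the
analysis side of such an experiment: it turns the raw multi-channel traces
into per-cycle arch metrics, fits the creep trajectory, locates the fatigue
inflection point, and runs the group statistics. A calibrated synthetic
cohort generator stands in for the cadaveric recordings (none are publicly
deposited), so the entire pipeline is testable end to end.

## The quantities computed

With navicular height `h` (mm) and foot length `l` (mm):

- **Bony arch index** `BAI = h / l`. Under load, `BAI < 0.21` defines a low
  (flat) arch; 0.21–0.27 is normal.
- **Deformation** `d = h_nwb − h_wb` (mm), the unloaded-minus-loaded height
  difference within one cycle; heights are read at the samples of minimum
  and maximum load (weight-bearing phase = load ≥ 50 N).
- **Flexibility** `= 1000·d / F` (μm/N) at peak load `F`.
- **Energy absorption** `E = (d/1000)·F / 2` (J), the elastic strain energy
  of one cycle.
- **Creep trajectory**: weight-bearing BAI at the checkpoint grid (cycle 1,
  1000, 2000, …, 10,000) is fitted with polynomials of order 1–5; the order
  is chosen by Akaike's information criterion in its Gaussian form,
  `AIC = n{log(2π·Se/n) + 1} + 2(p + 1)`, which selects the cubic. The
  stage-II→III fatigue transition is the root of the second derivative,
  `χ0 = −b2 / (3·b3)`.
- **Statistics**: Kolmogorov–Smirnov normality screen; Kruskal–Wallis across
  groups with Bonferroni-adjusted exact rank-sum pairwise tests gated on a
  significant omnibus; Friedman tests of within-group change over cycles;
  mean ± 95% CI group summaries; the first checkpoint at which a group's CI
  upper bound falls below BAI 0.21.

## Worked example

```r
library(archfatigue)

generator_params("obese")
#> <generator_params> group 'obese': 1000 N peak load, 10000 cycles @ 1 Hz (sampled 20 Hz)
#>   trajectory: B(1)=0.240, B(1000)=0.203, stationary inflection at 6500 cycles
#>   deformation: d0 6.0 mm, retained 60% at cycle 10000
#>   noise: marker 0.06 mm, specimen offset SD 0.0065 BAI, inflection jitter SD 548 cycles

coh  <- simulate_cohort(default_cohort_params(), n_per_group = 6, master_seed = 1)
mets <- lapply(coh$traces, function(tr)
  arch_metrics(segment_cycles(tr), tr$foot_length_mm))

fits <- fit_cohort(mets)
fits$fits$obese_01
#> <fatigue_fit> 11 points, candidate orders {1, 2, 3, 4, 5}
#>   selected order 3 by AIC (AIC -65.86, R^2 0.9327)
#>   inflection point(s): 6679.9 cycles

cohort_stats(mets, coh$manifest)
#> <cohort_stats>
#>   low-arch onset (CI upper bound < 0.21):
#>     insole   cycle 8000
#>     normal   never
#>     obese    cycle 2000
#>   within-group Friedman trends:
#>     normal   bai          chi2 =   57.42, p = 1.11e-08
#>     normal   flexibility  chi2 =    9.48, p = 0.487
#>     ...
#>   first-cycle Kruskal-Wallis: bai p = 0.641, flexibility p = 0.000511, energy p = 0.000511
```

Reading: the normal-weight group creeps slowly but keeps a normal arch for
all 10,000 cycles; both 1000 N groups drop significantly below the low-arch
threshold (the obese group much earlier than the insole group) and lose
flexibility and energy-absorbing capacity over time (Friedman p < 10⁻⁸),
while first-cycle BAI does not differ between groups.

The same workflow runs from the shell:

```sh
Rscript inst/scripts/archfatigue.R --outdir out --seed 1 \
    --config inst/extdata/default_config.yaml
```

writing per-specimen trace, cycle and metric tables, the fit report, and
the statistics report under `out/`. `--input-dir` analyses externally
supplied traces (CSV columns `time_s, load_N, tendon_N, navicular_y_mm`
plus a `manifest.csv`) without generation.

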