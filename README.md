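# ihsim — system-dynamics simulation of the disease course in idiopathic hypersomnia

Idiopathic hypersomnia (IH) is a central disorder of hypersomnolence whose
diagnosis rests on a single time point, while the burden patients actually
experience — sleepiness, sleep drunkenness, long unrefreshing sleep, work
and social impairment, comorbidity — evolves over decades. `ihsim` models
that evolution as a stock-and-flow system: every interview-derived clinical
parameter is *dynamized* into a per-year target trajectory on a common
scale, integrated as a target-seeking negative-feedback level, aggregated
into twelve clinical state variables, and summed into an overall-experience
level that can be compared against what the patient reports.

The package is aimed at researchers in sleep medicine and epidemiological
modelling who want a tested, scriptable implementation of this pipeline —
including a calibrated synthetic cohort generator, since the original
interview records are not publicly deposited.

## The model in brief

Each level `PV` seeks a time-varying target `g_t ∈ [−100, 100]` with
adjustment time `d` on a one-year clock (explicit Euler):

    PV_{t+1} = PV_t + cap((g_t − PV_t) / d, g_t)

where the cap bounds one year's movement by the target value — by a signed
minimum (`literal` mode, as in the classic rate law, which repels levels
from negative targets) or by magnitude (`symmetric` mode, the default,
which keeps negative targets attracting). For a constant target the
uncapped recursion converges geometrically: `PV_t = g + (IV − g)(1 − 1/d)^t`.

The twelve aggregates (anxiety, depression, sleep inertia, work and social
impairment, sleepiness, fatigue, naps, nocturnal sleep, other psychiatric
disorders, somatic pathologies, methylphenidate effect, modafinil effect)
combine their member parameters by per-year mean; the overall-experience
level seeks the per-year *sum* of all twelve. Simulated and reported
courses are compared by classifying every year-to-year segment as
decreasing / constant / increasing and pooling the share of matching
segments; scenario contribution tables report each aggregate's absolute
share `100·|s_i| / Σ|s_j|` of the summed output dynamics, with Mann–Whitney
comparisons between scenarios.

See `vignettes/ih-dynamics.Rmd` for the full account of the model,
parameters, defaults and limitations.

## Worked example

```r
library(ihsim)

# a synthetic 43-patient cohort with the study cohort's marginal structure
cfg     <- generator_config(43, seed = 20)
records <- sample_cohort(config = cfg)
models  <- lapply(records, build_patient_model)
results <- lapply(models, simulate_patient)

# patients reporting their own simulated course match it perfectly
records <- attach_reports(records, results, cfg)
fits <- Map(function(rec, res)
  fit_percentage(res$experience, rec$reported_course$values), records, results)
cohort_fit(fits)
#> [1] 100

# scenario contribution analysis
scen <- lapply(stats::setNames(nm = c("baseline", "last5", "medicated_only")),
               function(s) apply_scenario(results, models, s))
head(contribution_table(scen$baseline, "baseline"), 4)
#>                    aggregate signed_sum contribution_percent
#> 1                    Anxiety  -13431.24                  4.4
#> 2                 Depression  -20228.11                  6.7
#> 3              Sleep inertia  -55600.40                 18.3
#> 4 Work and social impairment  -58949.57                 19.4
```

The signed sum is the aggregate's level values summed over patients and
years (negative = net burden); the contribution percent is its share of the
total dynamics. On this synthetic cohort sleep inertia, impairment,
sleepiness and fatigue dominate — the qualitative profile expected for an
IH symptom set — while the stimulant effects contribute small positive
sums.

The same pipeline runs as a four-step analysis:

```sh
Rscript analysis/01_generate_cohort.R   # synthetic cohort + calibration summary
Rscript analysis/02_simulate.R          # dynamization + simulation
Rscript analysis/03_pattern_fit.R       # derivative-sign fit vs report noise
Rscript analysis/04_contributions.R     # scenario tables + Mann-Whitney
```

Step 3, for example, sweeps the report-corruption probability and shows the
pooled fit degrading from ~100% through the mid-70s% (at noise 0.25) to ~0%;
its table lands in `results/fit_by_noise.csv`.

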