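# lynxrescue

Genetic monitoring statistics and an individual-based genetic–demographic
model for planning the genetic rescue of small, reintroduced carnivore
populations, built around the Dinaric Eurasian lynx (*Lynx lynx*)
reinforcement as the motivating case.

Small populations founded by a handful of animals keep losing
heterozygosity to drift even when their census recovers; once the mean
inbreeding coefficient approaches that of a full-sib mating (F ≈ 0.25),
inbreeding depression can pull the population into an extinction vortex.
`lynxrescue` provides both sides of the management problem:

* **Monitoring** — read/write microsatellite genotype tables (long CSV
  and GenePop), observed and Nei's unbiased expected heterozygosity,
  allelic diversity and F<sub>is</sub>; *effective inbreeding* against
  the source gene pool, F<sub>e</sub> = 1 − H<sub>derived</sub>/H<sub>source</sub>,
  traced through time with a 60-sample travelling window; allele-dosage
  PCA; and a bias-corrected linkage-disequilibrium estimator of
  effective population size (Burrows composite r², Waples sampling
  correction, jackknife confidence intervals).
* **Projection** — a forward-time, overlapping-generation simulator in
  which every animal carries a genotype, a pedigree identity-by-descent
  coefficient F, and survives each year with probability
  (1 − m) · e<sup>−B·F</sup>, where B is the number of haploid lethal
  equivalents.  On top of it: calibration of B from the population's
  founding bottleneck, translocation-scenario evaluation against the
  0.15/0.25 inbreeding thresholds, minimum-translocation-size search,
  and a random-forest sensitivity metamodel with mean-decrease-in-impurity
  feature importance.

A synthetic study-data generator emulates the whole monitoring design
(a diverse source population, a bottlenecked descendant of six partially
related founders with 45 years of drift, longitudinal dated sampling,
a 12-animal reinforcement), so every stage is testable without the
original field data.

## Worked example

```r
library(lynxrescue)

study <- generate_study_dataset(seed = 105)   # synthetic stand-in data
study$dataset
#> genotype_dataset: 232 individuals, 19 loci
#> populations: Dinaric (162), Romania (22), Slovakia (48)
#> sampling years: 1979 - 2021

diversity_summary(study$dataset, "Slovakia")
#> population Slovakia (n = 48 individuals)
#>   He = 0.581 +/- 0.035
#>   Ho = 0.575 +/- 0.036
#>   A  = 3.58 +/- 0.309

pre <- subset_genotypes(study$dataset, "Dinaric", to_year = 2018)
diversity_summary(pre)
#> population all (n = 140 individuals)
#>   He = 0.544 +/- 0.037
#>   Ho = 0.558 +/- 0.037
#>   A  = 3.16 +/- 0.220
```

The bottlenecked population is measurably poorer than its source, and
its standing pedigree inbreeding (`mean(study$baseline_f)` ≈ 0.18 here)
has accumulated over 45 simulated years of drift.  Its recent effective
population size, estimated from linkage disequilibrium exactly as a
monitoring programme would:

```r
ld_ne(subset_genotypes(study$dataset, "Dinaric", from_year = 2011))
#> LD Ne estimate: 4.0 (95% CI 2.8-11.5)
#>   mean r^2 = 0.06332 (expectation under sampling 0.02128), S = 50.0
#>   50 individuals, 171 locus pairs, MAF threshold 0.02
```

Projection: calibrate the inbreeding load from the founding, then
compare management scenarios (50 replicates each):

```r
cal  <- calibrate_founders(study$slovakia, n_iterations = 100, seed = 1)
coef(cal)                      # lethal equivalents selected near 1.1
init <- lynx_start_state(generate_source_frequencies(he_target = 0.457,
                                                     population = "Dinaric",
                                                     seed = 2),
                         n0 = 130, baseline_f = cal$baseline_f)
noact <- run_scenario(scenario_spec("no action", n_years = 90), init,
                      source_he = 0.583, n_replicates = 50, seed = 3)
noact$derived$extinction$mean_year   # ~28 years without intervention
```

`run_scenario()` with `reinforcement_schedule()` evaluates the completed
12-animal programme, `minimum_translocation_size()` searches for the
smallest periodic translocation keeping mean IBD below 0.15, and
`build_design()` + `fit_rf_metamodel()` rank which model inputs drive
the projected inbreeding, Ne and heterozygosity.

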