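# rumenassembly

Ecological-assembly analysis for genome-resolved rumen metatranscriptomes:
how much of a rumen microbial community's structure is stochastic (drift +
immigration), and which taxa are under selection?

The package is aimed at microbiome researchers working with longitudinal
cattle feeding-trial designs: species-level genome bins (SGBs) quantified
as read counts across repeated rumen samples from animals classified by
feed efficiency (HFE/LFE) and diet (forage/grain), sampled at several
timepoints.

## What it computes

**Sloan neutral community model (NCM).** For each feed-efficiency group ×
timepoint slice, with metacommunity relative abundance
`p_i = Σ_j a_ij / Σ_ij a_ij` and occurrence frequency `F_i` (fraction of
animals with count ≥ 1), the neutral expectation is

    F̂_i = 1 − BetaCDF(d; α = Nm·p_i, β = Nm·(1 − p_i)),    d = 1/N

where `N` is the mean per-sample read total and `Nm` (community size ×
immigration probability) is the single free parameter, estimated by
Levenberg–Marquardt nonlinear least squares on `log Nm`. Fit quality is
`R² = 1 − SS_res/SS_tot`.

**Selection partitioning.** A 95% Wilson score band around the fitted
curve (binomial n = animals per slice) classifies each SGB as `above`
(positive selection), `neutral`, or `below` (negative selection), with
strict inequalities and ties neutral.

**Uncertainty.** Animal-level bootstrap (resampling animal columns,
refitting everything; 1000 replicates by default) gives percentile
intervals for `Nm` and `R²`; DerSimonian–Laird random-effects
meta-analysis pools the four timepoint estimates per group — `Nm` on the
log scale, `R²` linear — with between-timepoint heterogeneity `τ²`.

**Selection summaries.** Group-level and genus-level above/neutral/below
proportions per timepoint with min–max range strings ("20.4%–28.2%").

**Compositional statistics.** Base-2 CLR transform, Aitchison distance
(Euclidean on CLR), and CLR-difference log2 fold changes with bootstrap
intervals (optionally animal-blocked).

**CAZyme architecture profiling.** Parsing of ordered domain strings
("CBM11+CBM11+CBM11+GH51"), tandem-CBM run detection, per-genome counts
of CBM-associated catalytic enzyme structures, and group comparisons.

**Synthetic data.** A seeded generator reproducing the study design
(2 groups × 4 timepoints × 10 animals, long-tailed metacommunity,
Beta-distributed local abundances, multinomial read sampling, injected
selected taxa concentrated in designated genera), so the full pipeline is
testable without sequence data.

## Worked example

```r
library(rumenassembly)

study <- simulate_study(n_animals_per_cell = 10, n_sgb = 1000,
                        Nm_by_group = c(HFE = 1e4, LFE = 2e4),
                        selection_by_group = list(HFE = c(30, 10)),
                        depth_mean = 5e4, seed = 42)
report <- run_ncm_study(study$counts, study$metadata, B = 100, seed = 1)
report
#> Neutral community model study report
#>   8 slice(s) analyzed, 0 skipped, B = 100
#>   HFE: Nm = 17404 [95% CI 15200-19928];  R^2 = 0.768 [95% CI 0.730-0.806]
#>   LFE: Nm = 29483 [95% CI 26706-32548];  R^2 = 0.903 [95% CI 0.871-0.935]
```

Each group line is the DerSimonian–Laird pool of the four timepoint fits:
`Nm` is the effective immigration parameter (here correctly ordered,
HFE < LFE, matching the simulated truth 1e4 < 2e4 up to the upward bias
discussed in the vignette), and `R²` is the variance in occurrence
frequencies explained by the neutral curve.

```r
tabs <- lapply(report$slices[grep("^HFE", names(report$slices))],
               `[[`, "partition")
names(tabs) <- sub("HFE.", "", names(tabs), fixed = TRUE)
partition_proportions(tabs)$ranges
#>         above       neutral         below
#> "23.6%–28.3%" "69.4%–74.0%"   "1.9%–2.4%"

taxon_selection_ranges(tabs, study$taxonomy, c("TestPos", "Bg01"))$ranges
#>     genus   range_above range_neutral range_below n_timepoints_present
#> 1 TestPos 100.0%–100.0%     0.0%–0.0%   0.0%–0.0%                    4
#> 2    Bg01   25.5%–29.4%   66.7%–74.5%   0.0%–3.9%                    4
```

The genus seeded with persistent positive selection (`TestPos`, 30 SGBs
forced to full occupancy at every timepoint) is recovered at 100% above,
far outside the background genus's range — the contrast, not the
absolute above-fraction, is the signal (see the vignette for why a
20–30% above-fraction arises even under pure neutrality with n = 10
animals).

A thin command-line wrapper over the same functions ships in
`inst/exec/rumenassembly` (subcommands `simulate`, `fit-ncm`,
`run-study`, `summarize`, `clr`, `distance`, `log2fc`, `cbm-profile`;
every run writes a JSON manifest).

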