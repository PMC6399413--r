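# mycotrace

Quantitative tracing of dual ¹³C-CO₂ / ¹⁵N pulse-chase labels through an
ectomycorrhizal plant–soil system, in R.

In a split-root mesocosm, a plant canopy is pulse-labeled with ¹³C-CO₂ while
¹⁵N-labeled ammonium and amino acids are added to a root-inaccessible litter
compartment that only fungal hyphae can reach. Tracking both isotopes through
plant, soil and litter pools, into microbial membrane lipids (PLFA), into
chloroform-labile microbial biomass, and down to single hyphae and attached
cells imaged by NanoSIMS, reveals the bidirectional carbon-for-nitrogen
exchange of the mycorrhizal symbiosis. `mycotrace` implements the full
quantitative layer of such an experiment as composable, tested functions:

- **Isotope arithmetic** — conversions between isotope ratio R, atom
  percent `100·R/(1+R)`, and δ‰ against VPDB/AIR; atom% excess (APE) against
  unlabeled controls; label mass excess `m·APE/100`.
- **Label budgets** — per-compartment excess ¹³C (mg) and ¹⁵N (µg), percent
  of total recovered label with plant/soil+litter aggregates, per-replicate
  mean-of-ratios summaries; chamber CO₂ dose (ppm) and N dose (mg) arithmetic.
- **PLFA stable isotope probing** — internal-standard (FAME 19:0)
  quantification, methanolysis correction
  `PLFA = ((n+1)·FAME − methanol)/n`, biomarker→group assignment
  (Gram-positive, Actinobacteria, Gram-negative, fungal 18:1ω9 / 18:2ω6,9),
  and abundance-weighted group enrichment `Σ wᵢ·APEᵢ / Σ wᵢ`.
- **Chloroform fumigation extraction** — microbial biomass C/N as
  fumigated − unfumigated differences (no conversion factors), microbial
  ¹³C as the atom% difference net of controls, C/N ratios.
- **NanoSIMS ion-count stacks** — multi-page TIFF + JSON container for
  per-cycle count planes; per-pixel atom% maps from monomer
  (¹³C⁻/(¹²C⁻+¹³C⁻)) and dimer (¹²C¹³C⁻/(2·¹²C¹²C⁻+¹²C¹³C⁻)) ion pairs;
  relative N/C and P/C maps; counts/(s·pixel) intensity thresholds; ROI
  compositions from pooled counts with Poisson 1σ uncertainties
  `σ = 100·√(f(1−f)/(a+b))`; Welch t-tests of enrichment against
  natural-abundance controls.
- **Community statistics** — Mann–Whitney U (with a paired signed-rank
  variant), Kruskal–Wallis + Dunn/Bonferroni post-hoc with compact letter
  displays, correspondence analysis by SVD of chi-square standardized
  residuals, and seeded permutation ANOSIM
  `R = (r̄_between − r̄_within)/(M/2)`.
- **Synthetic data** — a seeded generator that emulates the whole
  experiment (pool tables, PLFA peaks, extract pairs, Poisson ion-count
  scenes of a hypha with attached cells) with known ground truth, so every
  stage is testable without instrument data.

All tabular functions take data frames and return tibbles; fitted objects
have `tidy()`/`glance()` methods and `plot_*()`/`autoplot()` figures.

## Worked example

Simulate a seven-box dual-label experiment under the default study
conditions and run the whole tabular pipeline:

```r
library(mycotrace)

sim <- simulate_experiment(experiment_config(), seed = 42)
rep <- pipeline_report(sim$pools, sim$plfa, sim$cfe)
dplyr::select(rep$budget_table, pool, excess_13c_mg, pct_13c, pct_15n)
#>   pool             excess_13c_mg pct_13c pct_15n
#> 1 leaves                  4.43    21.6     0.102
#> 2 stem                    7.47    36.3     1.08
#> 3 roots                   6.17    30.0     5.93
#> 4 rhizosphere_soil        0.904    4.43    4.25
#> 5 bulk_soil               1.48     7.23    9.50
#> 6 litter                  0.0924   0.454  79.1
#> 7 plant_biomass          18.1     87.9     7.11
#> 8 soil_litter             2.47    12.1    92.9
#> 9 total                  20.5    100     100
```

Most recovered ¹³C stays in plant biomass (~88%) with ~12% already moved
below ground 24 h after the pulse, while ~79% of the recovered ¹⁵N remains
in the litter compartment where it was added — the generator's programmed
allocation, recovered through the same code path that would process real
measurements. On the imaging side:

```r
sc   <- simulate_ion_stack(scene_spec(), seed = 42)
rois <- roi_composition(sc$stack, sc$region_mask)
dplyr::select(rois, roi_id, n_pixels, atom_pct_13c_dimer, sigma_13c_dimer)
#>   roi_id n_pixels atom_pct_13c_dimer sigma_13c_dimer
#> 1      1     1064               2.00          0.0130
#> 2      2       63               1.34          0.0376
#> 3      3       63               1.33          0.0376
#> 4      4       63               1.29          0.0371
```

ROI 1 is the hypha lumen (true 2.0 atom% ¹³C), ROIs 2–4 are surface-attached
cells (true 1.3 atom%): pooled-count estimates land within one to two
counting-statistics σ of the generating values.

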