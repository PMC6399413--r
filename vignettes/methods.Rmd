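---
title: "Methods: dual-isotope tracing in a mycorrhizal plant-soil system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-isotope tracing in a mycorrhizal plant-soil system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycotrace)
```

`mycotrace` implements the quantitative layer of a dual ¹³C-CO₂ / ¹⁵N
pulse-chase experiment in an ectomycorrhizal plant–soil mesocosm. This
vignette records the models, conventions and defaults the package commits
to, and why.

## Isotope notation

The canonical internal unit is the atom fraction `f = heavy/(heavy+light)`;
the canonical external unit is atom percent (`100 f`). δ‰ values appear only
at the boundary and always against an explicit standard: VPDB for carbon
(¹³C/¹²C = 0.0111802) and atmospheric N₂ for nitrogen
(¹⁵N/¹⁴N = 0.0036765). These ratios are the field's canonical values; they
are configuration constants (`isotope_standards` in the pipeline config),
not hard-wired, because different laboratories occasionally pin slightly
different reference ratios. All conversions round-trip to within 1e-12 over
atom% in (0, 99.9].

Enrichment is always expressed as atom percent *excess* (APE): sample atom%
minus the mean of matched natural-abundance controls. Negative APE values —
samples falling below the control through measurement noise — are preserved,
never clipped, so that rank-based tests downstream see undistorted data.
The package keeps absolute atom% and APE strictly apart in both argument
names and outputs; conflating the two (easy to do, since a strongly labeled
pool "looks the same" in either unit) changes values by the ~1.1 atom%
carbon baseline and is a real hazard when ROI ranges and excess values are
reported side by side.

## Dose arithmetic and the label budget

Chamber CO₂ doses are volume ratios: `ppm = V_injected / V_chamber × 1e6`.
The default chamber geometry (1350 × 545 × 320) is interpreted in
millimetres: a metre-scale canopy chamber of ~235 l, for which a 60 ml
injection is ~255 ppm. Read as centimetres the same numbers would describe
a physically implausible 13.5 m chamber and sub-ppm doses, so the package
commits to mm. Nitrogen doses use an elemental molar mass of 14.003 g/mol
by default (ordinary ¹⁴N accounting, which is what makes a 12 ml × 1 mM
dose equal 0.168 mg N); it is configurable for strict ¹⁵N bookkeeping.

`build_budget()` computes, per replicate box, each compartment's excess
tracer mass (`m_C · APE/100`, reported as mg ¹³C and µg ¹⁵N) and its share
of the box total. Shares are computed **per box and then averaged** (mean of
ratios): with allocation varying between replicates, the mean of per-box
percentages and the ratio of mean masses genuinely differ (on the scale of
these data, ~12% vs ~12.2% below ground), and the per-box convention is the
one consistent with reporting a standard error over replicates. The
ratio-of-means variant is exposed alongside (`pct_13c_pooled`) for
comparison. Aggregate rows (plant biomass = leaves+stem+roots;
soil + litter = rhizosphere+bulk+litter) are always recomputed from the
component pools, never stored, so conservation (shares summing to 100) is
checkable at any time. Aggregate standard errors are SEs of the per-box
aggregate values, not propagated component SEs.

## PLFA stable isotope probing

Quantification is single-point against the FAME 19:0 internal standard,
`conc = area/area_istd × amount_istd / dw`, with a relative response factor
of 1 by default and an overridable factor should compound-specific response
calibrations exist. The methanolysis correction removes the one methyl
carbon that derivatization adds from methanol: a FAME with n acyl carbons
mixes n parts lipid carbon with 1 part methanol carbon, so
`PLFA = ((n+1)·FAME − methanol)/n`. The methanol atom% defaults to
natural-abundance carbon (1.10566 atom%) since derivatization methanol is
rarely measured; corrected values outside [0, 100] are flagged, not
clamped. Acyl carbon counts ship as a default table (methyl branches
counted, e.g. 10Me17:0 → 18) and can be overridden.

Group assignment follows the standard diagnostic table: i15:0, a15:0,
i16:0, i17:0, a17:0 → Gram-positive; 10Me17:0 → Actinobacteria; 16:1ω5,
16:1ω7, cy17:0, cy19:0 → Gram-negative; 17:0 → general bacterial;
cis/trans18:1ω9 and 18:2ω6,9 → two *separate* fungal groups (the two fatty
acids vary independently across fungal taxa and respond differently along
the rhizosphere–litter gradient); 16:0, 18:0 → general. 16:1ω5 can also
derive from arbuscular-mycorrhizal fungi, but in host systems that do not
form AM symbioses (beech) it is treated as Gram-negative. ω-notation is
canonicalised ("18:2ω6,9" ≡ "18:2w6,9"). The composite `bacteria_general`
pool is the union of the three diagnostic bacterial groups plus 17:0.

Group enrichment is the abundance-weighted mean of member APEs. "Abundance"
defaults to the per-pool mean biomarker concentration across replicates
(`weight_by = "pool_mean"`), which stabilises the weights against
single-sample concentration noise; per-sample weighting is available. The
group's excess-¹³C mass `Σ concᵢ·APEᵢ/100` satisfies the identity
`mass = weighted-APE × total C / 100` when weights are the same
concentrations — a tested invariant.

## Chloroform fumigation extraction

Microbial biomass C and N are raw fumigated − unfumigated differences with
**no** extraction-efficiency factors (kEC/kEN), so values are directly
comparable only within the experiment. Negative differences are retained
and flagged. Microbial ¹³C is the difference in atom% between fumigated and
unfumigated extracts, net of the same difference in unlabeled controls —
the direct atom%-differencing convention. A mass-balance variant (excess-¹³C
mass difference divided by C mass difference) is provided under an explicit
`variant` flag; it is not the default and the two differ when the biomass
flush is small relative to background DOC. ¹³C in DOC uses unfumigated
extracts only. C/N ratios are computed per replicate and averaged (mean of
ratios), with Nmic ≤ 0 flagged as undefined.

## NanoSIMS ion-count stacks

A stack is one 3-D integer array per mass channel (rows × cols × cycles)
plus dwell time and raster size; persistence is one multi-page 16-bit TIFF
per channel with a JSON sidecar — exact for counts ≤ 65535 per pixel per
cycle, which comfortably covers dwell-time-limited count rates. Vendor
`.im` parsing is deliberately out of scope; `read_ion_stack()` is the
extension point. Dead-time and quasi-simultaneous-arrival corrections are
not applied (`pixel_filter` and the per-channel arrays are the hook if an
upstream correction supplies adjusted counts).

Carbon isotope composition is estimated two ways, and both are always
reported: the monomer ratio `¹³C⁻/(¹²C⁻+¹³C⁻)` and the dimer ratio
`¹²C¹³C⁻/(2·¹²C¹²C⁻+¹²C¹³C⁻)` (two carbon atoms per dimer; one ¹³C per
mixed dimer). Under random pairing of carbon atoms the dimer species are
binomial — P(¹²C¹²C) ∝ (1−f)², P(¹²C¹³C) ∝ 2f(1−f) — which makes the dimer
ratio an unbiased estimator of f and lets the two estimators cross-validate
on synthetic scenes (a tested invariant: agreement within 3 combined σ).
Nitrogen uses `¹²C¹⁵N⁻/(¹²C¹⁴N⁻+¹²C¹⁵N⁻)`. Relative elemental maps
normalise a species by the matrix carbon signal (e.g. (P/C)rel =
³¹P⁻/(¹²C⁻+¹³C⁻)) and are reported in arbitrary units with no calibration
claim. Pixels with a zero denominator are carried as `NA` — masked, never
imputed — so downstream statistics are unbiased.

Intensity thresholds are specified in counts/(s·pixel) and applied to
accumulated counts divided by `dwell × n_cycles`, with `≥` at the boundary.
Masking removes pixels; it never alters surviving values.

ROI statistics pool raw counts over the ROI's pixels and cycles and form
the ratio once (count-weighted pooling) — not a mean of per-pixel ratios,
which would be biased at low counts. Because multilayer boxplot summaries
are conventionally cycle-averaged, the per-cycle pooled series and its mean
are returned alongside; with uniform acquisition the two agree closely, and
discrepancies indicate drift across cycles. The 1σ counting uncertainty of
`f = a/(a+b)` is `√(f(1−f)/(a+b))` (Poisson/binomial propagation; ×100 for
atom%), and `2√(a·x·(a+x))/(2a+x)²` for the dimer form. The exact
uncertainty model behind published error bars is rarely printed; Poisson
propagation is this package's documented choice, and a Monte-Carlo
resampling check in the test suite confirms it to within 5%.

Enrichment against the natural-abundance control uses a two-sided Welch
t-test, with each group also screened by a Kolmogorov–Smirnov test against
a normal with the group's estimated moments. If both groups have zero
variance the limiting convention is p = 1 for equal means and p = 0
otherwise, with a `degenerate` flag.

## Community statistics

All group comparisons are rank-based. Unpaired two-sample comparisons use
the Mann–Whitney U test (exact for small untied samples, tie-corrected
normal approximation otherwise). For paired box-side comparisons — the two
sides of a split-root box share one plant and are not independent — the
package uses the Wilcoxon signed-rank test on within-pair differences.
"Mann–Whitney for paired samples" is a phrase that names no single standard
procedure; signed-rank is the conventional reading, and an exact
sign-permutation test on pair differences (all 2ⁿ sign assignments,
n ≤ 20) is provided as an assumption-lighter alternative. All-tied input
returns the conventional p = 1.

Kruskal–Wallis uses the tie-corrected H with a chi-square reference. Dunn's
post-hoc z statistics on pooled mean ranks use the standard tie correction;
raw two-sided p-values are Bonferroni-multiplied by the number of pairs and
capped at 1, and a compact letter display is derived from the adjusted-p
matrix (groups share a letter iff not significantly different). Reported
significance tiers follow the usual 0.05/0.01/0.001 convention, with
p < 0.001 the threshold for calling ROI enrichment significant.

Correspondence analysis decomposes the chi-square standardized residuals of
the relative frequency table by SVD; scores are returned in principal
coordinates, so weighted score means are zero and Euclidean distances
between row scores reproduce chi-square distances between row profiles
(both tested). Axis "variance explained" labels are inertia fractions
(squared singular values over total inertia). Axis signs are arbitrary in
the decomposition and fixed by the convention that the column with the
largest absolute loading is positive — determinism matters more than the
particular choice. Rank-deficient inputs return fewer axes; a rank-1
(independence) table returns zero axes and zero inertia.

ANOSIM ranks all pairwise dissimilarities once and compares mean
between-group to mean within-group rank, `R = (r̄_B − r̄_W)/(M/2)`.
Significance is by label permutation with the add-one convention
`p = (1+#{R* ≥ R})/(1+n_perm)`, seeded for reproducibility; exhaustive
enumeration over distinct labelings is available for small n, where the
observed labeling counts once in both numerator and denominator. The
default dissimilarity for PLFA abundance matrices is Bray–Curtis (the
community-ecology default; configurable), via `vegan::vegdist`. Singleton
groups contribute no within-group pairs and drop out of the within-group
mean. The hand implementation is cross-checked against `vegan::anosim` (R
statistic) and `vegan::cca` (CA inertias) in the test suite, keeping
implementation and oracle separate.

## The synthetic experiment generator

`simulate_experiment()` emulates the study design the package targets:
seven labeled split-root boxes plus three unlabeled controls; compartment C
and N masses on the published per-box scale; ¹³C allocation fractions
(leaves 20.86%, stem 35.92%, roots 31.47%, rhizosphere soil 4.35%, bulk
soil 7.04%, litter 0.36% — plant ≈ 88%, belowground ≈ 12%) and ¹⁵N
fractions dominated by the litter compartment (78.48%) that received the
tracer; total recovered excess 20.93 mg ¹³C and 319.62 µg ¹⁵N per box.
PLFA group abundances and enrichments are plausible per-pool values chosen
once (litter biomass ≈ 2–3× soil; rhizosphere enrichment strongest; the
fungal 18:2ω6,9 marker declining from rhizosphere to litter), and N
addition multiplies Gram-positive and actinobacterial concentrations on the
N-treated side by 0.6, reproducing the qualitative biomass decline the
analysis layer must detect.

The noise model has two parts, both chosen to be instrument-realistic and
then frozen. Concentrations and masses carry multiplicative lognormal noise
with CV 0.15 (typical between-replicate spread for soil pools). Isotope
measurements carry additive noise specified as δ-scale precision
(`noise_sd_delta`, default 0.2‰ — routine EA/GC-IRMS performance) and
converted to atom% per isotope via `d(atom%)/dδ = 100·R₀/(1000(1+R₀)²)`;
the conversion matters because the same per-mil precision corresponds to
~30× less atom% noise for ¹⁵N than for ¹³C. With both noise sources zeroed
the pipeline recovers every generating fraction exactly (a tested
invariant); under defaults, per-box budget shares scatter by ~1.5 points
(plant ¹³C) and ~3 points (litter ¹⁵N) about the generating values, and the
end-to-end test tolerances (±2 and ±4 points) are three delta-method
standard errors of the seven-box mean under exactly these conditions.

`simulate_ion_stack()` renders a deliberately simple scene — a horizontal
hyphal tube with elliptical cells on its surface — and draws every
channel's per-pixel, per-cycle counts as independent Poisson variates from
the region compositions (defaults: lumen 2.0 atom% ¹³C / 0.50 atom% ¹⁵N,
cells 1.3 / 0.44, background at natural abundance 1.10566 / 0.36630; cells
with elevated N/C and P/C, which is the biomass signature used to delineate
cell ROIs in real data). Geometric realism is explicitly out of scope: the
statistical structure (Poisson counting, binomial dimer pairing, known
region truth) is the contract. Consequently, passing tests demonstrate
correctness of the estimators under the stated count model — they do not
establish robustness to topography, drift between cycles, detector
dead-time or real matrix effects, none of which the generator produces.

## Problem sizes and numerical conventions

The test suite runs the oracle-equivalence check on 200 random stacks
(rasters 3–7 px, 1–4 cycles, all seven channels) against an explicit
pixel/cycle loop; scene recovery on 1000 seeded 24-px, 3-cycle scenes at
true values {0.37, 1.08, 1.5, 2.6} atom% requiring 3σ coverage ≥ 99%; and
rank-test size calibration on 10⁴ null replicates at n = 8 (U test) and
3 × 6 (Kruskal–Wallis), with empirical α required within 0.05 ± 0.01.
These sizes make the full suite complete in well under a minute while
keeping Monte-Carlo error a small fraction of each tolerance. The
acceptance script uses 400 scenes and 5 × 10³ null replicates per test for
the same quantities.

Floating-point conventions: percentage-conservation checks use absolute
0.05 on a 100-point scale; conversion round-trips 1e-12; CA reproductions
1e-9–1e-10. Ties in ranks use mid-ranks throughout. RNG is always an
explicit seed argument; functions that permute restore the caller's RNG
state.

## Known limitations

- No isotope fractionation corrections; tracer-level enrichments dominate
  natural fractionation here, but near-natural-abundance work would need
  them.
- CFE values carry no extraction-efficiency factors by design.
- The NanoSIMS layer has no image registration or drift correction between
  cycles, no dead-time/QSA correction, and reads no vendor formats.
- The generator's scene geometry is schematic; its tabular noise model is
  lognormal × Gaussian and does not emulate correlated instrument drift or
  batch effects.
- Exact ANOSIM enumeration and the sign-permutation test are limited to
  small n (≤ 9 observations and ≤ 20 pairs respectively) by combinatorial
  growth.
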