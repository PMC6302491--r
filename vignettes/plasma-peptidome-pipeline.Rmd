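---
title: "Differential analysis of plasma peptidome spectral counts and intensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential analysis of plasma peptidome spectral counts and intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdiff)
library(dplyr)
```

## The problem

Endogenous tryptic peptides — peptides cleaved from plasma proteins in vivo or
ex vivo by tryptic-like activity, without any laboratory digestion — can be
randomly and independently sampled from extracted plasma by LC–ESI–MS/MS.
Database search engines redundantly correlate each MS/MS spectrum to candidate
peptide sequences; after filtering, two independent lines of statistical
evidence distinguish disease from control plasma:

1. **Observation frequency (spectral counting).** The number of accepted
   peptide-spectrum matches (PSMs) per gene symbol per treatment is a
   semi-quantitative abundance proxy. After correcting for unequal sampling
   depth between treatments, large count differences are screened with a
   pseudocount-protected chi-square statistic.
2. **Precursor intensity.** The log10 precursor ion counts of accepted PSMs
   are approximately Gaussian and support a per-gene ANOVA across treatments
   with all-pairs Tukey–Kramer comparisons.

`pepdiff` implements both analyses as a tested, seedable pipeline, together
with a synthetic cohort generator whose ground truth (the truth log) makes
end-to-end recovery testable. Everything is tibble-in/tibble-out and composes
with the pipe.

## Acceptance rules for PSMs

A candidate PSM table has one row per (spectrum, candidate peptide, engine).
The acceptance cascade, in order:

* **Assignment.** Rows with no peptide (unassignable noise spectra) are
  dropped.
* **Intensity threshold.** Precursor intensity must be *strictly* greater
  than 1e4 counts. This working threshold sits at the 99th percentile of the
  noise intensity distribution, with median signal roughly one hundred times
  the median noise.
* **Best fit per spectrum.** Exactly one candidate survives per spectrum so
  no MS/MS spectrum is ever counted twice. Survivor: maximal score, then
  charge +2 over +3, then the lexicographically smaller peptide string. The
  last two steps only break exact score ties; a total order guarantees
  determinism. Selection runs within engine by default (engines are pooled
  afterwards); `engine =` restricts to a single engine because whether the
  original workflow deduplicated across engines is not documented — both
  readings stay testable.
* **Tryptic context.** The peptide must be fully tryptic in at least one
  mapped protein: preceded by K/R or the protein N-terminus, ending in K/R or
  at the protein C-terminus. Accepted charges are +2 and +3 only.
* **Pools.** A PSM is `STYP` iff it carries at least one phospho-S/T/Y
  modification, else `TRYP`. The two pools are analysed in parallel and never
  mixed within a frequency contrast.
* **Gene symbols.** Accessions collapse to the distinct gene symbols owning
  them. A peptide matching several accessions of one symbol counts once; a
  peptide spanning several symbols is flagged degenerate and contributes one
  count to each symbol (symbol-level tables report aggregates without a
  documented degeneracy resolution, so the flag is carried through rather
  than resolved).

## Frequency correction and the chi-square screen

Let `D_g` and `C_g` be accepted counts for gene symbol `g` in the disease and
control treatment, and `T_D`, `T_C` the treatment totals. Control counts are
scaled to the disease sampling depth,

```
C'_g = C_g * T_D / T_C ,
```

leaving disease counts untouched (their raw values are what the result tables
print). The correction conserves mass: the corrected control column sums
exactly to the disease total, so the delta distribution
`delta_g = D_g - C'_g` has mean zero on a null cohort — the quantile
diagnostic (`delta_quantile_diagnostic()`, `plot_delta_quantiles()`) makes
that visible and is the standard check that correction happened before
testing.

Each symbol is then screened with

```
chi2_g = (D_g - C'_g)^2 / (C'_g + 1)
```

The `+1` pseudocount keeps the statistic finite for symbols absent from the
control. Following the field's convention, `chi2_g` is referred to the
chi-square distribution with one degree of freedom, and p-values are
BH-adjusted within pool. Two caveats are deliberate:

* With the pseudocount (and a non-integer corrected control), the statistic
  is *not* exactly chi-square distributed under the null. The package
  reproduces the conventional p-value and leaves calibration questions to
  simulation: the recovery tests report the empirical false-selection rate on
  null cohorts instead of asserting a null distribution.
* Selection uses joint thresholds. The exploratory rule takes
  `chi2 > 15` and corrected `delta > 15` (both strict); the stringent
  table rule takes `chi2 >= 60`. Whether the published delta referred to the
  raw or corrected control is not stated; the corrected delta is used,
  consistent with the correction diagnostic.

Per-peptide p-values combine into a cumulative protein p-value by Fisher's
method (`-2 * sum(log p)` on chi-square with `2k` df); Stouffer's z is
available as a strategy switch. The combination method behind the original
"cumulative p-value" is not spelled out in the source literature, so the
default is the most common choice and the switch keeps the alternative
testable. Zero p-values are clamped to the smallest positive double with a
warning rather than propagating `-Inf`.

## Per-gene intensity ANOVA

For each selected gene symbol, log10 precursor intensities are modelled with
sequential (type-I) sums of squares in the fixed order

```
log10_intensity ~ Peptide_Sequence + Treatment_ID + Peptide_Sequence:Treatment_ID
```

matching the row order of standard R `anova()` output that the published
tables reproduce. Unbalanced, missing-cell data are the norm: the
rank-revealing fit drops inestimable interaction cells with degrees of
freedom adjusted accordingly, a single-peptide gene drops the peptide term
entirely, and a saturated fit (zero residual df) reports `NA` F/p with a
warning. Treatment summaries report the sample mean, SD (n−1 denominator),
SE = SD/sqrt(n) and n; singleton treatments print `NA` SD/SE.

Tukey–Kramer HSD compares all treatment pairs with the unequal-n standard
error `sqrt((MS_resid/2)(1/n_i + 1/n_j))` against the studentized range
critical value `q(alpha, k, df)`; at `k = 2` this reduces exactly to the
pooled two-sided t-test. Letters come from an insert-and-absorb construction
whose invariant — two treatments share a letter iff their difference is not
significant — is asserted by a property test on random problems.

Two design choices were genuinely open:

* **Which means carry the letters.** Least-squares means from the full model
  are undefined whenever a (peptide, treatment) cell is missing, which
  happens routinely here. The letters are therefore computed on the raw
  per-treatment means — the same means the report prints — while the error
  term is the *two-way model's* residual mean square, so the shared error
  still accounts for peptide structure. `error_model = "one_way"` re-derives
  the error from a one-way fit for sensitivity analysis.
* **Singletons.** Treatments with n = 1 stay in the model and in the pairwise
  tests via the unequal-n formula; they are never excluded.

## The synthetic cohort generator

No public PSM-level data accompany the study design this package targets, so
the generator is first-class, tested code that emulates the statistical
structure the downstream analysis assumes — not the physics of
chromatography or fragmentation (no retention times, no fragment spectra, no
engine score models).

* **Library.** `generate_protein_library()` builds proteins as concatenations
  of fully tryptic peptides (6–30 residues, terminal K/R, no internal K/R),
  so in-silico digestion recovers a known pool. Accessions of one symbol
  share core peptides and add isoform-specific ones, reproducing
  several-accessions-per-symbol mapping. The number of peptides per symbol is
  a tunable (shifted geometric, mean 8) because the empirical peptide-count
  distribution per protein is not documented.
* **Sampling model.** Per (sample, fraction), assignable spectra draw
  peptides *without replacement* from the pool with per-symbol weights —
  the simplest model consistent with random and independent sampling.
  Planted effects multiply their symbol's weight in the target treatment;
  acute-phase symbols are elevated (default 2x) in every disease-class
  treatment; ice-cold treatments multiply detection probability by 0.1 by
  default (a global scale, not per-protein effects, matching the broad
  "not detected in ice-cold plasma" behaviour).
* **Noise geometry.** Noise intensities are log-normal with
  `meanlog = log(1e4) - qnorm(0.99) * sdlog` (sdlog = 1), pinning the 99th
  percentile to the 1e4-count threshold; signal medians sit 100x above noise
  medians. `noise_fraction = 0.88` reproduces a low-teens percent fit rate
  on non-ice-cold treatments. Per-peptide log10 offsets (SD 0.3) and
  within-peptide residuals (SD 0.25) give log10 SDs in the 0.2–1.0 range the
  published summaries show.
* **Redundancy.** 30% of assigned spectra carry a second candidate at the
  other charge state with a lower score (same precursor m/z and intensity —
  a precursor is a spectrum property); optionally a second engine re-reports
  candidates with jittered scores. This is what the best-fit filter exists
  to remove.
* **Seeding.** One global integer seed draws the cross-sample latent
  structure (symbol weights, peptide offsets) and fans out to deterministic
  per-sample substreams, so cohorts are byte-reproducible and samples are
  independent.
* **STYP treatments** draw only from phospho-eligible (S/T/Y-containing)
  peptides and attach one phospho modification, mirroring the parallel
  phosphopeptide search of the same recordings as a separate treatment id.

What passing tests on these cohorts do **not** show: robustness to
correlated engine errors, retention-time or batch structure, intensity
saturation, real isoform complexity, or non-log-normal abundance tails. The
generator validates the statistical machinery, not the mass spectrometry.

## Numerical choices and degenerate inputs

* The intensity threshold is strict (`>`), per the working definition.
* `chi_square()` rejects negative inputs; `chi2 = 0` iff disease equals
  corrected control.
* BH is `stats::p.adjust(method = "BH")`, applied within pool.
* Tie-breaks in best-fit selection are a documented total order (score,
  charge, peptide string under C-locale collation).
* An all-noise cohort (`noise_fraction = 1`) yields an empty accepted set and
  empty downstream tables rather than errors; zero control totals and
  empty p-value lists are explicit errors.
* QQ diagnostics flag zero-variance samples instead of returning a spurious
  correlation.

## Problem sizes

The test suite and the acceptance script size their simulations to run on a
single CPU in a few minutes while keeping every check well-powered: cohorts
of 40–500 symbols, 2–8 treatments, 1–3 samples per treatment, 4–10 fractions
and 150–2450 spectra per fraction; 100 replicate seeds for recovery rates;
1000 random two-group datasets for the Tukey/t-test equivalence; a 500-symbol
null cohort with the 2.45x depth imbalance for the correction diagnostic.
These sizes are the package's own choices; all of them are parameters, and
larger studies only change runtime.

## Known limitations

* The chi-square screen is a ranking device, not a calibrated test; q-values
  inherit the df = 1 convention.
* Degenerate peptides double-count across symbols by design (flagged, not
  resolved); protein inference is out of scope.
* Network/enrichment analysis of selected gene lists depends on external,
  versioned databases and is limited here to exporting submission-ready
  lists.
* The pipeline consumes PSM tables in a fixed TSV dialect; raw spectrum
  formats (mzML/pepXML) must be converted upstream.
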