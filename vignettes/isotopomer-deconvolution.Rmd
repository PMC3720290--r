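---
title: "Isotopomer-group deconvolution of labelled-metabolite mass spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotopomer-group deconvolution of labelled-metabolite mass spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mida)
```

## The problem

A stable-isotope labelling experiment (e.g. growing bacteria on
[U-^13^C~6~]glucose and hydrolysing the protein into amino acids) produces
metabolites whose molecules carry 0, 1, ..., n heavy atoms. GC-MS resolves
*isotopomer groups* — sets of isotopologues sharing the same number of heavy
atoms, regardless of position — as the peak series M+0, M+1, ..., M+n of a
fragment. Two effects stand between the measured peak heights and the molar
group fractions a flux model needs:

1. **Natural abundance.** Every carbon position is ^13^C with probability
   ~1.11% even without labelling, so each labelled group leaks intensity
   into heavier masses.
2. **Instrumental artefacts** at the window edges: a proton-loss satellite
   at M−1, and contaminating signal above the plausible mass range.

`mida` converts the observed pattern into natural-abundance-corrected
isotopomer-group abundances and an absolute enrichment value, by linear
least squares.

## The model

For a fragment with $n$ labelable atoms and per-atom heavy-isotope
probability $p_1$ (with $p_0 = 1 - p_1$), the natural-abundance envelope is
binomial:

$$A_i = \binom{n}{i} p_0^{\,n-i} p_1^{\,i}, \qquad i = 0 \dots n .$$

A labelled sample with molar group fractions $x_0 \dots x_n$ produces the
predicted pattern $U = x * A$ (discrete convolution): each group's envelope
is the natural one shifted by the group's label count. Writing the
convolution as a matrix, the columns of the *abundance matrix* are shifted,
zero-padded copies of the generator $A$ — a lower-triangular Toeplitz
structure with one row per observed mass offset and one column per group.
Deconvolution is then the linear least-squares problem

$$\hat x = \arg\min_x \lVert \mathbf{A} x - P \rVert_2 ,$$

solved through the Moore–Penrose pseudoinverse. With at least as many usable
peaks as groups the system is over- (or exactly) determined; for a square
system the triangular structure makes the solution identical to forward
substitution, which the test suite exploits as an independent oracle.

Absolute enrichment — the mean fraction of labelled positions per molecule —
follows from the *normalized* fractions $f_i$:

$$\mathrm{Abs} = \frac{1}{a} \sum_{i=0}^{n} f_i \, i \in [0, 1],$$

with $a$ the labelable atom count. For a binomial distribution this equals
$p_1$ exactly (binomial mean $n p_1$), a closed-form identity the tests
check up to $n = 30$.

```{r}
na <- natural_abundance(3)             # 3-carbon fragment, natural 13C
round(normalize_to_percent(na), 6)
absolute_enrichment(as.numeric(na), 3)  # = p1 by the mean identity
```

## Parameters that matter

* **`p1`** (dimensionless fraction, default `0.0111`): per-atom heavy
  isotope abundance. The default is the natural ^13^C value the worked
  alanine example reproduces bit-for-bit; it is a plain argument rather
  than a constant because derivatization and instrument calibration can
  shift the effective value, and ^15^N work needs ~`0.00364`. Whether the
  original desktop tool hard-coded it is unknowable from its outputs; we
  chose configurability with the inferred default.
* **`extra_atoms`** (integer, default 0): carbons contributed by a
  derivatization agent (e.g. TBDMS) that add natural-abundance signal but
  can never be labelled. They widen the generator while the group count
  stays at the metabolite fragment's carbons, so the agent's contribution
  is filtered out of the reported distribution.
* **`max_heavy_atoms`** (integer, default = fragment carbons): sets the
  upper edge `m_max = m0 + max_heavy_atoms` of the usable mass window.
  The default is deliberately conservative; the worked alanine example's
  printed window (`m_max` 19 units above `m0`) is reproduced by passing
  `max_heavy_atoms = 19`. See *Open design points* below.
* **`sv_tol`** (default `1e-12`): relative singular-value cutoff below which
  the system is declared rank-deficient. The error carries the condition
  estimate, which verbose mode also logs for healthy fits.
* **`clamp`** (default `TRUE`): negative fitted abundances are numerical
  artifacts for truly absent groups and are clamped to zero before
  normalization (reports legitimately print exact 0%). Disable to inspect
  raw values; a constrained non-negative solver was considered and left as
  an extension, since clamping reproduces the reference behaviour.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()`/`generate_record()` simulate exactly the generative
assumptions of the correction model: a known fraction vector convolved with
a binomial envelope, scaled, with *multiplicative* Gaussian intensity noise
(relative sd `noise_sd`, truncated at zero) and a fixed +0.1 sub-integer
m/e offset emulating calibration drift. Multiplicative noise was chosen
because MS intensity error is predominantly relative; the reference material
states only an aggregate expectation (errors below 1%), not a noise model.
The jitter is deterministic so offset mapping is exactly testable.

Not emulated: chromatographic peak shapes, detector saturation, fragment
co-elution/contamination, isotope effects on fragmentation, and
multi-isotope elements (Si, S) that would need a multinomial model. A green
recovery test therefore establishes correctness of the *inversion* under
the model's own assumptions — not robustness to violations of them.
`recovery_experiment()` quantifies bias and RMSE per group over replicates;
at 1% relative noise and 500 replicates the per-group bias stays below 0.01,
consistent with the sub-1% error expectation for the numerical stage.

## Numerical choices

* Binomial terms are computed on the log scale (`lchoose`) so fragments
  beyond 20 carbons (derivatized species) cannot overflow, and renormalized
  to sum exactly to 1.
* The pseudoinverse is formed from `svd()` directly rather than the normal
  equations, avoiding the squared condition number; the condition estimate
  is reported.
* Conditioning of triangular systems: when the generator's first entry
  dominates (any natural-abundance envelope with $p_1 < 0.5$) the system is
  well conditioned and the SVD solution agrees with forward substitution to
  1e-10. Arbitrary positive generators can reach condition ~1e13 by
  $n = 10$, where no double-precision algorithm retains 10 significant
  digits — the property tests therefore draw generators from the
  physically meaningful dominant-first-entry family.
* `m0` is the *nearest integer* to the smallest observed m/e (not the
  floor): robust to calibration drift in either direction; an `m0` override
  exists for spectra whose lightest peak is itself the M−1 satellite.
* Missing offsets inside the window are treated as zero-intensity
  observations so the Toeplitz alignment is preserved.
* Writing `.ls` records uses the shortest decimal representation that
  parses back to the identical double, so write→parse round trips are
  bit-exact in both decimal locales.

## Open design points

Three places where the original method description is ambiguous, and the
choices made here:

* **Second regression stage.** The historical description re-draws the
  abundance matrix from "observed relative intensity values" and solves
  again — circular as written, since the output of stage one is also its
  input. The default pipeline is the single, well-posed natural-abundance
  deconvolution; `two_stage = TRUE` implements the re-drawn-matrix reading
  (generator = stage-one reconstruction) as a diagnostic.
* **Mass-window width.** The rule producing the reference window's upper
  edge (19 units above `m0` for a 3-carbon fragment) is unstated and does
  not match any printed atom count. Default here: fragment carbons above
  `m0`, with `max_heavy_atoms` as the override.
* **M−1 handling.** The reference computes M−1 but never says how it
  enters the regression. Here it is excluded from the fit, tagged as an
  M−1 candidate in the `excluded` table, and logged in verbose mode; it is
  *not* prepended as a regression column because the Toeplitz model gives a
  proton-loss peak no defined column.

## Worked example

```{r}
rec <- read_ls(system.file("extdata", "alanine.ls", package = "mida"))[[1]]
estimate_mass_window(rec, max_heavy_atoms = 19)
res <- analyze_records(list(rec), max_heavy_atoms = 19)[[1]]
res$result
```

The labelled-sample percentages reported for this fragment by the original
desktop tool (~70% unlabelled, ~30% fully labelled, 0% in between, absolute
enrichment 30.0%) are *not* reachable from the raw intensities by any
unambiguous reading of its printed equations — its intermediate fitted
vector appears to involve an undocumented step. The enrichment stage is
therefore validated against that printed fitted vector taken as input,
while the deconvolution stage is validated by property (round trips,
oracle equivalence, noisy recovery) on synthetic data:

```{r}
isotopomer_result(natural_abundance(3),
                  c(1.01811623727288, 0, 0, 0.436317933953475))
```

## Known limitations

* Strictly binomial (two-isotope) elements; no multinomial correction for
  Si/S from derivatization agents.
* Group-level (not positional) isotopomer resolution — an MS-physics limit,
  not a software one.
* No peak integration: input is integrated relative intensities from vendor
  software.
* Clamping is a projection, not a constrained fit; heavily noisy spectra
  with many near-zero groups would benefit from true NNLS.
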