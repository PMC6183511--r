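---
title: "Two-phase counting of uneven assemblages: model, estimator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase counting of uneven assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raricount)
```

## The counting model

A sample contains specimens from $S$ species with true relative abundances
$p_1 \ge p_2 \ge \dots \ge p_S$, $\sum_i p_i = 1$. An observer scans the
sample (a microscope slide, a quadrat, a transect) and identifies specimens
one at a time; we model the identified sequence as i.i.d. multinomial draws
from $(p_i)$. Observational effort is measured in **tracks** — traverses of
the slide — and we treat a track as a linear unit of effort: twice the
tracks, twice the expected encounters of every species. This linearity is
the single substantive assumption behind the combination estimator below;
it ignores spatial patchiness of specimens on real slides (see
*Limitations*).

Counting proceeds in two phases:

1. **Full phase.** Every specimen encountered is recorded, until $N_{full}$
   specimens have been counted over $T_{full}$ tracks.
2. **Rare phase.** The observer excludes the common species — those whose
   full-phase share exceeds a threshold $c$ — and continues for $T_{rare}$
   tracks, recording only non-excluded specimens. Encounters with excluded
   species consume effort but are not recorded; this is exactly what a
   human does when mentally blocking out the dominants, and it is what
   makes the rare phase fast.

### The effort-scaled estimator

For an excluded species $i$ with full-phase count $n_i$, the per-track
encounter rate is $n_i / T_{full}$. Extrapolating that rate over the rare
phase gives the estimated total

$$\hat n_i = n_i \left(1 + \frac{T_{rare}}{T_{full}}\right),$$

while a non-excluded species keeps its raw total
$\hat n_j = n_{full,j} + n_{rare,j}$. Estimated relative abundances are
$\hat p_i = \hat n_i / \sum_k \hat n_k$. The per-track (rather than
per-specimen) extrapolation is the simplest estimator consistent with
tracks as the effort unit; `combined_estimates()` keeps the fractional
$\hat n_i$ unrounded and stores raw counts separately, so the estimate is
always recomputable and alternative extrapolations can be swapped in.
Under the multinomial model $E[n_i] \propto p_i T$ in both phases, so
$\hat p_i$ is consistent as effort grows; the package verifies a mean
absolute relative bias below 2% for the excluded species at
$N_{full} = 2000$, $T_{rare} = 2\,T_{full}$ over 200 simulated surveys.

### Choosing the cut-off

A species at true abundance $p$ counted to $N$ specimens has binomial
standard error $\sqrt{p(1-p)/N}$ on its estimated share; relative to the
share itself,

$$\varepsilon(p, N; z) = \frac{z\sqrt{p(1-p)/N}}{p}.$$

`relative_error()` and `error_landscape()` expose this surface. At the
standard operating point ($p = 0.05$, $N = 2000$, $z = 1$),
$\varepsilon = 0.0975$: a 5% species is pinned down to roughly 4.5%–5.5%,
which is what justifies freezing the dominants at that point. The $z$
multiplier is an explicit argument because error-band conventions differ
($z = 1$ standard error, $z = 1.96$ a 95% band); the default is $z = 1$,
the convention under which the classic "just under 10% of the value" rule
holds. A second consideration handled by `threshold_summary()` is that a
usable threshold must leave *every* sample of a multi-sample study with at
least one species to exclude — raising the cut-off too far means some
samples must be counted entirely in full mode.

### Diversity feedback and the improvement estimator

`collector_curve()` gives the running (specimens, distinct taxa) curve; the
observer stops when it is flat enough for the question at hand, and samples
counted to equal terminal slopes are fairly comparable.
`fit_decaprariis()` fits the hyperbolic saturation curve
$S(n) = S_{max}\, n / (b + n)$, whose asymptote $S_{max}$ estimates
richness at infinite effort; $b$ is the half-saturation sample size.

Rarefaction supplies the expected richness of a subsample of $n$ specimens
drawn without replacement from counts $(N_i)$, total $N$:

$$E[S_n] = \sum_i \left[1 - \binom{N-N_i}{n}\Big/\binom{N}{n}\right],$$

computed in log space (`lchoose`) so $N$ of order $10^4$–$10^5$ cannot
overflow. `rarefy_mc()` is the Monte-Carlo counterpart, retained as an
independent cross-check and for statistics without closed forms.

`improvement_percent()` answers "what did rare mode buy?": with
$n_{actual}$ the number of events actually recorded across both phases and
$S_{obs}$ the distinct taxa recorded, it rarefies the *reconstructed*
assemblage — the combined estimated counts rounded to the nearest integer —
down to $n_{actual}$ to estimate the richness $S_{norare}$ a single-phase
count of the same size would have found, and reports
$100\,(S_{obs} - S_{norare})/S_{norare}$. The reconstructed assemblage is
used because the single-phase counterfactual needs a stand-in for the
common specimens that were deliberately not recorded; the rounding rule is
fixed (nearest integer) and tested. When the subsample size exceeds the
rounded total (possible only through rounding), it is clamped to the total.
By definition the improvement is 0 for sessions with no rare phase or an
empty exclusion set.

## Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `threshold` | exclusion cut-off on full-phase share | 0.05 | the ~5% operating point where $\varepsilon < 10\%$ at $N_{full} = 2000$ |
| `n_full` | specimens counted in full phase | (user) | 1,000–2,000 in practice; fixes the precision of the dominants' shares |
| `specimens_per_track` | specimens encountered per track | 100 | arbitrary scale for the effort unit — real per-track rates vary by slide and are not dictated by the method; only the ratio $T_{rare}/T_{full}$ enters the estimator |
| `z` | error-band multiplier | 1 | standard error; set 1.96 for 95% bands |
| `replicates` | rarefaction replicates in `improvement_percent()` | 1000 | the conventional choice; Monte-Carlo error on $S_{norare}$ is then well below 1 species at the sizes used here |

## The synthetic-data generator

`make_abundances()` provides geometric, Fisher log-series, lognormal
(deterministic quantile spectrum), uniform and explicit abundance models —
the classical shapes of ranked species-abundance distributions, from
strongly uneven to perfectly even. `draw_stream()` produces the i.i.d.
counting stream with track markers every `specimens_per_track` draws, and
`simulate_session()` runs the full two-phase protocol against the true
proportions.

The study conditions used throughout the tests and the acceptance script
are an explicit assemblage of 206 species: 6 commons at 12.5% each (75% of
specimens) plus 200 equally rare species sharing 25%, counted with
$N_{full}$ between 500 and 2,000, a 5% cut-off and
$T_{rare} = 2\,T_{full}$. This mirrors a documented field situation —
excluding the six most common species removes about three quarters of the
specimens, roughly trebling the effective sampling rate for the rare tail —
while remaining small enough that hundreds of replicate surveys run in
minutes (the acceptance script simulates 200 surveys for the bias check and
30 per count size for the improvement curve).

What the generator deliberately does **not** emulate: spatial clustering of
specimens within and across tracks (real tracks are not exchangeable
multinomial blocks), identification error, detection probability varying
with preservation or size, and taxon abundances drifting within a slide.
Passing tests therefore demonstrate the correctness and internal
consistency of the estimators under the stated sampling model, not
robustness to those field realities — notably, patchiness inflates the
variance (though not the mean) of the effort-scaled estimates relative to
the binomial landscape.

## Numerical and design choices

* **Event sourcing.** A session's state is a pure function of its initial
  taxa list plus the ordered action log; `replay_session()` reproduces it
  exactly, and the interactive interface's action log doubles as a replay
  script. Undo is the exact inverse of the last action (count, track, or
  on-the-fly addition) and stops at the rare-mode boundary — the exclusion
  set is a one-time, frozen decision, so un-entering rare mode is not
  allowed. Counting an excluded taxon in rare mode is a hard, classed error
  rather than a silent skip: silent skips would corrupt the record that the
  estimator depends on.
* **Rare mode is entered at most once per session.** Incremental per-taxon
  freezing is a different protocol (with a different estimator) and is out
  of scope.
* **Checkpoints** are versioned JSON (format tag + version field), a
  deliberately internal format distinct from SOD: SOD files are for
  completed, validated counts.
* **Exclusion shares use full-phase counts only**, because the decision is
  made at the mode switch, before any rare counts exist.
* **Curve fitting** uses bounded Levenberg–Marquardt (`minpack.lm::nlsLM`)
  with analytic starting values ($S_{max,0} = 2\max S$, $b_0$ = first $n$
  with $S \ge \max S/2$) and bounds $S_{max} > 0$, $b \ge 0$. Degenerate
  inputs are handled explicitly: fewer than 3 distinct points is an error;
  a constant curve returns its exact limit ($S_{max} = S$, $b = 0$); a
  curvature-free (linear) curve is reported `converged = FALSE` since the
  asymptote is unidentifiable — operationally, a fitted $b$ beyond 20× the
  observed range or $S_{max}$ below the observed maximum flags the fit.
* **Ties** in the exclusion dialog's descending-abundance ordering are
  broken alphabetically by taxon id, so orderings are stable across runs.
* **Randomness** is confined to explicitly seeded calls
  (`withr::with_seed`); no function touches the global RNG stream, and
  identical seeds give byte-identical streams, sessions and files.
* **SOD layout.** The four blocks are written as a UTF-8 tab-delimited
  grid: file metadata upper-left (label, value), per-sample metadata
  upper-right (label column 4, one value column per sample), taxa name
  parts lower-left (Genus/Species/Author header), counts lower-right under
  the sample-id header cells — so every value cell has an adjacent label
  and the file opens cleanly in any spreadsheet. The field definitions for
  the O (ocean drilling: Leg/Site/Hole, Core-Section-Interval sample
  naming) and L (land section: Region/Section, Formation/Lithology/Level)
  dialects ship as a data table (`sod_field_definitions()`, also as
  `inst/extdata/sod_field_definitions.tsv`); new types or versions are
  added by editing the table, not the code. Per-phase track counters, the
  exclusion threshold and the excluded-taxa list are stored as sample
  metadata — block D stays raw and integer — which makes the effort-scaled
  estimates recomputable from the file alone (`sod_estimates()`).
  Validation findings carry 1-based row/column grid coordinates
  (spreadsheet convention).
* **Config parsing.** Header names are matched case-insensitively through
  an extendable synonym table; unrecognized columns are preserved verbatim
  in an `extras` column and used nowhere else. A `button = yes` row without
  a label gets a generated abbreviation with a warning rather than an
  error, since minimal genus/species/button files are legitimate.

## A small demonstration

```{r demo}
assemblage <- make_abundances(
  "explicit", weights = c(rep(0.125, 6), rep(0.25 / 200, 200)))
session <- simulate_session(assemblage, n_full = 1000, threshold = 0.05,
                            rare_tracks = 20, specimens_per_track = 100,
                            seed = 42)
session
head(combined_estimates(session), 7)
improvement_percent(session, replicates = 500, seed = 1)
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(fit_decaprariis(collector_curve(session)))
autoplot(error_landscape(seq(0.01, 0.3, by = 0.01),
                         round(exp(seq(log(100), log(10000),
                                       length.out = 30)))))
```

## Known limitations

* The i.i.d. multinomial sampling model ignores spatial structure; on
  patchy slides the track-ratio extrapolation remains unbiased in
  expectation but its variance exceeds the binomial prediction.
* The improvement estimator's counterfactual depends on the reconstructed
  assemblage being adequate for rarefaction; with very short full phases
  the reconstruction itself is noisy, and the reported improvement inherits
  that noise.
* The hyperbolic asymptote is an extrapolation: on curves far from
  saturation it is honest about non-convergence, but a converged fit is
  still only as good as the saturation assumption.
* Exactly one exclusion event per session; per-taxon staggered freezing is
  not supported.
* SOD support covers the O and L dialects at version 1; other dialects
  require extending the definition table.
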