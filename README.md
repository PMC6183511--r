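# raricount

Rare-category point counting with effort-scaled abundance estimation.

## The problem

Ecological and paleontological assemblages are almost always strongly
uneven: a handful of species dominate, and most of the diversity sits in a
long tail of rare species. Counting specimens at random from such a
population wastes nearly all of the observer's time re-counting the same
few dominants, while the rare species — the ones that matter for richness
estimation and biodiversity assessment — trickle in slowly. Observers (for
example micropaleontologists counting radiolarians under the microscope)
therefore use a **two-phase protocol**: count *everything* until the common
species' relative abundances are pinned down (typically 1,000–2,000
specimens), then stop counting species above an abundance cut-off
(typically ~5%) and continue scanning for **rare species only**, which is
several times faster per specimen encountered.

The catch is bookkeeping. To combine the two phases into one abundance
table you must know how much observational effort each phase consumed. The
unit of effort is the **track** — one traverse of a microscope slide —
recorded by a counter the observer clicks while scanning. If an excluded
taxon was counted `n_full` times over `T_full` tracks, its estimated total
after a further `T_rare` tracks of rare-only scanning is

```
n_hat = n_full * (1 + T_rare / T_full)
```

while non-excluded taxa keep their raw totals `n_full + n_rare`; estimated
relative abundances are these totals normalized. The cut-off itself is
justified by the binomial error of a counted proportion, relative to the
proportion:

```
epsilon = z * sqrt(p (1 - p) / N) / p
```

At `p = 5%` and `N = 2000` this is 0.0975 — just under 10% of the value, an
abundance band of roughly 4.5%–5.5% — which is why "stop at 1,000–2,000
specimens, exclude above ~5%" is a sound rule of thumb.

`raricount` implements this whole workflow as a scriptable R package:

* an **event-sourced counting session** (`count_session()`,
  `record_count()`, `undo_last()`, `increment_track()`,
  `enter_rare_mode()`, `add_taxon()`) with checkpoint/resume and exact
  replay;
* the **statistical core**: `suggest_exclusions()`,
  `combined_estimates()`, `relative_error()`, `error_landscape()`,
  `eliminated_fraction()`, `threshold_summary()`;
* **diversity feedback**: collector's curves (`collector_curve()`),
  closed-form and Monte-Carlo rarefaction (`expected_richness()`,
  `rarefy_mc()`), hyperbolic de Caprariis asymptote fits
  (`fit_decaprariis()`), and `improvement_percent()`, the rarefaction-based
  estimate of how many more species two-phase counting yielded;
* the **SOD (Stratigraphic Occurrence Data) file format**: a versioned,
  self-describing, four-block tab-text layout for occurrence matrices with
  full metadata (`read_sod()`, `write_sod()`, `validate_sod()`,
  `session_to_sod()`, `sod_estimates()`, `sod_to_long()`);
* a **synthetic-assemblage simulator** (`make_abundances()`,
  `draw_stream()`, `simulate_session()`) so every claim is testable without
  field data;
* a **terminal interface**: `run_interactive()` for live counting from
  typed commands, and `run_batch()` / `exec/raricount` for batch use.

## Worked example

Simulate a realistic survey — 206 species, six commons holding 75% of the
specimens — count 1,000 specimens in full mode, exclude everything above
5%, then scan 20 more tracks in rare mode:

```r
library(raricount)

assemblage <- make_abundances(
  "explicit", weights = c(rep(0.125, 6), rep(0.25 / 200, 200)))
session <- simulate_session(assemblage, n_full = 1000, threshold = 0.05,
                            rare_tracks = 20, specimens_per_track = 100,
                            seed = 42)
session
#> <count_session: 206 taxa, 1518 events (1000 full / 518 rare), mode=rare, tracks 10+20>
#>   excluded in rare mode: sp001, sp005, sp002, sp004, sp003, sp006

head(combined_estimates(session), 8)
#>   taxon_id n_full n_rare estimated_count proportion basis
#> 1 sp001       144      0             432    0.145   effort_scaled
#> 2 sp002       128      0             384    0.129   effort_scaled
#> ...
#> 7 sp007         0      6               6    0.00201 observed
```

The six excluded dominants were each counted ~100–150 times over 10 full
tracks; scanning 20 further tracks without recording them scales their
estimates by `1 + 20/10 = 3` (e.g. 144 → 432), and the normalized
proportions land near the true 12.5%. What did rare mode buy?

```r
improvement_percent(session, replicates = 1000, seed = 1)
#>   improvement_pct S_obs S_norare n_actual replicates  seed
#> 1            13.2   202     178.     1518       1000     1
```

202 species were observed; rarefying the reconstructed assemblage back to
the same 1,518 recorded events says single-phase counting would have found
about 178 — a 13% richness gain, which grows sharply for smaller full
counts. The error rule behind the 5% cut-off:

```r
relative_error(p = 0.05, N = 2000)
#>      p    N z epsilon
#>   0.05 2000 1  0.0975
```

Results are saved as a self-describing SOD file whose estimates can be
recomputed from the file alone:

```r
doc <- session_to_sod(session, metadata = list(
  file_type = "O", site = "751", hole = "A",
  sample_id = "751A-6H-6, 98-100"))
write_sod(doc, "count.sod")
sod_estimates(read_sod("count.sod"))
```

A shell entry point wraps the batch commands:

```sh
exec/raricount simulate --species 206 --model lognormal --param 1.5 \
    --n-full 1000 --threshold 0.05 --rare-tracks 20 \
    --specimens-per-track 100 --seed 7 --out session.json
exec/raricount estimate session.json --out estimates.tsv
exec/raricount landscape --p 0.01:0.3:20 --n 100:10000:20 --out landscape.tsv
```

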