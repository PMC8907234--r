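# cotransl

Detecting and modelling co-translational protein-complex assembly.

Large complexes such as the nuclear pore complex face a combinatorial
problem: the more subunits and surfaces in play, the more promiscuous
interactions compete with the specific ones, and the longer an orphan
subunit waits for its partner the likelier it is lost to misassembly or
aggregation. Cells mitigate both by assembling subunits
*co-translationally* — a partner binds the nascent chain as its interaction
surface emerges from the ribosome exit tunnel. `cotransl` provides the
analysis stack for the two experimental readouts of that process and for
the kinetic model that explains its benefit:

* **SeRP enrichment profiles and onset calling.** Selective ribosome
  profiling (SeRP) compares ribosome footprints affinity-purified with a
  bait to the total translatome. Per-codon enrichment
  `E(c) = (smooth(IP) + α) / (smooth(total) + α)` is computed from RPM
  densities with a gliding average (default window 15 codons, pseudocount
  0.5 RPM). The onset of co-translational engagement is the first codon
  where `E(c) ≥ θ·b` (background `b` = 5′-quarter median, `θ = 2`) for a
  sustained run, sharpened by a local negative-binomial step alignment on
  the raw pooled counts; the 30–40-residue exit-tunnel offset then maps the
  onset codon to the nascent-chain residues `[c₀−40, c₀−30]` just exposed,
  which are intersected with annotated interaction motifs.
* **RIP-qPCR calls.** Fold enrichment over the no-bait background,
  `f = 2^(Ct_ctrl − Ct_bait)`, after technical-triplicate QC; a pair is
  co-translational when the mean cycloheximide fold is ≥ 1.5 *and* the
  signal drops significantly under puromycin (two-sided paired t-test,
  α = 0.05) — puromycin releases the nascent chain, so only genuine
  co-translational enrichment collapses.
* **Translatome statistics.** Gene-level total enrichment (TE, the log2
  IP-vs-total footprint share) tested with a re-implemented empirical-Bayes
  moderated t-statistic (method-of-moments prior on the log variances) and
  Benjamini–Hochberg FDR control.
* **Pull-down proteomics.** iBAQ median normalization → bait normalization
  → batch-stratified mutant-vs-wildtype fold changes, and unpaired t-tests
  on log2 folds between protein groups (only when both groups have n > 4).
* **Assembly-yield model.** For a binary assembly tree with per-join
  specificity `s`, orphan hazard `λ`, wait `τ` and co-translational dwell
  factor `δ`, the expected yield is
  `Y = ∏ s_eff × exp(−λ Σ aᵤ)` with
  `s_eff = sδ / (sδ + 1 − s)` and `aᵤ` the exposure of every part from
  birth to joining. Sequential assembly without hazard gives
  `Y = s^(n−1)` — exponential decay in subunit number; hierarchy and
  co-translational capture shrink the exposure sum. A seeded Monte-Carlo
  simulator doubles as an oracle for the closed form.

Seeded generators (`sim_footprints()`, `sim_qpcr_wells()`, `sim_ibaq()`,
`sim_annotation()`) emulate each input, so the entire pipeline runs and is
tested without any external data.

## Worked example

Simulate a two-transcript SeRP experiment — one transcript whose bait
engages the nascent chain at codon 130, one null — then profile and call:

```r
library(cotransl)
library(dplyr)

spec <- serp_sim_spec(n_transcripts = 2, orf_length = 300,
                      onset_codon = c(130, NA), enrichment_fold = 4,
                      mean_depth = 5, nb_dispersion = 0.3, n_replicates = 4)
sim <- sim_footprints(spec, seed = 1)
profile <- serp_enrichment(sim$tracks)
call_onset(profile)
#> # A tibble: 2 × 8
#>   transcript_id detected onset_codon background theta min_run exposure_lo exposure_hi
#>   <chr>         <lgl>          <int>      <dbl> <dbl>   <int>       <dbl>       <dbl>
#> 1 TX0001        TRUE             130      0.477     2      15          90         100
#> 2 TX0002        FALSE             NA      0.479     2      15          NA          NA
```

The engaged transcript is detected with its onset recovered exactly at
codon 130; the exit-tunnel offset places the freshly exposed interaction
surface at residues 90–100. The null transcript is not called.
`autoplot(profile, calls = call_onset(profile))` draws the profiles with
the onset marked.

RIP-qPCR, from Ct wells to the two-criterion call:

```r
wells <- sim_qpcr_wells(true_fold = 4, ct_sd = 0.3, n_bio = 5, seed = 1)
qpcr_calls(wells) |> select(bait, mean_chx, mean_puro, p_value, co_translational)
#> # A tibble: 1 × 5
#>   bait  mean_chx mean_puro p_value co_translational
#>   <chr>    <dbl>     <dbl>   <dbl> <lgl>
#> 1 bait      4.31      1.06 0.00812 TRUE
```

The mean cycloheximide fold (4.31) clears the 1.5 threshold and collapses
to ~1 under puromycin (paired p = 0.008), so the pair is called
co-translational.

Assembly yield, chain versus balanced hierarchy for four subunits
(`s = 0.9`, `λ = 0.1`, `τ = 1`):

```r
glance(closed_form_yield(sequential_pathway(4, s = 0.9, lambda = 0.1)))$yield
#> [1] 0.2963893
glance(closed_form_yield(balanced_pathway(4, s = 0.9, lambda = 0.1)))$yield
#> [1] 0.4000837
```

Both pathways pay the same specificity cost (0.9³ = 0.729), but the chain
accumulates 9 time units of orphan exposure against the balanced tree's 6,
so hierarchy lifts the yield from 0.30 to 0.40. `yield_vs_n()` traces the
exponential decay with subunit number and `simulate_assembly()` verifies
any closed-form value by Monte-Carlo.

See the vignette (`vignettes/cotranslational-assembly.Rmd`) for the full
model descriptions, parameter meanings and numerical conventions.

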