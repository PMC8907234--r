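---
title: "Detecting and modelling co-translational protein-complex assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and modelling co-translational protein-complex assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotransl)
library(dplyr)
```

Many large complexes — the nuclear pore complex being the extreme case —
assemble while some of their subunits are still being synthesized. A subunit
that engages its partner co-translationally is captured as a ribosome-nascent
chain complex: its interaction surface is bound as soon as it emerges from
the exit tunnel, before promiscuous binders can reach it and before the
orphan subunit can aggregate. `cotransl` implements the computational side of
detecting such events and of reasoning about why they help:

1. **SeRP enrichment profiles** — selective ribosome profiling compares
   ribosome footprints co-purified with a bait against the total translatome;
   a step-like footprint enrichment along an ORF marks where along synthesis
   the bait engages the nascent chain.
2. **Onset calling** — the first codon of sustained enrichment, mapped
   through the ribosome exit tunnel to the nascent-chain residues exposed at
   that moment.
3. **RIP-qPCR calls** — fold enrichment of a partner mRNA in a bait
   pull-down, with puromycin sensitivity separating co-translational binding
   from mere RNA binding.
4. **Translatome-wide statistics** — a gene-level total-enrichment (TE)
   contrast with an empirical-Bayes moderated t-test and FDR control.
5. **Pull-down proteomics** — iBAQ normalization chains and group
   comparisons for bait co-enrichment.
6. **An assembly-yield model** — a kinetic model of why hierarchical and
   co-translational assembly raise the success rate of multi-subunit
   biogenesis.

Every stage has a matching synthetic-data generator, so the full pipeline is
exercised end to end without external data. All generators are pure
functions of their parameters and a seed.

## SeRP enrichment profiles

Input is a per-codon footprint count track per library (IP or total,
replicate by replicate), either simulated or read from a
`transcript_id / pos_nt / count` TSV with [read_position_counts()].
Nucleotide positions are collapsed by `codon(p) = floor((p-1)/3) + 1` after
an optional P-site offset; positions are treated as already P-site-assigned
by the upstream pipeline, so the offset defaults to 0 nt.

Densities are reads-per-million (RPM); replicates are combined by the mean
of per-replicate RPM (a pooled-count mode exists); each combined track is
smoothed with a centred gliding average (default window `w = 15` codons,
truncated at the ORF edges so the profile keeps the ORF length); and the
enrichment is

$$E(c) = \frac{\mathrm{smooth}(\mathrm{IP})(c) + \alpha}
              {\mathrm{smooth}(\mathrm{total})(c) + \alpha},$$

with pseudocount $\alpha = 0.5$ RPM keeping the ratio finite over sparsely
covered codons. Window, pseudocount and combination rule are free
parameters recorded in the output; no published value fixes them, so the
defaults are conventions chosen for transcripts of a few hundred codons at
a few reads per codon.

```{r serp}
spec <- serp_sim_spec(n_transcripts = 2, orf_length = 300,
                      onset_codon = c(130, NA), enrichment_fold = 4,
                      mean_depth = 5, nb_dispersion = 0.3, n_replicates = 4)
sim <- sim_footprints(spec, seed = 1)
profile <- serp_enrichment(sim$tracks)
head(profile, 3)
```

## Onset calling

Detection is a threshold-run rule. The background $b$ is the median
enrichment over the 5' quarter of the ORF (at least 20 codons; shorter ORFs
fall back to the whole-ORF median). The onset is the first codon where
$E(c) \ge \theta b$ holds for `min_run` consecutive codons, and a
transcript counts as detected only if the mean enrichment from that codon
to the stop codon also clears $\theta b$ — true onsets stay elevated to the
end of the ORF, transient spikes do not. Defaults: $\theta = 2$,
`min_run = 15`. The run length exceeds the smoothing window so that a
single smoothed noise excursion (which spans at most `w` codons) cannot
satisfy the run by itself.

The smoothed crossing localizes the onset only to within roughly half a
window, and at low coverage the crossing jitters further. When pooled raw
IP counts are available the caller therefore sharpens each detected onset
by a local maximum-likelihood step alignment: within ±15 codons of the
run-rule onset it places the step where the negative-binomial likelihood of
the pooled counts is maximal, with the pre/post means taken from 40-codon
flanks and the overdispersion estimated by method of moments; three
re-centred passes are run. Detection itself is never altered — the
alignment only repositions an onset the run rule already found, and
profiles without count columns are called by the run rule alone. In
simulations at 5 reads/codon with heavy overdispersion (NB size 0.3) this
lifts the fraction of onsets within ±5 codons of truth from roughly 70% to
above 90%, close to the ~95% ceiling of a changepoint estimator that knows
the true count distributions.

The exit tunnel buries the 30–40 most recently synthesized residues, so an
onset at codon $c_0$ means residues $[c_0 - 40,\, c_0 - 30]$ (clipped at 1)
have just emerged — the window intersected with annotated motifs by
[annotate_motif_overlap()].

```{r onset}
calls <- call_onset(profile)
calls
```

A noise-free step at codon 130 is called at exactly 130 for any threshold
up to the step height and any run length up to the post-onset run — the
constructed-profile check in the test suite sweeps that grid.

## RIP-qPCR enrichment and the decision rule

Technical triplicates are averaged after a quality rule patterned on
instrument software: a well deviating from the median of its group by more
than 0.5 Ct is omitted (worst first, re-checking), and a group needing two
omissions fails QC, excluding the biological replicate. Fold enrichment of
a bait over the no-bait background is $f = E^{\,Ct_{ctrl} - Ct_{bait}}$
with amplification efficiency $E = 2$ (configurable; no efficiency
calibration is modelled).

A bait–target pair is called co-translational when
(I) the mean cycloheximide fold is at least the signal threshold 1.5
(inclusive), and (II) the signal drops significantly under puromycin —
two-sided paired t-test at $\alpha = 0.05$, paired by biological replicate,
with the CHX mean exceeding the puromycin mean. Zero paired differences are
reported as $p = 1$; a constant non-zero difference (noise-free data) as
$p = 0$; unpairable designs fall back to an unpaired test with a warning.

The generator draws a biological mean Ct per replicate (SD `ct_sd`) and
technical wells around it with the tighter pipetting-scale SD
`min(ct_sd, 0.1)` — triplicates re-measure one cDNA, so giving them the
full biological spread would mostly exercise the QC filter rather than the
decision rule. Puromycin wells are always centred on fold 1: releasing the
nascent chain abolishes a genuinely co-translational enrichment.

```{r qpcr}
wells <- sim_qpcr_wells(true_fold = 4, ct_sd = 0.3, n_bio = 5, seed = 1)
qpcr_calls(wells) |> select(bait, mean_chx, mean_puro, p_value, co_translational)
```

## Translatome-wide TE statistics

For each gene and replicate pair, the total enrichment is
$TE = \log_2\frac{k_{IP} + \alpha}{N_{IP}} - \log_2\frac{k_{tot} + \alpha}{N_{tot}}$
($\alpha = 0.5$ counts). Across genes, [fit_moderated()] shrinks the
per-gene variances: sample variances $s_g^2$ with $d$ degrees of freedom
are modelled as scaled-F draws around a prior $(d_0, s_0^2)$ estimated by
method of moments on $\log s_g^2$ (digamma/trigamma moment matching, with
a Newton inversion of the trigamma function); the moderated statistic is

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}, \qquad
  t_g = \frac{\bar{TE}_g}{\tilde s_g / \sqrt{n}},$$

on $d_0 + d$ degrees of freedom. $d_0 = 0$ recovers the ordinary t-test
and $d_0 \to \infty$ full shrinkage — both limits are tested, and the whole
fit is cross-checked against an independent established implementation in
the test suite. P-values are Benjamini–Hochberg adjusted ([bh_adjust()]
fronts the standard step-up procedure and is tested against a brute-force
implementation of the definition). [event_density()] divides
co-translational events by proteins per group, with collective bindings
collapsed to one event by the caller.

## iBAQ co-enrichment

The normalization chain mirrors pull-down proteomics practice: per-sample
median normalization over the proteins detected in all samples (the
detected set is configurable), division by the bait's iBAQ profile, and
mutant-vs-wildtype ratios stratified by batch so multiplicative batch
effects cancel exactly. Group comparisons (e.g. central-transport Nups vs
cytoplasmic-filament Nups) use a two-sided unpaired t-test on log2 folds,
run only when both groups exceed `min_n = 4` values; smaller groups get
descriptive medians and an explicit untested flag. Log2 folds stabilize the
variance of ratio data; the noise-free chain recovers injected folds
exactly (a property the tests assert).

## The assembly-yield model

An assembly pathway is a binary tree over $n$ subunits with $n-1$ pairwise
joins and deterministic, level-synchronous scheduling: a join fires one
waiting time $\tau$ after the later of its inputs exists. Two failure modes
compete with success:

* **Specificity.** Each join is the specific interaction with probability
  $s$, against the pool of promiscuous alternatives. Co-translational
  capture holds the partners together longer, multiplying the specific
  odds by a dwell factor $\delta \ge 1$:
  $s_{\mathrm{eff}} = \frac{s\delta}{s\delta + (1-s)}$.
* **Orphan hazard.** Every part (subunit or intermediate) accrues exposure
  $a_u$ from its birth (time 0 for subunits, its own join time for
  intermediates) until it joins, and survives with probability
  $e^{-\lambda a_u}$. A co-translationally captured subunit is held at the
  ribosome and accrues no exposure; its join waits $\tau_{tr}$, set by
  translation speed rather than diffusion of dilute species.

The closed-form expected yield is

$$Y = \prod_{\mathrm{joins}} s_{\mathrm{eff}}
      \;\times\; \exp\!\Big(-\lambda \sum_u a_u\Big).$$

For a sequential chain the exposures sum to
$\tau\,(n(n-1)/2 + n - 1)$, so without hazard
$Y = s^{\,n-1}$ — yield decays exponentially with subunit number — and
with hazard $\log Y$ acquires a quadratic term $-\lambda\tau n^2/2$,
decaying even faster. A balanced tree cuts the exposure sum to
$O(n \log n)$, which is the quantitative sense in which hierarchical
assembly rescues large complexes; co-translational flags additionally zero
captured-leaf exposures and raise $s_{\mathrm{eff}}$, so they can only
increase $Y$.

```{r yield}
glance(closed_form_yield(sequential_pathway(4, s = 0.9, lambda = 0.1)))
glance(closed_form_yield(balanced_pathway(4, s = 0.9, lambda = 0.1)))
```

[simulate_assembly()] is a seeded Monte-Carlo oracle: with deterministic
waits it draws the same Bernoulli/survival events the closed form
multiplies, so the two must agree to binomial error (asserted across a
40-point parameter grid); with exponential waits it replaces each diffusive
wait by an exponential of the same mean. Randomizing waits *raises* the
expected yield at equal means — $e^{-\lambda a}$ is convex in the exposure,
so by Jensen's inequality $\mathbb{E}[e^{-\lambda A}] \ge
e^{-\lambda \mathbb{E}[A]}$ — and the property test asserts that
direction.

This exposure-based formulation is this package's concretization of the
verbal model; it is deliberately isolated behind the `assembly_pathway`
interface so a different parameterization can be swapped in. It is not a
spatial or mass-action simulation, and it is not fitted to data.

## What the generators emulate — and what they do not

* **Footprints**: negative-binomial counts per codon (`nb_dispersion` is
  the NB size; variance $\mu + \mu^2/\mathrm{size}$, Poisson as size
  $\to\infty$) with a hard enrichment step (optional linear ramp) and
  independent replicates. Real SeRP adds codon-level occupancy structure
  (pause sites, ramps at start codons), library-specific coverage biases
  and correlated replicates — so passing recovery tests here demonstrates
  estimator correctness under the assumed noise, not performance on any
  particular deposited dataset.
* **qPCR**: Gaussian Ct noise at two scales, perfect efficiency 2 by
  default, no plate effects or reference-gene chains.
* **iBAQ**: log-normal intensities, bait-proportional preys,
  multiplicative batch and sample-scale factors, no missing-value
  mechanism — dropout, the dominant nuisance in real affinity-purification
  MS, is out of scope.

## Numerical choices and edge cases

* Gliding averages truncate at edges (no padding), so profiles keep the
  ORF length; `w` must be odd.
* Zero total density with $\alpha = 0$ is an error advising a pseudocount.
* Zero per-gene variances are floored at $10^{-12}$ before the log-moment
  fit; genes with fewer than two TE replicates are dropped with a message.
* Ties in the onset run rule and in the step alignment resolve to the
  smallest codon (the first onset).
* ORFs shorter than the 20-codon background minimum use the whole-ORF
  median, with a message.
* All simulation entry points take an explicit seed and restore the
  caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen to
keep Monte-Carlo error well below the asserted margins: 200 transcripts of
300 codons (plus 100 null transcripts) for onset recovery, 200 simulation
repetitions for the qPCR operating characteristics, 1,000 genes for the
null FDR check, 20,000 trials per point on a 40-point grid for the
yield-model agreement, and complexes up to 64 subunits for the topology
inequalities.

## Limitations

* One onset per transcript: no multi-onset segmentation and no
  hidden-Markov machinery; the local step alignment refines a single
  detected onset only.
* The TE model is a one-coefficient IP-vs-total contrast; no
  mean-variance weighting and at most a single blocking factor.
* qPCR efficiency is assumed, not estimated from standard curves.
* The yield model's level-synchronous scheduling is an analytic
  convenience; the Monte-Carlo engine's exponential-wait mode is the only
  asynchronous variant.
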