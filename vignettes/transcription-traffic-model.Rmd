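---
title: "Modelling RNA polymerase queuing, elongation kinetics and transcription fidelity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling RNA polymerase queuing, elongation kinetics and transcription fidelity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`polqueue` simulates transcription elongation as a driven lattice gas: a gene
is a one-dimensional lattice of `L` nucleotide sites, and each elongation
complex (an engaged RNA polymerase) is a stochastic stepper whose active site
occupies one lattice position while the complex as a whole covers
`footprint = d` consecutive sites (default 35 nt). The dynamics are those of
a totally asymmetric exclusion process of extended particles with two extra
reactions at designated *pause sites*:

* initiation: when sites `1..d` are all free, a new complex enters at site 1
  with attempt rate `alpha` (1/s);
* stepping: an active complex advances one site with rate `epsilon` (nt/s),
  unless the target site falls inside the footprint of the complex ahead;
* stalling: an active complex sitting on a pause site enters a stalled state
  with rate `f` (1/s); stalled complexes do not move but keep blocking
  traffic;
* rescue: a stalled complex returns to the active state with rate `1/tau`,
  so `tau` (s) is the mean stall duration;
* termination: a complex whose active site passes `L` leaves and counts as a
  completed transcript.

Backtracked or otherwise arrested polymerases are abstracted into the single
stalled state; rescue happens in place (no repositioning), since only the
stall *duration* matters for traffic. The Gre factor's action is expressed as
one of three single-parameter perturbations of a wild-type baseline
(`scenario()`): losing it either prolongs stalls (`tau` x100), makes them
more frequent (`f` x5), or — as a deliberately contrasting hypothesis —
halves the stepping rate. Each scenario changes exactly one kinetic field.

Pause sites are drawn once per gene (uniformly, without replacement, from a
seed) and shared by all complexes and replicate runs: they stand for
sequence-encoded pause signals, not per-molecule accidents.

## The simulation engine

Time advances in fixed steps `dt` (constructor default 0.01 s; the presets
use 0.003 s, see below). Per step each reaction fires with probability
`rate * dt`. Within a step, complexes are updated from the most downstream
to the most upstream, so a complex never reacts to a same-step move of the
complex behind it; initiation is attempted last. A random-permutation update
order is available (`update_order = "random"`) for sensitivity checks — the
invariants hold under both orders.

Numerical guards and biases:

* **Timestep validity.** The engine refuses any parameter set with
  `dt * max(alpha, epsilon, f, 1/tau) > 0.2`. Mean waiting times of the
  discrete geometric clocks are exact at any `dt` (each site costs on
  average `1/epsilon` seconds), but event *interleaving* degrades as the
  per-step probabilities grow. The guard is why the presets pair the
  measured wild-type stepping rate of 62 nt/s with `dt = 0.003` s rather
  than 0.01 s.
* **Stall-before-step.** At a pause site the stall draw precedes the step
  draw within one timestep; the induced bias in the stall count per passage
  is O(`f*dt`), i.e. about 1% at the presets.
* **Saturated current.** At full promoter saturation with `d = 1` the
  steady-state current approaches the maximal-current value `epsilon/4`
  from above by a finite-size correction of order `1/L` plus a
  discretization correction of order `epsilon*dt`; the tests run `L = 300`,
  `epsilon*dt = 0.005` and check agreement within 2.5%. For the extended
  footprint the current stays well below `epsilon/(1+sqrt(d))^2`.

The engine is validated against a closed form: a lone complex's mean transit
time is exactly `(L + n_pause * f * tau) / epsilon`
(`analytic_transit_time()`), and the pause-free transit-time distribution is
a sum of `L` geometric steps whose mean and variance the tests check.

## Default parameters and how they were chosen

| parameter | default | units | rationale |
|---|---|---|---|
| `epsilon` | 62 | nt/s | the wild-type in vivo elongation velocity measured by the two-probe assay |
| `alpha` | 0.3 | 1/s | a moderately expressed gene: initiation-limited, but with enough traffic for queues to matter |
| `d` | 35 | nt | polymerase footprint of the modelling framework this builds on |
| `dt` | 0.003 | s | largest timestep passing the validity guard at 62 nt/s |
| pause density | 0.002 | sites/nt | sparse pause sites (5-6 on the 2700-nt reporter); see below |
| `f` (WT) | 4 | 1/s | per-transit stall probability `n*f/epsilon` of about 17% |
| `tau` (WT) | 0.15 | s | wild-type stalls are brief and kinetically invisible (`n*f*tau/epsilon` < 0.1 s per transit) |
| duration scenario | `tau` x100 = 15 s | s | "long-lived" pauses: far longer than stepping times, comparable to the observation window |
| frequency scenario | `f` x5 from a baseline `f = 0.15`, `tau = 40 s` | | this hypothesis requires rare-but-long pauses already in the wild type |
| stepping scenario | `epsilon` / 2 | | the contrast hypothesis: slower but steady elongation |
| induction window | 150 | s | comparable to a several-minute induction time course; first transit takes ~44 s |

The quantitative kinetic values of the study this package models are not
published, so the defaults were *calibrated to its reported phenomenology*,
which constrains them surprisingly tightly. Three observations must hold
simultaneously under one parameter set:

1. the two-probe velocity of the wild type is ~62 nt/s, and pause scenarios
   leave velocity nearly unchanged while reducing how many complexes reach
   the gene end (late/early slope ratio below 0.9 within the window);
2. the expression cost of losing Gre grows with expression level;
3. that cost is approximately independent of gene length.

Observation 1 needs stall durations comparable to the observation window
(tens of seconds): short pauses relax to steady state too fast and the
slopes equalize. Observations 2-3 limit how strongly pauses may interact:
a stalled complex accumulates a queue of roughly `J * tau` complexes
(`J` = flux), i.e. `J * tau * d` nucleotides of packed polymerases. If that
extent reaches the typical spacing between pause sites, queued complexes
get parked *on* upstream pause sites, where they stall in turn — jams breed
jams, and the throughput then falls steadily with the *number* of pause
sites, making long genes disproportionately sensitive (the finite-buffer
flow-line effect). Sparse pauses (0.002/nt, ~500 nt apart) with
`tau = 15 s` at the default expression level keep the queue extent
(~100-200 nt) below the spacing, and the measured fold change varies by
only ~10-18% over a tenfold length range, while the same preset still
reproduces the slope discrimination. This is also why the pause-site
density was set below an earlier working value of 0.005/nt.

One regime is worth stating openly: at *saturating* initiation rates
(`alpha` around 0.8/s, where the wild type runs at its maximal current),
the model's fold change does grow with gene length under any pause
parameters that also produce the slope signature — serial intermittent
blockers with finite buffers cannot be made length-neutral at full load.
The documented length-independence experiment therefore runs at the default
moderate initiation rate; the saturated-load behaviour is a genuine model
prediction, not an artifact, and can be reproduced with
`sweep_length(..., base_params with alpha = 0.8)`.

`sweep_length()` draws an independent pause-site layout per replicate
(shared between the paired wild-type and scenario arms), so length effects
are averaged over layouts instead of being tied to one random draw — with
only a handful of pause sites on short genes, a single layout is not
representative.

## The virtual two-probe experiment

`simulate_induction()` starts every replicate from an empty lattice (the
moment of induction) and records, every 0.5 s, the run-averaged cumulative
number of transcripts whose active site has passed the 3' end of the early
(`[1, 500]`) and late (`[2201, 2700]`) probe windows — a transcript
hybridizes to a probe only once it contains the full probe sequence.
`estimate_velocity()` then fits a straight line to each signal's rising
phase (the points between 10% and 50% of its final value; the lower cutoff
skips the curved foot, the upper one stays clear of plateau effects), takes
the x-intercepts as onset times, and divides the probe distance (2200 nt)
by the onset difference. Initiation delay cancels in the difference, so the
estimator converges on the stepping rate when pausing is negligible; at
1000 runs it lands within ~1% of the configured 62 nt/s. A
threshold-crossing onset detector (`method = "threshold"`) is provided for
robustness checks; it is exact only when both signals share a common final
value, and the fit method is the default for that reason.

`signal_slopes()` fits the last 40% of the window. With 150-s windows that
region lies beyond the late-probe onset of every preset, including the
half-speed scenario (late onset ~90 s).

## Steady-state experiments

`steady_state_rate()` discards a burn-in (default 10%; the length sweeps
use 25% because a long gene's first transits plus jam relaxation must
complete before sampling), then reports completions per second, the mean
occupancy, and the mean on-gene velocity (accepted steps per complex-second,
so pauses and queuing are included). Rate, occupancy and velocity obey the
flux relation `rate * L / velocity = occupancy` up to boundary terms, which
the tests assert; it is the model's version of "average velocity is what
limits highly expressed genes". Runs that expect fewer than ~100
post-burn-in completions warn; zero completions raise an error rather than
returning 0/0.

Queue statistics define a traffic jam operationally: a maximal run of
complexes at spacing exactly `d` whose most downstream stalled member leads
it; the queue size is the number of complexes packed behind that leader.
Fold changes in the sweeps are wild type / scenario (values above 1 mean
expression is lost without Gre), with bootstrap CIs over replicate runs
(200 resamples by default).

## Synthetic sequencing data and the mismatch pipeline

`generate_reference()` draws a uniform-composition reference (default GC
0.4, the pneumococcal neighbourhood). `generate_reads()` samples 135-nt
read origins uniformly from both strands and applies three independent
Bernoulli substitution channels in biological order — transcription,
reverse transcription, sequencing — each replacing a base with one of the
three alternatives uniformly. A manifest records every read's origin and
the injected positions per channel, so every downstream estimate has ground
truth. Channel masks are drawn from per-channel sub-seeds: two libraries
generated with the same seed but different rates in one channel share the
other channels' error positions exactly (common random numbers), which is
what makes the genotype and enzyme comparisons sharp at moderate read
counts. Qualities follow a phred-38 plateau decaying to 30 over the last 35
cycles, with a 0.5% rate of low-quality bases (phred 3-14) to exercise the
quality filter.

The pipeline applies, in this order: rejection of reads containing a
homopolymer run of five or more (on the *raw* read — the run may sit in the
to-be-trimmed ends), indiscriminate trimming of the first and last 20 bases
(135 to 95 nt), a quality filter (mean phred >= 25 and no base below 15),
exhaustive ungapped mapping against the reference (both strands; a read is
kept only with a unique best placement at <= 6 mismatches; ties are
discarded), and a strand-aware position-by-position tally. `N` bases are
excluded from both numerator and denominator. Note that on random sequence
the homopolymer rule alone removes roughly a third of all reads — the
cascade is deliberately strict. Both the per-base mismatch percentage
(the headline metric) and the fraction of reads carrying at least one
mismatch are reported, because descriptions of such metrics vary; the two
are not interchangeable and both appear in the TSV report.

The estimator is unbiased for the generator's combined per-base error
probability `1 - (1-e_tx)(1-e_rt)(1-e_seq)` (channel collisions contribute
below 1e-5 at the preset rates); the tests check the mean standardized bias
across seeds and a pooled binomial CI. The four library presets
(`fidelity_presets()`) decompose published overall mismatch percentages
(~0.23/0.50% wild type, ~0.24/0.55% mutant for the high-/low-fidelity
enzymes) into channel rates by least squares under additivity; the
enzyme-fidelity ratio (~4.6x) sits inside the 3-6-fold range quoted by the
enzyme's supplier. Only the *orderings* across the grid are treated as
reproducible claims.

What the generator does not emulate: indels (the pipeline is ungapped by
design), realistic position- and context-dependent Illumina error spectra,
PCR duplicates, adapter read-through, and coverage bias. Passing tests
therefore show that the pipeline measures what was injected under its own
error model — not that it would be unbiased on real libraries with indel
errors or systematic miscalls.

## Problem sizes used by the tests

The test suite and the acceptance script size their simulations to run on a
single CPU in a few minutes: 1000-run inductions for velocity estimation,
10^4-10^5 replicates for transit-time oracles, 10^6-step steady-state runs
(3000 s of simulated time) with 6 replicates per sweep point, and 600-900
reads per fidelity library on an 8-10 kb reference. These are a scaled-down
analogue of a full study (which would use ~4.5x10^6-step time averages and
genome-scale references); the statistical design — seeded replicates,
layout averaging, paired seeds, bootstrap CIs — is what keeps the scaled
runs decisive.

## Known limitations

* No backtracking as explicit negative displacement, no premature
  termination or drop-off, and no ribosome coupling; the stalled state
  summarizes all of these as a single dwell.
* Pause strength is site-independent; no DNA sequence is modelled beneath
  the lattice.
* The fixed-timestep scheme slightly overshoots continuous-time currents at
  high per-step probabilities; keep `dt * max rate` well under the 0.2
  guard when measuring currents to better than a few percent.
* Fold changes at saturating initiation rates depend on gene length (see
  above); comparisons across lengths are only meaningful with the
  expression level stated.
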