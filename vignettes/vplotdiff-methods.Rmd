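---
title: "Models and methods in vplotdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in vplotdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
what is modeled, what is assumed, which knobs matter, what the simulator
does and does not emulate, and where the design was genuinely open.

## 1. Fragment-level conventions

All coordinates are 0-based half-open (BED convention); 1-based inclusive
genome-browser spans are converted on input (`from_browser = TRUE`).
A fragment record is the span between two Tn5 insertion events. Because
fragment files carry no per-read strand, the insertion-offset correction is
applied at the fragment level: the left coordinate (always the plus-strand
read start) moves +4 bp and the right coordinate (the minus-strand read
start) moves −5 bp, which is exactly the per-read correction expressed on
the fragment. Every corrected fragment is 9 bp shorter; fragments of ≤ 9 bp
would invert and are dropped and counted rather than silently mangled.

Fragment size classes use the conventional 150-bp boundary. The nucleosomal
class is *strictly* greater than the threshold ("fragment size > 150"), so
a 150-bp fragment is sub-nucleosomal. This tie rule is applied consistently
in `classify_size()`, `size_partitioned_track()`, `occupancy_proxy()` and
the nucleosomal rows of the V-plot log ratio.

Malformed BED lines abort by default with the offending line number; a
permissive mode skips and counts them. Silent corruption is worse than
failure.

## 2. The peak caller

Coverage is per-base fragment overlap. Peak calling slices the genome into
maximal runs of positions with coverage ≥ `min_coverage` (default 10); each
run's summit is its coverage argmax, and the emitted peak is the
`width`-bp interval centered at the summit (default 500 bp for union peak
sets; 200 bp is the conventional width when intersecting with motifs).
Numerical choices:

* **Summit ties break leftmost.** Any rule works; this one is
  deterministic and order-free.
* Peaks are emitted at the fixed width even when the raw run is wider or
  narrower; only clipping at position 0 can shorten a peak, and such peaks
  carry a `clipped` flag.
* Union sets merge overlapping *and bookended* intervals into maximal
  disjoint intervals. Whether the original analyses deduplicated
  summit-centered intervals before merging is not recoverable from printed
  counts; merging is the conservative choice and is noted as a divergence
  risk for full-data reproduction.

Conservation filtering keeps intervals with mean score strictly > 0.8, per
the usual phrasing of phastCons cutoffs.

The consensus scanner uses per-position allowed-base sets (no PWM, no
scoring): patterns like `(A/C/G)AGGAA(G/A)T` are the published form of
ETS-family consensus sequences, and a set-matching scanner reproduces them
exactly. Minus-strand hits are found by scanning the reverse-complemented
pattern and reported in forward coordinates; `N` never matches.

## 3. V-plots

The grid defaults — 640-bp window, 10-bp position bins, fragment sizes
[50, 370) in 10-bp bins, hence a 32 × 64 matrix — keep the matrix small
enough for desk-scale VAE training while resolving the sub-nucleosomal
(< 150 bp) and mono-nucleosomal (~180–250 bp) bands. Only the 640-bp window
width is externally fixed; bin sizes and size bounds are configuration and
full-data work may need them retuned.

A fragment is assigned by its **midpoint** (the standard V-plot
convention), contributing one count iff the midpoint is inside the window
and the length is in `[size_min, size_max)`. Midpoint assignment makes mass
conservation exact: the matrix total equals the number of qualifying
fragments, which the tests assert against a double-loop oracle.

Aggregation normalizes each V-plot to a density and averages; zero-total
regions are *excluded* (and counted) rather than contributing zeros,
because an empty region carries no density information, only depth
information.

The accessibility-ratio track scales both tracks to their mean total mass
inside the window before forming `(num + 1)/(den + 1)`; the normalization
makes the ratio invariant to sequencing depth, and the pseudocount of 1
read is the smallest value that tames empty positions. The occupancy proxy
is a Gaussian kernel sum (sd 20 bp) over nucleosomal-fragment midpoints —
a deliberately transparent stand-in for model-based nucleosome callers,
adequate for locating positioned nucleosomes in simulated data but not a
substitute for occupancy HMMs on real signal.

## 4. The conditional VAE

Each region-by-sample V-plot `x` is modeled as multinomial over grid cells
given a K-dimensional Gaussian latent `z` (K = 5) and the sample indicator
`s`; the encoder approximates the posterior `q(z|x,s)` as a diagonal
Gaussian. Training maximizes the evidence lower bound

    log p(x|s) ≥ E_q(z|x,s) log p(x|z,s) − KL[q(z|x,s) ‖ p(z)]

with a standard-normal prior, one reparameterized Monte Carlo draw per
step, and Adam (learning rate 0.01) under a linear warmup (50 steps) and
cosine decay to zero at `total_steps` (default 2000), batch 64. The KL term
is always the closed form for diagonal Gaussians; `elbo()` additionally
includes the multinomial normalization constant so its value is a true
lower bound on `log p(x|s)`.

Design choices made where the design was open:

* **Decoder family: multinomial.** A V-plot is a vector of counts with a
  fixed total; a multinomial (cross-entropy reconstruction against the
  softmax decoder output) respects that structure and makes the
  reconstruction term well defined without any continuous relaxation.
* **Architecture: one-hidden-layer dense networks** (default width 64,
  ReLU) for encoder and decoder, with the sample one-hot concatenated to
  the input of each. On a 32 × 64 grid at desk scale a dense stack trains
  in seconds and recovers the planted structure; it also keeps the package
  free of deep-learning runtime dependencies, since the gradients are
  hand-derived matrix expressions. Convolutional stacks are the natural
  upgrade path at larger grids but are not required at this problem size
  (this is a deliberate deviation from a convolutional design).
* **Encoder input is the count matrix normalized to a density**, so the
  encoder sees composition, not depth; depth enters the likelihood through
  the multinomial total.
* Log-variances are clamped to ±10 for numerical safety; a non-finite loss
  aborts training naming the step rather than continuing silently.
* All randomness flows from `config$seed`. Training is deterministic per
  seed and platform (floating-point reduction order may differ across BLAS
  backends — the usual caveat).

## 5. The differential test

Replicate posteriors are pooled per condition as the posterior of the
replicate *mean*: pooled mean = average of means, pooled variance =
average variance / number of replicates (replicates are analyzed
separately and averaged). The statistic

    T = Σ_k (μ̄A,k − μ̄B,k)² / (σ̄²A,k + σ̄²B,k)

is the natural Wald-type standardized distance and is referred to the
upper tail of χ²(K) — the named test and degrees of freedom leave the
statistic itself open; posterior *means* (not sampled z's) are used, which
keeps the test deterministic given the model. Under the statistic's own
assumptions T is exactly χ²(K), which the acceptance suite verifies by
Monte Carlo calibration (10,000 null draws, KS uniformity, type-I rate in
[0.03, 0.07]).

Benjamini–Hochberg adjustment is the standard step-up rule, implemented
directly and cross-checked against an independent implementation.

**The log ratio.** The selection rule "adjusted p < 0.05 and log ratio
< −0.2" requires an effect-direction measure that the upstream description
leaves undefined. The package defines it as the log ratio of *central
nucleosomal density*: for each condition's pooled V-plot, the fraction of
mass in size bins with lower edge ≥ 150 bp and position bins inside the
central 200 bp, with a one-count pseudocount applied to the numerator
count and the total (`(c+1)/(T+1)`). The pseudocount sits on counts, not
densities, so it guards empty cells without compressing the scale.
Negative values mean condition A has proportionally fewer central
nucleosomal fragments than B — the sign convention under which nucleosome
displacement in A (increased accessibility) gives log ratio < −0.2. This
is a declared stand-in definition; its sign contract, a hand-computed toy
value, and its behaviour on the simulator are all tested.

Ranking is by ascending adjusted p-value with ascending log ratio as
tie-breaker; a region's percentile is `rank / n`.

## 6. Motif deviation scores

The observed motif count per sample is compared to the expectation
`E[j,n] = (Σ member read fractions) × sample total`; the raw deviation
`(obs − E)/E` is standardized against `n_background = 50` random interval
sets of the same size drawn to match the motif's members on
mean-accessibility decile. Variability is the standard deviation of a
motif's deviations across samples, with an upper-tail empirical p-value
from the background variability distribution (add-one smoothed, so never
exactly zero — resolution is bounded by `1/(n_background+1)`).

Two documented divergences from the original deviation-score tooling:
background matching uses accessibility deciles only (no GC matching, since
sequence composition may be unavailable), and the background distribution
is the p-value reference rather than an analytic null. Deviations are
invariant to uniform global scaling of counts (tested), and the PCA of
deviations fixes component signs by making each component's
largest-magnitude loading positive — explained-variance fractions are what
matter, signs are conventions. Heatmap orders come from Euclidean-distance
average-linkage clustering; no linkage is externally specified, and
average linkage is the common default for deviation heatmaps.

## 7. The simulator: a stated world

`sim_config()` defaults *are* the stated experimental world and are not
tuned per test:

| knob | default | meaning |
|---|---|---|
| `n_regions` / `n_displaced` | 200 / 40 | motif-centric 640-bp regions; displaced in condition B |
| `fragments_per_region` | 300 | per region per sample |
| conditions × replicates | 2 × 2 | condition B is the perturbation |
| `pi_nfr_base` → `pi_nfr_displaced` | 0.2 → 0.7 | sub-nucleosomal mixture weight |
| NFR fragment length | Normal(75, 15) on [30, 150] | sub-nucleosomal band |
| nucleosomal length | Normal(200, 25) on [151, 330] | mono-nucleosomal band |
| `dyads` | 135, 320, 505 | one nucleosome over the central motif, flanked at ~185-bp spacing |
| `nfr_offsets` | 245–395 | central 150-bp nucleosome-free sub-interval |
| `dyad_jitter_sd` | 10 bp | positioning noise |
| `batch_len_shift` | 0 | per-sample length shift (batch effect) |

Sub-nucleosomal midpoints are uniform in the NFR sub-interval; nucleosomal
midpoints snap a uniform draw to the nearest dyad plus jitter. Displacement
raises the sub-nucleosomal weight of the *whole region* from 0.2 to 0.7 in
condition B, which simultaneously depletes central nucleosomal mass — the
V-plot signature the test is built to detect. The dyad geometry (a
nucleosome directly over the motif) encodes the biological premise that
the factor targets nucleosome-occupied motifs.

What the generator does **not** emulate: Tn5 sequence/GC insertion bias,
PCR duplicates, sequencing error, chromatin heterogeneity between cells,
correlated neighboring regions, and real nucleosome spacing disorder. A
green recovery test therefore establishes that the pipeline detects the
modeled effect at the stated effect size and depth — not that it would
attain the same sensitivity on real libraries.

The grouping fixture is constructed so that the default peak caller
recovers the intended open/closed code exactly: "open" regions receive 60
fragments concentrated in the central window (central coverage ≈ 60,
comfortably over the threshold of 10), "closed" regions receive 2 stray
fragments; 2-kb spacing prevents 500-bp peaks from bleeding into
neighbors.

In the planted-motif deviation fixture, baseline interval accessibility is
gamma-distributed rather than flat. With a flat baseline the planted 3×
intervals become the *entire* top accessibility decile, so decile-matched
backgrounds reproduce the planted signal and cancel it — a degenerate
configuration, not a realistic one; heterogeneous baselines are what real
peak sets look like.

## 8. Known limitations

* The dense VAE has no spatial weight sharing; very fine grids or much
  larger region sets would favor the convolutional architecture it
  deliberately forgoes.
* The χ² test conditions on the fitted model; miscalibration of posterior
  variances transfers to the test. The joint selection rule (adjusted p
  *and* log ratio) empirically suppresses the resulting false positives in
  the batch-shift scenario, but the p-values themselves are
  model-conditional.
* The occupancy proxy is descriptive, not a nucleosome caller.
* Deviation-score backgrounds match accessibility only; on real data with
  strong GC effects the scores will differ from GC-matched
  implementations.
* `filter_conserved` consumes precomputed interval-mean scores; it does
  not compute conservation.
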