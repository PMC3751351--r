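---
title: "Genome size and repeat structure from k-mer abundance spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome size and repeat structure from k-mer abundance spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kspectra)
```

## The problem

Short-read shotgun sequencing samples a genome densely but assembles it only
partially: ribosomal RNA (*rrn*) operons, insertion-sequence (IS) elements
and other repeats longer than the read length collapse into single contigs,
so the assembly conceals both the total genome size and how much sequence
exists at each copy number. The information is nevertheless present in the
raw reads. If every overlapping window of k consecutive bases (a *k-mer*,
k = 21 by default) is counted across the read set, single-copy sequence
forms a peak in the histogram of k-mer abundances at the per-k-mer
sequencing depth c, and sequence repeated n times forms a peak at n·c. The
histogram — the *abundance spectrum* — therefore encodes the genome's
repeat structure without any assembly, and `kspectra` recovers it by
fitting a mixture model to the spectrum.

## Counting

K-mers are counted in *canonical* form: a window and its reverse complement
are the same observation on opposite strands, so each window is recorded
under the lexicographic minimum of the pair. For odd k no window is its own
reverse complement, hence there are exactly 4^k / 2 canonical k-mers
(`n_canonical_kmers()`); at k = 15 that is already ~5.4 × 10^8, far more
than the bases in any prokaryotic genome, so k-mers of length ≥ 15 from
single-copy sequence map essentially uniquely. The default k = 21 is long
enough to separate single-copy coding sequence and short enough to detect
small repeated elements; k is accepted in the range 1–31 (the 2-bit rolling
encoding fits a 64-bit word), with 15–31 the analytically sensible range.
Windows containing any non-ACGT symbol are skipped; input is case-folded;
mates of paired-end runs are treated as independent reads, since reads
serve only as k-mer carriers here. Counting is exact (a hash table over
2-bit-encoded k-mers, in C++), intended for desk-scale inputs up to roughly
10^9 bases; probabilistic or disk-backed counting is out of scope.

## The model

Let z_x be the number of distinct canonical k-mers observed exactly x
times. If reads sampled a repeat-free genome uniformly, z_x would follow a
single Poisson shape a_1 · Poisson(x; c), where a_1 is the number of
single-copy k-mers and c the per-k-mer depth. Repeats add components at
integer multiples of c, and real coverage is never perfectly even, which
broadens every peak beyond Poisson. The expected spectrum is therefore

  E[z_x] = Σ_{n=1..N} a_n · NB(x; mean = c·n, alpha = s/n),

a mixture of negative binomial components sharing a single overdispersion
shape s (component n gets dispersion s/n, so absolute peak widths grow like
√n as repeat peaks do). The coefficient a_n is the amount of unique
sequence at copy number n, in k-mers ≈ bp. Two derived quantities summarise
the fit: the number of distinct k-mers N_unique = Σ a_n and the genome size
G = Σ n·a_n, which weights each piece of unique sequence by its copy
number — so multicopy plasmids count in proportion to their molecular
abundance, as they do in the read pool.

We use the mu–alpha parameterization of the negative binomial with
variance = mean + alpha·mean², i.e. size r = 1/alpha; this is the standard
convention and the only one whose alpha → 0 limit is the Poisson shape the
mixture must reduce to for perfectly even coverage. (One sometimes sees the
variance written as (1 + alpha)·mean²; that form does not have the Poisson
limit and is not what is implemented.) Probabilities are evaluated through
`stats::dnbinom`/`dpois`, which work on log scale internally, so large
abundances do not underflow, and non-integer means are handled by the
gamma-function form.

The observed bin counts are treated as independent Poisson draws around
their expectations, giving the log-likelihood

  log L = Σ_i log Poisson(z_i; E[z_i]),

summed over every integer abundance in the fitted range, including
abundances at which z_i = 0 — omitting the zero bins would let the model
place mass where none is observed at no cost.

## Fitting

`fit_spectrum()` maximises this likelihood in stages, which is what makes
the optimisation stable on real spectra:

1. **Peak location.** Sequencing errors turn high-abundance k-mers into
   novel rare ones, so the spectrum always begins with a steep
   error-driven descent. `initial_peak_estimate()` scans the transformed
   series x·z_x, passes the first local minimum (the error valley) and
   takes the argmax beyond it as c₀, breaking ties toward smaller x. A
   series that never rises again means the coverage peak has merged into
   the error slope — below roughly 10× per-k-mer depth — and fitting stops
   with a `kspectra_low_coverage` error.
2. **Low-abundance cutoff.** Bins below x_min = c/2 are excluded from the
   likelihood; this removes the error mass without modelling it. The
   cutoff needs c, which needs a fit, so it is bootstrapped from c₀ and
   recomputed once if the stage-1 fitted c moves by more than 10%. A
   manual cutoff can override the rule (useful for extreme-coverage
   spectra of tiny genomes, fitted with `max_components = 1`).
3. **Principal peak.** (a₁, c, s) are fitted on bins in [x_min, 1.5c].
4. **Sequential extension.** For n = 2..N (N = 30 by default, i.e. repeat
   components at 2×..30×), coefficient a_n is initialised by weighted
   least squares of the residual counts against the component shape over
   [(n−0.5)c, (n+0.5)c] with weights 1/max(z_x, 1), clipped at zero; the
   mask widens to (n+0.5)c and all parameters are re-optimised jointly
   under a_n ≥ 0, c > 0, s ≥ 0. A stage whose initialised coefficient is
   below 1 k-mer keeps the near-zero value without re-optimisation —
   negligible components stay at zero and the zeros appear naturally in
   the derived tables. The exact masking schedule and WLS weighting are
   design choices of this package; s is re-fitted jointly at every stage.
5. **Final polish.** A joint optimisation over the full masked range, with
   restarts (see below).

The optimiser is box-constrained L-BFGS-B with analytic gradients: the
gradient in each a_n and in c is exact (∂logNB/∂mean = (x−mean)·r /
(mean·(r+mean))), and in s uses the digamma form of ∂logNB/∂r except very
near the s = 0 boundary, where a forward difference is more accurate.
Because the likelihood is nearly flat along exchanges between a₁, s and
small neighbouring coefficients, the final stage restarts the optimiser
(refreshing the Hessian approximation) until the improvement is below
10⁻⁶ relative; convergence within each stage is declared at 10⁻⁸ relative
improvement, at most 500 iterations.

Two termination rules protect against extrapolation. The fitted abundance
range ends at min(max observed abundance, (N+0.5)c); k-mer mass above it —
a very-high-copy plasmid, say — is reported as `unmodeled_instances`
rather than silently dropped. And a component whose centre n·c lies beyond
the highest observed abundance is excluded outright: its peak is
unobserved, so both the WLS initialiser and the likelihood would estimate
it from a bare tail, which is exactly the ill-conditioning the sequential
scheme is meant to avoid.

A fit whose coverage peak lands below 10× is flagged `reliable = FALSE`:
at that depth the error and signal regions of the spectrum overlap and the
estimates should not be trusted, though they are still returned.

## Synthetic data: what it emulates and what it does not

`generate_genome()` builds a genome from a declared architecture — a list
of (copy number, length) blocks, e.g. a 5.4-kb block at 7 copies emulating
an *rrn* operon and a 1-kb block at 15 copies emulating an IS element —
embedding each repeat's copies in shuffled order, separated by unique
random spacers (200 bp by default, comfortably above k so boundary windows
stay unique). The "true" repeat profile returned alongside is computed by
exact counting on the emitted sequence, so boundary windows and any chance
k-mer collisions are part of the truth rather than assumed away.
`simulate_reads()` draws single-end reads uniformly from both strands to a
target depth and applies independent per-base substitution errors (default
read length 76 bp, a typical Illumina short-read length).

Uniform sampling gives genuinely Poisson per-k-mer abundances — the
regime the mixture model treats as s ≈ 0. Real libraries add GC and
positional coverage bias, PCR duplication and adapter contamination; none
of these are simulated, which is deliberate: the model absorbs coverage
unevenness into s rather than modelling its mechanism, and the synthetic
suite exercises the estimator, not the sequencer. Passing recovery tests
on simulated reads therefore demonstrates correctness of counting,
modelling and optimisation under the model's own assumptions — it does not
certify accuracy on biased real libraries, where the broadened peaks make
copy-number assignment genuinely harder.

A read of length L contributes L−k+1 windows, so read depth d corresponds
to k-mer depth d·(L−k+1)/L, and a fraction (1−e)^k of windows survive a
per-base error rate e untouched; at d = 60×, L = 76, e = 1% the expected
coverage peak is 60 · 56/76 · 0.99²¹ ≈ 35.8, which the simulations
reproduce. Errors displace the peak but, crucially, do not remove k-mers
from the genome's complement — every true k-mer is still observed at
c ≈ 36 — so genome-size estimates are nearly error-rate-invariant, which
the test suite checks by halving the error rate and requiring the estimate
to move by less than 1%.

## Problem sizes and defaults in the validation suite

The end-to-end validation uses a 0.5-Mb genome (442-kb single-copy block,
a 7 × 5.4-kb repeat and a 15 × 1-kb repeat) at 60× coverage with 1%
error — about 30 Mb of reads, which counts in ~15 s and fits in a few
seconds. The multi-seed recovery property runs ten replicates on a scaled
100-kb genome at the same depth to keep the whole suite under a couple of
minutes. Noiseless self-consistency constructs a spectrum as rounded model
expectations from (c = 50, s = 0.3, a₁ = 10⁶, a₂ = 10⁴, a₇ = 5×10³) and
requires the re-fit to recover c and Σ n·a_n within 1%; with rounding as
the only noise, the staged fitter lands within ~0.5% of both. On
coefficient exchanges that move the likelihood by only a few units (a₂
against a₁ and s in that fixture) the optimum is genuinely shallow, and
individual small coefficients are recovered less precisely than their
weighted sum — a property of the model, not of the optimiser.

## Reporting

`genome_copy_table()` tabulates exact per-copy-number content of an
assembled genome for comparison with fitted profiles; `report_table()`
formats one or more profiles into the conventional binned layout
(1×..10×, 11×–20×, 21×–79× by default — presentation bins only,
configurable); `transformed_spectrum()` emits the x·z_x series used for
plotting (never for fitting); and `rank_order_stats()` computes the
rank-order abundance distribution and the cumulative fraction of k-mer
instances consumed by the top-ranked k-mers — two summaries that remain
stable under changes of sampling depth, and useful for diagnosing
artifact-dominated or contaminated libraries even when a mixture fit
fails. Histograms are read and written in the plain `abundance count`
two-column text format shared by common k-mer counters, so externally
produced histograms can be fitted directly.

## Known limitations

- Sequencing error k-mers are excluded by the cutoff, not modelled; data
  with error rates above ~5% leave too few intact k-mers to fit.
- Inference is unsupported below ~10× per-k-mer coverage (flagged), and
  accuracy degrades gradually below ~75×.
- Copy numbers above N (default 30) are reported only as unmodeled mass.
- Identical-sequence repeats are what k-mer multiplicity measures:
  near-identical repeat copies contribute their shared sequence at the
  full copy number and their variant positions at lower copy numbers.
- Diploid/polyploid genomes and metagenomes violate the single-genome
  mixture assumption and are out of scope.
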