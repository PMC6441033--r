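---
title: "Models and methods behind topoperturb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind topoperturb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoperturb)
```

`topoperturb` measures how a chromatin-perturbing treatment reshapes 3D
genome organization, starting from binned cis contact maps and companion
tracks rather than raw reads. This vignette explains the generative model
behind the synthetic data, each estimator and its assumptions, the
numerical choices, and what the test suite does and does not establish
about real data.

## The synthetic-data generator

Every downstream stage is validated against data with known ground truth.
The generator produces a single-chromosome cis map at 20-kb resolution
whose expected value factorizes as

$$E_{ij} \;=\; C\, |i-j|^{\alpha} \cdot T_{ij} \cdot L_{ij} \cdot
\max\!\bigl(1 + \kappa\, c_i c_j,\ 0.05\bigr) \cdot b_i b_j ,$$

where $\alpha$ is the distance-decay exponent (default $-1$, the
fractal-globule reference), $T_{ij}$ is the TAD boost (an `intra_boost`
$\ge 1$ where both bins fall in one domain), $L_{ij}$ a focal loop boost,
$c$ a per-bin compartment profile in $[-1, 1]$ with strength $\kappa$
(floored at 0.05 so Poisson means stay positive under strong
anti-correlation), $b$ strictly positive per-bin biases, and $C$ set so the
off-diagonal expectation sums to the target depth. Counts are independent
Poisson draws per upper-triangle cell, mirrored to symmetry. Poisson
rather than negative-binomial sampling is the simplest model sufficient
for testing the estimators; overdispersion would widen Monte-Carlo bands
but not move their centers.

The treated condition rescales the generative structures *before*
sampling: `border_weaken_factor` multiplies $(T-1)$, so 0.5 halves the
excess within-TAD contact density; each loop survives with probability
`loop_retention`; the compartment profile is blended with a random
permutation of itself (`compartment_mix`); de-novo loop dots arrive at a
per-Mb rate. Peak sets are perturbed by Bernoulli dropout, independent
Gaussian boundary jitter and novel-peak insertion; contact sets by
Bernoulli retention plus de-novo pairs. One master seed streams to named
sub-generators (`sub_seed`), making every dataset individually
reproducible and the whole run bit-identical under a fixed seed.

The treated preset (`perturbation_preset("treated")`) encodes the
magnitudes the comparisons are run at: 40% peak dropout and 30% contact
retention match the reported depletion and persistence levels this kind of
treatment produces; border weakening, loop loss and compartment mixing are
set to 0.5 each because the available measurements provide directions and
persistence fractions but no effect sizes for these — they are free
parameters of the emulation, chosen once as a visible, middle-of-range
perturbation.

What the generator does *not* emulate: read-level artifacts (ligation
junctions, mappability), trans contacts, replicate structure,
overdispersion beyond Poisson, and sequence-driven bias correlations.
Passing tests therefore demonstrate correctness of the estimators under
the stated model, not robustness to every artifact of real libraries.

## spFRET mixture model

Each single-particle event carries donor/acceptor intensities; the
cross-talk-corrected proximity ratio is
$E_{PR} = (I_a - 0.19\,I_d)/(I_a + 0.81\,I_d)$, attainable range
$(-0.19/0.81,\ 1]$ for non-negative intensities. The generator draws a
latent conformational state by mixture weight, a target ratio from that
state's Gaussian (rejection-sampled into the attainable range), a total
intensity from a log-normal (meanlog $\log 100$, sdlog 0.3 — arbitrary
units; only ratios matter downstream), and solves the two intensities
exactly, so recomputing the ratio round-trips to machine precision.

The preset state means (0.04/0.47 untreated, 0.04/0.38 treated, 0.02 free
DNA) and weights (27/73 and 39/61) are the measured two-state values for
nucleosome linker conformations. The component standard deviations are not
published; we fixed them once at 0.10 (open), 0.13 (closed) and 0.06
(free DNA), typical widths for single-particle proximity-ratio histograms,
and they are exposed in `fret_preset()`.

Fitting follows the plot-fitting convention: histogram-space least squares
on a fixed grid covering $(-0.25, 1.05]$ with bin width 0.05 (a declared,
configurable default), not event-space maximum likelihood. A sum of
one or two Gaussians is fitted with bounded Levenberg–Marquardt
(`minpack.lm`), multistart initialization (means at the 25th/75th weighted
percentiles, s.d.s at the bin width, five jittered restarts), and s.d.s
bounded below at half the bin width to prevent spike collapse. State
fractions are analytic component areas over the total area — invariant to
histogram rescaling — and between-condition deltas carry first-order
uncertainties from the least-squares covariance. Components are matched
across conditions by nearest mean, consistent with the shared open-state
peak near 0.04.

## Balancing, observed/expected, and their contracts

Iterative correction repeats {divide each row/column by its marginal,
renormalize biases to mean 1} until the maximum relative marginal
deviation falls below `tol` ($10^{-8}$ default, 500 iterations max). The
diagonal is excluded from the marginals and all downstream statistics
(self-ligation artifacts; the analyses concern distal contacts). Masking —
all zero-coverage bins plus the lowest-coverage 2% of the rest — is
standard practice; the fraction is our declared default, not inferred
from any reference run. The balanced map keeps the exact factorization
`raw = balanced × b_i b_j`, which the contact caller uses to return to raw
count units. Constructive tests recover planted biases to $10^{-6}$, and
rebalancing a balanced map moves biases by less than the tolerance.

The observed/expected transform divides each diagonal by its mean over
unmasked cells; by construction every included diagonal then averages 1,
which the suite asserts directly. Diagonals with zero mean are excluded
and flagged.

## TAD segmentation and border strength

Candidate domain quality is $q(k,l) = S(k,l)/d^{\gamma} - \mu_\gamma(d)$,
with $S$ the sum of distinct within-window pairs (diagonal excluded) via
2-D prefix sums, and $\mu_\gamma(d)$ the mean of $S/d^\gamma$ over **all**
windows of size $d$ on the chromosome. We compute each size's mean from
its own windows, however few: a borrowed neighboring-size mean makes the
whole-chromosome window score spuriously positive (window sums grow faster
than $d^\gamma$), which breaks the defining property that a uniform map
scores zero everywhere. With per-size means the uniform-map score is
exactly zero and the dynamic program — maximize the sum of positive-quality
disjoint domains over prefixes, allowing gap bins — provably matches
exhaustive enumeration (fuzz-tested on 8–10-bin maps). Domain size limits
default to 3–200 bins; γ defaults to 0.3.

Border strength for abutting domains A and B is
$(\mathrm{intra}_A + \mathrm{intra}_B)/\mathrm{inter}_{AB}$ — the
within-over-between form, so a stronger border has a larger value and a
treatment-induced weakening is a decrease. The reciprocal phrasing that
sometimes appears in figure legends is treated as informal. Intra sums
exclude the diagonal (a declared choice; self-ligation bins carry no
distal information). Borders are
evaluated only between abutting domains (adjacency tolerance 0); an
inter-sum of zero flags the record invalid and excludes it from summaries.
The paired comparison evaluates both conditions at the control borders,
reports quartiles and the fraction of borders below the diagonal, and runs
a two-sided paired *t*-test.

## Compartments and saddles

The compartment profile is the first principal component of the Pearson
correlation matrix of the O/E map. Two readings of "PCA on the map" exist
in the field; we chose the correlation-matrix variant, and center it
(`prcomp`): the *uncentered* leading eigenvector of a mostly-positive
correlation matrix is all one sign (Perron–Frobenius) and carries no
compartment signal. The component is oriented so that it correlates
positively with GC content, making A the GC-richer compartment by
convention; flipping the GC track provably flips every label.

Saddles sort usable bins by ascending control-condition eigenvector (ties
by bin index), permute the O/E map, and aggregate into 20 equal-count
groups; with ascending order the (B,B) corner is top-left. The
compartmentalization strength is the mean of the two 3×3 same-compartment
corner blocks over the mean of the two anti-corner blocks; 1 means no
segregation, and a profile-shuffled map is flat by construction (asserted
within Monte-Carlo error). Contact fractions AA/BB/AB are sums of
depth-normalized cells at separations of at least 2 bins, normalized to 1.

## Scaling curves

$P(s)$ uses log-spaced distance bands (8 per decade) rather than raw
diagonals to stabilize long-range estimates; each band averages its
per-diagonal means weighted by unmasked cell count, the band's abscissa is
the mean separation of contributing cells, and the curve is normalized to
unit integral over bands so different depths are comparable. The slope is
an ordinary least-squares fit of $\log P$ on $\log s$ within a caller-
chosen range (the comparative analyses use 100 kb–2 Mb; no universal fit
range exists, so it is a mandatory argument). On noiseless power
laws the estimator is exact to well under 0.01; the crossover report
returns the band boundary nearest the first sign change of
$\log(P_{\rm treated}/P_{\rm control})$.

## Distal contact calls and persistence

The caller is a declared simplification of hierarchical promoter–enhancer
callers, not a reimplementation: within each TAD, the expected balanced
value at separation $s$ is the within-domain mean at $s$ shrunk toward the
chromosome-wide decay with prior weight 10 pseudo-cells; each cell at
separation ≥ 40 kb gets an upper-tail Poisson p-value on its raw count
(expected mapped to raw units through the balancing biases), BH-corrected
across all tested cells, discovery at q < 0.05. Type-I error on null maps
stays at or below the nominal FDR (simulation-tested). The hierarchical
background initialization of the original approach has no analog here —
a known fidelity gap, which is why results are labelled as coming from
this surrogate.

Persistence matches control and treated records one-to-one, greedily by
total anchor distance with both anchors within 1 bin (20 kb — annotation
jitter at bin scale is expected); unmatched control records are lost,
unmatched treated records de novo. Swapping the inputs provably swaps
lost and de novo.

## Peaks, deserts, RNA

Peak persistence uses the percent-of-intersection rule — overlap over the
larger peak length — with a *strict* inequality at the 50% threshold (a
peak persists only if strictly more than half of the larger peak is
shared). Novel peaks are obtained by the same
rule in reverse (treated versus control), the default of the two
reasonable readings. Candidate pairs come from an IRanges overlap query;
a brute-force all-pairs classifier confirms the result on fuzzed set
pairs.

Gene deserts are the complement of the merged gene span, filtered to
length ≥ 500 kb (inclusive). The normalized RNA signal divides each bin's
read count by the total mapped reads; an alternative per-bin-count
denominator is implemented behind a switch but is off by default, since a
bin-count denominator would not produce a normalized read count in the
usual library-share sense. The desert border comparison is an unpaired
two-sided *t*-test of desert borders against all borders; identical
samples return t = 0, p = 1 by contract.

## Pipeline, problem sizes, and limitations

`run_pipeline()` executes the stages in a fixed order on a simulated pair
of conditions and returns one structured report; it is deterministic under
the master seed, and a re-run reproduces every number bit-identically. We
dropped the idea of content-hash caching between stages: at the problem
sizes used (150–500-bin maps, $10^6$–$5\times10^6$ read pairs, 1,000-peak
and 2,000-contact sets, 2,000–4,500 FRET events, 20 replicates for
stochastic summaries) a full run takes seconds, so a cache would add
failure modes without benefit. These sizes were chosen to put every
Monte-Carlo band comfortably below the effect sizes being measured.

Known limitations: single-chromosome cis analysis only (no
per-chromosome-arm handling, no trans saddles); one γ per segmentation run
(no multi-γ ensembles or TAD hierarchy); insulation-score borders are not
implemented (border strength is the intra/inter ratio); the contact caller
is a surrogate, not the hierarchical original; and the FRET analysis
starts from intensity tables, not photon traces — burst detection and
cross-talk calibration are upstream of this package.
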