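# topoperturb

Comparative analysis of drug-induced 3D-genome perturbation from binned
Hi-C contact maps, peak interval sets, gene annotations and
single-particle FRET event streams.

Chromatin-perturbing small molecules (such as DNA-intercalating curaxins)
can reshape genome architecture at every scale: topologically associating
domains (TADs) lose insulation, chromatin loops dissolve, A/B compartments
intermix, architectural-protein binding sites are lost, and nucleosome
linker DNA changes conformation. `topoperturb` implements the complete
control-versus-treated comparison for measuring those effects, together
with a synthetic-data generator with recorded ground truth, so that every
estimator can be validated end to end without external data.

## What it computes

* **Contact-map model and normalization** — triplet/BED I/O, depth
  normalization, iterative correction (matrix balancing: find per-bin
  biases *b* such that the marginals of *W<sub>ij</sub>/(b<sub>i</sub>
  b<sub>j</sub>)* are uniform), observed/expected transform (each diagonal
  divided by its chromosome-wide mean), and log2 difference maps.
* **TADs** — the single optimal Armatus-score segmentation by dynamic
  programming: domain quality *q(k,l) = S(k,l)/d<sup>γ</sup> −
  μ<sub>γ</sub>(d)* with *S* the within-window contact sum, *d* the window
  size and *μ<sub>γ</sub>* the same-size window mean; default γ = 0.3.
* **TAD border strength** — for abutting domains A, B: (intra-A + intra-B)
  contact sums over the inter-A,B sum; paired control/treated comparison
  with a two-sided paired *t*-test.
* **A/B compartments** — first principal component of the Pearson
  correlation matrix of the observed/expected map, oriented so A has the
  higher GC; 20×20 eigenvector-ordered saddle plots (control ordering
  reused for the treated map) and a corner-ratio compartmentalization
  strength; AA/BB/AB contact fractions.
* **Scaling** — log-binned contact probability *P(s)* versus genomic
  distance, power-law slope estimation, and the crossover distance where
  the treated/control log-ratio changes sign.
* **Distal contact calls** — a deliberately simple domain-conditioned
  over-expected caller (within-TAD distance-decay expected, Poisson upper
  tail, Benjamini–Hochberg) plus one-to-one persistence classification
  (preserved / lost / de novo) at 1-bin anchor tolerance.
* **Peak persistence** — the percent-of-intersection rule: a control peak
  persists iff overlap ÷ length of the larger peak strictly exceeds 50%
  against its best-matching treated peak.
* **Gene deserts** — intergenic regions ≥ 500 kb, per-bin normalized
  nascent-RNA signal, and the desert-versus-all border-strength test.
* **spFRET** — proximity ratio *E*<sub>PR</sub> = (I<sub>a</sub> − 0.19
  I<sub>d</sub>)/(I<sub>a</sub> + 0.81 I<sub>d</sub>), fixed-grid
  relative-frequency histograms, one/two-Gaussian least-squares fits with
  area-fraction state populations, and between-condition deltas with
  propagated uncertainties.

## Worked example

The numbered scripts under `analysis/` run the whole study on simulated
paired conditions (a 400-bin, 20-kb-resolution chromosome; the treated
condition has TAD boosts halved, half the loops dropped, compartments
half-mixed, 40% peak dropout and 30% contact retention). After
`Rscript analysis/01_simulate_conditions.R` through `06_spfret.R`:

```
median strength control 12.15 -> treated 8.00
fraction of borders below the diagonal: 1.00
paired t-test: t = -7.34, p = 4.38e-05
compartmentalization strength: control 1.86, treated 1.21
contact fractions treated: AA 0.33 BB 0.28 AB 0.39
treated/control crossover near 300 kb
peaks: 1000 control, 595 remaining (60%), 405 lost, 3 novel
desert vs all border strength: t = 0.58, p = 0.575
minus_drug: state 2: mean 0.467, sd 0.132, fraction 72.6%
open-state fraction change (+drug - -drug): +13.5 +/- 3.4 points
```

Reading: every border weakened (all points below the diagonal, a highly
significant paired *t*), compartment segregation dropped by a third with
between-compartment contacts doubling, short-range contacts were lost and
long-range ones gained (crossover at 300 kb), 40% of peaks disappeared
under the strict 50% rule, border weakening was indistinguishable inside
transcriptionally silent gene deserts, and the nucleosome open-linker
population grew by ~13 percentage points under the drug — each number
matching what the generator planted.

A single-call alternative is `run_pipeline(list(seed = 17, n_bins = 300))`,
which returns all sections as one structured report.

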