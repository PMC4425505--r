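---
title: "Methods: splice-variant quantification, site-strength modelling, distances and congruency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splice-variant quantification, site-strength modelling, distances and congruency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceodiv)
```

This vignette is the package's own account of the methods it implements: the
models, their assumptions, the tunable parameters that matter, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## The locus model

A `gene_model` stores one locus in 0-based half-open coordinates on the
forward genome strand, with strand-aware interpretation. Splice sites follow
the intron-edge convention: a donor's position is the first intronic base
(the G of GT), an acceptor's position the last intronic base (the G of AG).
This makes junction matching unambiguous and BED-compatible: the intron of an
event is exactly `[donor_position, acceptor_position + 1)` on the plus
strand. Validation reads every declared site's dinucleotide on the
*transcribed* strand, so minus-strand models store forward-strand coordinates
but are checked (and spliced) in transcription orientation.

The locus of interest has a cassette exon between two constitutive exons:
one shared upstream donor, three alternative acceptors that differ only in
the 5' edge they give the cassette exon (variants X2, X3, X4), the cassette's
own donor, and the downstream constitutive acceptor. The four *discriminating*
junctions — upstream donor joined to each alternative acceptor, or to the
downstream acceptor (skipping) — identify the variants uniquely; the
inclusion junction from the cassette donor to the downstream acceptor is
shared by X2/X3/X4 and cannot discriminate them, so it is not part of the
event catalog and accumulates under `unassigned` if present in the input.

The reading frame of the cassette insert is, by default, frame 0 relative to
the insert start (`translate_insert(frame_offset = 0)`); the insert peptide
is fixed by the biology but the bookkeeping of where translation enters the
insert is not, so the offset is exposed.

## Junction quantification

Junction tables carry `(chrom, intron_start, intron_end, strand, count,
sample, group)`. Matching tolerance defaults to 0 bp because junction callers
emit exact splice coordinates; a non-zero tolerance is available for sloppy
upstream processing, and a junction matching two catalog events at the given
tolerance is an error rather than a silent double count.

Relative frequencies are computed **per replicate** and then summarised as
mean ± sample SD (n − 1), matching the usual "mean ± SD over replicates"
reporting; pooling counts before dividing would weight replicates by depth
and understate between-replicate variability. The denominator is the sum over
the four discriminating events only.

The across-variant comparison is a one-way ANOVA over the three inclusion
variants followed by pairwise two-sample *t* tests with pooled variance —
the classical reading of "Bonferroni's test" — with raw p values multiplied
by the number of comparisons and capped at 1. Welch tests are available via
`welch = TRUE`. Degenerate inputs are handled explicitly: if all groups have
zero within-group variance the F statistic is reported as undefined and
flagged; if the groups are identical with internal scatter, F = 0 and p = 1
fall out naturally.

## Maximum-entropy splice-site models

A motif model is the distribution of maximal entropy over L-mers whose
marginals on a chosen set of position subsets match the training data. The
defaults follow the classical splice-site windows: donors are 9-mers (3
exonic + 6 intronic bases, GT obligate at positions 4–5), acceptors are
23-mers (20 intronic + 3 exonic, AG at positions 19–20). The default
constraint set is all singletons plus all adjacent pairs.

*Fitting.* For L ≤ 9 the full probability table over 4^L states is fitted by
iterative proportional fitting (IPF), cycling over constraints and rescaling
the table to each target marginal until the maximum absolute marginal
residual drops below `tol` (default 1e-8) or `max_iter` sweeps pass;
diagnostics (`iterations`, `max_residual`, `converged`, `entropy_bits`) are
attached, and non-convergence flags the model rather than erroring. For
longer motifs (the 23-mer acceptor) the model is represented as a first-order
chain built from the adjacent-pair marginals,
P(x) = P(x₁)·∏ᵢ P(xᵢ₊₁ | xᵢ). When the constraint set is exactly the chain of
adjacent pairs this factorisation *is* the maximum-entropy solution, so it is
exact for the default constraints, not an approximation of them — though it
cannot express longer-range constraints a full-table fit could.

*Pseudocounts and consistency.* IPF requires targets that agree on shared
positions. A naive per-subset pseudocount breaks this (a singleton table with
+0.5 per cell no longer equals the marginal of a pair table with +0.5 per
cell), so `empirical_marginals()` adds the pseudocount (default 0.5) only to
*maximal* subsets and derives contained subsets by marginalisation. Mutually
inconsistent targets beyond `consistency_tol` are a fit error, not a warning.

*Scoring.* The splicing strength of an L-mer is
log₂ P_model(x) / P_bg(x) in bits, with a uniform background by default
(a length-4 composition vector or a 4 × L matrix may be supplied). With
singleton-only constraints the model factorises over positions and the score
reduces exactly to the classical PWM log-odds — a useful closed-form check.
Scanning scores every window that carries the obligate dinucleotide at the
spec's offsets; windows lacking it are "disrupted" and omitted, which is how
a single G→T substitution silences a donor. Site ranking extracts each
labelled site's window from the reference on the transcribed strand and ranks
donors and acceptors separately, breaking score ties by ascending genomic
position for determinism.

Published donor/acceptor score tables can be imported
(`import_score_table()`, a two-column k-mer/score text format) so sites can
be scored under the original published model; a retrained model on other data
will not numerically match published strengths, only the import path can.

## Composite-likelihood TN93 distances and Neighbor-Joining

Distances are estimated under the Tamura–Nei (1993) substitution model,
which separates purine transitions, pyrimidine transitions and transversions
with stationary base frequencies. "Composite likelihood" is implemented as:
the two transition/transversion rate ratios are **shared across all pairs**
and estimated by maximising the summed pairwise log-likelihood (alternating
between per-pair distance optimisation and shared-ratio optimisation,
`outer_iter = 4` sweeps, which converges well before that in practice); each
pair's distance then maximises its own likelihood under the shared ratios.
Transition probabilities are computed exactly by eigen-decomposition of the
normalised rate matrix (via the symmetrising similarity transform, so the
decomposition is of a symmetric matrix).

Columns containing any non-A/C/G/T character — gaps and IUPAC ambiguity
codes alike, since the two are not worth distinguishing here — are removed
per pair independently (pairwise deletion). With `composition_correction =
TRUE` (default) each pair's likelihood uses the pair's own empirical base
frequencies, absorbing composition bias between sequences; `FALSE` uses
alignment-wide pooled frequencies. Saturated pairs (distance estimates
beyond `max_distance = 10` substitutions per site) are flagged inestimable
(`NA`), never clamped; Neighbor-Joining refuses matrices containing them and
says so.

The exact iteration used by legacy GUI phylogenetics programs for this
estimator is not published in detail, so numerical agreement with them is a
goal, not a contract; the implementation is validated instead against the
Jukes–Cantor closed form (to which TN93 reduces under equal rates and
frequencies) and by end-to-end topology recovery on simulated alignments.

Neighbor-Joining is the standard Saitou–Nei agglomeration: at each step join
the pair minimising Q(i,j) = (m−2)d(i,j) − R(i) − R(j), with Studier–Keppler
branch lengths and the reduced-matrix update. Ties in Q break at the
lexicographically lowest active-index pair, making the result deterministic
across platforms. Negative branch lengths are reported as computed (their sum
is also reported separately by `total_branch_length()`); `clamp_negative`
exists but is off by default — transparency over prettiness. Newick output
rounds branch lengths to 8 decimals.

## Line-scan congruency

Scans are consumed as tables (one row per pixel: position in µm and the
VIAAT, HA and gephyrin intensities, 0–255 grey levels). Clusters are local
maxima of the VIAAT channel. The threshold floor is the mean + 3 SD of the
lowest-decile pixels (a background estimate); because that floor sits *below*
typical background whenever there is pixel noise, candidates must also reach
a fraction `rel_height` (default 0.2) of the channel's dynamic range above
background — without this, noise bumps qualify as clusters and contaminate
the correlation with near-baseline points. Accepted maxima must be at least
`min_separation` (default 1 µm) apart, kept greedily in order of decreasing
intensity.

For each cluster a full window (2–3 µm, default 2.5, centred on the cluster)
is taken; the peak window (≥ 0.66 µm, i.e. ≥ 4 pixels at the default
0.165 µm/pixel, derived from a 4-pixel minimum) is centred on the **HA
intensity maximum** within the full window — the natural reading of a window
that "covers the HA peak", and the one implemented. The congruency ratio is
mean HA over the peak window divided by mean gephyrin over the same pixels;
1 indicates perfect congruency. Clusters whose windows clip the scan edge are
excluded with reason `edge`; clusters with mean gephyrin below 1 grey level
are flagged `no_local_gephyrin` rather than producing an unbounded ratio.
Histograms use left-closed bins of width 0.2 anchored at 0, so a ratio of
exactly 1 falls in [1.0, 1.2).

The headline correlation is computed **across clusters** (per-cluster HA
peak-window mean vs gephyrin mean); whether such correlations should be per
pixel or per cluster is genuinely ambiguous in common practice, so a pooled
per-pixel mode is available via `correlation = "pixel"`.

## What the generators emulate — and what they do not

All generators are seed-deterministic and emit inputs their consumer module
parses directly.

* `generate_locus()` models the species toggle exactly as a single
  thymine/guanine substitution at the cassette donor (`create_donor`):
  the sequence differs in that one base only, and without the donor the
  model collapses to the skip variant. Donors get a consensus CAG|GTAAGT
  context; acceptors get polypyrimidine tracts of configurable length,
  planted only where they do not collide with coding sequence — the X4
  acceptor sits inside the X3 insert, so its context is fixed by the coding
  sequence, which is also true at the real locus where the acceptors are
  nested.
* `simulate_junction_reads()` draws multinomial counts over the event
  catalog at stated proportions, or Dirichlet-multinomial when a finite
  `dispersion` concentration is given. The two-group scenario used by the
  acceptance script (X3 at 23% embryonic / 19.5% adult, X2 = X4 = 7%,
  depth 5000, 10 replicates, concentration 400) reproduces replicate SDs of
  about 2 percentage points, the scatter scale reported for this kind of
  developmental RNA-seq comparison. Replicate counts per group are not
  recoverable from the original report, so 10 is a configurable default.
* `simulate_alignment()` evolves sites independently along a (given or
  random) binary tree under TN93, using exact per-branch transition
  probabilities from the eigen-decomposition — not event-by-event
  simulation, which would add cost without adding exactness.
* `simulate_line_scans()` plants Gaussian cluster peaks on a 0.165 µm pixel
  grid with channel coupling `congruent` (gephyrin amplitude equals HA),
  `independent`, or `partial` (a stated mixing weight), additive truncated-
  Gaussian noise, and 8-bit clipping/rounding.

What passing tests on these inputs show is that the *estimators* behave as
specified under their own assumptions: multinomial counting noise,
site-independent substitution, Gaussian peaks with additive noise. Real data
violate all of these in places — overdispersion beyond Dirichlet, alignment
errors and indel ambiguity, non-Gaussian synapse shapes, bleed-through
between channels — so green tests here do not certify performance on any
particular real dataset; quantities that depend on external data (public
RNA-seq junction tables, published score-table values, a particular
27-species alignment) can be reproduced by feeding those inputs through the
same functions, and are deliberately not bundled.

## Problem sizes and tolerances used by the checks

The test suite and acceptance script run at desk scale: 2-taxon alignments
of 1e5 sites for the Jukes–Cantor limiting case (3-SE agreement), 100 random
additive 6–10-leaf matrices for NJ (recovery to 1e-9), 20 random L = 3
constraint problems for IPF against a brute-force exponential-family dual
optimiser (total variation < 1e-6), junction studies at depth 5000 with 10
replicates, and line-scan sets of 100 planted clusters. These sizes were
chosen so each statistical check has comfortable power while the whole suite
stays fast to iterate on.

## Known limitations

* The maximum-entropy module fits full tables only to L ≤ 9; longer motifs
  are chain-factorised, so deliberately long-range constraint sets on long
  motifs are rejected rather than approximated silently.
* `mcl_distances()` estimates two shared rate ratios; it does not estimate
  per-pair gamma rate variation or invariant sites.
* No bootstrap support, ML/Bayesian tree search, or divergence-time
  estimation; no isoform-abundance EM; junction discovery from BAM CIGARs is
  out of scope (junction tables are the input contract).
* Line scans are strictly 1-D; no 2-D segmentation, background rolling-ball
  subtraction or deconvolution.
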