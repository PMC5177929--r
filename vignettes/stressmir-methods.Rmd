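---
title: "Methods: small RNA annotation and stress time-course differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA annotation and stress time-course differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressmir)
```

# Overview

`stressmir` implements a complete small RNA sequencing inference chain for
plant stress time-course experiments: raw reads are trimmed, size-selected
and collapsed into *distinct tags*; tags are promoted to *genuine conserved
miRNAs* only when a precursor locus, a stable hairpin fold and a star
sequence with canonical processing geometry all support them; the annotated
miRNA counts are then tested for differential expression over a
treatment-by-time factorial design; and plant-style complementarity scoring
predicts their mRNA targets. A synthetic-data generator plants all of these
features with recorded ground truth, so each stage — and the chain as a
whole — is verifiable at desk scale.

The experimental frame is a 4 treatment (control, heat, continuous light,
UV) x 3 replicate x 6 time point (0, 1, 2, 3, 7, 10 days after treatment)
design, i.e. 72 libraries.

# Preprocessing model

Reads are insert + 3' adapter, sequenced for 50 cycles. Trimming returns
the prefix before the leftmost exact occurrence of an adapter prefix of at
least `min_overlap = 5` bases that extends to the read end; reads without
such a match are flagged untrimmed and carry no insert. Inserts of 18-24 nt
are retained — the size range of plant regulatory small RNAs — and collapsed
across *all* libraries into distinct tags. Tag identifiers are assigned
after sorting the pooled sequence set, so they depend only on the set of
sequences, never on read order or library order.

Expression is reported as RPM (reads per million): counts divided by the
library's retained (size-selected) read total, times 10^6. The denominator
is taken *before* contaminant removal, following the processing order in
which tags are collapsed and normalized first and decoy-matching tags
removed afterwards. Consequently RPM sums to exactly 10^6 per library over
the collapsed tag table, and to less after decoy removal.

Contaminant removal is deliberately the strictest reproducible rule: a tag
is removed iff its sequence or reverse complement is an exact substring of
any ncRNA/chloroplast decoy reference (after a single U->T
canonicalization). Quality filtering is a configurable mean-Phred gate
(default >= 20); with the generator's default perfect qualities it is a
no-op, and it stands in for the upstream diagnostic quality checking whose
exact parameters are not part of the model. The expression filter keeps
tags reaching >= 10 RPM in at least one library, inclusively at the
threshold.

# Hairpin folding and the MFE gate

Precursor candidates must fold into a stable hairpin: folding free energy
per nucleotide strictly below -0.2 kcal/mol/nt, with the full precursor
length as denominator. The package applies this gate to energies from
either of two providers:

* `parse_dotbracket()` ingests the conventional two-line sequence /
  dot-bracket format with a trailing `(energy)`, for interoperability with
  external folding tools;
* `fold_mfe()` is a built-in Zuker-style dynamic program over a
  deliberately simplified nearest-neighbour model.

The built-in energy model is: stacking energies for the six admissible pair
types (AU, UA, GC, CG, GU, UG) on a shipped, strand-rotation-symmetric
parameter table approximating published nearest-neighbour values; hairpin
loops penalized `4.5 + 1.6 log(l/3)` kcal/mol for `l >= 3` unpaired bases;
bulge/interior loops penalized `3.2 + 1.1 log(u)` for `u` unpaired bases,
capped at `max_interior = 12`; multiloops closed at a constant 3.4 kcal/mol
with free unpaired bases; no pseudoknots; minimum hairpin loop of 3. The
empty structure has energy 0, so the MFE is never positive. This is not the
full Turner model — the downstream criterion consumes only MFE per
nucleotide, and interoperability with a full thermodynamic folder is
preserved through the parser. The folding temperature and parameter set of
any external folder are outside the model; the provider abstraction is the
deliberate answer to that unknown.

Ties between co-optimal structures are broken by a fixed traceback
preference (pair the earliest exterior position; hairpin before
stack/interior with the smallest loop before multiloop with the earliest
branch). This makes the reported structure deterministic; it approximates,
but does not guarantee, the lexicographically smallest dot-bracket among
co-optima. The optimal *energy* — the only quantity consumed downstream —
is unaffected, and is verified against exhaustive enumeration of all nested
structures for short sequences in the test suite.

# Star geometry

Genuine DCL1 processing excises a mature/star duplex whose two strands each
carry 2-nt 3' overhangs. With the precursor's 1-based pair table `pt` and a
mature interval `[a, b]`, the predicted star interval is

```
star_end   = pt[i1] + overhang + (i1 - a)
star_start = pt[i2] - ((b - overhang) - i2)
```

where `i1` is the first paired position at or after `a` and `i2` the last
paired position at or before `b - overhang`; the shift terms extrapolate
across unpaired (bulged) edge bases. Predictions are rejected with reason
codes when the mature folds back on itself or sits in the hairpin loop
(`spans_loop`), is paired below the tolerance (`low_pairing`, default >=
60% of mature bases paired — the tolerance is configurable because no
canonical value exists), or when the star interval would leave the
precursor (`out_of_bounds`), overlap the mature (`overlaps_mature`) or
cross the hairpin loop (`crosses_loop`). A prediction is flagged `exact`
only when both anchors are paired and the anchored duplex is bulge-free;
with one planted bulge the interval is recovered within +-1 nt and flagged
inexact.

A useful consequence of the geometry: when a *star-arm* tag is itself
evaluated as a mature candidate, its inferred partner interval necessarily
dips into the hairpin loop (the mature's 3' overhang sits loop-side), so
star-arm tags are deterministically rejected as mature candidates with
reason `crosses_loop`. Expression of the star is still credited to the
mature through `check_star_expression()`.

# Classification and families

A tag is a genuine miRNA iff it (i) matches at least one precursor locus
perfectly, (ii) that locus passes the MFE gate, and (iii) the star geometry
is valid there. Star *support* additionally requires the predicted star
sequence to be expressed (count >= 1 in any library) among the distinct
tags. Because published analyses differ on whether star expression is
required or merely recorded, the classifier stores both verdicts:
`accepted` (geometry only) and `accepted_strict` (geometry + expressed
star). Multiple precursor/catalog sets are combined by OR; a multi-locus
tag is counted once (expression is tag-level) with all supporting loci
listed as evidence. Every accepted tag stores a witness (locus, mature
interval, star interval, MFE/nt) that can be revalidated on demand.

Families are assigned from a known-mature catalog: exact sequence match,
or — configurably — equal length, at most 2 mismatches and an identical
seed (positions 2-8). Tags matching entries of more than one family are
labelled `AMBIGUOUS`; reporting names embed the family and the exact tag
sequence (`miR398_tgtgttcccagctcgaccccg` style).

# Differential expression

Normalization follows the trimmed-mean-of-M-values recipe: the reference
library is the one whose upper quartile of count proportions is closest to
the mean; M and A statistics are computed over tags nonzero in both
libraries; the extreme 30% of M and 5% of A are discarded; the factor is 2
to the precision-weighted mean of the remaining M values, and factors are
rescaled to geometric mean 1. One consequential definitional choice: M is
the log2 ratio of *raw counts*, not of count proportions. This makes the
factor absorb depth as well as composition (a tagwise-doubled library gets
factor sqrt(2) after rescaling, identical libraries get exactly 1), and is
the definition the package's closed-form tests pin down. Offsets for the
GLM are `log(library_size x factor)`. Because a raw-count factor already
tracks depth, these offsets over-correct depth differences; the generator
therefore defaults to a uniform expected depth per library (the libraries
of the emulated design were pooled and sequenced together), and
heterogeneous depth is exposed as an explicit `size_factors` argument for
studies of that effect.

Counts are modelled per tag as negative binomial with log link over
`~ treatment * time` (both factors; control and 0 DAT as baselines; 24
coefficients at the full design), fitted by iteratively reweighted least
squares at fixed dispersion. The common dispersion maximizes the summed
Cox-Reid adjusted profile likelihood (fit log-likelihood minus half the log
determinant of the Fisher information) by 1-D search on a log scale in
[1e-6, 10]; tagwise values are per-tag moment estimates shrunk toward the
common value with 10 prior degrees of freedom (infinite prior recovers the
common value). The dispersion machinery is specified explicitly rather than
delegated, so its behaviour is testable from the model description alone.

"Differentially expressed upon a stress" is defined as the likelihood-ratio
test of all terms involving that treatment (main effect + its 5 time
interactions, 6 degrees of freedom) against the full model — the
treatment-level reading that matches per-treatment DE set counts — with
BH-FDR within each treatment family and alpha = 0.05. Direction at each
time point is the sign of the estimated log2 fold change versus control at
that time (main effect + interaction), reported with a Wald test and
BH-corrected within each treatment x time family; direction tables count
signs among the treatment-level DE set. Whether a study's headline DE
counts were computed within-time or pooled cannot generally be recovered
from a methods section, so both scopes are emitted side by side.

Heat-map matrices are `log2(count / effective_size x 1e6 + 1)` (pseudocount
1, an unstated-but-standard choice), clustered by average-linkage
hierarchical clustering on Euclidean distances in both dimensions.

# Target prediction

The target score ("expectation") follows the classical plant predictors'
penalty model: the miRNA is aligned antisense (5'->3' against the site read
3'->5') by a global alignment minimizing summed penalties — match 0, G:U
wobble 0.5, mismatch 1, gap 2 — doubled within the seed (miRNA positions
2-13 from the 5' end). The cutoff (expectation <= 3) and all penalties are
configuration, since "default parameters" is the only recoverable
specification. Site gaps between miRNA positions k and k+1 take the seed
factor of position k+1; a gap after the miRNA 3' end is unweighted.

The transcript scanner evaluates every window of length L-1, L, L+1
(L = miRNA length). For speed it uses a vectorized at-most-one-gap scorer;
this is exact for every reported hit because a two-gap alignment costs at
least 4 > 3 = cutoff, so any window whose one-gap score is within the
cutoff has its true optimum there. If the cutoff is raised to >= 4 the
scanner automatically falls back to the full dynamic program per window.
Hits are ordered by (expectation, transcript, position), so each
transcript's best site precedes its weaker ones. Central-mismatch
(translational-inhibition) heuristics are annotations for the reader, not
filters.

# The synthetic-data generator

`simulate_experiment()` plants, with recorded truth: 50 hairpin precursors
(mature on the 5' arm, star on the 3' arm, perfect duplex with 2-nt 3'
overhangs; optional 1-2 planted bulges), star reads at a few percent of the
mature baseline, 200 contaminant tags that are exact substrings of
generated ncRNA/chloroplast decoy references, 300 siRNA-like 24-mers with
no precursor, and negative-binomial counts (default dispersion 0.1, the
order of magnitude typical for replicated plant sRNA libraries) over the
full 72-library design. Mature lengths are drawn with a 21-nt mode (55%)
and a 24-nt shoulder, matching the size profile of conserved plant miRNAs;
baselines are log-normal (median ~80 reads) so that every planted mature
clears 10 RPM at the default depth of roughly 20-30k retained reads per
library — sequencing depth is a free parameter of the simulation, chosen
at desk scale. The default effect table emulates a heat-dominated response:
34% of matures perturbed by heat at 0-1 DAT (55% of them down, log2FC 2),
and one miRNA each for light and UV.

Reads are emitted in the DNA alphabet (sequencer convention) as insert +
3' adapter, padded with run-off `A` cycles to 50 nt — the pad is inert
because trimming only consumes the prefix before the adapter — with
constant Phred 40 qualities by default and an optional uniform substitution
error rate. Within a library, read order is a seeded permutation, so output
is byte-identical given the same inputs and seed.

What the generator deliberately does **not** emulate: 5'-adapter chemistry,
ligase sequence preferences, PCR amplification bias, index hopping,
position-dependent error profiles, isomiR-generating imprecise processing,
multi-locus repeat-derived tags, and genomic context beyond the precursor
itself. Passing the planted-truth tests therefore demonstrates the
*internal consistency* of the chain — each stage inverts what the generator
planted under error-free conditions — not performance on real libraries,
where contaminant matching is inexact, precursors carry asymmetric bulges
and expression is far more skewed.

# Numerical choices and degenerate inputs

* Intervals are 1-based and closed throughout the R API (the idiom of this
  language's sequence infrastructure); reports use the same convention.
* Folding requires 10-500 nt and an ACGU/ACGT alphabet; degenerate inputs
  (no possible pair) return the empty structure at energy 0.
* IRLS caps the linear predictor at +-30 to avoid overflow, declares
  convergence on a relative deviance change below 1e-8 within 50
  iterations, and flags non-converged fits, which are excluded from
  testing. All-zero tags are excluded from dispersion estimation and
  testing.
* The common-dispersion search runs on the log scale with tolerance 1e-3;
  moment estimates are floored at 0 before shrinkage and the shrunk values
  at 1e-6.
* RPM with a zero denominator and nonzero counts is a hard error; zero/zero
  is 0.
* Trimming scans subsequent seed occurrences when the first adapter-seed
  match does not extend to the read end, so adapter-like k-mers inside an
  insert cannot truncate it.

# Problem sizes in the shipped checks

The packaged tests and the acceptance script run entirely on generated
data, at sizes chosen for a single desk-scale run: the full 72-library
design with 50 planted precursors, 200 contaminants and 300 siRNA tags for
the end-to-end check; 200 random sequences of <= 14 nt against exhaustive
structure enumeration for the folding oracle; 100 perfect and 30 bulged
hairpins for the star-geometry oracle; 10 (tests) or 5 (acceptance script)
global-null simulations of 2,000 tags at dispersion 0.1 plus one
planted-effect simulation (50 tags at |log2FC| = 2, mean 1,000) for DE
calibration and power; and 200 random duplexes plus 30 planted sites for
the target-scoring oracle.

# Known limitations

* The folding model is a reduced nearest-neighbour approximation: no
  dangling ends, no terminal-mismatch or special-loop corrections, no
  temperature dependence, no partition function. It ranks hairpin stability
  well enough to drive the MFE/nt gate, which is its only consumer.
* The raw-count TMM definition couples depth and composition in one factor
  (see above); with strongly heterogeneous depths the resulting offsets
  over-correct, which is why the generator's default depths are uniform.
* The treatment-level likelihood-ratio test spends 6 degrees of freedom per
  treatment; single-time effects are diluted, and its chi-square reference
  is mildly anti-conservative at n = 3 replicates per cell (the BH-level
  null calibration is verified by simulation in the tests).
* Family assignment is catalog-driven; novel miRNAs without a precursor
  match are out of scope by design, mirroring the conservative annotation
  philosophy the package implements.
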