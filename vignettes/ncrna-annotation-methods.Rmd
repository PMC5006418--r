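---
title: "Methods: sensitivity-tuned homology annotation of ncRNAs"
author: "rnahomology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensitivity-tuned homology annotation of ncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnahomology)
```

## The problem

Homology annotation of non-coding RNA genes in a freshly assembled,
highly fragmented draft genome — hundreds of thousands of mostly
sub-kilobase, AT-rich contigs — fails when run as a single search with
default parameters.  Many ncRNA families (snRNAs, snoRNAs, diverged
miRNAs) sit at 60–80 % identity to their nearest annotated relatives,
below what default nucleotide search parameters detect reliably.  The
package implements a multi-stage protocol: an ensemble of
sensitivity-tuned local searches casts a wide net, rule-based filters
and structure-aware probabilistic models (profile HMMs and covariance
models) then cut the candidate list down to a high-confidence
annotation, and the final set feeds comparative analyses
(gain/loss histories under Dollo parsimony).

Because ncRNAs are short (typically < 200 nt) and unspliced, severe
assembly fragmentation is tolerable: a locus nearly always fits inside
one contig.

## Search strategy ensemble

`make_strategy()` exposes nine parameterisations of word-seeded local
alignment — match reward `r`, mismatch penalty `q`, gap open `G`, gap
extend `E` (a gap of length $k$ costs $G + kE$), word size `W` and an
expectation cutoff — eight tuned presets plus the standard default
(`r=1, q=-3, G=5, E=2, W=11, e=10`).  Low-threshold presets pair small
words (`W=7`) with reward/penalty ratios of +5/−4 or +4/−5, whose
optimal-alignment target identities sit near 65 %, and expectation
cutoffs up to 1000.  Presets that leave the cutoff unstated fall back
to the default of 10.  The preset table is config-overridable because
the printed source of such tables is typographically fragile; the
default row anchors the column order to the standard `blastn`
parameters.

The aligner itself (`blast_search()`, Rcpp) is a classic three-stage
seed-and-extend: exact `W`-mer seeding against a hashed query, ungapped
X-drop extension (X-drop `20*r`), and a banded affine-gap local
alignment (band 40 diagonals) around segments that reach a trigger
score (`W*r` plus six extra match-equivalents; all three knobs are
exposed in the config).  E-values use Karlin–Altschul statistics
$E = K m n e^{-\lambda S}$ with $\lambda$ solved by bisection from the
background composition and $K$ from the ungapped geometric-series
approximation.  The gapped $\lambda$ is approximated by the ungapped
one, the standard shortcut when no island calibration is run; E-values
therefore rank and threshold rather than estimate literal probabilities
— visibly so for cheap-gap schemes such as +4/−5 with `G=3`, where the
nominal E-values are optimistic by orders of magnitude.  The
downstream model validation, not the E-value, carries the specificity
burden (see below).

`N` is allowed in genomic sequence; it never seeds a word and scores as
a mismatch everywhere.

## Filtering, merging, extension

Raw hits pass four rules, with the boundary semantics taken literally
from their wording: query coverage at least 40 % (inclusive), alignment
length strictly greater than 20 columns, identity at least 75 %
(inclusive), and same-strand merging of near-adjacent hits (gap at most
30 nt, a deliberately small default relative to typical ncRNA lengths)
provided the merged hull does not exceed 125 % of the query length.
Whether coverage should be tested before or after merging is
under-determined; the filter runs before merging, and since merging can
only increase coverage while keeping identity a match-weighted mean of
passing values, a post-merge re-check is implied automatically.
Surviving hits are extended to the query length (centred; asymmetric
when a contig edge clips one side) plus 10 nt flanks.  Regions from
different queries of one family that overlap reciprocally by ≥ 90 % are
collapsed, accumulating the supporting species and strategy sets — the
bookkeeping that later reports which species' queries support each
locus.

## Profile HMMs

`build_phmm()` estimates a profile from the family seed alignment:
match columns are those with < 50 % gaps, emissions and transitions get
Laplace (+1) pseudocounts, inserts emit the background, and the null
model is the seed's residue composition.  Scoring is local (uniform
entry/exit over match states, free flanks) with forward, Viterbi and
forward–backward posteriors computed in compiled code; the scan runs
windows of `2M` with stride `M` on both strands.  E-values come from a
maximum-likelihood Gumbel fit to forward bitscores of
mononucleotide-shuffled genome windows (default 1000; at least 100
enforced), scaled by the number of windows scanned, with hits kept at
E ≤ 0.01.  The reported interval is the posterior envelope: the maximal
run of positions whose posterior probability of being emitted by the
model is at least 0.5.

## Miniature covariance models

`build_cm()` compiles the seed's consensus structure into a guide tree
of MATP (paired columns, 16-way pair emissions), MATL/MATR (unpaired)
and BIF (multiloop) nodes; per-node match/delete transitions are
estimated from column usage, inserts carry a flat per-residue penalty
(`t_ins = 0.01`).  An optional taxon filter drops seed rows before
counting, mirroring clade-specific model construction; topology always
comes from the structure line alone.

`cm_cyk()` runs exhaustive CYK: global in the model (every consensus
position matched or deleted) and local in the sequence — the best parse
of any substring is reported, with flanking residues free.  The
strictly global score (`bitscore_global`), in which every residue must
be emitted, is also returned; it is the quantity the exhaustive parse
enumeration in the test suite defines.  The local-in-sequence
convention is what makes scores comparable between a tight candidate
region and the same candidate re-extracted with 300 nt flanks at
curation; charging every flank residue as an insert would make windowed
re-scoring structurally impossible.  Sequences longer than `4*clen`
must go through the windowed scan (`cm_score_window()`: windows of
`2*clen`, 50 % overlap).

Calibration (`calibrate_cm()`) scores mononucleotide shuffles of the
model consensus (default 1000) and fits a Gumbel by maximum
likelihood.  E-values use the exact Gumbel tail scaled by the number of
scoring trials — the exact tail, rather than its exponential
approximation, so that the self-consistency identity (the median null
score has E ≈ n/2 under its own calibration set) holds by construction;
for significant hits the two agree.  Real family models come with a
curated gathering threshold; toy and synthetic families have none, so
`GA` defaults to the maximum calibration-null score plus 2 bits and can
be overridden.

Acceptance at screening requires all three of: bitscore **not lower
than** GA, E < 0.01, and model coverage (matched consensus positions /
`clen`) of at least 70 %.  Overlapping same-family hits merge to their
coordinate hull; across families the better bitscore wins, with ties
broken by E-value and then family name.  Final curation re-extracts
each accepted hit with 300 nt flanks, re-scores, and keeps loci with
E < 0.01 and bitscore **strictly greater than** GA — the asymmetry
(≥ at screening, > at curation) follows the differing wording of the
two stages' rules.  Curated coordinates are tightened to the re-scored
alignment footprint; hits with less than 300 nt of available flank are
curated on the clipped window and flagged.

## Contamination screen

Two rules flag a contig as bacterial/archaeal contamination: any HSP
against the contaminant reference set with E < 1e−10, identity > 75 %
and length > 20 nt; or a merged HSP footprint covering ≥ 70 % of the
contig at ≥ 80 % identity ("similarity" is implemented as alignment
identity; the sources give it no separate definition).  Coverage counts
overlapping HSP intervals once.  Flagged contigs are removed before
annotation.

## Performance estimation

`shuffle_sequence()` provides mononucleotide (Fisher–Yates) and
dinucleotide (Altschul–Erickson Eulerian-walk) shuffles; the
mononucleotide order is the default, with the dinucleotide option
available because structure-biased nulls matter when covariance models
are involved.  `evaluate_strategy()` builds per-strategy,
per-RNA-class confusion matrices: TP counts truth loci recovered by
filtered candidates at ≥ 50 % reciprocal overlap (an operational
definition chosen here; "detected locus" has no canonical one), FP
counts shuffled query sequences (not individual hits, keeping FP
bounded by the number of nulls) that yield a passing candidate.
Sensitivity is TP/(TP+FN), specificity TN/(FP+TN).

Filter-stage specificity is deliberately not the headline number: with
expectation cutoffs of 1000 and cheap gaps, a 90 nt query finds a
35–40-column, 75 %-identity local alignment somewhere in megabases of
random sequence quite often.  The protocol's specificity claim is about
the full pipeline — `pipeline_specificity()` sends every shuffle
through search, filters, CM validation and curation, where the
structure model removes essentially all of them.

## Dollo parsimony

Each family is gained exactly once and may be lost repeatedly.  The
gain is placed at the MRCA of the presence leaves; nodes on paths from
the gain to presence leaves are present; losses are edges from a
present parent into an absent subtree.  This minimises losses subject
to the single-gain rule (verified against exhaustive enumeration in the
tests).  Ancestral-state constraints are hard: published knowledge
overrides parsimony, relocating the gain if a constrained presence sits
above it, and contradictions with observed leaves are errors rather
than soft conflicts.  Edge and node aggregates satisfy
`count(child) = count(parent) + gains − losses` on every edge — the
identity that lets printed ancestral counts be propagated along printed
edge events (e.g. 58 snoRNA families + 18 − 1 + 6 − 1 = 80;
37 miRNA families + 50 − 5 = 82).  `family_sets()` reports shared and
group-specific families, e.g. colonial versus solitary tunicates.  The
shipped species tree (12 chordate/outgroup taxa, named internal nodes)
is an editable Newick fixture, not data.

## Synthetic benchmark genomes

`build_genome()` emulates the statistical shape of a fragmented draft
assembly: i.i.d. background at GC 0.36, log-normal contig lengths
(median 500 nt, sdlog 0.65, truncated to [200 nt, 25 kb]) putting
roughly 85 % of contigs under 1 kb; planted family instances derived
from the seed consensus (so model scores have a well-defined optimum)
and mutated to a controlled identity with indels planned first and
substitutions compensating, keeping the trace-derived identity within
rounding of the target; pseudogenised copies truncated to 40–70 %
length with extra divergence; and contaminant contigs copied from a
reference at 95–100 % identity.  A machine-readable truth table records
every planted interval.

What the generator does **not** model: dinucleotide correlations and
isochore-like composition heterogeneity of real genomes, sequencing
error, assembly artefacts (chimeras, collapsed repeats), paralog
clustering, and realistic family-specific conservation patterns (each
synthetic family is a random consensus with a simple stem).  Passing
the planted-truth benchmark therefore demonstrates that the machinery
implements its decision rules correctly at realistic divergences and
scale — not that real-genome sensitivity will match it.

## Numerical and design choices

* Coordinates are 0-based half-open on the forward strand internally;
  minus-strand features carry forward coordinates plus a strand flag.
  GFF3 conversion (1-based inclusive) happens in exactly one writer.
* U→T at read time; one DNA alphabet everywhere.
* The forward scan runs in scaled linear space (per-position
  renormalisation), the short-sequence DP in log space; CYK is max-plus
  in log space.  Gumbel fitting solves the profile likelihood in the
  scale parameter with `uniroot`.
* Ties in CYK tracebacks resolve in a fixed operation order (match,
  delete, insert; leftmost split first), making tracebacks
  deterministic.
* Overlap arbitration ties resolve by E-value, then lexicographic
  family id — determinism over aesthetics.
* All stochastic steps (shuffles, calibrations, generators) take
  explicit seeds and restore the caller's RNG state; identical inputs
  give byte-identical outputs.

Benchmark problem sizes used by the shipped checks: the planted-truth
suite runs three families (80–110 nt) on a 2 Mb genome with 1000
shuffled nulls and 1000-sample calibrations; the acceptance script uses
a 600 kb genome, 500-sample calibrations and 300 nulls per family.
These sizes give stable pass/fail behaviour for the properties tested;
scaling them up changes runtimes, not conclusions.

## Known limitations

* The covariance models are miniature: no local model ends, no
  truncated-hit states, no query-dependent banding; whole-genome CM
  scanning is possible via windowing but the intended use is validating
  candidate regions from the sequence-based tracks, which is also how
  the protocol deploys it.
* Gapped E-values inherit the ungapped lambda; do not read them as
  probabilities for permissive gap costs.
* The theoretical-frequency column of the strategy table is carried as
  metadata only; its published derivation is not reproduced here, and
  our Karlin–Altschul target frequency differs for the +5/−4 schemes
  (≈ 0.65 vs the printed 69 %).
* Dollo parsimony assumes orthology calls are correct; it cannot
  distinguish true loss from assembly gaps or divergence beyond
  recognition — which is precisely why the comparative module treats
  absence constraints as hard external knowledge.
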