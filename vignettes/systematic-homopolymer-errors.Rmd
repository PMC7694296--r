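---
title: "Profiling systematic homopolymer indel errors in hybrid assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling systematic homopolymer indel errors in hybrid assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sysindel)
```

## The problem

Single-molecule long-read sequencing historically miscounts the length of
homopolymer tracts. In high-GC bacterial genomes this produces *systematic*
errors: at specific G/C homopolymers, the large majority of long reads carry
the same single-base deletion, so the error is incorporated into the
consensus assembly and survives coverage-based polishing unless accurate
short reads are brought in. Left uncorrected, each such deletion is a
frameshift; genome-wide they masquerade as hundreds of pseudogenes
("apparent mutants"), splitting essential genes such as the DNA gyrase
subunits into two or three spurious ORFs.

`sysindel` implements the full characterization of this phenomenon as a
reusable, tested pipeline:

1. a **synthetic-data generator** (multi-replicon high-GC genome, CDS
   annotations, planted systematic deletions, pre-aligned long/short read
   sets with known truth),
2. **pileup-based detection** of loci where the long-read consensus indel is
   rejected by the short-read consensus,
3. **homopolymer context** statistics (which tract classes are affected, and
   what fraction of the eligible class),
4. **coding-frame impact** (how many CDS fragment, and into how many ORFs),
5. a **flanking-motif consensus search** (PWM information content with a
   permutation null), and
6. **replicon copy-number ratios** from relative read depth.

## The model

### Reads and pileups

Reads are exchanged pre-aligned in a PAF-like TSV with explicit `{=, X, I,
D}` edit operations; `M` is deliberately not supported because indel-versus-
mismatch ambiguity is fatal to pileup-based indel calling. All internal
coordinates are 0-based half-open; GFF3 on disk is 1-based inclusive. The
pileup records, per reference position, total depth (including reads that
delete the base), base counts (matches count the reference base, mismatches
the read base), deletion support, and insertion support attached to the
column of the preceding base, so that `depth = sum(base_counts) +
del_support` holds at every column — a conservation law asserted by the
tests.

### Detection

Detection is two-staged:

* **candidate gate** — a column (or a single inserted allele) must reach 50%
  of the local depth to be a consensus indel call at all. This formalizes
  "the error that the assembler would incorporate into the consensus".
  Adjacent deletion columns are merged into one call (allele = concatenated
  bases, support and depth = the run minima, conservatively).
* **systematic label** — a long-read call is labelled systematic when its
  concordance passes the long-read threshold (default 0.9) *and* the
  short-read pileup at the same locus (depth ≥ 10) agrees with the
  reference at ≥ the short threshold (default 0.9) across the call's span.

**How the long threshold is applied.** The thresholds describe a property
of the locus — "more than 90% of the long reads carry the same error" —
while the pileup only ever shows a binomial *sample* of that concordance.
If the generating concordance sits exactly at the threshold (the default
study condition), comparing the sample fraction directly against the
threshold rejects half of the true loci by symmetric binomial fluctuation,
at any depth. `sysindel` therefore applies the long-read threshold as an
exact one-sided binomial criterion: a call is kept unless its support count
falls below `qbinom(alpha, depth, long_threshold)`, i.e. unless the data
are inconsistent (at level `alpha`, default 0.01) with a true concordance
at or above the threshold. A locus whose true concordance equals the
threshold is then retained with probability `1 - alpha` ≈ 0.99 instead of
~0.5. The literal sample-fraction comparison remains available as
`detection_params(long_rule = "point")`. The short-read side keeps the
point rule: with a per-base error rate of 0.002, its true reference
agreement (~0.998) is nowhere near the 0.9 threshold, so the boundary
problem does not arise.

Ties at a threshold count as passing (`>=`): the source material is
inconsistent between "more than 90%" and "90%", and the inclusive reading
is the one that keeps the two 90% figures symmetric.

### Homopolymer context

Tracts are maximal runs of one base; the inventory is enumerated at
`min_len = 2` and the *eligibility* filter (base in {G, C}, length in
[5, 6]) is applied at summary time. The published "1.64% of those present
in the genome" does not say whether the denominator is all G/C homopolymers
or only the 5–6-mer class; both readings are computed
(`eligible_affected_fraction` and `all_affected_fraction`) and the headline
figure uses the eligible class, which is the class the planted fraction is
defined on. Deletion calls are left-aligned, so context assignment allows
one base of slack at the tract boundaries, and the deleted allele must
equal the tract base. A tract counts as affected once, however many
discrepancies fall in it.

### Coding impact

`apply_indels()` reconstructs the erroneous consensus sequence and a
coordinate map; each CDS interval is carried across the map and translated
on its strand from frame 0. A premature stop ends an ORF fragment;
scanning resumes at the next start codon at *any* offset within the
original CDS footprint — this mirrors how annotation pipelines split a
frameshifted gene into consecutive ORFs, which is exactly the published
gyrase observation (one deletion → two ORFs; two spaced deletions → three).
Choices where the source is silent: countable fragments need ≥ 30 aa (a
typical annotation floor); start codons are the bacterial table-11 set
{ATG, GTG, TTG}; and "disrupted" requires a frameshift that either
fragments the CDS or costs ≥ 20% of the C-terminus to a premature stop —
a plain point comparison of sample translation against annotation would
otherwise count synonymous-frame perturbations that no annotator would
call a pseudogene.

### Motif search

For each affected tract, the 20 bp immediately upstream and downstream
(tract excluded) are concatenated into a 40 bp forward-strand window. The
statistic is the **maximum per-position information content** in bits,
`ic_j = sum_b p_bj log2(p_bj / q_b)` with a 0.5 pseudocount, against base
frequencies `q` estimated from the whole genome — windows near G/C tracts
are compositionally biased, so the window set itself would be an unfair
null reference. Max-IC (not mean) is the statistic because the question is
whether a *localized* consensus exists; mean IC is reported alongside. The
null is built by resampling unaffected eligible tracts matched exactly on
the (base, length) histogram of the observed loci, and
`p = (1 + #{null >= observed}) / (n_perm + 1)`. Calibration (type-I error
at the nominal level) and power on a planted flank k-mer are both part of
the test suite.

### Copy numbers

Mean depth is total aligned reference bases over replicon length, counting
zero-coverage positions. The display convention **truncates toward zero at
two significant figures** ("x:1"): this is the convention that reproduces
all three published ratio displays (1.368 → "1.3:1", 0.384 → "0.38:1",
1.319 → "1.3:1") where round-half-up would not. The small-plasmid ratio is
published as "1:1.3" but the megaplasmid as "1.3:1"; the package always
puts the replicon first. A consequence of truncation worth knowing: a
sampled ratio of 1.2999 displays as "1.2:1" — the numeric `ratio` column
is the quantitative record, the display is cosmetic.

## The generator and what it does (not) emulate

The generator's defaults are the study conditions: four circular replicons
with the published lengths (2,021,843 / 370,865 / 77,135 / 9,799 bp) and
depth-derived copy numbers (1 : 1.3 : 0.38 : 1.3), 68.79% GC, deletions
planted at 1.64% of eligible G/C 5–6-mer tracts, 0.9 long-read concordance
per covering read (independently, i.e. binomially), 300× long / 50× short
chromosome depth, 11,306 bp long reads and 250 bp short reads (the upper
end of the published mate-pair read-length range; pairing itself is not
modelled, as it adds nothing to single-position indel consensus).

Base composition is calibrated analytically: CDS interiors are drawn from
the composition-implied codon distribution conditioned on not being a stop,
which enriches G+C, while the fixed ATG starts and stop codons deplete it;
`simulate_genome()` solves for the per-base G+C probability that makes the
expected realized genome hit the GC parameter, and at 2.48 Mbp the realized
value concentrates within ~0.03 percentage points. Annotation density
defaults to about one CDS per 3 kb (300–1500 bp, both strands,
non-overlapping, origin region left free) — sparser than a real bacterial
genome, which keeps intergenic space for homopolymer statistics at desk
scale; at 68.79% GC the eligible 5–6-mer tract density is ~5.6 per kb, so
no extra tract boosting is needed (a `homopolymer_boost` knob exists for
lower-GC settings).

Background sequencing noise is a per-base rate (2% long, 0.2% short)
split 80/10/10 between substitutions, 1-bp insertions and 1-bp deletions —
an invented, configurable profile; the source gives none. Not modelled:
quality scores, chimeric reads, GC-dependent coverage bias, mate-pair
structure, length-dependent homopolymer error escalation. Reads are emitted
pre-aligned (mapping is out of scope by design), so passing tests say
nothing about alignment artefacts on real data; they do establish that the
*measurement chain* — pileup, consensus, technology comparison, context,
translation, depth ratios — recovers known truth under realistic
statistical structure.

Reads longer than a replicon (the default long-read length exceeds the
smallest plasmid) are truncated to one full circle; reads crossing the
origin of a circular replicon are split into two alignment records sharing
a read id (`/a`, `/b`), keeping pileup logic linear.

## Numerical and reproducibility choices

* Every stage seed is derived deterministically from one master seed
  (multiplicative hash, kept below 2^31); identical configuration implies
  byte-identical report payloads, and the report carries no timestamps.
* Detection is invariant to read order (pileups are order-free tallies),
  and single-threaded by construction.
* Degenerate inputs: empty read sets give empty pileups and empty call
  tables, not errors; a zero planted fraction yields an empty truth set and
  the pipeline skips the motif stage with a stated reason; a locus without
  usable short-read coverage is dropped with a warning rather than
  silently classified.
* Problem sizes: the analysis scripts and the end-to-end test run a 250 kb
  four-replicon scale model (~1,400 eligible tracts, ~23 planted loci),
  which this package treats as its standard desk-scale system; the
  acceptance script re-runs the recovery at the full 2.48 Mbp scale
  (~13,900 eligible tracts, 228 planted).

## Known limitations

* The binomial-boundary labelling rule admits loci whose true concordance
  is slightly below the nominal threshold (by design — they are the same
  phenomenon); users wanting the literal cutoff can switch to
  `long_rule = "point"`, at the cost of ~50% recall when the true
  concordance sits at the threshold.
* Insertion alleles are compared by exact string equality; two different
  inserted strings at one column are distinct alleles and do not pool.
* The ORF scanner restarts at the first start codon after a premature stop;
  real annotators may choose a different (e.g. RBS-guided) restart, so
  fragment counts should be read as "consecutive ORFs an automated
  annotator would emit", not gene models.
* Multi-base deletions are represented and called (as merged runs), but the
  planted truth only ever contains single-base events, matching the studied
  error mode.
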