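# sysindel

Systematic homopolymer indel profiling for hybrid long/short-read bacterial
assemblies.

## The problem

Single-molecule long-read chemistry miscounts homopolymer lengths. In
high-GC bacteria this failure is not random noise: at specific G/C
homopolymer tracts (typically 5–6 bp), the large majority of long reads
carry the *same* single-base deletion, so the error enters the consensus
assembly and looks exactly like a real mutation. Genome-wide, an
uncorrected long-read draft of a ~2.5 Mbp, ~69% GC genome can carry on the
order of one such deletion per kilobase — each one a frameshift that splits
coding genes into spurious ORF fragments (a DNA gyrase subunit appearing as
two or three "genes", and hundreds of artifactual pseudogenes overall).
Accurate short reads at the same loci show no interruption, which is both
the diagnostic and the cure.

`sysindel` is for bioinformaticians who assemble or polish such genomes and
want the error mode itself characterized: where the systematic indels are,
what fraction of the homopolymer inventory they hit, what they do to the
annotation, whether their flanking sequence carries any predictive
consensus, and — from the same read data — the per-replicon copy-number
ratios.

## What it computes

Given a reference genome, CDS annotations, and aligned long- and short-read
sets (or its own synthetic versions of all three, with planted ground
truth):

* **Pileups and consensus calls** — per-position tallies with the
  conservation law `depth = matches + mismatches + deletions`; a candidate
  indel call requires ≥ 50% consensus at ≥ a minimum depth.
* **Systematic discrepancies** — a long-read call is *systematic* when its
  support passes the 0.9 concordance threshold (applied as an exact
  one-sided binomial criterion on the support count, so a locus whose true
  concordance sits at the threshold is retained with probability ~0.99)
  and the short-read pileup agrees with the reference at ≥ 0.9 at the same
  locus.
* **Homopolymer context** — the fraction of eligible G/C 5–6-mer tracts
  affected (the study-condition value is 1.64%), with per-(base, length)
  class tables.
* **ORF impact** — applies the indels, translates each CDS in the shifted
  coordinates (bacterial table 11, restart at the next start codon after a
  premature stop), and counts ORF fragments ≥ 30 aa: one mid-gene deletion
  → 2 ORFs, two spaced deletions → 3.
* **Motif search** — 20 bp flanks either side of each affected tract,
  position frequency matrix, per-position information content
  `ic_j = Σ_b p̂_bj log2(p̂_bj / q_b)` in bits against the genome
  background, and a permutation p-value from resampling unaffected tracts
  matched on (base, length).
* **Copy numbers** — mean depth per replicon relative to the chromosome,
  displayed truncated toward zero at two significant figures ("1.3:1").

## Worked example

Copy-number ratios from the published per-replicon depths of a four-replicon
*Thermus* genome (shipped in `inst/extdata/nar1_replicon_stats.tsv`):

```r
library(sysindel)
tab <- readr::read_tsv(system.file("extdata", "nar1_replicon_stats.tsv",
                                   package = "sysindel"), show_col_types = FALSE)
copy_ratio(setNames(tab$mean_depth, tab$replicon_id), "Chromosome",
           lengths = setNames(tab$length, tab$replicon_id))
#>   replicon_id  length mean_depth     ratio ratio_display
#> 1  Chromosome 2021843      339.8 1.0000000         1.0:1
#> 2     pTTHNP2    9799      448.2 1.3190112         1.3:1
#> 3     pTTHNP3   77135      130.5 0.3840494        0.38:1
#> 4     pTTHNP4  370865      464.9 1.3681577         1.3:1
```

The megaplasmid pTTHNP4 sits at 1.3 copies per chromosome, pTTHNP3 at 0.38
— it is being lost from part of the population — and the small plasmid
pTTHNP2 at 1.3.

An end-to-end run on a small synthetic system (70 kb, two replicons,
deletions planted at 1.64% of eligible G/C 5–6-mers with 0.9 long-read
concordance, 300×/50× depth):

```r
cfg <- pipeline_config(
  genome_params = genome_params(replicon_lengths = c(60000, 10000),
                                gc_fraction = 0.6879,
                                copy_numbers = c(1, 1.3), seed = 7),
  error_params  = error_model_params(affected_fraction = 0.0164,
                                     concordance = 0.9, seed = 7),
  long_params   = tech_params("long", mean_read_len = 2000, depth = 300, seed = 7),
  short_params  = tech_params("short", depth = 50, seed = 7),
  n_perm = 199, seed = 7)
run_pipeline(cfg, quiet = TRUE)
#> <pipeline_report>
#>   genome: 2 replicon(s), GC 69.19%
#>   discrepancies: 7 (7 del / 0 ins), 0.1 deletions/kb
#>   eligible tracts affected: 7 / 417 (1.68%)
#>   disrupted CDS: 2
#>   motif test: max IC 0.897 bits, p = 0.105
```

All 7 planted loci are recovered (7/417 = 1.68% against the planted
round(0.0164 × 417)/417 = 1.68%), two CDS are frameshifted into fragments,
and the flanking-motif test finds no consensus — the expected negative on
data with no planted motif.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on a 250 kb scale
model and write their tables under `results/` (bulky intermediates go to
`scratch/`):

```sh
Rscript analysis/01_simulate.R     # genome, CDS, truth set, read sets
Rscript analysis/02_detect.R      # pileups, calls, systematic discrepancies
Rscript analysis/03_context_orf.R # homopolymer context + ORF fragmentation
Rscript analysis/04_motif.R       # flanking-motif permutation test
Rscript analysis/05_copy_number.R # copy-number ratios, published + simulated
```

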