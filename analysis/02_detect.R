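#!/usr/bin/env Rscript
# Detect systematic discrepancies: per-technology pileups, long-read
# consensus indel calls, and the long-vs-short comparison at the 0.9 / 0.9
# concordance thresholds. Writes the discrepancy table and a genome-wide
# summary.

library(sysindel)

datadir <- "scratch/sim_data"
g <- read_fasta(file.path(datadir, "genome.fasta"))
long_reads <- read_alignments(file.path(datadir, "long_reads.tsv"), g)
short_reads <- read_alignments(file.path(datadir, "short_reads.tsv"), g)

dp <- detection_params(long_threshold = 0.9, short_threshold = 0.9)
calls <- list()
short_piles <- list()
for (r in g) {
  pl <- build_pileup(long_reads[long_reads$replicon_id == r$id, ], r)
  calls[[r$id]] <- call_indels(pl, dp, "long")
  short_piles[[r$id]] <- build_pileup(
    short_reads[short_reads$replicon_id == r$id, ], r)
  message(sprintf("%s: %d long-read consensus indel calls at mean depth %.0fx",
                  r$id, nrow(calls[[r$id]]), mean_depth(pl)))
}
disc <- compare_technologies(dplyr::bind_rows(calls), short_piles, dp)

es <- summarize_discrepancies(disc, g)
print(es)
message(sprintf("%d of %d calls are systematic (high long-read concordance, rejected by short reads)",
                nrow(disc), nrow(dplyr::bind_rows(calls))))

write_discrepancies(disc, "results/discrepancies.tsv")
jsonlite::write_json(unclass(es), "results/error_summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/discrepancies.tsv and results/error_summary.json")
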