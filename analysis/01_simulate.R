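#!/usr/bin/env Rscript
# Build the synthetic study system: a four-replicon high-GC genome scaled to
# 250 kb (same replicon proportions and copy numbers as the full 2.48 Mbp
# system), CDS annotations, systematic single-base deletions planted at
# 1.64% of the eligible G/C 5-6-mer tracts, and pre-aligned long (300x) and
# short (50x) read sets. Everything downstream reads the files written here.

library(sysindel)

outdir <- "scratch/sim_data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 2024L

gp <- genome_params(replicon_lengths = c(200000L, 30000L, 12000L, 8000L),
                    gc_fraction = 0.6879,
                    copy_numbers = c(1, 1.3, 0.38, 1.3), seed = seed)
sim <- simulate_genome(gp)
message(sprintf("genome: %s bp over %d replicons, GC %.2f%% (target 68.79%%)",
                format(genome_size(sim$genome), big.mark = ","),
                length(sim$genome), 100 * gc_fraction(sim$genome)))

em <- error_model_params(affected_fraction = 0.0164, concordance = 0.9,
                         seed = seed + 1L)
truth <- plant_systematic_errors(sim$genome, sim$cds, em)
message(sprintf("planted %d deletions in %d eligible G/C 5-6-mer tracts (%.2f%%)",
                sum(truth$loci$planted), nrow(truth$loci),
                100 * mean(truth$loci$planted)))

long_reads <- simulate_reads(sim$genome, truth,
                             tech_params("long", seed = seed + 2L))
short_reads <- simulate_reads(sim$genome, truth,
                              tech_params("short", seed = seed + 3L))
message(sprintf("simulated %s long and %s short aligned reads",
                format(nrow(long_reads), big.mark = ","),
                format(nrow(short_reads), big.mark = ",")))

write_fasta(sim$genome, file.path(outdir, "genome.fasta"))
write_gff3(sim$cds, file.path(outdir, "cds.gff3"))
write_truth(truth$loci, file.path(outdir, "truth.tsv"))
write_alignments(long_reads, file.path(outdir, "long_reads.tsv"))
write_alignments(short_reads, file.path(outdir, "short_reads.tsv"))
message("wrote genome, annotations, truth set and alignments under ", outdir)
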