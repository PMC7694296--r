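#!/usr/bin/env Rscript
# Flanking-motif consensus search: does the sequence context around affected
# homopolymer tracts carry positional information that unaffected tracts of
# the same base and length composition lack? Position frequency matrix over
# 20 bp flanks, information content against the genome background, and a
# class-matched permutation test.

library(sysindel)

datadir <- "scratch/sim_data"
g <- read_fasta(file.path(datadir, "genome.fasta"))
disc <- readr::read_tsv("results/discrepancies.tsv", show_col_types = FALSE)

em <- error_model_params()
tracts <- find_homopolymers_genome(g, min_len = 2)
elig <- tracts[tracts$base %in% em$target_bases &
                 tracts$length >= em$target_len_range[1] &
                 tracts$length <= em$target_len_range[2], ]

aff <- disc[!is.na(disc$tract_start), ]
aff_loci <- unique(tibble::tibble(replicon_id = aff$replicon_id,
                                  start = aff$tract_start,
                                  length = aff$tract_len,
                                  base = aff$tract_base))
unaff <- elig[!paste(elig$replicon_id, elig$start) %in%
                paste(aff_loci$replicon_id, aff_loci$start), ]
message(sprintf("%d affected loci vs %d unaffected eligible tracts",
                nrow(aff_loci), nrow(unaff)))

obs <- extract_flanks(g, aff_loci, w = 20)
res <- permutation_consensus_test(obs, unaff, g, n_perm = 999, seed = 99)
print(res)
if (res$p_value > 0.05) {
  message("no significant flanking sequence consensus at the affected loci")
} else {
  message("flanking consensus signal detected (check for planted motifs)")
}

write.table(res$pfm, "results/motif_pfm.tsv", sep = "\t", quote = FALSE,
            col.names = FALSE)
readr::write_tsv(tibble::tibble(position = seq_along(res$ic) - 21L,
                                ic_bits = res$ic),
                 "results/motif_ic.tsv")
jsonlite::write_json(
  list(max_ic = res$max_ic, mean_ic = res$mean_ic, p_value = res$p_value,
       n_perm = res$n_perm, n_windows = res$n_windows, seed = res$seed),
  "results/motif_result.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/motif_pfm.tsv, results/motif_ic.tsv, results/motif_result.json")
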