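# Shared toy fixtures, built in code at test time.

# small two-replicon genome + annotations at the study's GC
toy_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_genome(genome_params(
        replicon_lengths = c(60000, 10000), gc_fraction = 0.6879,
        copy_numbers = c(1, 1.3), seed = 7))
    }
    cache
  }
})

# a hand-built frameshift gene: ATG, a GCC stretch, a GTA|AAC junction whose
# -1-shifted reading is a TAA stop, a CCA spacer, an in-frame restart ATG,
# a second GCC stretch and the terminal stop. Deleting the third base of the
# second codon (pos 5) shifts the GCC stretch to CCG codons, trips the
# hidden TAA, and leaves the downstream ATG...TAA as a second ORF.
gyr_gene_2frag <- function() {
  paste0("ATG", strrep("GCC", 30), "GTA", "AAC", strrep("CCA", 5),
         "ATG", strrep("GCC", 40), "TAA")
}

# same construction twice over: two spaced deletions yield three ORFs
gyr_gene_3frag <- function() {
  paste0("ATG", strrep("GCC", 30), "GTA", "AAC", strrep("CCA", 5),
         "ATG", strrep("GCC", 40), "GTA", "AAC", strrep("CCA", 5),
         "ATG", strrep("GCC", 40), "TAA")
}

# wrap a gene into a replicon with A-padding so tract scans stay quiet
gene_replicon <- function(gene, pad = 30L, id = "gx") {
  seq <- paste0(strrep("A", pad), gene, strrep("A", pad))
  list(
    rep = replicon(id, seq, topology = "linear"),
    cds = tibble::tibble(cds_id = "g1", replicon_id = id, start = pad,
                         end = pad + nchar(gene), strand = "+")
  )
}

# deterministic tiny read tibble helper
mk_read <- function(id, rid, start, ops, seq, strand = "+") {
  tibble::tibble(read_id = id, replicon_id = rid, start = as.integer(start),
                 strand = strand, ops = ops, seq = seq)
}

# construct a pileup object directly for arithmetic cases
mk_pileup <- function(ref, depth, del = 0L, ins = NULL, id = "chr") {
  L <- nchar(ref)
  depth <- rep_len(as.integer(depth), L)
  del <- rep_len(as.integer(del), L)
  refc <- strsplit(ref, "")[[1]]
  bc <- matrix(0L, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(L)) bc[refc[j], j] <- depth[j] - del[j]
  structure(list(replicon_id = id, length = L, ref = ref, depth = depth,
                 del = del, base_counts = bc,
                 ins = if (is.null(ins))
                   tibble::tibble(pos = integer(), allele = character(),
                                  count = integer()) else ins),
            class = "pileup")
}

# end-to-end toy run: simulate genome + truth + both read sets, detect
run_toy_detection <- function(sim, em, long_seed = 5, short_seed = 6,
                              long_len = 2000, depth_long = 300,
                              depth_short = 50, bg_long = 0.02,
                              bg_short = 0.002, dp = detection_params()) {
  truth <- plant_systematic_errors(sim$genome, sim$cds, em)
  lr <- simulate_reads(sim$genome, truth,
                       tech_params("long", mean_read_len = long_len,
                                   depth = depth_long,
                                   background_error = bg_long, seed = long_seed))
  sr <- simulate_reads(sim$genome, truth,
                       tech_params("short", depth = depth_short,
                                   background_error = bg_short, seed = short_seed))
  pl <- lapply(sim$genome, function(r)
    build_pileup(lr[lr$replicon_id == r$id, ], r))
  ps <- lapply(sim$genome, function(r)
    build_pileup(sr[sr$replicon_id == r$id, ], r))
  calls <- dplyr::bind_rows(lapply(pl, call_indels, params = dp, which = "long"))
  disc <- compare_technologies(calls, ps, dp)
  list(truth = truth, long = lr, short = sr, piles_long = pl, piles_short = ps,
       calls = calls, disc = disc)
}

rand_genome <- function(n_rep = 2, len = 3000, seed = 1) {
  withr::with_seed(seed, {
    genome(lapply(seq_len(n_rep), function(i) {
      replicon(paste0("r", i),
               paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                            prob = c(0.16, 0.34, 0.34, 0.16)), collapse = ""),
               topology = "circular")
    }))
  })
}

# naive interval lookup of the CDS containing each discrepancy position
assign_cds_ids_for_test <- function(disc, cds) {
  vapply(seq_len(nrow(disc)), function(i) {
    hit <- which(cds$replicon_id == disc$replicon_id[i] &
                   cds$start <= disc$pos[i] & disc$pos[i] < cds$end)
    if (length(hit)) cds$cds_id[hit[1]] else NA_character_
  }, character(1))
}
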