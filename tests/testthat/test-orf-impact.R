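disc_row <- function(pos, kind = "deletion", allele = "G", rid = "gx") {
  tibble::tibble(replicon_id = rid, pos = as.integer(pos), kind = kind,
                 allele = allele, support_fraction = 1, depth = 300L)
}

test_that("applying no indels is the identity with an identity map", {
  out <- apply_indels("ACGTACGT", disc_row(integer(0))[0, ])
  expect_equal(out$seq, "ACGTACGT")
  expect_equal(out$map, 0:8)
})

test_that("a 1-bp deletion shifts the coordinate map as expected", {
  seq <- strrep("ACGTA", 20)   # 100 bp
  out <- apply_indels(seq, disc_row(10, allele = substr(seq, 11, 11)))
  expect_equal(nchar(out$seq), 99L)
  expect_equal(out$map[9 + 1], 9L)
  expect_equal(out$map[11 + 1], 10L)
  expect_equal(out$map[100 + 1], 99L)

  ins <- apply_indels(seq, tibble::tibble(pos = 10L, kind = "insertion",
                                          allele = "GG"))
  expect_equal(nchar(ins$seq), 102L)
  expect_equal(ins$map[10 + 1], 10L)
  expect_equal(ins$map[11 + 1], 13L)
})

test_that("planted deletions can be reverted to reconstruct the original", {
  sim <- toy_sim()
  r <- sim$genome[["chr"]]
  truth <- plant_systematic_errors(sim$genome, sim$cds,
                                   error_model_params(affected_fraction = 0.05,
                                                      seed = 3))
  planted <- truth$loci[truth$loci$planted & truth$loci$replicon_id == "chr", ]
  dels <- tibble::tibble(replicon_id = "chr", pos = planted$pos,
                         kind = "deletion", allele = planted$base,
                         support_fraction = 1, depth = 300L)
  mut <- apply_indels(r$seq, dels)
  # invert: insert the deleted base after the preceding surviving position,
  # using mutated coordinates
  inv <- tibble::tibble(replicon_id = "chr",
                        pos = mut$map[dels$pos + 1] - 1L,
                        kind = "insertion", allele = dels$allele,
                        support_fraction = 1, depth = 300L)
  back <- apply_indels(mut$seq, inv)
  expect_equal(back$seq, r$seq)
})

test_that("overlapping discrepancies are rejected", {
  d <- dplyr::bind_rows(disc_row(5, allele = "GG"), disc_row(6))
  d$allele <- c("GG", "G")
  expect_error(apply_indels(strrep("G", 20), d), "overlapping")
})

test_that("an intact CDS translates to a single undisrupted fragment", {
  fx <- gene_replicon(gyr_gene_2frag())
  mut <- apply_indels(fx$rep$seq, disc_row(integer(0))[0, ])
  rec <- fragment_count(fx$cds, mut$seq, mut$map)
  expect_equal(rec$n_fragments, 1L)
  expect_false(rec$disrupted)
  expect_equal(rec$net_frame_offset, 0L)
})

test_that("gyr-like fixtures fragment into two and three ORFs, matching the translation oracle", {
  fx2 <- gene_replicon(gyr_gene_2frag())
  d2 <- disc_row(30 + 5, allele = substr(fx2$rep$seq, 36, 36))
  mut2 <- apply_indels(fx2$rep$seq, d2)
  rec2 <- fragment_count(fx2$cds, mut2$seq, mut2$map, d2)
  want2 <- oracle_fragments(substr(mut2$seq, mut2$map[fx2$cds$start + 1] + 1,
                                   mut2$map[fx2$cds$end + 1]))
  expect_equal(rec2$n_fragments, sum(want2 >= 30))
  expect_equal(rec2$n_fragments, 2L)
  expect_true(rec2$disrupted)
  expect_equal(rec2$net_frame_offset, 2L)   # -1 mod 3

  fx3 <- gene_replicon(gyr_gene_3frag())
  d3 <- dplyr::bind_rows(
    disc_row(30 + 5, allele = substr(fx3$rep$seq, 36, 36)),
    disc_row(30 + 119, allele = substr(fx3$rep$seq, 150, 150)))
  mut3 <- apply_indels(fx3$rep$seq, d3)
  rec3 <- fragment_count(fx3$cds, mut3$seq, mut3$map, d3)
  want3 <- oracle_fragments(substr(mut3$seq, mut3$map[fx3$cds$start + 1] + 1,
                                   mut3$map[fx3$cds$end + 1]))
  expect_equal(rec3$n_fragments, sum(want3 >= 30))
  expect_equal(rec3$n_fragments, 3L)
  expect_true(rec3$disrupted)
})

test_that("compensating indels inside one codon leave the frame and protein intact", {
  fx <- gene_replicon(gyr_gene_2frag())
  pad <- 30L
  d <- dplyr::bind_rows(
    tibble::tibble(replicon_id = "gx", pos = pad + 4L, kind = "insertion",
                   allele = "C", support_fraction = 1, depth = 300L),
    tibble::tibble(replicon_id = "gx", pos = pad + 5L, kind = "deletion",
                   allele = substr(fx$rep$seq, pad + 6, pad + 6),
                   support_fraction = 1, depth = 300L))
  mut <- apply_indels(fx$rep$seq, d)
  rec <- fragment_count(fx$cds, mut$seq, mut$map, d)
  expect_equal(rec$net_frame_offset, 0L)
  expect_equal(rec$n_fragments, 1L)
})

test_that("fragment counts equal the translation oracle on random frameshifts", {
  sim <- toy_sim()
  cds <- sim$cds[sim$cds$replicon_id == "chr", ]
  r <- sim$genome[["chr"]]
  withr::with_seed(41, {
    picks <- sample(nrow(cds), 15)
    for (j in picks) {
      p <- cds$start[j] + sample.int(cds$end[j] - cds$start[j] - 3, 1)
      d <- tibble::tibble(replicon_id = "chr", pos = p, kind = "deletion",
                          allele = substr(r$seq, p + 1, p + 1),
                          support_fraction = 1, depth = 300L)
      mut <- apply_indels(r$seq, d)
      rec <- fragment_count(cds[j, ], mut$seq, mut$map, d)
      nt <- substr(mut$seq, mut$map[cds$start[j] + 1] + 1,
                   mut$map[cds$end[j] + 1])
      if (cds$strand[j] == "-") {
        nt <- chartr("ACGT", "TGCA", paste(rev(strsplit(nt, "")[[1]]),
                                           collapse = ""))
      }
      expect_equal(rec$n_fragments, sum(oracle_fragments(nt) >= 30))
      expect_equal(rec$net_frame_offset, 2L)
    }
  })
})

test_that("CDS impact counting follows interval overlap and the truth set", {
  sim <- toy_sim()
  none <- count_affected_cds(sim$cds, disc_row(integer(0))[0, ], sim$genome)
  expect_equal(none$n_affected, 0L)

  # a discrepancy strictly between two CDS disrupts nothing
  cds <- sim$cds[sim$cds$replicon_id == "chr", ]
  gap_pos <- cds$end[1] + 3L
  stopifnot(gap_pos < cds$start[2])
  between <- tibble::tibble(replicon_id = "chr", pos = gap_pos,
                            kind = "deletion",
                            allele = substr(sim$genome[["chr"]]$seq,
                                            gap_pos + 1, gap_pos + 1),
                            support_fraction = 1, depth = 300L)
  expect_equal(count_affected_cds(sim$cds, between, sim$genome)$n_affected, 0L)

  # planted in-CDS loci: affected CDS = distinct CDS hit by a frameshift
  em <- error_model_params(affected_fraction = 0.1, cds_fraction = 0.6, seed = 9)
  truth <- plant_systematic_errors(sim$genome, sim$cds, em)
  planted <- truth$loci[truth$loci$planted, ]
  disc <- tibble::tibble(replicon_id = planted$replicon_id, pos = planted$pos,
                         kind = "deletion", allele = planted$base,
                         support_fraction = 1, depth = 300L)
  got <- count_affected_cds(sim$cds, disc, sim$genome)
  hit_cds <- unique(stats::na.omit(assign_cds_ids_for_test(disc, sim$cds)))
  expect_equal(nrow(got$records), length(hit_cds))
  expect_gt(got$n_affected, 0L)
  expect_lte(got$n_affected, length(hit_cds))
  # every record with a frameshift is disrupted or explained by a short
  # first fragment retained above the 80% cutoff
  expect_true(all(got$records$n_indels >= 1L))
})

test_that("adding discrepancies never un-disrupts a CDS", {
  sim <- toy_sim()
  em <- error_model_params(affected_fraction = 0.1, cds_fraction = 0.6, seed = 9)
  truth <- plant_systematic_errors(sim$genome, sim$cds, em)
  planted <- truth$loci[truth$loci$planted, ]
  disc <- tibble::tibble(replicon_id = planted$replicon_id, pos = planted$pos,
                         kind = "deletion", allele = planted$base,
                         support_fraction = 1, depth = 300L)
  half <- disc[seq_len(nrow(disc)) %% 2 == 0, ]
  a <- count_affected_cds(sim$cds, half, sim$genome)
  b <- count_affected_cds(sim$cds, disc, sim$genome)
  disrupted_a <- a$records$cds_id[a$records$disrupted]
  disrupted_b <- b$records$cds_id[b$records$disrupted]
  expect_true(all(disrupted_a %in% disrupted_b))
})
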