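test_that("pileup columns reproduce single-read and two-read bookkeeping", {
  rep <- replicon("chr", "ACGTACGTAC")
  pu <- build_pileup(mk_read("r1", "chr", 0, "5=", "ACGTA"), rep)
  cols <- pileup_columns(pu)
  expect_equal(cols$pos, 0:4)
  expect_equal(cols$depth, rep(1L, 5))
  expect_equal(cols$A + cols$C + cols$G + cols$T, rep(1L, 5))
  expect_equal(unname(pu$base_counts["A", 1]), 1L)

  reads <- dplyr::bind_rows(mk_read("r1", "chr", 0, "2=1D2=", "ACAC"),
                            mk_read("r2", "chr", 0, "5=", "ACGTA"))
  pu <- build_pileup(reads, rep)
  expect_equal(pu$depth[3], 2L)
  expect_equal(pu$del[3], 1L)
  expect_equal(sum(pu$base_counts[, 3]), 1L)
})

test_that("insertion support attaches to the preceding base's column", {
  rep <- replicon("chr", "ACGTACGTAC")
  pu <- build_pileup(mk_read("r1", "chr", 0, "3=2I2=", "ACGGGTA"), rep)
  expect_equal(pu$ins$pos, 2L)
  expect_equal(pu$ins$allele, "GG")
  expect_equal(pu$ins$count, 1L)
})

test_that("a read past a linear replicon end is an error", {
  rep <- replicon("chr", "ACGTACGTAC")
  expect_error(build_pileup(mk_read("r1", "chr", 8, "5=", "ACGTA"), rep),
               "past the end")
})

test_that("pileup depth equals the interval-stabbing oracle on random reads", {
  withr::with_seed(21, {
    rep <- replicon("chr", paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                                 collapse = ""))
    n <- 1000
    starts <- sample(0:450, n, TRUE)
    lens <- sample(10:50, n, TRUE)
    lens <- pmin(lens, 500 - starts)
    reads <- tibble::tibble(
      read_id = sprintf("r%04d", seq_len(n)), replicon_id = "chr",
      start = starts, strand = "+", ops = sprintf("%d=", lens),
      seq = substring(rep$seq, starts + 1, starts + lens))
    pu <- build_pileup(reads, rep)
    expect_equal(pu$depth, oracle_depth(reads, 500))
  })
})

test_that("depth decomposes into matches, mismatches and deletions everywhere", {
  sim <- toy_sim()
  em <- error_model_params(affected_fraction = 0.05, seed = 3)
  out <- run_toy_detection(sim, em, depth_long = 40, depth_short = 20)
  for (pu in c(out$piles_long, out$piles_short)) {
    expect_equal(pu$depth, as.integer(colSums(pu$base_counts) + pu$del))
  }
})

test_that("consensus calls obey the 0.5 gate and the depth gate", {
  pu <- mk_pileup(strrep("G", 5), depth = c(300L, 300L, 300L, 5L, 5L),
                  del = c(0L, 280L, 0L, 5L, 0L))
  calls <- call_indels(pu, detection_params(), "long")
  expect_equal(nrow(calls), 1L)    # the depth-5 column is gated out
  expect_equal(calls$pos, 1L)
  expect_equal(calls$kind, "deletion")
  expect_equal(calls$allele, "G")
  expect_equal(calls$support_fraction, 280 / 300)

  expect_equal(nrow(call_indels(mk_pileup("ACGT", 0L), detection_params(), "long")), 0L)
})

test_that("adjacent deletion columns merge into one multi-base call", {
  pu <- mk_pileup("ACGTT", depth = 100L, del = c(0L, 90L, 85L, 0L, 0L))
  calls <- call_indels(pu, detection_params(), "long")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$allele, "CG")
  expect_equal(calls$support_fraction, 0.85)   # conservative minimum
})

test_that("insertion alleles are called by exact string identity", {
  ins <- tibble::tibble(pos = 1L, allele = c("G", "GG"), count = c(160L, 30L))
  pu <- mk_pileup("ACGT", depth = 300L, ins = ins)
  calls <- call_indels(pu, detection_params(), "long")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$kind, "insertion")
  expect_equal(calls$allele, "G")
  expect_equal(calls$support_fraction, 160 / 300)
})

test_that("systematic labelling needs concordant long support and short rejection", {
  dp <- detection_params()
  long_calls <- tibble::tibble(
    replicon_id = "chr", pos = c(10L, 20L), kind = "deletion", allele = "G",
    support_fraction = c(280 / 300, 0.85), depth = c(300L, 300L))
  short_ref <- strrep("A", 30)
  sp <- mk_pileup(short_ref, depth = 50L)
  # 96% short reference agreement at pos 10
  sp$base_counts["A", 11] <- 48L
  sp$base_counts["G", 11] <- 2L
  disc <- compare_technologies(long_calls, list(chr = sp), dp)
  expect_equal(disc$pos, 10L)              # 0.933 in, 0.85 out (at 300x)
  expect_equal(disc$short_ref_fraction, 48 / 50)

  # under the point rule, sample fraction is compared directly
  dp_point <- detection_params(long_rule = "point")
  disc2 <- compare_technologies(long_calls, list(chr = sp), dp_point)
  expect_equal(disc2$pos, 10L)
})

test_that("a call without usable short coverage is dropped with a warning", {
  long_calls <- tibble::tibble(replicon_id = "chr", pos = 10L,
                               kind = "deletion", allele = "G",
                               support_fraction = 0.95, depth = 300L)
  sp <- mk_pileup(strrep("A", 30), depth = 2L)    # below min_depth_short
  expect_warning(out <- compare_technologies(long_calls, list(chr = sp),
                                             detection_params()),
                 "dropped")
  expect_equal(nrow(out), 0L)
})

test_that("raising the long threshold never adds discrepancies", {
  sim <- toy_sim()
  em <- error_model_params(affected_fraction = 0.05, seed = 3)
  out <- run_toy_detection(sim, em, depth_long = 100, depth_short = 30)
  n_prev <- Inf
  for (thr in c(0.6, 0.75, 0.9, 0.97)) {
    dp <- detection_params(long_threshold = thr)
    n <- nrow(compare_technologies(out$calls, out$piles_short, dp))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("detection is invariant under read-order permutation", {
  sim <- toy_sim()
  em <- error_model_params(affected_fraction = 0.05, seed = 3)
  truth <- plant_systematic_errors(sim$genome, sim$cds, em)
  lr <- simulate_reads(sim$genome, truth,
                       tech_params("long", mean_read_len = 2000, depth = 50,
                                   seed = 5))
  r <- sim$genome[["chr"]]
  rr <- lr[lr$replicon_id == "chr", ]
  shuffled <- withr::with_seed(99, rr[sample.int(nrow(rr)), ])
  p1 <- build_pileup(rr, r)
  p2 <- build_pileup(shuffled, r)
  expect_equal(p1$depth, p2$depth)
  expect_equal(p1$del, p2$del)
  expect_equal(p1$base_counts, p2$base_counts)
  expect_equal(call_indels(p1, detection_params(), "long"),
               call_indels(p2, detection_params(), "long"))
})

test_that("discrepancy summaries reproduce the published density arithmetic", {
  g <- genome(list(replicon("chr", "ACGT")))
  empty <- tibble::tibble(replicon_id = character(), pos = integer(),
                          kind = character(), allele = character(),
                          support_fraction = numeric(), depth = integer())
  s0 <- summarize_discrepancies(empty, g)
  expect_equal(s0$n_total, 0L)
  expect_equal(s0$deletions_per_kb, 0)

  # 2927 deletions on the 2,479,642 bp four-replicon genome -> 1.18 / kb,
  # the study's "around one deletion every 1000 bases"
  sizes <- c(2021843L, 370865L, 77135L, 9799L)
  g4 <- genome(lapply(seq_along(sizes), function(i)
    replicon(paste0("r", i), strrep("ACGT", ceiling(sizes[i] / 4)))))
  g4 <- genome(lapply(seq_along(sizes), function(i)
    replicon(paste0("r", i), substr(g4[[i]]$seq, 1, sizes[i]))))
  d <- tibble::tibble(replicon_id = "r1", pos = seq_len(2927),
                      kind = "deletion", allele = "G",
                      support_fraction = 1, depth = 300L)
  s <- summarize_discrepancies(d, g4)
  expect_equal(s$genome_size, 2479642)
  expect_equal(round(s$deletions_per_kb, 2), 1.18)

  # the comparison genome: 481 deletions over 5 Mbp -> ~one per 10 kb
  g5 <- genome(list(replicon("chr", strrep("ACGT", 1250000))))
  d5 <- tibble::tibble(replicon_id = "chr", pos = seq_len(481),
                       kind = "deletion", allele = "G",
                       support_fraction = 1, depth = 300L)
  expect_equal(round(summarize_discrepancies(d5, g5)$deletions_per_kb, 3), 0.096)
})
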