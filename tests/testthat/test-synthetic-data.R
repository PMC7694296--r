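test_that("simulated replicons have the requested lengths and structure", {
  sim <- toy_sim()
  expect_equal(unname(replicon_lengths(sim$genome)), c(60000, 10000))
  expect_equal(sim$genome[[1]]$role, "chromosome")
  expect_equal(sim$genome[[1]]$copy_number, 1)
  expect_equal(sim$genome[[2]]$copy_number, 1.3)
})

test_that("zero cds_count yields an empty annotation set", {
  sim <- simulate_genome(genome_params(replicon_lengths = 5000,
                                       gc_fraction = 0.6, copy_numbers = 1,
                                       cds_count = 0L, seed = 1))
  expect_equal(nrow(sim$cds), 0L)
})

test_that("carved CDS start with ATG, end with a stop, and do not overlap", {
  sim <- toy_sim()
  cds <- sim$cds
  expect_true(all(cds$end - cds$start >= 300 & cds$end - cds$start <= 1500))
  for (i in seq_len(nrow(cds))) {
    r <- sim$genome[[cds$replicon_id[i]]]
    s <- substr(r$seq, cds$start[i] + 1, cds$end[i])
    if (cds$strand[i] == "-") s <- chartr("ACGT", "TGCA",
                                          paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    expect_equal(substr(s, 1, 3), "ATG")
    expect_true(substr(s, nchar(s) - 2, nchar(s)) %in% c("TAA", "TAG", "TGA"))
    frags <- oracle_fragments(s)
    expect_equal(length(frags), 1L)   # no internal in-frame stops
  }
  expect_silent(validate_cds(cds, sim$genome))
})

test_that("genome GC composition matches the parameter closely", {
  sim <- toy_sim()   # 70 kb
  expect_lt(abs(gc_fraction(sim$genome) - 0.6879), 0.005)
})

test_that("planting selects round(fraction x eligible) tracts, checked against a brute-force tract scan", {
  sim <- toy_sim()
  em <- error_model_params(affected_fraction = 0.0164, seed = 3)

  # independent eligible-tract count (linearized scan misses only runs that
  # wrap the origin, which we exclude from the comparison)
  n_or <- 0L
  for (r in sim$genome) {
    o <- oracle_homopolymers(r$seq, 5)
    o <- o[o$base %in% c("G", "C") & o$length <= 6 &
             o$start > 0 & o$start + o$length < nchar(r$seq), ]
    n_or <- n_or + nrow(o)
  }
  truth <- plant_systematic_errors(sim$genome, sim$cds, em)
  interior <- truth$loci[truth$loci$tract_start > 0, ]
  expect_equal(nrow(interior), n_or)
  expect_equal(sum(truth$loci$planted), round(0.0164 * nrow(truth$loci)))

  expect_equal(sum(plant_systematic_errors(
    sim$genome, sim$cds, error_model_params(affected_fraction = 0, seed = 1)
  )$loci$planted), 0L)

  all_of_them <- plant_systematic_errors(
    sim$genome, sim$cds, error_model_params(affected_fraction = 1, seed = 1))
  expect_true(all(all_of_them$loci$planted))
})

test_that("planting errors on a genome without eligible tracts", {
  g <- genome(list(replicon("flat", strrep("ACAC", 500))))
  expect_error(plant_systematic_errors(g, empty_cds(),
                                       error_model_params(affected_fraction = 0.5)),
               "no eligible homopolymer tract")
})

test_that("long reads carry a planted deletion at the concordance rate", {
  g <- genome(list(replicon("c", rand_genome(1, 20000, seed = 4)[[1]]$seq,
                            topology = "circular", role = "chromosome")))
  em <- error_model_params(concordance = 0.9, seed = 2)
  truth <- plant_systematic_errors(g, empty_cds(), em)
  # force exactly one planted locus
  truth$loci$planted <- FALSE
  truth$loci$planted[1] <- TRUE
  p <- truth$loci$pos[1]
  lt <- tech_params("long", mean_read_len = 2000, depth = 300,
                    background_error = 0, seed = 8)
  reads <- simulate_reads(g, truth, lt)
  pu <- build_pileup(reads, g[[1]])
  frac <- pu$del[p + 1] / pu$depth[p + 1]
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.9 * 0.1 / 300))
})

test_that("short reads follow the reference at planted loci when error-free", {
  sim <- toy_sim()
  em <- error_model_params(affected_fraction = 0.05, seed = 3)
  truth <- plant_systematic_errors(sim$genome, sim$cds, em)
  st <- tech_params("short", depth = 30, background_error = 0, seed = 5)
  reads <- simulate_reads(sim$genome, truth, st)
  expect_true(all(grepl("^[0-9]+=$", reads$ops)))
  pu <- build_pileup(reads[reads$replicon_id == "chr", ], sim$genome[["chr"]])
  planted <- truth$loci[truth$loci$planted & truth$loci$replicon_id == "chr", ]
  expect_true(all(pu$del[planted$pos + 1] == 0))
})

test_that("aligned bases per replicon track depth x copy number", {
  sim <- toy_sim()
  em <- error_model_params(affected_fraction = 0, seed = 1)
  truth <- plant_systematic_errors(sim$genome, sim$cds, em)
  lt <- tech_params("long", mean_read_len = 2000, depth = 100,
                    background_error = 0, seed = 12)
  reads <- simulate_reads(sim$genome, truth, lt)
  for (r in sim$genome) {
    rr <- reads[reads$replicon_id == r$id, ]
    got <- oracle_total_aligned(rr) / nchar(r$seq)
    expect_lt(abs(got / (100 * r$copy_number) - 1), 0.05)
  }
})

test_that("the simulator is reproducible from its seeds", {
  gp <- genome_params(replicon_lengths = c(20000, 5000), gc_fraction = 0.65,
                      copy_numbers = c(1, 2), seed = 9)
  expect_identical(simulate_genome(gp), simulate_genome(gp))
  sim <- simulate_genome(gp)
  em <- error_model_params(affected_fraction = 0.1, seed = 4)
  t1 <- plant_systematic_errors(sim$genome, sim$cds, em)
  t2 <- plant_systematic_errors(sim$genome, sim$cds, em)
  expect_identical(t1, t2)
  lt <- tech_params("long", mean_read_len = 1500, depth = 40, seed = 3)
  expect_identical(simulate_reads(sim$genome, t1, lt),
                   simulate_reads(sim$genome, t2, lt))
})

test_that("with concordance 1 and no background error, pileups are unanimous", {
  sim <- toy_sim()
  em <- error_model_params(affected_fraction = 0.05, concordance = 1, seed = 3)
  out <- run_toy_detection(sim, em, bg_long = 0, bg_short = 0,
                           depth_long = 60, depth_short = 30)
  planted <- out$truth$loci[out$truth$loci$planted, ]
  for (r in sim$genome) {
    pu <- out$piles_long[[r$id]]
    pp <- planted$pos[planted$replicon_id == r$id]
    expect_true(all(pu$del[pp + 1] == pu$depth[pp + 1]))
    others <- setdiff(seq_len(pu$length), pp + 1)
    expect_true(all(pu$del[others] == 0))
    expect_equal(nrow(pu$ins), 0L)
  }
  # and detected discrepancies equal the planted truth as a set
  expect_setequal(paste(out$disc$replicon_id, out$disc$pos),
                  paste(planted$replicon_id, planted$pos))
})
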