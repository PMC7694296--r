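#' Simulate a multi-replicon genome with carved CDS annotations
#'
#' Draws each replicon i.i.d. from the base distribution implied by
#' `gc_fraction` (G and C equiprobable, likewise A and T), then carves
#' non-overlapping CDS into the sequence: each CDS starts with ATG, ends
#' with a stop codon, and has interior codons drawn from the same
#' GC-matched composition conditioned on not being a stop. Replicons are
#' circular; the first is the chromosome, the others megaplasmids
#' (>= 100 kb) or plasmids. Output is identical for identical parameters.
#'
#' At 2.48 Mbp the realized genome GC fraction concentrates within well
#' under 0.1 percentage points of the parameter (binomial standard error
#' ~0.03 points).
#'
#' @param params a [genome_params()] object.
#' @return A list with elements `genome` (a [genome()]) and `cds`
#'   (CDS tibble as in [read_gff3()]).
#' @examples
#' gp <- genome_params(replicon_lengths = c(50000, 8000), gc_fraction = 0.6879,
#'                     copy_numbers = c(1, 1.3), seed = 42)
#' sim <- simulate_genome(gp)
#' gc_fraction(sim$genome)
#' @export
simulate_genome <- function(params) {
  assert(inherits(params, "genome_params"), "params must come from genome_params()")
  withr::with_seed(derive_seed(params$seed, "genome"), {
    n_rep <- length(params$replicon_lengths)
    ids <- c("chr", if (n_rep > 1) sprintf("p%d", seq_len(n_rep - 1)))
    roles <- c("chromosome",
               if (n_rep > 1) ifelse(params$replicon_lengths[-1] >= 1e5,
                                     "megaplasmid", "plasmid"))
    x <- calibrate_gc(params)
    base_probs <- setNames(c((1 - x) / 2, x / 2, x / 2, (1 - x) / 2), DNA_BASES)
    reps <- vector("list", n_rep)
    cds_all <- vector("list", n_rep)
    for (i in seq_len(n_rep)) {
      L <- params$replicon_lengths[i]
      chars <- sample(DNA_BASES, L, replace = TRUE, prob = base_probs)
      carved <- carve_cds(chars, params$cds_count[i], params$cds_length_range,
                          base_probs, ids[i])
      chars <- carved$chars
      if (params$homopolymer_boost > 0) {
        chars <- boost_homopolymers(chars, carved$cds, params$homopolymer_boost)
      }
      reps[[i]] <- replicon(ids[i], paste(chars, collapse = ""),
                            topology = "circular", role = roles[i],
                            copy_number = params$copy_numbers[i])
      cds_all[[i]] <- carved$cds
    }
    list(genome = genome(reps), cds = dplyr::bind_rows(cds_all))
  })
}

# Solve for the per-base G+C probability that makes the expected realized
# genome composition equal gc_fraction: CDS interiors are drawn conditioned
# on not being a stop codon (which enriches G+C), and the fixed ATG starts
# and stop codons deplete it, so the raw parameter would miss the target by
# ~0.2 points at the default annotation density.
calibrate_gc <- function(params) {
  total <- sum(as.numeric(params$replicon_lengths))
  n_cds <- sum(params$cds_count)
  if (n_cds == 0L) return(params$gc_fraction)
  mean_codons <- mean(params$cds_length_range) / 3
  n_interior <- n_cds * (mean_codons - 2)
  n_int <- total - 3 * (2 * n_cds + n_interior)
  expected_gc <- function(x) {
    bp <- setNames(c((1 - x) / 2, x / 2, x / 2, (1 - x) / 2), DNA_BASES)
    ct <- codon_table(bp)
    gc_codon <- vapply(strsplit(ct$codon, ""), function(b)
      sum(b %in% c("G", "C")), numeric(1))
    e_interior <- sum(ct$p[!ct$stop] * gc_codon[!ct$stop]) / sum(ct$p[!ct$stop])
    e_stop <- sum(ct$p[ct$stop] * gc_codon[ct$stop]) / sum(ct$p[ct$stop])
    (n_int * x + n_cds * (1 + e_stop) + n_interior * e_interior) / total
  }
  stats::uniroot(function(x) expected_gc(x) - params$gc_fraction,
                 c(0.05, 0.95), tol = 1e-9)$root
}

# codon sampling table: 64 codons with composition-implied probabilities
codon_table <- function(base_probs) {
  codons <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
  p <- apply(do.call(rbind, strsplit(codons, "")), 1, function(b) prod(base_probs[b]))
  tibble::tibble(codon = codons, p = p, stop = codons %in% c("TAA", "TAG", "TGA"))
}

carve_cds <- function(chars, n_cds, len_range, base_probs, rid) {
  L <- length(chars)
  if (n_cds == 0L) return(list(chars = chars, cds = empty_cds()))
  lens <- 3L * sample(seq(len_range[1] %/% 3L, len_range[2] %/% 3L),
                      n_cds, replace = TRUE)
  assert(sum(lens) <= 0.9 * L,
         "CDS demand (%d bp) exceeds capacity of replicon '%s' (%d bp)",
         sum(lens), rid, L)
  # rejection-sample non-overlapping placements (linear coordinates; the
  # origin-spanning region is left CDS-free, as real annotations avoid it)
  starts <- integer(n_cds)
  placed_s <- integer(0)
  placed_e <- integer(0)
  for (j in seq_len(n_cds)) {
    ok <- FALSE
    for (try in seq_len(500L)) {
      s <- sample.int(L - lens[j] + 1L, 1L) - 1L
      e <- s + lens[j]
      if (!any(s < placed_e & e > placed_s)) {
        ok <- TRUE
        break
      }
    }
    assert(ok, "could not place %d non-overlapping CDS on replicon '%s'", n_cds, rid)
    starts[j] <- s
    placed_s <- c(placed_s, s)
    placed_e <- c(placed_e, e)
  }
  ct <- codon_table(base_probs)
  sense <- ct[!ct$stop, ]
  stops <- ct[ct$stop, ]
  strands <- sample(c("+", "-"), n_cds, replace = TRUE)
  for (j in seq_len(n_cds)) {
    n_codon <- lens[j] %/% 3L
    body <- sample(sense$codon, n_codon - 2L, replace = TRUE, prob = sense$p)
    orf <- paste0("ATG", paste(body, collapse = ""),
                  sample(stops$codon, 1L, prob = stops$p))
    if (strands[j] == "-") orf <- revcomp(orf)
    chars[(starts[j] + 1L):(starts[j] + lens[j])] <- strsplit(orf, "")[[1]]
  }
  cds <- tibble::tibble(
    cds_id = NA_character_,
    replicon_id = rid, start = starts, end = starts + lens, strand = strands
  )
  cds <- cds[order(cds$start), ]
  cds$cds_id <- sprintf("%s_cds%04d", rid, seq_len(n_cds))
  list(chars = chars, cds = cds)
}

# overwrite extra G/C runs (length 4-8) at random intergenic positions
boost_homopolymers <- function(chars, cds, boost) {
  L <- length(chars)
  in_cds <- logical(L)
  if (nrow(cds)) {
    for (j in seq_len(nrow(cds))) in_cds[(cds$start[j] + 1L):cds$end[j]] <- TRUE
  }
  free <- which(!in_cds)
  n_runs <- stats::rpois(1L, boost * length(free) / 1e4)
  if (n_runs == 0L) return(chars)
  run_len <- sample(4:8, n_runs, replace = TRUE)
  run_base <- sample(c("G", "C"), n_runs, replace = TRUE)
  pos <- sample(free, n_runs)
  for (k in seq_len(n_runs)) {
    idx <- pos[k]:min(pos[k] + run_len[k] - 1L, L)
    idx <- idx[!in_cds[idx]]
    chars[idx] <- run_base[k]
  }
  chars
}
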