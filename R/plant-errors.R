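#' Plant systematic indel errors at eligible homopolymer tracts
#'
#' Enumerates the eligible homopolymer tracts of the genome (base in
#' `target_bases`, length in `target_len_range`), selects
#' `round(affected_fraction * n_eligible)` of them uniformly without
#' replacement (seeded), and records one single-base deletion (or
#' insertion) per selected tract, positioned at the tract start
#' (left-aligned). When `cds_fraction > 0` the sample is stratified so that
#' at least that fraction of planted loci fall inside annotated CDS.
#'
#' @param g a `genome`.
#' @param cds CDS tibble (used only when `em$cds_fraction > 0`).
#' @param em an [error_model_params()].
#' @return A `truth_set`: list with `loci` (one row per eligible tract with
#'   a logical `planted` column plus `pos` of the planted indel), `params`,
#'   and `motif` (NULL until [plant_flank_motif()] is used).
#' @export
plant_systematic_errors <- function(g, cds = empty_cds(), em = error_model_params()) {
  assert(inherits(em, "error_model_params"), "em must come from error_model_params()")
  tracts <- find_homopolymers_genome(g, min_len = 2L)
  elig <- eligible_tracts(tracts, em)
  n_elig <- nrow(elig)
  if (em$affected_fraction > 0 && n_elig == 0L) {
    abort("affected_fraction > 0 but the genome has no eligible homopolymer tract")
  }
  n_plant <- round(em$affected_fraction * n_elig)
  planted_idx <- integer(0)
  if (n_plant > 0) {
    planted_idx <- withr::with_seed(derive_seed(em$seed, "plant"), {
      if (em$cds_fraction > 0 && nrow(cds) > 0) {
        in_cds <- tract_in_cds(elig, cds)
        k_cds <- min(ceiling(em$cds_fraction * n_plant), sum(in_cds))
        c(sample(which(in_cds), k_cds),
          sample(which(!in_cds), n_plant - k_cds))
      } else {
        sample.int(n_elig, n_plant)
      }
    })
  }
  loci <- tibble::tibble(
    replicon_id = elig$replicon_id,
    tract_start = elig$start,
    tract_len = elig$length,
    base = elig$base,
    planted = seq_len(n_elig) %in% planted_idx,
    concordance = em$concordance,
    pos = elig$start,
    indel_type = em$indel_type
  )
  structure(list(loci = loci, params = em, motif = NULL), class = "truth_set")
}

tract_in_cds <- function(tracts, cds) {
  out <- logical(nrow(tracts))
  for (rid in unique(tracts$replicon_id)) {
    cc <- cds[cds$replicon_id == rid, ]
    if (nrow(cc) == 0L) next
    rows <- which(tracts$replicon_id == rid)
    cc <- cc[order(cc$start), ]
    j <- findInterval(tracts$start[rows], cc$start)
    out[rows] <- j >= 1L & tracts$start[rows] < cc$end[pmax(j, 1L)]
  }
  out
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> %d eligible tracts, %d planted %ss (concordance %.2f)%s\n",
              nrow(x$loci), sum(x$loci$planted), x$params$indel_type,
              x$params$concordance,
              if (is.null(x$motif)) "" else sprintf(", motif %s", x$motif$kmer)))
  invisible(x)
}

#' Write a fixed k-mer into the upstream flank of every planted locus
#'
#' Overwrites the genome bases at offset `offset` upstream of each planted
#' tract with `kmer` (no length change), producing a genome in which the
#' flanks of affected loci share a fixed motif. Used to give the
#' permutation consensus test a positive control with known signal.
#'
#' @param g a `genome`.
#' @param truth a `truth_set` from [plant_systematic_errors()].
#' @param kmer motif string over ACGT.
#' @param offset gap in bases between the end of the motif and the tract
#'   start (default 5).
#' @return List with modified `genome` and updated `truth`.
#' @export
plant_flank_motif <- function(g, truth, kmer, offset = 5L) {
  assert(grepl("^[ACGT]+$", kmer), "kmer must be a non-empty ACGT string")
  k <- nchar(kmer)
  planted <- truth$loci[truth$loci$planted, ]
  for (i in seq_len(nrow(planted))) {
    rid <- planted$replicon_id[i]
    s <- planted$tract_start[i] - offset - k   # 0-based start of the motif
    L <- nchar(g[[rid]]$seq)
    idx <- ((s:(s + k - 1L)) %% L) + 1L        # circular wrap
    chars <- strsplit(g[[rid]]$seq, "")[[1]]
    chars[idx] <- strsplit(kmer, "")[[1]]
    g[[rid]]$seq <- paste(chars, collapse = "")
  }
  truth$motif <- list(kmer = kmer, offset = as.integer(offset))
  list(genome = g, truth = truth)
}
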