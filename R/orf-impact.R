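#' Apply indel discrepancies to a replicon sequence
#'
#' Reconstructs the erroneous long-read consensus: deletions remove the
#' stated bases, insertions add their allele after the stated position. A
#' coordinate map translates original positions to the mutated sequence so
#' that CDS intervals can be carried across.
#'
#' @param seq replicon sequence (character string).
#' @param disc discrepancy tibble for this replicon, sorted by position;
#'   deletion spans must not overlap each other or insertion anchors.
#' @return List with `seq` (mutated string) and `map`, an integer vector of
#'   length `nchar(seq) + 1` where `map[i + 1]` is the 0-based mutated
#'   coordinate of original position `i` (a deleted base maps to the
#'   coordinate where it would have been, i.e. the next surviving base);
#'   `map[L + 1]` is the mutated length.
#' @examples
#' m <- apply_indels("AACCGGTT",
#'   tibble::tibble(pos = 2L, kind = "deletion", allele = "C"))
#' m$seq
#' @export
apply_indels <- function(seq, disc) {
  L <- nchar(seq)
  if (nrow(disc) == 0L) {
    return(list(seq = seq, map = 0:L))
  }
  disc <- disc[order(disc$pos), ]
  del <- disc$kind == "deletion"
  span_end <- disc$pos + ifelse(del, nchar(disc$allele), 1L)
  if (nrow(disc) > 1L && any(disc$pos[-1] < span_end[-length(span_end)])) {
    abort("overlapping discrepancies cannot be applied")
  }
  delta <- integer(L + 1L)   # length change taking effect at original pos i
  pieces <- character(2L * nrow(disc) + 1L)
  cursor <- 0L
  for (i in seq_len(nrow(disc))) {
    k <- nchar(disc$allele[i])
    if (del[i]) {
      assert(substr(seq, disc$pos[i] + 1L, disc$pos[i] + k) == disc$allele[i],
             "deletion allele does not match the reference at position %d",
             disc$pos[i])
      pieces[2L * i - 1L] <- substr(seq, cursor + 1L, disc$pos[i])
      pieces[2L * i] <- ""
      if (disc$pos[i] + k <= L) delta[disc$pos[i] + k + 1L] <-
          delta[disc$pos[i] + k + 1L] - k
      cursor <- disc$pos[i] + k
    } else {
      pieces[2L * i - 1L] <- substr(seq, cursor + 1L, disc$pos[i] + 1L)
      pieces[2L * i] <- disc$allele[i]
      delta[min(disc$pos[i] + 2L, L + 1L)] <-
        delta[min(disc$pos[i] + 2L, L + 1L)] + k
      cursor <- disc$pos[i] + 1L
    }
  }
  pieces[2L * nrow(disc) + 1L] <- substr(seq, cursor + 1L, L)
  mutated <- paste(pieces, collapse = "")
  naive <- (0:L) + cumsum(delta)
  # a deleted base maps forward to the next surviving coordinate
  map <- rev(cummin(rev(naive)))
  list(seq = mutated, map = map)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Count ORF fragments of a CDS after applying indels
#'
#' Translates the mutated CDS interval on its strand starting in frame 0.
#' A premature stop codon ends a fragment; scanning then resumes at the
#' next start codon in any frame within the interval (mirroring how
#' annotation pipelines split a frameshifted gene into consecutive ORFs).
#' `n_fragments` counts start-to-stop segments of at least `min_aa`
#' residues. Start codons default to the bacterial set {ATG, GTG, TTG}
#' (translation table 11).
#'
#' A CDS is `disrupted` when it carries at least one indel and either
#' fragments into more than one ORF or loses at least 20% of its C-terminus
#' to a premature stop.
#'
#' @param cds one-row CDS tibble.
#' @param mutated_seq mutated replicon sequence from [apply_indels()].
#' @param map coordinate map from [apply_indels()].
#' @param disc discrepancies falling inside this CDS (tibble; may be empty).
#' @param min_aa minimum fragment length in amino acids (default 30).
#' @param start_codons codons at which scanning may resume.
#' @return One-row tibble: `cds_id`, `n_indels`, `net_frame_offset`,
#'   `n_fragments`, `first_fragment_aa`, `disrupted`.
#' @export
fragment_count <- function(cds, mutated_seq, map, disc = NULL, min_aa = 30L,
                           start_codons = c("ATG", "GTG", "TTG")) {
  assert(nrow(cds) == 1L, "fragment_count() takes a single CDS row")
  ms <- map[cds$start + 1L]
  me <- map[cds$end + 1L]
  s <- substr(mutated_seq, ms + 1L, me)
  assert(nchar(s) >= 3L, "CDS '%s' interval collapsed below one codon", cds$cds_id)
  if (cds$strand == "-") s <- revcomp(s)
  frags <- scan_orf_fragments(s, start_codons)
  n_indels <- if (is.null(disc)) 0L else nrow(disc)
  ins_b <- del_b <- 0L
  if (n_indels > 0L) {
    ins_b <- sum(nchar(disc$allele[disc$kind == "insertion"]))
    del_b <- sum(nchar(disc$allele[disc$kind == "deletion"]))
  }
  original_aa <- (cds$end - cds$start) %/% 3L - 1L
  first_aa <- if (length(frags)) frags[1] else 0L
  tibble::tibble(
    cds_id = cds$cds_id,
    replicon_id = cds$replicon_id,
    start = cds$start,
    n_indels = n_indels,
    net_frame_offset = as.integer((ins_b - del_b) %% 3L),
    n_fragments = sum(frags >= min_aa),
    first_fragment_aa = first_aa,
    disrupted = n_indels > 0L &&
      (sum(frags >= min_aa) > 1L || first_aa < 0.8 * original_aa)
  )
}

# fragment lengths (aa, stop excluded) from a nucleotide interval: translate
# from position 1 in frame 0; on a stop, resume at the next start codon at
# any offset; the final open fragment is truncated by the interval end
scan_orf_fragments <- function(s, start_codons) {
  n <- nchar(s)
  frags <- integer(0)
  i <- 1L
  while (i + 2L <= n) {
    codon_starts <- seq(i, n - 2L, by = 3L)
    codons <- substring(s, codon_starts, codon_starts + 2L)
    hit <- which(codons %in% STOP_CODONS)
    if (!length(hit)) {
      frags <- c(frags, length(codons))
      break
    }
    frags <- c(frags, hit[1] - 1L)
    after <- codon_starts[hit[1]] + 3L
    if (after + 2L > n) break
    restart_at <- seq(after, n - 2L)
    restart <- which(substring(s, restart_at, restart_at + 2L) %in% start_codons)
    if (!length(restart)) break
    i <- restart_at[restart[1]]
  }
  frags
}

#' Count CDS disrupted by systematic discrepancies
#'
#' Assigns each discrepancy to the CDS whose interval overlaps it, applies
#' all of a replicon's discrepancies to its sequence once, and evaluates
#' [fragment_count()] for every CDS that carries at least one indel.
#'
#' @param cds CDS tibble.
#' @param disc discrepancy tibble.
#' @param g the `genome`.
#' @inheritParams fragment_count
#' @return List with `n_affected` (number of CDS with `disrupted = TRUE`)
#'   and `records` (one [fragment_count()] row per CDS carrying an indel,
#'   sorted by replicon and start).
#' @export
count_affected_cds <- function(cds, disc, g, min_aa = 30L,
                               start_codons = c("ATG", "GTG", "TTG")) {
  records <- list()
  for (rid in unique(cds$replicon_id)) {
    dd <- disc[disc$replicon_id == rid, , drop = FALSE]
    cc <- cds[cds$replicon_id == rid, , drop = FALSE]
    if (nrow(dd) == 0L || nrow(cc) == 0L) next
    mut <- apply_indels(g[[rid]]$seq, dd)
    d_end <- dd$pos + ifelse(dd$kind == "deletion", nchar(dd$allele), 1L)
    for (j in seq_len(nrow(cc))) {
      inside <- dd$pos < cc$end[j] & d_end > cc$start[j]
      if (!any(inside)) next
      records[[length(records) + 1L]] <-
        fragment_count(cc[j, ], mut$seq, mut$map, dd[inside, , drop = FALSE],
                       min_aa = min_aa, start_codons = start_codons)
    }
  }
  records <- if (length(records)) dplyr::bind_rows(records) else
    tibble::tibble(cds_id = character(), replicon_id = character(),
                   start = integer(), n_indels = integer(),
                   net_frame_offset = integer(), n_fragments = integer(),
                   first_fragment_aa = integer(), disrupted = logical())
  records <- records[order(records$replicon_id, records$start), ]
  list(n_affected = sum(records$disrupted), records = records)
}
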