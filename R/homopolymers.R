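#' Enumerate maximal homopolymer tracts
#'
#' Returns exactly the maximal runs of identical bases of length
#' `>= min_len`, as a tibble with columns `replicon_id`, `start` (0-based),
#' `length` and `base`, sorted by start. On a circular replicon a run that
#' spans the origin is reported once, with `start` near the sequence end and
#' `length` crossing the boundary.
#'
#' @param rep a `replicon`, or (for `find_homopolymers_genome`) a `genome`.
#' @param min_len minimum tract length (default 2). The default keeps the
#'   full inventory; eligibility filters (base in {G,C}, length in 5-6) are
#'   applied at summary time.
#' @return Tract tibble.
#' @examples
#' r <- replicon("x", "AGGGGGT")
#' find_homopolymers(r, min_len = 5)
#' @export
find_homopolymers <- function(rep, min_len = 2L) {
  assert(inherits(rep, "replicon"), "rep must be a replicon")
  assert(is_count(min_len) && min_len >= 2, "min_len must be >= 2")
  chars <- strsplit(rep$seq, "")[[1]]
  L <- length(chars)
  r <- rle(chars)
  starts <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  lens <- r$lengths
  bases <- r$values
  if (rep$topology == "circular" && length(lens) > 1L &&
      bases[1] == bases[length(bases)]) {
    # merge the origin-spanning run; report once with start near the end
    lens[length(lens)] <- lens[length(lens)] + lens[1]
    starts <- starts[-1]
    lens <- lens[-1]
    bases <- bases[-1]
  }
  keep <- lens >= min_len
  tibble::tibble(replicon_id = rep$id, start = as.integer(starts[keep]),
                 length = as.integer(lens[keep]), base = bases[keep])
}

#' @rdname find_homopolymers
#' @param g a `genome`.
#' @export
find_homopolymers_genome <- function(g, min_len = 2L) {
  dplyr::bind_rows(lapply(g, find_homopolymers, min_len = min_len))
}

# eligibility under an error model: base in target set, length in target range
eligible_tracts <- function(tracts, em) {
  tracts[tracts$base %in% em$target_bases &
           tracts$length >= em$target_len_range[1] &
           tracts$length <= em$target_len_range[2], ]
}

#' Attach homopolymer context to discrepancies
#'
#' Assigns each discrepancy to the homopolymer tract containing its
#' position, allowing one base of slack on either side (an indel inside a
#' homopolymer is positionally ambiguous; calls are left-aligned, so the
#' position may sit one base off the tract boundary). For a deletion the
#' deleted allele must equal the tract base for the assignment to count as
#' eligible context. Lookup is by binary search over the sorted tract
#' starts.
#'
#' @param disc discrepancy tibble (from [compare_technologies()] or
#'   [call_indels()]); needs `replicon_id`, `pos`, `kind`, `allele`.
#' @param tracts tract tibble from [find_homopolymers_genome()], sorted.
#' @return `disc` with columns `tract_start`, `tract_len`, `tract_base`
#'   (NA where unassigned).
#' @export
assign_context <- function(disc, tracts) {
  disc$tract_start <- NA_integer_
  disc$tract_len <- NA_integer_
  disc$tract_base <- NA_character_
  if (nrow(disc) == 0L || nrow(tracts) == 0L) return(disc)
  for (rid in unique(disc$replicon_id)) {
    tr <- tracts[tracts$replicon_id == rid, ]
    if (nrow(tr) == 0L) next
    rows <- which(disc$replicon_id == rid)
    # candidate = last tract with start <= pos + 1 (slack), check containment
    j <- findInterval(disc$pos[rows] + 1L, tr$start)
    hit <- j >= 1L &
      disc$pos[rows] >= tr$start[pmax(j, 1L)] - 1L &
      disc$pos[rows] <= tr$start[pmax(j, 1L)] + tr$length[pmax(j, 1L)]
    hit[is.na(hit)] <- FALSE
    k <- j[hit]
    disc$tract_start[rows[hit]] <- tr$start[k]
    disc$tract_len[rows[hit]] <- tr$length[k]
    disc$tract_base[rows[hit]] <- tr$base[k]
    # allele of a deletion must match the tract base to keep the context
    del <- which(!is.na(disc$tract_base[rows]) & disc$kind[rows] == "deletion")
    mism <- del[vapply(rows[del], function(i) {
      !identical(gsub(disc$tract_base[i], "", disc$allele[i]), "")
    }, logical(1))]
    disc$tract_start[rows[mism]] <- NA_integer_
    disc$tract_len[rows[mism]] <- NA_integer_
    disc$tract_base[rows[mism]] <- NA_character_
  }
  disc
}

#' Summarize discrepancies by homopolymer context
#'
#' Tabulates tracts and affected tracts by (base, length) class and reports
#' the headline eligible-affected fraction: the fraction of eligible tracts
#' (base in the error model's target set, length in its target range) that
#' carry at least one systematic discrepancy. A tract counts as affected at
#' most once regardless of how many discrepancies fall in it. Both
#' denominators are reported: all homopolymer tracts in the inventory, and
#' the eligible class only (the headline figure).
#'
#' @param disc discrepancy tibble with context assigned ([assign_context()]).
#' @param tracts full tract inventory.
#' @param em [error_model_params()] defining eligibility.
#' @return A `context_summary`: list with `by_class` tibble, counts, and
#'   `eligible_affected_fraction`.
#' @export
summarize_context <- function(disc, tracts, em = error_model_params()) {
  affected_key <- unique(paste(disc$replicon_id, disc$tract_start, sep = ":")[
    !is.na(disc$tract_start)])
  tr_key <- paste(tracts$replicon_id, tracts$start, sep = ":")
  tracts$affected <- tr_key %in% affected_key
  by_class <- dplyr::summarise(
    dplyr::group_by(tracts, .data$base, .data$length),
    n_tracts = dplyr::n(), n_affected = sum(.data$affected), .groups = "drop"
  )
  elig <- eligible_tracts(tracts, em)
  n_elig <- nrow(elig)
  n_elig_aff <- sum(elig$affected)
  in_elig <- !is.na(disc$tract_base) &
    disc$tract_base %in% em$target_bases &
    disc$tract_len >= em$target_len_range[1] &
    disc$tract_len <= em$target_len_range[2]
  structure(list(
    by_class = by_class,
    n_tracts = nrow(tracts),
    n_affected = sum(tracts$affected),
    n_eligible = n_elig,
    n_eligible_affected = n_elig_aff,
    eligible_affected_fraction = if (n_elig > 0) n_elig_aff / n_elig else 0,
    all_affected_fraction = if (nrow(tracts) > 0) sum(tracts$affected) / nrow(tracts) else 0,
    offtarget_count = sum(!in_elig),
    n_deletions = sum(disc$kind == "deletion"),
    n_insertions = sum(disc$kind == "insertion")
  ), class = "context_summary")
}

#' @export
print.context_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<context_summary> %d discrepancies (%d del / %d ins)\n",
    "  eligible tracts: %d, affected: %d (%.3g%%)\n",
    "  all tracts: %d, affected: %d (%.3g%%); off-target discrepancies: %d\n"),
    x$n_deletions + x$n_insertions, x$n_deletions, x$n_insertions,
    x$n_eligible, x$n_eligible_affected, 100 * x$eligible_affected_fraction,
    x$n_tracts, x$n_affected, 100 * x$all_affected_fraction, x$offtarget_count))
  invisible(x)
}
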