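#' Call consensus indels from a pileup
#'
#' Emits a candidate call at every column with depth at or above the
#' technology's minimum where the deletion support fraction reaches the 0.5
#' consensus gate, or where a single inserted allele reaches 0.5 of the
#' column depth. Runs of adjacent deletion columns are merged into one call
#' whose allele is the concatenated deleted reference bases; the recorded
#' support fraction and depth are the minima over the run (conservative).
#' Ties at a threshold count as passing.
#'
#' @param p a `pileup`.
#' @param params a [detection_params()].
#' @param which `"long"` or `"short"` — selects the depth gate.
#' @return Call tibble: `replicon_id`, `pos` (0-based), `kind`, `allele`,
#'   `support_fraction`, `depth`, sorted by position.
#' @export
call_indels <- function(p, params = detection_params(), which = c("long", "short")) {
  which <- match.arg(which)
  min_depth <- params[[paste0("min_depth_", which)]]
  cand <- p$depth >= min_depth & p$del >= 0.5 * p$depth & p$del > 0L
  out <- list()
  if (any(cand)) {
    r <- rle(cand)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    runs <- which(r$values)
    frac <- p$del / pmax(p$depth, 1L)
    out[[1]] <- tibble::tibble(
      replicon_id = p$replicon_id,
      pos = run_start[runs] - 1L,
      kind = "deletion",
      allele = substring(p$ref, run_start[runs], run_end[runs]),
      support_fraction = vapply(runs, function(k)
        min(frac[run_start[k]:run_end[k]]), numeric(1)),
      depth = vapply(runs, function(k)
        min(p$depth[run_start[k]:run_end[k]]), integer(1))
    )
  }
  if (nrow(p$ins)) {
    d <- p$depth[p$ins$pos + 1L]
    keep <- d >= min_depth & p$ins$count >= 0.5 * d
    if (any(keep)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        replicon_id = p$replicon_id,
        pos = p$ins$pos[keep],
        kind = "insertion",
        allele = p$ins$allele[keep],
        support_fraction = p$ins$count[keep] / d[keep],
        depth = d[keep]
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(replicon_id = character(), pos = integer(),
                          kind = character(), allele = character(),
                          support_fraction = numeric(), depth = integer()))
  }
  calls <- dplyr::bind_rows(out)
  calls[order(calls$pos), ]
}

#' Label long-read calls as systematic using the short-read pileup
#'
#' A long-read call becomes a systematic discrepancy iff its support passes
#' the long-read concordance threshold (see `long_rule` in
#' [detection_params()]) and the short-read pileup at the
#' same locus has depth at least `min_depth_short` with a
#' reference-agreement fraction of at least `short_threshold` at every
#' position of the call's span. Reference agreement at a position is the
#' fraction of short reads carrying the reference base (for insertion
#' calls, additionally not carrying that insertion). Loci without usable
#' short-read coverage are dropped with a warning.
#'
#' @param long_calls calls from [call_indels()] on long-read pileups (any
#'   number of replicons, concatenated).
#' @param short_pileups named list of `pileup` objects keyed by replicon id
#'   (a single `pileup` is accepted).
#' @param params a [detection_params()].
#' @return Discrepancy tibble: the call columns plus `short_ref_fraction`,
#'   sorted by (replicon, pos).
#' @export
compare_technologies <- function(long_calls, short_pileups,
                                 params = detection_params()) {
  if (inherits(short_pileups, "pileup")) {
    short_pileups <- setNames(list(short_pileups), short_pileups$replicon_id)
  }
  pass <- if (params$long_rule == "binomial") {
    # keep unless support is significantly below the threshold: the
    # threshold describes the locus's true concordance, and a point
    # comparison at the generating value would drop half the true loci
    count <- round(long_calls$support_fraction * long_calls$depth)
    count >= stats::qbinom(params$boundary_alpha, long_calls$depth,
                           params$long_threshold)
  } else {
    long_calls$support_fraction >= params$long_threshold
  }
  lc <- long_calls[pass, , drop = FALSE]
  if (nrow(lc) == 0L) {
    return(tibble::tibble(lc, short_ref_fraction = numeric(0)))
  }
  srf <- rep(NA_real_, nrow(lc))
  for (i in seq_len(nrow(lc))) {
    sp <- short_pileups[[lc$replicon_id[i]]]
    if (is.null(sp)) next
    span <- if (lc$kind[i] == "deletion") {
      lc$pos[i] + seq_len(nchar(lc$allele[i])) - 1L
    } else {
      lc$pos[i]
    }
    if (any(span >= sp$length)) next
    d <- sp$depth[span + 1L]
    if (any(d < params$min_depth_short)) next
    refc <- substring(sp$ref, span + 1L, span + 1L)
    agree <- sp$base_counts[cbind(match(refc, DNA_BASES), span + 1L)]
    if (lc$kind[i] == "insertion") {
      ic <- sp$ins$count[sp$ins$pos == lc$pos[i] & sp$ins$allele == lc$allele[i]]
      agree <- agree - sum(ic)
    }
    srf[i] <- min(pmax(agree, 0L) / d)
  }
  miss <- is.na(srf)
  if (any(miss)) {
    warning(sprintf("%d long-read call(s) dropped: no usable short-read coverage",
                    sum(miss)), call. = FALSE)
  }
  keep <- !miss & srf >= params$short_threshold
  out <- tibble::tibble(lc[keep, ], short_ref_fraction = srf[keep])
  out[order(out$replicon_id, out$pos), ]
}

#' Genome-wide discrepancy summary
#'
#' Counts discrepancies by kind and by replicon, and reports the deletion
#' density per 1000 genome bases (genome size = sum of replicon lengths).
#'
#' @param disc discrepancy tibble.
#' @param g the `genome` (for replicon lengths).
#' @return An `error_summary` list.
#' @export
summarize_discrepancies <- function(disc, g) {
  size <- genome_size(g)
  per_rep <- dplyr::count(disc, .data$replicon_id, name = "n")
  n_del <- sum(disc$kind == "deletion")
  structure(list(
    n_total = nrow(disc),
    n_deletions = n_del,
    n_insertions = sum(disc$kind == "insertion"),
    per_replicon = per_rep,
    genome_size = size,
    deletions_per_kb = if (size > 0) n_del / (size / 1000) else 0
  ), class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary> %d systematic discrepancies (%d deletions, %d insertions) on %s bp: %.3g deletions/kb\n",
              x$n_total, x$n_deletions, x$n_insertions,
              format(x$genome_size, big.mark = ","), x$deletions_per_kb))
  invisible(x)
}

#' Write / read the discrepancy table
#'
#' TSV columns: `replicon_id`, `pos` (0-based), `kind`, `allele`,
#' `long_support`, `short_ref_fraction`, `tract_start`, `tract_len`,
#' `tract_base`, `cds_id` (context columns empty when not assigned).
#'
#' @param disc discrepancy tibble (context columns optional).
#' @param path TSV path.
#' @export
write_discrepancies <- function(disc, path) {
  for (col in c("tract_start", "tract_len", "tract_base", "cds_id")) {
    if (!col %in% names(disc)) disc[[col]] <- NA
  }
  out <- tibble::tibble(
    replicon_id = disc$replicon_id, pos = disc$pos, kind = disc$kind,
    allele = disc$allele, long_support = disc$support_fraction,
    short_ref_fraction = disc$short_ref_fraction,
    tract_start = disc$tract_start, tract_len = disc$tract_len,
    tract_base = disc$tract_base, cds_id = disc$cds_id
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
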