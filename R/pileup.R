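#' Build a per-position pileup for one replicon
#'
#' Walks every read's edit operations and tallies, per reference position:
#' total depth (reads whose reference span covers the position, including
#' reads deleting it), base counts over A/C/G/T (matches count the
#' reference base, mismatches the read base), deletion support, and
#' insertion support keyed by inserted sequence, attached to the column of
#' the base preceding the insertion. Interval arithmetic
#' (difference-array/cumsum) makes the construction linear in the number of
#' ops rather than in aligned bases.
#'
#' @param reads read tibble (all rows must belong to `rep`).
#' @param rep the `replicon` the reads are aligned to.
#' @return A `pileup` object: list with `replicon_id`, `length`, `ref`,
#'   integer vectors `depth` and `del` (length of the replicon),
#'   `base_counts` (4 x length matrix, rows A,C,G,T) and `ins` tibble
#'   (`pos`, `allele`, `count`).
#' @export
build_pileup <- function(reads, rep) {
  assert(inherits(rep, "replicon"), "rep must be a replicon")
  assert(all(reads$replicon_id == rep$id),
         "all reads must belong to replicon '%s'", rep$id)
  L <- nchar(rep$seq)
  depth_d <- integer(L + 1L)
  match_d <- integer(L + 1L)
  del <- integer(L)
  bc <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(DNA_BASES, NULL))
  ins <- tibble::tibble(pos = integer(), allele = character(), count = integer())
  if (nrow(reads) > 0L) {
    ot <- ops_table(reads$ops)
    ref_consume <- ot$len * (ot$op %in% c("=", "X", "D"))
    read_consume <- ot$len * (ot$op %in% c("=", "X", "I"))
    cum_ref <- cumsum(ref_consume) - ref_consume
    cum_read <- cumsum(read_consume) - read_consume
    first <- !duplicated(ot$idx)
    base_ref <- cum_ref[first][ot$idx]
    base_read <- cum_read[first][ot$idx]
    ref_off <- cum_ref - base_ref          # ref consumed before this op
    read_off <- cum_read - base_read       # read bases consumed before this op
    abs_start <- reads$start[ot$idx] + ref_off
    spans <- op_spans(ot, nrow(reads))
    ends <- reads$start + spans[, "ref"]
    if (any(ends > L)) {
      abort("read '%s' extends past the end of replicon '%s'",
            reads$read_id[which(ends > L)[1]], rep$id)
    }
    add_iv <- function(d, from, to) {        # [from, to) 0-based
      d + tabulate(from + 1L, L + 1L) - tabulate(to + 1L, L + 1L)
    }
    depth_d <- add_iv(depth_d, reads$start, ends)
    is_eq <- ot$op == "="
    match_d <- add_iv(match_d, abs_start[is_eq], abs_start[is_eq] + ot$len[is_eq])
    # expand sparse events (X and D ops, usually length 1)
    expand <- function(rows) {
      if (!length(rows)) return(list(pos = integer(), row = integer(), k = integer()))
      lens <- ot$len[rows]
      row <- rep(rows, lens)
      k <- sequence(lens) - 1L
      list(pos = abs_start[row] + k, row = row, k = k)
    }
    dx <- expand(which(ot$op == "D"))
    if (length(dx$pos)) del <- del + tabulate(dx$pos + 1L, L)
    xx <- expand(which(ot$op == "X"))
    if (length(xx$pos)) {
      b <- substring(reads$seq[ot$idx[xx$row]],
                     read_off[xx$row] + xx$k + 1L, read_off[xx$row] + xx$k + 1L)
      for (bb in DNA_BASES) {
        sel <- b == bb
        if (any(sel)) bc[bb, ] <- bc[bb, ] + tabulate(xx$pos[sel] + 1L, L)
      }
    }
    ii <- which(ot$op == "I")
    if (length(ii)) {
      ipos <- abs_start[ii] - 1L   # column of the preceding reference base
      allele <- substring(reads$seq[ot$idx[ii]],
                          read_off[ii] + 1L, read_off[ii] + ot$len[ii])
      keep <- ipos >= 0L
      ins <- dplyr::count(
        tibble::tibble(pos = ipos[keep], allele = allele[keep]),
        .data$pos, .data$allele, name = "count")
    }
  }
  depth <- cumsum(depth_d)[seq_len(L)]
  match_cov <- cumsum(match_d)[seq_len(L)]
  refc <- strsplit(rep$seq, "")[[1]]
  for (bb in DNA_BASES) {
    sel <- refc == bb
    bc[bb, sel] <- bc[bb, sel] + match_cov[sel]
  }
  structure(list(replicon_id = rep$id, length = L, ref = rep$seq,
                 depth = as.integer(depth), del = del, base_counts = bc,
                 ins = ins),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %s: %s bp, mean depth %.1f, %d deletion-supported and %d insertion-supported columns\n",
              x$replicon_id, format(x$length, big.mark = ","),
              mean(x$depth), sum(x$del > 0), length(unique(x$ins$pos))))
  invisible(x)
}

#' Tabular view of covered pileup columns
#'
#' @param p a `pileup`.
#' @return Tibble with one row per reference position with any coverage:
#'   `pos` (0-based), `depth`, `A`, `C`, `G`, `T`, `del_support`.
#' @export
pileup_columns <- function(p) {
  covered <- which(p$depth > 0L)
  tibble::tibble(
    replicon_id = p$replicon_id, pos = covered - 1L, depth = p$depth[covered],
    A = p$base_counts["A", covered], C = p$base_counts["C", covered],
    G = p$base_counts["G", covered], T = p$base_counts["T", covered],
    del_support = p$del[covered]
  )
}
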