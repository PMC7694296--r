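#' Aligned-read interchange (tab-separated)
#'
#' Reads are exchanged in a PAF-like TSV dialect with columns `read_id`,
#' `replicon_id`, `start` (0-based position of the first aligned reference
#' base), `strand`, `ops` and `seq`. `ops` is a CIGAR-style edit string over
#' `{=, X, I, D}` — match, mismatch, insertion-to-reference,
#' deletion-from-reference — with explicit `=`/`X` so that indels and
#' mismatches are unambiguous in the pileup. `seq` holds the aligned read
#' bases in reference orientation.
#'
#' Invariants enforced on read: lengths of `{=, X, I}` ops sum to
#' `nchar(seq)`; no two adjacent ops of the same kind; ops letters known.
#'
#' @param path TSV file path.
#' @param g optional `genome` for bounds checking against replicon lengths.
#' @return `read_alignments()` returns the validated read tibble.
#' @export
read_alignments <- function(path, g = NULL) {
  assert(file.exists(path), "alignment file not found: %s", path)
  reads <- readr::read_tsv(
    path,
    col_types = readr::cols(
      read_id = readr::col_character(),
      replicon_id = readr::col_character(),
      start = readr::col_integer(),
      strand = readr::col_character(),
      ops = readr::col_character(),
      seq = readr::col_character()
    ),
    progress = FALSE
  )
  validate_reads(reads, g)
}

#' @rdname read_alignments
#' @param reads read tibble with the six dialect columns.
#' @export
write_alignments <- function(reads, path, g = NULL) {
  reads <- validate_reads(reads, g)
  readr::write_tsv(reads, path, progress = FALSE)
  invisible(path)
}

#' Parse CIGAR-style op strings into a long table
#'
#' @param ops character vector of op strings like `"10=1D10="`.
#' @return A tibble with columns `idx` (index into `ops`), `op`, `len`.
#' @keywords internal
ops_table <- function(ops) {
  m <- stringr::str_match_all(ops, "(\\d+)([=XID])")
  consumed <- vapply(m, function(x) sum(nchar(x[, 1])), numeric(1))
  bad <- which(consumed != nchar(ops))
  if (length(bad)) abort("malformed ops string: '%s'", ops[bad[1]])
  n <- vapply(m, nrow, integer(1))
  assert(all(n > 0L), "empty ops string")
  tibble::tibble(
    idx = rep(seq_along(ops), n),
    op = unlist(lapply(m, function(x) x[, 3]), use.names = FALSE),
    len = as.integer(unlist(lapply(m, function(x) x[, 2]), use.names = FALSE))
  )
}

# reference / read space consumed by each read's ops
op_spans <- function(ot, n_reads) {
  ref <- rowsum(ot$len * (ot$op %in% c("=", "X", "D")), ot$idx)
  rd <- rowsum(ot$len * (ot$op %in% c("=", "X", "I")), ot$idx)
  out <- matrix(0L, nrow = n_reads, ncol = 2)
  out[as.integer(rownames(ref)), 1] <- as.integer(ref)
  out[as.integer(rownames(rd)), 2] <- as.integer(rd)
  colnames(out) <- c("ref", "read")
  out
}

#' @rdname read_alignments
#' @export
validate_reads <- function(reads, g = NULL) {
  need <- c("read_id", "replicon_id", "start", "strand", "ops", "seq")
  assert(all(need %in% names(reads)), "read table must have columns %s",
         paste(need, collapse = ", "))
  if (nrow(reads) == 0L) return(reads)
  assert(all(reads$strand %in% c("+", "-")), "read strand must be '+' or '-'")
  assert(all(reads$start >= 0L), "read start must be >= 0")
  ot <- ops_table(reads$ops)
  # no two adjacent ops of the same kind
  same <- ot$idx[-1] == ot$idx[-nrow(ot)] & ot$op[-1] == ot$op[-nrow(ot)]
  if (any(same)) abort("adjacent ops of the same kind in read '%s'",
                       reads$read_id[ot$idx[which(same)[1]]])
  spans <- op_spans(ot, nrow(reads))
  bad <- which(spans[, "read"] != nchar(reads$seq))
  if (length(bad)) {
    abort("read '%s': ops consume %d read bases but seq has %d",
          reads$read_id[bad[1]], spans[bad[1], "read"], nchar(reads$seq[bad[1]]))
  }
  if (!is.null(g)) {
    lens <- replicon_lengths(g)
    assert(all(reads$replicon_id %in% names(lens)),
           "read on unknown replicon '%s'",
           setdiff(reads$replicon_id, names(lens))[1])
    ends <- reads$start + spans[, "ref"]
    bad <- which(ends > lens[reads$replicon_id])
    if (length(bad)) abort("read '%s' extends past the end of replicon '%s'",
                           reads$read_id[bad[1]], reads$replicon_id[bad[1]])
  }
  reads
}

#' Truth-set I/O
#'
#' The simulator's planted loci travel as a TSV with columns `replicon_id`,
#' `tract_start`, `tract_len`, `base`, `planted` (logical) and `concordance`,
#' one row per eligible homopolymer tract.
#'
#' @param truth truth tibble (the `loci` element of a [plant_systematic_errors()]
#'   result, or any tibble with the six columns).
#' @param path TSV path.
#' @return `read_truth()` returns the truth tibble.
#' @export
write_truth <- function(truth, path) {
  need <- c("replicon_id", "tract_start", "tract_len", "base", "planted", "concordance")
  assert(all(need %in% names(truth)), "truth table must have columns %s",
         paste(need, collapse = ", "))
  readr::write_tsv(truth[need], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  assert(file.exists(path), "truth file not found: %s", path)
  readr::read_tsv(
    path,
    col_types = readr::cols(
      replicon_id = readr::col_character(),
      tract_start = readr::col_integer(),
      tract_len = readr::col_integer(),
      base = readr::col_character(),
      planted = readr::col_logical(),
      concordance = readr::col_double()
    ),
    progress = FALSE
  )
}

#' Homopolymer tract BED I/O
#'
#' Tracts are written as 0-based half-open BED with a fourth `base` column.
#'
#' @param tracts tract tibble from [find_homopolymers()].
#' @param path BED path.
#' @return `read_tracts_bed()` returns the tract tibble.
#' @export
write_tracts_bed <- function(tracts, path) {
  bed <- tibble::tibble(chrom = tracts$replicon_id, start = tracts$start,
                        end = tracts$start + tracts$length, name = tracts$base)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_tracts_bed
#' @export
read_tracts_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                         col_types = "ciic", progress = FALSE)
  tibble::tibble(replicon_id = bed$chrom, start = bed$start,
                 length = bed$end - bed$start, base = bed$name)
}
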