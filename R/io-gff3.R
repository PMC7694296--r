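#' CDS annotation I/O (GFF3)
#'
#' Internally a CDS set is a tibble with columns `cds_id`, `replicon_id`,
#' `start`, `end` (0-based half-open on the forward coordinate system) and
#' `strand` (`+`/`-`). On disk GFF3 uses 1-based inclusive coordinates; the
#' reader/writer pair converts between the two and round-trips exactly.
#' Validation enforces `0 <= start < end`, length divisible by 3,
#' non-overlapping CDS per replicon, and — when a genome is supplied —
#' intervals within the replicon.
#'
#' @param path path to a GFF3 file; only `CDS` lines are consumed.
#' @param g optional `genome` used to validate coordinates against replicon
#'   lengths.
#' @return `read_gff3()` returns the CDS tibble, sorted as on disk.
#' @export
read_gff3 <- function(path, g = NULL) {
  assert(file.exists(path), "GFF3 file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) return(validate_cds(empty_cds(), g))
  f <- strsplit(lines, "\t", fixed = TRUE)
  assert(all(lengths(f) == 9L), "malformed GFF3: expected 9 tab-separated columns")
  m <- do.call(rbind, f)
  keep <- m[, 3] == "CDS"
  m <- m[keep, , drop = FALSE]
  start1 <- as.integer(m[, 4])
  end1 <- as.integer(m[, 5])
  bad <- which(end1 < start1)
  if (length(bad)) abort("GFF3 CDS with end < start at line for seqid '%s'", m[bad[1], 1])
  ids <- stringr::str_match(m[, 9], "(?:^|;)ID=([^;]+)")[, 2]
  assert(!anyNA(ids), "GFF3 CDS line without an ID attribute")
  cds <- tibble::tibble(
    cds_id = ids,
    replicon_id = m[, 1],
    start = start1 - 1L,     # GFF3 1-based inclusive -> 0-based half-open
    end = end1,
    strand = m[, 7]
  )
  validate_cds(cds, g)
}

#' @rdname read_gff3
#' @param cds CDS tibble as returned by [read_gff3()] or [simulate_genome()].
#' @export
write_gff3 <- function(cds, path, g = NULL) {
  cds <- validate_cds(cds, g)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(cds) > 0) {
    writeLines(sprintf("%s\t.\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                       cds$replicon_id, cds$start + 1L, cds$end,
                       cds$strand, cds$cds_id), con)
  }
  invisible(path)
}

empty_cds <- function() {
  tibble::tibble(cds_id = character(), replicon_id = character(),
                 start = integer(), end = integer(), strand = character())
}

#' @rdname read_gff3
#' @export
validate_cds <- function(cds, g = NULL) {
  need <- c("cds_id", "replicon_id", "start", "end", "strand")
  assert(all(need %in% names(cds)), "CDS table must have columns %s",
         paste(need, collapse = ", "))
  if (nrow(cds) == 0L) return(cds)
  assert(all(cds$strand %in% c("+", "-")), "CDS strand must be '+' or '-'")
  assert(!anyDuplicated(cds$cds_id), "duplicate cds_id")
  bad <- which(!(cds$start >= 0 & cds$start < cds$end))
  if (length(bad)) abort("CDS '%s' has an invalid interval [%d, %d)",
                         cds$cds_id[bad[1]], cds$start[bad[1]], cds$end[bad[1]])
  bad <- which((cds$end - cds$start) %% 3L != 0L)
  if (length(bad)) abort("CDS '%s' length %d is not divisible by 3",
                         cds$cds_id[bad[1]], cds$end[bad[1]] - cds$start[bad[1]])
  if (!is.null(g)) {
    lens <- replicon_lengths(g)
    assert(all(cds$replicon_id %in% names(lens)),
           "CDS on unknown replicon '%s'",
           setdiff(cds$replicon_id, names(lens))[1])
    bad <- which(cds$end > lens[cds$replicon_id])
    if (length(bad)) abort("CDS '%s' extends past the end of replicon '%s'",
                           cds$cds_id[bad[1]], cds$replicon_id[bad[1]])
  }
  # non-overlap within each replicon
  for (rid in unique(cds$replicon_id)) {
    sub <- cds[cds$replicon_id == rid, ]
    o <- order(sub$start)
    if (any(sub$start[o][-1] < sub$end[o][-nrow(sub)])) {
      abort("overlapping CDS on replicon '%s'", rid)
    }
  }
  cds
}
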