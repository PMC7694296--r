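#' Read a multi-replicon genome from FASTA
#'
#' One FASTA record per replicon, in file order. The header token before the
#' first whitespace becomes the replicon id; `topology=`, `role=` and
#' `copy_number=` key=value pairs in the description are honoured when
#' present (defaults: linear plasmid, copy number 1). The alphabet is
#' strictly ACGT; N or IUPAC ambiguity codes are rejected with the offending
#' position.
#'
#' @param path path to an existing FASTA file.
#' @return A `genome` object (empty list of class `genome` for an empty file).
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  assert(file.exists(path), "FASTA file not found: %s", path)
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(set) == 0L) return(genome(list()))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) abort("duplicate replicon id in FASTA: '%s'",
                                ids[duplicated(ids)][1])
  reps <- lapply(seq_along(set), function(i) {
    desc <- sub("^\\S+\\s*", "", headers[i])
    kv <- parse_kv(desc)
    replicon(
      id = ids[i],
      seq = as.character(set[[i]]),
      topology = kv[["topology"]] %||% "linear",
      role = kv[["role"]] %||% "plasmid",
      copy_number = as.numeric(kv[["copy_number"]] %||% 1)
    )
  })
  genome(reps)
}

#' Write a genome to FASTA
#'
#' Deterministic byte output for a fixed input: headers carry
#' `topology= role= copy_number=` key=value pairs so that
#' `read_fasta(write_fasta(g))` round-trips exactly.
#'
#' @param g a `genome` or list of `replicon`s.
#' @param path output path.
#' @param line_width sequence bases per line (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(g, path, line_width = 70L) {
  assert(is_count(line_width) && line_width >= 1, "line_width must be >= 1")
  if (!inherits(g, "genome")) g <- genome(g)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (r in g) {
    writeLines(sprintf(">%s topology=%s role=%s copy_number=%s",
                       r$id, r$topology, r$role, format(r$copy_number)), con)
    n <- nchar(r$seq)
    starts <- seq(1L, n, by = line_width)
    writeLines(substring(r$seq, starts, pmin(starts + line_width - 1L, n)), con)
  }
  invisible(path)
}

parse_kv <- function(desc) {
  if (!nzchar(desc)) return(list())
  toks <- strsplit(trimws(desc), "\\s+")[[1]]
  toks <- toks[grepl("=", toks, fixed = TRUE)]
  vals <- sub("^[^=]*=", "", toks)
  setNames(as.list(vals), sub("=.*$", "", toks))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
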