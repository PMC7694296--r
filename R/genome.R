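#' Replicons and genomes
#'
#' A `replicon` is one independently replicating DNA element (chromosome,
#' megaplasmid or plasmid): an id, a sequence over the strict ACGT alphabet,
#' a topology (bacterial replicons are usually circular), a role, and — on
#' the simulation side only — a per-cell copy number relative to the
#' chromosome. A `genome` is an ordered list of replicons with unique ids;
#' by convention the first replicon is the chromosome (copy number 1).
#'
#' @param id single non-empty string, unique within a genome.
#' @param seq DNA sequence as one character string over {A,C,G,T}.
#' @param topology `"circular"` or `"linear"`.
#' @param role `"chromosome"`, `"megaplasmid"` or `"plasmid"`.
#' @param copy_number positive real; expected per-cell copies relative to the
#'   chromosome. Only consumed by the read simulator.
#' @return `replicon()` returns a `replicon` object; `genome()` a `genome`
#'   (list of replicons).
#' @examples
#' r <- replicon("chr", "ACGTACGT", topology = "circular", role = "chromosome")
#' g <- genome(list(r))
#' replicon_lengths(g)
#' @export
replicon <- function(id, seq, topology = c("linear", "circular"),
                     role = c("plasmid", "chromosome", "megaplasmid"),
                     copy_number = 1) {
  topology <- match.arg(topology)
  role <- match.arg(role)
  assert(is_scalar_string(id) && nzchar(id), "replicon id must be a non-empty string")
  assert(is_scalar_string(seq), "replicon seq must be a single character string")
  assert(nzchar(seq), "replicon '%s' has an empty sequence", id)
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L) {
    abort("replicon '%s' contains non-ACGT character '%s' at position %d",
          id, substr(seq, bad, bad), as.integer(bad))
  }
  assert(is_scalar_number(copy_number) && copy_number > 0,
         "copy_number must be a positive number")
  structure(
    list(id = id, seq = seq, topology = topology, role = role,
         copy_number = copy_number),
    class = "replicon"
  )
}

#' @rdname replicon
#' @param replicons list of `replicon` objects.
#' @export
genome <- function(replicons) {
  assert(is.list(replicons) && all(vapply(replicons, inherits, logical(1), "replicon")),
         "genome() expects a list of replicon objects")
  ids <- vapply(replicons, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    abort("duplicate replicon id: '%s'", ids[duplicated(ids)][1])
  }
  names(replicons) <- ids
  structure(replicons, class = "genome")
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon> %s: %s bp, %s %s, copy number %.3g\n",
              x$id, format(nchar(x$seq), big.mark = ","), x$topology, x$role,
              x$copy_number))
  invisible(x)
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %d replicon(s), %s bp, GC %.2f%%\n",
              length(x), format(genome_size(x), big.mark = ","),
              100 * gc_fraction(x)))
  for (r in x) print(r)
  invisible(x)
}

#' Genome summary helpers
#'
#' `replicon_lengths()` returns the named vector of replicon lengths,
#' `genome_size()` their sum, and `gc_fraction()` the G+C fraction of the
#' concatenated genome (or of a single replicon) by direct base counting.
#'
#' @param g a `genome` (or, for `gc_fraction()`, a `replicon`).
#' @return Numeric vector or scalar.
#' @export
replicon_lengths <- function(g) {
  vapply(g, function(r) nchar(r$seq), numeric(1))
}

#' @rdname replicon_lengths
#' @export
genome_size <- function(g) {
  sum(replicon_lengths(g))
}

#' @rdname replicon_lengths
#' @export
gc_fraction <- function(g) {
  seqs <- if (inherits(g, "replicon")) g$seq else vapply(g, `[[`, character(1), "seq")
  n_gc <- sum(nchar(gsub("[AT]", "", seqs)))
  n_gc / sum(nchar(seqs))
}
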