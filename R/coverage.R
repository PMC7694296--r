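#' Mean read depth of a replicon
#'
#' Total aligned reference bases divided by replicon length, counting every
#' position including zero-coverage ones (the convention behind published
#' per-replicon coverage figures).
#'
#' @param x a read tibble or a `pileup`.
#' @param rep the `replicon` (required for a read tibble; ignored for a
#'   pileup, which knows its replicon).
#' @return Mean depth (real, >= 0).
#' @export
mean_depth <- function(x, rep = NULL) {
  if (inherits(x, "pileup")) {
    return(sum(as.numeric(x$depth)) / x$length)
  }
  assert(inherits(rep, "replicon"), "rep must be a replicon")
  reads <- x[x$replicon_id == rep$id, , drop = FALSE]
  if (nrow(reads) == 0L) return(0)
  ot <- ops_table(reads$ops)
  sum(as.numeric(ot$len[ot$op %in% c("=", "X", "D")])) / nchar(rep$seq)
}

#' Replicon copy-number ratios from read depth
#'
#' Divides each replicon's mean depth by the chromosome's. The display
#' string truncates the ratio toward zero at two significant figures and
#' formats it as `"x:1"` — the convention that reproduces published
#' depth-ratio statements (1.368 -> "1.3:1", 0.384 -> "0.38:1").
#'
#' @param depths named numeric vector of per-replicon mean depths.
#' @param chromosome_id name of the chromosome entry (default: first).
#' @param lengths optional named vector of replicon lengths for the output
#'   table.
#' @return A `coverage_summary` tibble: `replicon_id`, `length`,
#'   `mean_depth`, `ratio`, `ratio_display`.
#' @examples
#' copy_ratio(c(chr = 339.8, pTTHNP4 = 464.9))
#' @export
copy_ratio <- function(depths, chromosome_id = names(depths)[1], lengths = NULL) {
  assert(!is.null(names(depths)), "depths must be a named vector")
  assert(chromosome_id %in% names(depths), "unknown chromosome id '%s'", chromosome_id)
  chr_depth <- depths[[chromosome_id]]
  assert(chr_depth > 0, "chromosome depth must be positive")
  ratio <- unname(depths / chr_depth)
  out <- tibble::tibble(
    replicon_id = names(depths),
    length = if (is.null(lengths)) NA_integer_ else
      as.integer(lengths[names(depths)]),
    mean_depth = unname(depths),
    ratio = ratio,
    ratio_display = vapply(ratio, fmt_ratio, character(1))
  )
  class(out) <- c("coverage_summary", class(out))
  out
}

# truncate toward zero at two significant figures, format as "x:1"
fmt_ratio <- function(x) {
  if (x == 0) return("0:1")
  e <- floor(log10(abs(x)))
  y <- trunc(x / 10^(e - 1)) * 10^(e - 1)
  sprintf("%.*f:1", max(0L, as.integer(1 - e)), y)
}

#' Per-replicon coverage summary from reads or pileups
#'
#' @param x read tibble covering one or more replicons, or a named list of
#'   `pileup`s.
#' @param g the `genome`.
#' @param chromosome_id chromosome replicon id (default: first of `g`).
#' @return A `coverage_summary` (see [copy_ratio()]).
#' @export
coverage_summary <- function(x, g, chromosome_id = names(g)[1]) {
  depths <- vapply(g, function(rep) {
    if (is.list(x) && !is.data.frame(x)) {
      p <- x[[rep$id]]
      if (is.null(p)) 0 else mean_depth(p)
    } else {
      mean_depth(x, rep)
    }
  }, numeric(1))
  copy_ratio(depths, chromosome_id, lengths = replicon_lengths(g))
}

#' @rdname coverage_summary
#' @param cov a `coverage_summary`.
#' @param path TSV path.
#' @export
write_coverage_tsv <- function(cov, path) {
  readr::write_tsv(tibble::as_tibble(cov), path, progress = FALSE)
  invisible(path)
}
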