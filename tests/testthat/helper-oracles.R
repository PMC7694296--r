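# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# maximal identical-base runs by linear character walk (linear topology)
oracle_homopolymers <- function(seq, min_len) {
  chars <- strsplit(seq, "")[[1]]
  out <- list()
  i <- 1L
  while (i <= length(chars)) {
    j <- i
    while (j < length(chars) && chars[j + 1L] == chars[i]) j <- j + 1L
    if (j - i + 1L >= min_len) {
      out[[length(out) + 1L]] <- data.frame(start = i - 1L, length = j - i + 1L,
                                            base = chars[i])
    }
    i <- j + 1L
  }
  if (!length(out)) {
    return(data.frame(start = integer(), length = integer(), base = character()))
  }
  do.call(rbind, out)
}

# reference span of an ops string by naive token walk
oracle_ref_span <- function(ops) {
  m <- regmatches(ops, gregexpr("[0-9]+[=XID]", ops))[[1]]
  lens <- as.integer(sub("[=XID]$", "", m))
  kinds <- sub("^[0-9]+", "", m)
  sum(lens[kinds %in% c("=", "X", "D")])
}

# per-position depth by interval stabbing: count reads covering each position
oracle_depth <- function(reads, L) {
  depth <- integer(L)
  for (i in seq_len(nrow(reads))) {
    span <- oracle_ref_span(reads$ops[i])
    if (span == 0) next
    idx <- (reads$start[i] + 1L):(reads$start[i] + span)
    depth[idx] <- depth[idx] + 1L
  }
  depth
}

# ORF fragments by direct translation of the mutated interval with
# Biostrings: translate from frame 0; on a stop, look for the next
# ATG/GTG/TTG at any offset and translate from there; report fragment
# lengths in amino acids (stops excluded)
oracle_fragments <- function(nt, start_codons = c("ATG", "GTG", "TTG")) {
  frags <- integer(0)
  from <- 1L
  repeat {
    n_codons <- (nchar(nt) - from + 1L) %/% 3L
    if (n_codons < 1L) break
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(nt, from, from + 3L * n_codons - 1L)),
      if.fuzzy.codon = "X"))
    stop_at <- regexpr("*", aa, fixed = TRUE)
    if (stop_at < 0L) {
      frags <- c(frags, nchar(aa))
      break
    }
    frags <- c(frags, stop_at - 1L)
    after <- from + 3L * stop_at           # first nt after the stop codon
    found <- NA
    if (after <= nchar(nt) - 2L) {
      for (q in after:(nchar(nt) - 2L)) {
        if (substr(nt, q, q + 2L) %in% start_codons) {
          found <- q
          break
        }
      }
    }
    if (is.na(found)) break
    from <- found
  }
  frags
}

# aligned reference bases per replicon by direct summation
oracle_total_aligned <- function(reads) {
  sum(vapply(reads$ops, oracle_ref_span, numeric(1)))
}
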