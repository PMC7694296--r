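#' Simulate pre-aligned reads with planted systematic indels
#'
#' Emits reads already placed on the reference (no aligner is involved; the
#' analysis under test starts at the pileup). Reads are placed uniformly,
#' wrapping across the origin of circular replicons; a wrapped read is split
#' into two alignment records sharing the read id with `/a` and `/b`
#' suffixes, so downstream pileup logic stays linear. Per-replicon expected
#' depth is `tech$depth * copy_number`.
#'
#' For the long technology, each read covering a planted locus carries the
#' planted single-base indel independently with probability
#' `truth$params$concordance`; the short technology follows the reference at
#' planted loci. Background errors are applied per base at
#' `tech$background_error`, as 80% substitutions, 10% 1-bp insertions and
#' 10% 1-bp deletions. Output is deterministic for fixed parameters and
#' seeds.
#'
#' Reads longer than a replicon are truncated to the replicon length (the
#' smallest plasmid of the default genome is shorter than a long read).
#'
#' @param g a `genome`.
#' @param truth a `truth_set` from [plant_systematic_errors()] (ignored for
#'   the short technology).
#' @param tech a [tech_params()].
#' @return Read tibble in the [read_alignments()] dialect.
#' @export
simulate_reads <- function(g, truth, tech) {
  assert(inherits(tech, "tech_params"), "tech must come from tech_params()")
  planted <- if (inherits(truth, "truth_set")) {
    truth$loci[truth$loci$planted, ]
  } else {
    truth   # already a loci tibble (or empty)
  }
  concordance <- if (inherits(truth, "truth_set")) truth$params$concordance else 1
  withr::with_seed(derive_seed(tech$seed, paste0("reads_", tech$name)), {
    dplyr::bind_rows(lapply(g, function(rep) {
      sim_replicon_reads(rep, planted[planted$replicon_id == rep$id, ],
                         tech, concordance)
    }))
  })
}

sim_replicon_reads <- function(rep, planted, tech, concordance) {
  L <- nchar(rep$seq)
  len <- min(tech$mean_read_len, L)
  circ <- rep$topology == "circular"
  n <- round(tech$depth * rep$copy_number * L / len)
  assert(n >= 1, "depth %.3g infeasible for read length %d on replicon '%s'",
         tech$depth * rep$copy_number, len, rep$id)
  starts <- if (circ) sample.int(L, n, replace = TRUE) - 1L else
    sample.int(L - len + 1L, n, replace = TRUE) - 1L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  ids <- sprintf("%s_%s_%06d", rep$id, tech$name, seq_len(n))
  refc <- strsplit(rep$seq, "")[[1]]
  ref2 <- if (circ) paste0(rep$seq, rep$seq) else rep$seq

  ev <- sim_events(rep, planted, tech, concordance, starts, len, circ, refc, L)

  has_ev <- logical(n)
  if (nrow(ev)) has_ev[unique(ev$ridx)] <- TRUE
  wrap <- circ & (starts + len > L)
  ops <- character(n)
  seqs <- character(n)

  plain <- which(!wrap & !has_ev)
  if (length(plain)) {
    ops[plain] <- sprintf("%d=", len)
    seqs[plain] <- substring(ref2, starts[plain] + 1L, starts[plain] + len)
  }
  evset <- which(!wrap & has_ev)
  chunk <- 2000L
  for (lo in if (length(evset)) seq(1L, length(evset), by = chunk) else integer(0)) {
    idx <- evset[lo:min(lo + chunk - 1L, length(evset))]
    sub <- ev[ev$ridx %in% idx, ]
    sub$ridx <- match(sub$ridx, idx)
    built <- build_aln_batch(ref2, starts[idx], len, sub)
    ops[idx] <- built$ops
    seqs[idx] <- built$seq
  }
  out <- tibble::tibble(read_id = ids, replicon_id = rep$id, start = starts,
                        strand = strand, ops = ops, seq = seqs)
  widx <- which(wrap)
  if (length(widx)) {
    parts <- lapply(widx, function(i) {
      pieces <- read_pieces(starts[i], len, ev[ev$ridx == i, ])
      halves <- split_pieces(pieces, cut = L - starts[i])
      a <- collapse_pieces(halves$a, ref2)
      rows <- tibble::tibble(read_id = paste0(ids[i], "/a"),
                             replicon_id = rep$id, start = starts[i],
                             strand = strand[i], ops = a$ops, seq = a$seq)
      if (!is.null(halves$b)) {
        halves$b$from <- halves$b$from - L   # second arm restarts at origin
        b <- collapse_pieces(halves$b, ref2)
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          read_id = paste0(ids[i], "/b"), replicon_id = rep$id, start = 0L,
          strand = strand[i], ops = b$ops, seq = b$seq))
      }
      rows
    })
    out <- dplyr::bind_rows(out[-widx, ], dplyr::bind_rows(parts))
    out <- out[order(out$read_id), ]
  }
  out
}

# one row per (read, position) event; planted indels take priority over
# background noise at the same position
sim_events <- function(rep, planted, tech, concordance, starts, len, circ, refc, L) {
  evs <- list()
  if (tech$name == "long" && nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      p <- planted$pos[i]
      off <- if (circ) (p - starts) %% L else p - starts
      cover <- which(off >= 0L & off < len)
      carry <- cover[stats::runif(length(cover)) < concordance]
      if (length(carry)) {
        ptype <- if (planted$indel_type[i] == "deletion") "D" else "I"
        evs[[length(evs) + 1L]] <- tibble::tibble(
          ridx = carry, pos = off[carry], type = ptype,
          base = if (ptype == "I") planted$base[i] else "")
      }
    }
  }
  if (tech$background_error > 0) {
    n_bg <- stats::rbinom(length(starts), len, tech$background_error)
    tot <- sum(n_bg)
    if (tot > 0) {
      ridx <- rep(seq_along(starts), n_bg)
      off <- sample.int(len, tot, replace = TRUE) - 1L
      type <- sample(c("X", "I", "D"), tot, replace = TRUE, prob = c(0.8, 0.1, 0.1))
      abs_pos <- if (circ) (starts[ridx] + off) %% L else starts[ridx] + off
      ref_base <- refc[abs_pos + 1L]
      # substitute with one of the three other bases, uniformly
      alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                    nrow = 4, byrow = TRUE, dimnames = list(DNA_BASES, NULL))
      base <- character(tot)
      is_x <- type == "X"
      base[is_x] <- alt[cbind(match(ref_base[is_x], DNA_BASES),
                              sample.int(3L, sum(is_x), replace = TRUE))]
      is_i <- type == "I"
      base[is_i] <- sample(DNA_BASES, sum(is_i), replace = TRUE)
      evs[[length(evs) + 1L]] <- tibble::tibble(ridx = ridx, pos = off,
                                                type = type, base = base)
    }
  }
  if (!length(evs)) {
    return(tibble::tibble(ridx = integer(), pos = integer(),
                          type = character(), base = character()))
  }
  ev <- dplyr::bind_rows(evs)       # planted rows first: they win the dedupe
  ev <- ev[!duplicated(ev[c("ridx", "pos")]), ]
  ev[order(ev$ridx, ev$pos), ]
}

# vectorized ops/seq construction for a batch of reads that all carry >= 1
# event and do not wrap. Pieces: for each event a leading "=" gap then the
# 1-base op; one trailing "=" per read; zero-length gaps dropped; adjacent
# same-kind ops merged.
build_aln_batch <- function(ref2, starts, len, ev) {
  m <- length(starts)
  n_ev <- nrow(ev)
  first <- !duplicated(ev$ridx)
  prev_pos <- c(-1L, ev$pos[-n_ev])
  prev_pos[first] <- -1L
  cons_before <- prev_pos + 1L
  gap <- ev$pos - cons_before + (ev$type == "I")
  last <- !duplicated(ev$ridx, fromLast = TRUE)
  last_pos <- ev$pos[last][order(ev$ridx[last])]   # one per read, reads 1..m
  trail <- len - (last_pos + 1L)

  p_ridx <- c(ev$ridx, ev$ridx, seq_len(m))
  p_pos <- c(ev$pos, ev$pos, rep(len, m))
  p_rank <- c(rep(0L, n_ev), rep(1L, n_ev), rep(0L, m))
  p_len <- c(gap, rep(1L, n_ev), trail)
  p_op <- c(rep("=", n_ev), ev$type, rep("=", m))
  p_from <- c(starts[ev$ridx] + cons_before, rep(NA_integer_, n_ev),
              starts + last_pos + 1L)
  p_txt <- c(rep(NA_character_, n_ev), ifelse(ev$type == "D", "", ev$base),
             rep(NA_character_, m))
  ord <- order(p_ridx, p_pos, p_rank)
  keep <- ord[p_len[ord] > 0L]
  r_ridx <- p_ridx[keep]; r_len <- p_len[keep]; r_op <- p_op[keep]
  r_from <- p_from[keep]; r_txt <- p_txt[keep]

  # seq: substring for "=" pieces, event text otherwise, in order
  eq <- is.na(r_txt)
  r_txt[eq] <- substring(ref2, r_from[eq] + 1L, r_from[eq] + r_len[eq])
  fr <- factor(r_ridx, levels = seq_len(m))
  seqs <- vapply(split(r_txt, fr), paste, character(1), collapse = "")

  # ops: merge adjacent same-kind pieces within each read
  nk <- length(r_ridx)
  new_grp <- c(TRUE, r_ridx[-1] != r_ridx[-nk] | r_op[-1] != r_op[-nk])
  gid <- cumsum(new_grp)
  mlen <- as.integer(rowsum(r_len, gid))
  mop <- r_op[new_grp]
  mridx <- r_ridx[new_grp]
  ops <- vapply(split(paste0(mlen, mop), factor(mridx, levels = seq_len(m))),
                paste, character(1), collapse = "")
  list(ops = unname(ops), seq = unname(seqs))
}

# scalar piece table for one read (possibly origin-wrapping, coordinates in
# the unwrapped/doubled frame)
read_pieces <- function(start, len, ev) {
  pieces <- list()
  cons <- 0L
  if (nrow(ev)) {
    ev <- ev[order(ev$pos), ]
    for (k in seq_len(nrow(ev))) {
      gap <- ev$pos[k] - cons + (ev$type[k] == "I")
      if (gap > 0) {
        pieces[[length(pieces) + 1L]] <-
          list(len = gap, op = "=", from = start + cons, txt = NA_character_)
      }
      pieces[[length(pieces) + 1L]] <-
        list(len = 1L, op = ev$type[k], from = NA_integer_,
             txt = if (ev$type[k] == "D") "" else ev$base[k])
      cons <- ev$pos[k] + 1L
    }
  }
  if (len - cons > 0) {
    pieces[[length(pieces) + 1L]] <-
      list(len = len - cons, op = "=", from = start + cons, txt = NA_character_)
  }
  do.call(rbind.data.frame, pieces)
}

# split a piece table at a reference-consumption offset (for origin wrap)
split_pieces <- function(pieces, cut) {
  consumes <- pieces$op %in% c("=", "X", "D")
  cum <- cumsum(ifelse(consumes, pieces$len, 0L))
  before <- cum - ifelse(consumes, pieces$len, 0L)
  a_rows <- which(cum <= cut | (!consumes & before <= cut))
  b_rows <- setdiff(seq_len(nrow(pieces)), a_rows)
  straddle <- which(consumes & before < cut & cum > cut)
  if (length(straddle)) {
    s <- straddle[1]
    take <- cut - before[s]
    a <- pieces[c(a_rows[a_rows < s], s), , drop = FALSE]
    a$len[nrow(a)] <- take
    b_first <- pieces[s, , drop = FALSE]
    b_first$len <- pieces$len[s] - take
    if (!is.na(b_first$from)) b_first$from <- b_first$from + take
    b <- rbind(b_first, pieces[b_rows[b_rows > s], , drop = FALSE])
  } else {
    a <- pieces[a_rows, , drop = FALSE]
    b <- pieces[b_rows, , drop = FALSE]
    if (nrow(b) == 0L) b <- NULL
  }
  list(a = a, b = b)
}

collapse_pieces <- function(pieces, ref2) {
  txt <- pieces$txt
  eq <- is.na(txt)
  txt[eq] <- substring(ref2, pieces$from[eq] + 1L, pieces$from[eq] + pieces$len[eq])
  n <- nrow(pieces)
  new_grp <- c(TRUE, pieces$op[-1] != pieces$op[-n])
  gid <- cumsum(new_grp)
  mlen <- as.integer(rowsum(pieces$len, gid))
  mop <- pieces$op[new_grp]
  list(ops = paste0(mlen, mop, collapse = ""), seq = paste(txt, collapse = ""))
}
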