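#' Extract flanking windows around homopolymer loci
#'
#' For each locus, takes `w` bases immediately upstream of the tract start
#' and `w` bases immediately downstream of the tract end, concatenated into
#' one forward-strand window of length `2w` that excludes the tract itself.
#' Circular replicons wrap across the origin; on linear replicons loci
#' closer than `w` to an end are dropped with a warning.
#'
#' @param g a `genome`.
#' @param loci tibble with `replicon_id`, `tract_start` (or `start`) and
#'   `tract_len` (or `length`).
#' @param w flank width in bases (default 20).
#' @return A `flank_window_set`: list with `windows` (character vector of
#'   length-`2w` strings), `loci` (the retained loci) and `w`.
#' @export
extract_flanks <- function(g, loci, w = 20L) {
  assert(is_count(w) && w >= 1, "w must be a positive integer")
  if ("tract_start" %in% names(loci)) {
    starts <- loci$tract_start
    lens <- loci$tract_len
  } else {
    starts <- loci$start
    lens <- loci$length
  }
  windows <- character(nrow(loci))
  ok <- logical(nrow(loci))
  for (rid in unique(loci$replicon_id)) {
    rows <- which(loci$replicon_id == rid)
    rep <- g[[rid]]
    assert(!is.null(rep), "locus on unknown replicon '%s'", rid)
    L <- nchar(rep$seq)
    if (rep$topology == "circular") {
      s3 <- paste0(rep$seq, rep$seq, rep$seq)   # centre copy, wrap both ways
      up_from <- L + starts[rows] - w
      down_from <- L + starts[rows] + lens[rows]
      windows[rows] <- paste0(
        substring(s3, up_from + 1L, up_from + w),
        substring(s3, down_from + 1L, down_from + w))
      ok[rows] <- TRUE
    } else {
      fits <- starts[rows] >= w & starts[rows] + lens[rows] + w <= L
      keep <- rows[fits]
      if (length(keep)) {
        windows[keep] <- paste0(
          substring(rep$seq, starts[keep] - w + 1L, starts[keep]),
          substring(rep$seq, starts[keep] + lens[keep] + 1L,
                    starts[keep] + lens[keep] + w))
        ok[keep] <- TRUE
      }
      if (any(!fits)) {
        warning(sprintf("%d locus/loci within %d bp of an end of linear replicon '%s' dropped",
                        sum(!fits), w, rid), call. = FALSE)
      }
    }
  }
  structure(list(windows = windows[ok], loci = loci[ok, , drop = FALSE],
                 w = as.integer(w)),
            class = "flank_window_set")
}

#' Position frequency matrix of a window set
#'
#' @param windows character vector of equal-length ACGT strings, or a
#'   `flank_window_set`.
#' @return 4 x width integer count matrix with rows A, C, G, T; every
#'   column sums to the number of windows.
#' @export
build_pfm <- function(windows) {
  if (inherits(windows, "flank_window_set")) windows <- windows$windows
  assert(length(windows) >= 1, "at least one window is required")
  width <- unique(nchar(windows))
  assert(length(width) == 1L, "windows must all have the same length")
  pfm_from_codes(encode_windows(windows), width)
}

# integer-coded window matrix (n x width), A=1 .. T=4
encode_windows <- function(windows) {
  width <- nchar(windows[1])
  m <- matrix(match(unlist(strsplit(windows, ""), use.names = FALSE), DNA_BASES),
              ncol = width, byrow = TRUE)
  assert(!anyNA(m), "windows must be over the ACGT alphabet")
  m
}

pfm_from_codes <- function(codes, width) {
  pfm <- vapply(seq_len(width), function(j) tabulate(codes[, j], 4L),
                integer(4L))
  rownames(pfm) <- DNA_BASES
  pfm
}

#' Per-position information content of a PFM
#'
#' Kullback-Leibler information content in bits:
#' `ic_j = sum_b p_bj * log2(p_bj / q_b)` with pseudocounted frequencies
#' `p_bj = (n_bj + pc) / (n + 4 pc)` against background `q`.
#'
#' @param pfm count matrix from [build_pfm()].
#' @param background base frequencies (named or in A,C,G,T order), strictly
#'   positive, summing to 1. Defaults to uniform.
#' @param pseudocount per-base pseudocount (default 0.5).
#' @return Numeric vector of per-position bits.
#' @export
ic_profile <- function(pfm, background = rep(0.25, 4), pseudocount = 0.5) {
  assert(all(background > 0), "background frequencies must be strictly positive")
  assert(abs(sum(background) - 1) < 1e-8, "background must sum to 1")
  if (!is.null(names(background))) background <- background[DNA_BASES]
  n <- sum(pfm[, 1])
  p <- (pfm + pseudocount) / (n + 4 * pseudocount)
  term <- p * log2(p / background)
  term[p == 0] <- 0            # 0 * log(0) convention
  colSums(term)
}

#' Genome background base frequencies
#'
#' @param g a `genome`.
#' @return Named frequency vector over A, C, G, T summing to 1.
#' @export
base_freqs <- function(g) {
  chars <- unlist(strsplit(vapply(g, `[[`, character(1), "seq"), ""),
                  use.names = FALSE)
  tab <- tabulate(match(chars, DNA_BASES), 4L)
  setNames(tab / sum(tab), DNA_BASES)
}

#' Permutation test for a flanking sequence consensus
#'
#' Tests whether the flanks of affected homopolymer tracts carry more
#' positional sequence information than flanks of unaffected tracts of the
#' same base and length composition. The statistic is the maximum
#' per-position information content of the observed window set (mean IC is
#' reported alongside); the null distribution is built by drawing `n_perm`
#' random subsets of unaffected eligible tracts matched exactly on the
#' (base, length) histogram of the observed loci, and the p-value is
#' `(1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param observed `flank_window_set` of the affected loci.
#' @param eligible_tracts tibble of unaffected eligible tracts
#'   (`replicon_id`, `start`, `length`, `base`).
#' @param g the `genome` (flank extraction and background frequencies).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param pseudocount passed to [ic_profile()].
#' @return A `motif_result`: list with `pfm`, `ic`, `max_ic`, `mean_ic`,
#'   `p_value`, `n_perm`, `background`, `n_windows`, `seed`.
#' @export
permutation_consensus_test <- function(observed, eligible_tracts, g,
                                       n_perm = 999L, seed = 1L,
                                       pseudocount = 0.5) {
  assert(inherits(observed, "flank_window_set"), "observed must be a flank_window_set")
  assert(is_count(n_perm) && n_perm >= 1, "n_perm must be a positive integer")
  n_obs <- length(observed$windows)
  assert(n_obs >= 1, "observed window set is empty")
  background <- base_freqs(g)
  pfm <- build_pfm(observed)
  ic <- ic_profile(pfm, background, pseudocount)
  stat_obs <- max(ic)

  obs_loci <- observed$loci
  obs_base <- if ("base" %in% names(obs_loci)) obs_loci$base else obs_loci$tract_base
  obs_len <- if ("tract_len" %in% names(obs_loci)) obs_loci$tract_len else obs_loci$length
  obs_class <- paste(obs_base, obs_len, sep = ":")
  class_need <- table(obs_class)
  null_class <- paste(eligible_tracts$base, eligible_tracts$length, sep = ":")
  for (cl in names(class_need)) {
    assert(sum(null_class == cl) >= class_need[[cl]],
           "not enough unaffected tracts of class %s for matched resampling", cl)
  }
  # pre-extract null flanks once; permutations only index into the code matrix
  null_fl <- extract_flanks(g, eligible_tracts, observed$w)
  null_class <- paste(null_fl$loci$base, null_fl$loci$length, sep = ":")
  for (cl in names(class_need)) {
    assert(sum(null_class == cl) >= class_need[[cl]],
           "not enough unaffected tracts of class %s survive flank extraction", cl)
  }
  codes <- encode_windows(null_fl$windows)
  width <- 2L * observed$w
  class_rows <- split(seq_len(nrow(codes)), null_class)
  stat_null <- withr::with_seed(derive_seed(seed, "motif_perm"), {
    vapply(seq_len(n_perm), function(b) {
      rows <- unlist(lapply(names(class_need), function(cl)
        sample(class_rows[[cl]], class_need[[cl]])), use.names = FALSE)
      pfm_b <- pfm_from_codes(codes[rows, , drop = FALSE], width)
      max(ic_profile(pfm_b, background, pseudocount))
    }, numeric(1))
  })
  structure(list(
    pfm = pfm, ic = ic, max_ic = stat_obs, mean_ic = mean(ic),
    p_value = (1 + sum(stat_null >= stat_obs)) / (n_perm + 1),
    n_perm = as.integer(n_perm), background = background,
    n_windows = n_obs, seed = as.integer(seed)
  ), class = "motif_result")
}

#' @export
print.motif_result <- function(x, ...) {
  cat(sprintf("<motif_result> %d windows, max IC %.3f bits (mean %.3f), p = %.4g (%d permutations)\n",
              x$n_windows, x$max_ic, x$mean_ic, x$p_value, x$n_perm))
  invisible(x)
}
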