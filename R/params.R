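#' Simulation and detection parameter sets
#'
#' Validated parameter constructors for the synthetic-data generator and the
#' discrepancy caller. The defaults encode the study conditions the package
#' emulates: a four-replicon ~2.48 Mbp genome at 68.79% GC with copy numbers
#' estimated from read depth; systematic single-base deletions at G/C
#' homopolymer tracts of length 5-6 affecting 1.64% of the eligible tracts,
#' carried by ~90% of the long reads covering a locus; ~300x long-read and
#' ~50x short-read depth.
#'
#' @param replicon_lengths integer vector of replicon lengths (bp); the first
#'   replicon is the chromosome.
#' @param gc_fraction target genome G+C fraction in (0, 1).
#' @param copy_numbers positive reals, per-cell copy number relative to the
#'   chromosome; first element must be 1.
#' @param cds_count non-negative integers, number of CDS to carve per
#'   replicon. `NULL` scales with replicon length (about one CDS per 3 kb).
#' @param cds_length_range CDS length interval in bp; both ends multiples of 3.
#' @param homopolymer_boost non-negative real; expected number of extra G/C
#'   runs (length 4-8) written per 10 kb of intergenic sequence, on top of
#'   the runs that arise naturally from the base composition. The default 0
#'   suffices: at 68.79% GC, 5-6 bp G/C runs already occur at several per kb.
#' @param seed integer seed for this stage.
#' @return A validated parameter list of class `genome_params`,
#'   `error_model_params`, `tech_params` or `detection_params`.
#' @export
genome_params <- function(replicon_lengths = c(2021843L, 370865L, 77135L, 9799L),
                          gc_fraction = 0.6879,
                          copy_numbers = c(1, 1.3, 0.38, 1.3),
                          cds_count = NULL,
                          cds_length_range = c(300L, 1500L),
                          homopolymer_boost = 0,
                          seed = 1L) {
  assert(length(replicon_lengths) >= 1 && all(replicon_lengths >= 1),
         "replicon_lengths must be positive integers")
  assert(is_scalar_number(gc_fraction) && gc_fraction > 0 && gc_fraction < 1,
         "gc_fraction must lie in (0, 1)")
  assert(length(copy_numbers) == length(replicon_lengths),
         "copy_numbers and replicon_lengths must have equal length")
  assert(all(copy_numbers > 0), "copy_numbers must be positive")
  assert(abs(copy_numbers[1] - 1) < 1e-12,
         "the first replicon is the chromosome and must have copy number 1")
  if (is.null(cds_count)) cds_count <- as.integer(replicon_lengths %/% 3000)
  assert(length(cds_count) == length(replicon_lengths) && all(cds_count >= 0),
         "cds_count must be one non-negative integer per replicon")
  assert(length(cds_length_range) == 2 && cds_length_range[1] <= cds_length_range[2] &&
           all(cds_length_range %% 3 == 0) && cds_length_range[1] >= 6,
         "cds_length_range must be an increasing interval of multiples of 3 (>= 6)")
  assert(is_scalar_number(homopolymer_boost) && homopolymer_boost >= 0,
         "homopolymer_boost must be non-negative")
  structure(
    list(replicon_lengths = as.integer(replicon_lengths),
         gc_fraction = gc_fraction,
         copy_numbers = as.numeric(copy_numbers),
         cds_count = as.integer(cds_count),
         cds_length_range = as.integer(cds_length_range),
         homopolymer_boost = homopolymer_boost,
         seed = as.integer(seed)),
    class = "genome_params"
  )
}

#' @rdname genome_params
#' @param target_bases bases whose homopolymer tracts are error-prone
#'   (default G and C).
#' @param target_len_range tract-length interval eligible for planting
#'   (default 5-6).
#' @param affected_fraction fraction of eligible tracts that receive one
#'   planted systematic indel (default 0.0164).
#' @param concordance fraction of long reads covering a planted locus that
#'   carry the planted indel (default 0.9); must exceed 0.5 so the indel is
#'   the locus consensus.
#' @param indel_type `"deletion"` (default) or `"insertion"`.
#' @param cds_fraction minimum fraction of planted loci that must fall inside
#'   annotated CDS (0 = no constraint; sampling is then uniform over all
#'   eligible tracts).
#' @export
error_model_params <- function(target_bases = c("G", "C"),
                               target_len_range = c(5L, 6L),
                               affected_fraction = 0.0164,
                               concordance = 0.9,
                               indel_type = c("deletion", "insertion"),
                               cds_fraction = 0,
                               seed = 1L) {
  indel_type <- match.arg(indel_type)
  assert(all(target_bases %in% DNA_BASES), "target_bases must be in {A,C,G,T}")
  assert(length(target_len_range) == 2 && target_len_range[1] >= 2 &&
           target_len_range[1] <= target_len_range[2],
         "target_len_range must be an increasing interval with minimum >= 2")
  assert(is_scalar_number(affected_fraction) &&
           affected_fraction >= 0 && affected_fraction <= 1,
         "affected_fraction must lie in [0, 1]")
  assert(is_scalar_number(concordance) && concordance > 0.5 && concordance <= 1,
         "concordance must lie in (0.5, 1]")
  assert(is_scalar_number(cds_fraction) && cds_fraction >= 0 && cds_fraction <= 1,
         "cds_fraction must lie in [0, 1]")
  structure(
    list(target_bases = target_bases,
         target_len_range = as.integer(target_len_range),
         affected_fraction = affected_fraction,
         concordance = concordance,
         indel_type = indel_type,
         cds_fraction = cds_fraction,
         seed = as.integer(seed)),
    class = "error_model_params"
  )
}

#' @rdname genome_params
#' @param name `"long"` (single-molecule, indel-prone) or `"short"`
#'   (accurate). Defaults for read length, depth and background error follow
#'   the technology: long reads 11,306 bp at 300x with 2% background error,
#'   short reads 250 bp at 50x with 0.2%.
#' @param mean_read_len positive integer read length (bp).
#' @param depth target chromosome depth; each replicon gets
#'   `depth * copy_number`.
#' @param background_error per-base random error rate, applied as 80%
#'   substitutions, 10% 1-bp insertions, 10% 1-bp deletions.
#' @export
tech_params <- function(name = c("long", "short"),
                        mean_read_len = NULL,
                        depth = NULL,
                        background_error = NULL,
                        seed = 1L) {
  name <- match.arg(name)
  if (is.null(mean_read_len)) mean_read_len <- if (name == "long") 11306L else 250L
  if (is.null(depth)) depth <- if (name == "long") 300 else 50
  if (is.null(background_error)) background_error <- if (name == "long") 0.02 else 0.002
  assert(is_count(mean_read_len) && mean_read_len >= 1, "mean_read_len must be a positive integer")
  assert(is_scalar_number(depth) && depth > 0, "depth must be positive")
  assert(is_scalar_number(background_error) && background_error >= 0 && background_error < 1,
         "background_error must lie in [0, 1)")
  structure(
    list(name = name, mean_read_len = as.integer(mean_read_len), depth = depth,
         background_error = background_error, seed = as.integer(seed)),
    class = "tech_params"
  )
}

#' @rdname genome_params
#' @param long_threshold minimum long-read support fraction for a call to be
#'   labelled systematic (default 0.9, inclusive).
#' @param short_threshold minimum short-read reference-agreement fraction at
#'   the same locus (default 0.9, inclusive).
#' @param min_depth_long,min_depth_short minimum pileup depth for the long
#'   and short technology (defaults 20 and 10).
#' @param long_rule how the long-read threshold is applied. `"binomial"`
#'   (default) treats the threshold as a statement about the locus's true
#'   read concordance and keeps a call unless its support count falls
#'   significantly below the threshold (exact one-sided binomial criterion
#'   at level `boundary_alpha`): a locus whose true concordance sits exactly
#'   at the threshold is then retained with probability `1 - boundary_alpha`
#'   instead of ~0.5, which is what a point comparison against the sample
#'   fraction would give. `"point"` compares the sample fraction directly.
#' @param boundary_alpha one-sided level for the binomial rule (default 0.01).
#' @export
detection_params <- function(long_threshold = 0.9,
                             short_threshold = 0.9,
                             min_depth_long = 20L,
                             min_depth_short = 10L,
                             long_rule = c("binomial", "point"),
                             boundary_alpha = 0.01) {
  long_rule <- match.arg(long_rule)
  assert(is_scalar_number(boundary_alpha) && boundary_alpha > 0 && boundary_alpha < 0.5,
         "boundary_alpha must lie in (0, 0.5)")
  assert(is_scalar_number(long_threshold) && long_threshold > 0.5 && long_threshold <= 1,
         "long_threshold must lie in (0.5, 1]")
  assert(is_scalar_number(short_threshold) && short_threshold > 0.5 && short_threshold <= 1,
         "short_threshold must lie in (0.5, 1]")
  assert(is_count(min_depth_long) && min_depth_long >= 1, "min_depth_long must be >= 1")
  assert(is_count(min_depth_short) && min_depth_short >= 1, "min_depth_short must be >= 1")
  structure(
    list(long_threshold = long_threshold, short_threshold = short_threshold,
         min_depth_long = as.integer(min_depth_long),
         min_depth_short = as.integer(min_depth_short),
         long_rule = long_rule, boundary_alpha = boundary_alpha),
    class = "detection_params"
  )
}
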