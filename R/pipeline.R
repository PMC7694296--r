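#' Pipeline configuration
#'
#' A pipeline run is driven by one configuration: either file paths to an
#' existing genome/annotation/alignment trio, or a simulation block that
#' generates them. Every stage seed is derived deterministically from one
#' master seed, so two runs with the same configuration produce identical
#' reports.
#'
#' @param genome_params a [genome_params()] (simulation mode) or NULL.
#' @param error_params an [error_model_params()].
#' @param long_params,short_params [tech_params()] for the two technologies.
#' @param detection a [detection_params()].
#' @param genome_fasta,cds_gff3,long_tsv,short_tsv input paths (file mode;
#'   all four required when `genome_params` is NULL).
#' @param motif_w flank width for the consensus test (default 20).
#' @param n_perm permutations for the consensus test (default 999).
#' @param min_aa minimum ORF fragment length (default 30).
#' @param seed master seed; stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genome_params = NULL,
                            error_params = error_model_params(),
                            long_params = tech_params("long"),
                            short_params = tech_params("short"),
                            detection = detection_params(),
                            genome_fasta = NULL, cds_gff3 = NULL,
                            long_tsv = NULL, short_tsv = NULL,
                            motif_w = 20L, n_perm = 999L, min_aa = 30L,
                            seed = 1L) {
  have_files <- !is.null(genome_fasta) && !is.null(long_tsv) && !is.null(short_tsv)
  assert(!is.null(genome_params) || have_files,
         "config needs either a simulation block or input file paths")
  structure(
    list(genome_params = genome_params, error_params = error_params,
         long_params = long_params, short_params = short_params,
         detection = detection, genome_fasta = genome_fasta,
         cds_gff3 = cds_gff3, long_tsv = long_tsv, short_tsv = short_tsv,
         motif_w = as.integer(motif_w), n_perm = as.integer(n_perm),
         min_aa = as.integer(min_aa), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors [pipeline_config()]: top-level keys `seed`, `motif_w`,
#' `n_perm`, `min_aa`, optional path keys, and optional blocks `genome`,
#' `errors`, `long`, `short`, `detection` whose entries are passed to the
#' corresponding parameter constructors.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, block) if (is.null(block)) NULL else do.call(ctor, block)
  pipeline_config(
    genome_params = build(genome_params, y$genome),
    error_params = build(error_model_params, y$errors) %||% error_model_params(),
    long_params = build(tech_params, c(list(name = "long"), y$long)),
    short_params = build(tech_params, c(list(name = "short"), y$short)),
    detection = build(detection_params, y$detection) %||% detection_params(),
    genome_fasta = y$genome_fasta, cds_gff3 = y$cds_gff3,
    long_tsv = y$long_tsv, short_tsv = y$short_tsv,
    motif_w = y$motif_w %||% 20L, n_perm = y$n_perm %||% 999L,
    min_aa = y$min_aa %||% 30L, seed = y$seed %||% 1L
  )
}

#' Run the full error-characterization pipeline
#'
#' Simulate (or load) -> pileup & detect -> homopolymer context -> ORF
#' impact -> flanking-motif permutation test -> replicon copy-number
#' ratios. Per-stage tables are written under `outdir` when given; the
#' returned report (also written as `report.json`) contains every summary
#' plus the seeds, and carries no timestamps so that identical
#' configurations yield byte-identical payloads.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory for per-stage files (NULL = no files).
#' @param quiet suppress stage messages.
#' @return A `pipeline_report` list.
#' @export
run_pipeline <- function(config, outdir = NULL, quiet = FALSE) {
  assert(inherits(config, "pipeline_config"), "config must come from pipeline_config()")
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      abort("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    say("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - s)
    out
  }
  # re-seed every stage from the master seed
  config$error_params$seed <- derive_seed(config$seed, "errors")
  config$long_params$seed <- derive_seed(config$seed, "long")
  config$short_params$seed <- derive_seed(config$seed, "short")

  truth <- NULL
  if (!is.null(config$genome_params)) {
    config$genome_params$seed <- derive_seed(config$seed, "genome_stage")
    sim <- stage("simulate", {
      simg <- simulate_genome(config$genome_params)
      tr <- plant_systematic_errors(simg$genome, simg$cds, config$error_params)
      list(g = simg$genome, cds = simg$cds, truth = tr,
           long = simulate_reads(simg$genome, tr, config$long_params),
           short = simulate_reads(simg$genome, tr, config$short_params))
    })
    truth <- sim$truth
  } else {
    sim <- stage("load", {
      g <- read_fasta(config$genome_fasta)
      cds <- if (is.null(config$cds_gff3)) empty_cds() else
        read_gff3(config$cds_gff3, g)
      list(g = g, cds = cds,
           long = read_alignments(config$long_tsv, g),
           short = read_alignments(config$short_tsv, g))
    })
  }
  g <- sim$g

  piles <- stage("pileup", {
    list(long = lapply(g, function(r)
           build_pileup(sim$long[sim$long$replicon_id == r$id, ], r)),
         short = lapply(g, function(r)
           build_pileup(sim$short[sim$short$replicon_id == r$id, ], r)))
  })
  disc <- stage("detect", {
    long_calls <- dplyr::bind_rows(lapply(piles$long, call_indels,
                                          params = config$detection, which = "long"))
    compare_technologies(long_calls, piles$short, config$detection)
  })
  tracts <- stage("context", find_homopolymers_genome(g, min_len = 2L))
  disc <- assign_context(disc, tracts)
  disc$cds_id <- assign_cds_id(disc, sim$cds)
  err_sum <- summarize_discrepancies(disc, g)
  ctx_sum <- summarize_context(disc, tracts, config$error_params)

  orf <- stage("orf", count_affected_cds(sim$cds, disc, g, min_aa = config$min_aa))

  motif <- stage("motif", {
    aff <- disc[!is.na(disc$tract_start), , drop = FALSE]
    aff_key <- unique(paste(aff$replicon_id, aff$tract_start))
    elig <- eligible_tracts(tracts, config$error_params)
    unaff <- elig[!paste(elig$replicon_id, elig$start) %in% aff_key, , drop = FALSE]
    aff_loci <- unique(aff[c("replicon_id", "tract_start", "tract_len", "tract_base")])
    names(aff_loci) <- c("replicon_id", "start", "length", "base")
    if (nrow(aff_loci) == 0L) {
      list(skipped = "no systematic discrepancies in homopolymer context")
    } else if (nrow(unaff) < nrow(aff_loci)) {
      list(skipped = "fewer unaffected eligible tracts than observed loci")
    } else {
      obs <- extract_flanks(g, aff_loci, config$motif_w)
      res <- permutation_consensus_test(obs, unaff, g, n_perm = config$n_perm,
                                        seed = derive_seed(config$seed, "motif"))
      unclass(res)[c("max_ic", "mean_ic", "p_value", "n_perm", "n_windows")]
    }
  })

  cov <- stage("coverage", coverage_summary(piles$long, g))

  report <- list(
    tool = list(package = "sysindel",
                version = as.character(utils::packageVersion("sysindel"))),
    seed = config$seed,
    genome = list(replicons = names(g),
                  lengths = unname(replicon_lengths(g)),
                  gc_percent = 100 * gc_fraction(g)),
    error_summary = unclass(err_sum),
    context_summary = unclass(ctx_sum)[c(
      "n_tracts", "n_affected", "n_eligible", "n_eligible_affected",
      "eligible_affected_fraction", "all_affected_fraction",
      "offtarget_count", "n_deletions", "n_insertions")],
    orf_impact = list(n_affected_cds = orf$n_affected,
                      n_records = nrow(orf$records),
                      total_fragments = sum(orf$records$n_fragments)),
    motif = motif,
    coverage = as.data.frame(tibble::as_tibble(cov)),
    truth = if (!is.null(truth)) list(
      n_eligible = nrow(truth$loci),
      n_planted = sum(truth$loci$planted),
      planted_fraction = mean(truth$loci$planted)) else NULL
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(g, file.path(outdir, "genome.fasta"))
    write_gff3(sim$cds, file.path(outdir, "cds.gff3"))
    if (!is.null(truth)) write_truth(truth$loci, file.path(outdir, "truth.tsv"))
    write_discrepancies(disc, file.path(outdir, "discrepancies.tsv"))
    write_tracts_bed(tracts, file.path(outdir, "tracts.bed"))
    readr::write_tsv(orf$records, file.path(outdir, "orf_impact.tsv"),
                     progress = FALSE)
    write_coverage_tsv(cov, file.path(outdir, "coverage.tsv"))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  say("pipeline finished in %.1fs", proc.time()[["elapsed"]] - t0)
  structure(c(report, list(discrepancies = disc, orf_records = orf$records)),
            class = "pipeline_report")
}

# cds_id of the CDS overlapping each discrepancy (NA when intergenic)
assign_cds_id <- function(disc, cds) {
  out <- rep(NA_character_, nrow(disc))
  if (nrow(cds) == 0L) return(out)
  for (rid in unique(disc$replicon_id)) {
    cc <- cds[cds$replicon_id == rid, ]
    if (nrow(cc) == 0L) next
    cc <- cc[order(cc$start), ]
    rows <- which(disc$replicon_id == rid)
    j <- findInterval(disc$pos[rows], cc$start)
    hit <- j >= 1L & disc$pos[rows] < cc$end[pmax(j, 1L)]
    out[rows[hit]] <- cc$cds_id[j[hit]]
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  genome: %d replicon(s), GC %.2f%%\n",
              length(x$genome$replicons), x$genome$gc_percent))
  cat(sprintf("  discrepancies: %d (%d del / %d ins), %.3g deletions/kb\n",
              x$error_summary$n_total, x$error_summary$n_deletions,
              x$error_summary$n_insertions, x$error_summary$deletions_per_kb))
  cat(sprintf("  eligible tracts affected: %d / %d (%.3g%%)\n",
              x$context_summary$n_eligible_affected, x$context_summary$n_eligible,
              100 * x$context_summary$eligible_affected_fraction))
  cat(sprintf("  disrupted CDS: %d\n", x$orf_impact$n_affected_cds))
  if (!is.null(x$motif$skipped)) {
    cat(sprintf("  motif test: skipped (%s)\n", x$motif$skipped))
  } else {
    cat(sprintf("  motif test: max IC %.3f bits, p = %.4g\n",
                x$motif$max_ic, x$motif$p_value))
  }
  invisible(x)
}
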