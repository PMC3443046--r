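# End-to-end orchestration: simulate -> align -> profile -> recalibrate ->
# call -> validate / discover, as a single seeded, reproducible run.

#' Pipeline configuration
#'
#' Bundles the stage configurations under one seed. All fields serialise to
#' a single YAML file via [write_pipeline_config()].
#'
#' @param sim A [sim_config()]; its seed is overridden by `seed`.
#' @param scheme A [scoring_scheme()].
#' @param genotyper A [genotyper_config()].
#' @param n_amplicons,amplicon_len Panel layout.
#' @param min_obs Recalibration minimum observations per covariate bin.
#' @param seed Master seed for the whole run.
#' @param out_dir Optional output directory; when set, every stage product is
#'   written in its standard format.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), scheme = scoring_scheme(),
                            genotyper = genotyper_config(),
                            n_amplicons = 4L, amplicon_len = 2000L,
                            min_obs = 100L, seed = 1L, out_dir = NULL) {
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, scheme = scheme, genotyper = genotyper,
                 n_amplicons = as.integer(n_amplicons),
                 amplicon_len = as.integer(amplicon_len),
                 min_obs = as.integer(min_obs), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  plain <- rapply(unclass(config), identity, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    sim = do.call(sim_config, y$sim[setdiff(names(y$sim), "seed")]),
    scheme = do.call(scoring_scheme, y$scheme),
    genotyper = do.call(genotyper_config, y$genotyper),
    n_amplicons = y$n_amplicons, amplicon_len = y$amplicon_len,
    min_obs = y$min_obs, seed = y$seed, out_dir = y$out_dir
  )
}

run_shared_stages <- function(config) {
  stage <- "simulate"
  result <- tryCatch({
    sim <- make_panel(config$sim, config$n_amplicons, config$amplicon_len)
    reads <- simulate_reads(sim, config$sim)
    stage <- "align"
    if (nrow(reads$reads) == 0L) abort("no reads to align")
    aln <- align_reads(reads$reads, sim$panel, config$scheme)
    stage <- "profile"
    events <- alignment_events(aln, sim$panel)
    profile <- profile_errors(aln, sim$panel, events = events)
    stage <- "recalibrate"
    recal_table <- build_recal_table(aln, sim$panel,
                                     known_sites = sim$variants,
                                     events = events)
    recal_reads <- recalibrate_reads(reads$reads, recal_table,
                                     min_obs = config$min_obs)
    # recalibration changes qualities only, so the alignments carry over;
    # re-attach the new qualities in aligned orientation
    recal_qual <- setNames(recal_reads$qual, recal_reads$name)
    recal_aln <- aln |>
      mutate(qual = purrr::map2(.data$qname, .data$strand, function(q, s) {
        v <- recal_qual[[q]]
        if (s == "-") rev(v) else v
      }))
    recal_events <- alignment_events(recal_aln, sim$panel)
    list(sim = sim, reads = reads, aln = aln, events = events,
         profile = profile, recal_table = recal_table,
         recal_reads = recal_reads, recal_aln = recal_aln,
         recal_events = recal_events)
  }, error = function(e) {
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })
  result
}

write_bundle_files <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(x) file.path(config$out_dir, x)
  write_fasta(bundle$sim$panel, p("panel.fasta"))
  write_vcf(bundle$sim$variants, p("truth.vcf"), refs = bundle$sim$panel)
  write_fastq(bundle$reads$reads, p("reads.fastq"))
  write_sam(bundle$reads$truth, bundle$sim$panel, p("truth.sam"))
  write_sam(bundle$aln, bundle$sim$panel, p("aligned.sam"))
  write_fastq(bundle$recal_reads, p("reads.recal.fastq"))
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("longampr")),
    stage_hashes = list(
      panel = rlang::hash(bundle$sim$panel),
      truth = rlang::hash(bundle$sim$variants),
      reads = rlang::hash(bundle$reads$reads),
      alignments = rlang::hash(bundle$aln)
    )
  )
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(config$out_dir)
}

#' Run the validation experiment end to end
#'
#' Simulates the validation design (truth-status sites on a diploid amplicon
#' panel), aligns, profiles, recalibrates, force-calls every truth site and
#' classifies the outcomes, then quantifies reference bias at the
#' heterozygous truth sites.
#'
#' @param config A [pipeline_config()].
#' @return A report bundle: list with the stage products (`sim`, `reads`,
#'   `aln`, `profile`, `recal_table`, `validation`, `refbias`, plus the
#'   truth-alignment counterparts used for the bias comparison).
#' @export
run_validation_experiment <- function(config = pipeline_config()) {
  bundle <- run_shared_stages(config)
  stage <- "validate"
  result <- tryCatch({
    validation <- genotype_and_validate(bundle$recal_aln, bundle$sim$panel,
                                        bundle$sim$variants,
                                        config$genotyper,
                                        events = bundle$recal_events)
    het <- bundle$sim$variants |> filter(.data$status == "TRUE_DE_NOVO")
    stage <- "refbias"
    bias_aligned <- allele_balance(bundle$recal_aln, bundle$sim$panel, het,
                                   config$genotyper$min_base_quality,
                                   events = bundle$recal_events)
    truth_events <- alignment_events(bundle$reads$truth, bundle$sim$panel)
    bias_truth <- allele_balance(bundle$reads$truth, bundle$sim$panel, het,
                                 config$genotyper$min_base_quality,
                                 events = truth_events)
    hidden <- hidden_allele_summary(bundle$recal_aln, bundle$sim$panel, het,
                                    events = bundle$recal_events)
    c(bundle, list(validation = validation, bias_aligned = bias_aligned,
                   bias_truth = bias_truth, hidden = hidden,
                   truth_events = truth_events))
  }, error = function(e) {
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })
  if (!is.null(config$out_dir)) write_bundle_files(result, config)
  result
}

#' Run the discovery experiment end to end
#'
#' Discovery-mode calling over the panel (no forced alleles), followed by a
#' concordance comparison against the planted truth set. Missed sites are
#' partitioned into `low_coverage` (retained depth below `low_cov_depth`),
#' `reference_bias` (at least `min_hidden` reads carry the alternate allele
#' hidden inside nearby insertions) and `other`.
#'
#' @param config A [pipeline_config()].
#' @param low_cov_depth Depth threshold for the low-coverage miss class.
#' @param min_hidden Minimum hidden-allele reads for the reference-bias
#'   miss class.
#' @return A report bundle with `calls`, `concordance` (per planted site)
#'   and `miss_reasons`.
#' @export
run_discovery_experiment <- function(config = pipeline_config(),
                                     low_cov_depth = 10L, min_hidden = 2L) {
  bundle <- run_shared_stages(config)
  stage <- "discover"
  result <- tryCatch({
    calls <- call_region(bundle$recal_aln, bundle$sim$panel, config$genotyper,
                         events = bundle$recal_events, all_calls = TRUE)
    planted <- bundle$sim$variants |> filter(.data$status == "TRUE_DE_NOVO")
    hidden <- hidden_allele_summary(bundle$recal_aln, bundle$sim$panel,
                                    planted, events = bundle$recal_events)
    concordance <- planted |>
      left_join(calls |> select("contig", "pos", "alt", "qual", "depth_used",
                                "genotype", "polymorphic"),
                by = c("contig", "pos", "alt")) |>
      left_join(hidden |> select("contig", "pos", "alt", "n_hidden"),
                by = c("contig", "pos", "alt")) |>
      mutate(
        called = dplyr::coalesce(.data$polymorphic, FALSE),
        miss_reason = dplyr::case_when(
          .data$called ~ NA_character_,
          dplyr::coalesce(.data$depth_used, 0L) < low_cov_depth ~ "low_coverage",
          dplyr::coalesce(.data$n_hidden, 0L) >= min_hidden ~ "reference_bias",
          TRUE ~ "other"
        )
      )
    false_calls <- calls |>
      filter(.data$polymorphic) |>
      dplyr::anti_join(planted, by = c("contig", "pos", "alt"))
    c(bundle, list(calls = calls, concordance = concordance,
                   false_calls = false_calls,
                   sensitivity = mean(concordance$called),
                   miss_reasons = concordance |>
                     filter(!.data$called) |>
                     count(.data$miss_reason)))
  }, error = function(e) {
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })
  if (!is.null(config$out_dir)) write_bundle_files(result, config)
  result
}
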