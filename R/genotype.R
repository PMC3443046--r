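# Bayesian diploid SNP genotyping on pileups of high-indel long reads.
#
# Two adaptations for indel-dominated data: a low minimum base quality
# (default Q10, since empirical qualities sit around Q20-24) and a site-level
# deletion-fraction tolerance (sites where more than half the spanning reads
# carry a deletion are not called).

#' Genotyper configuration
#'
#' @param min_base_quality Minimum PHRED quality for a base to enter the
#'   likelihood (default 10).
#' @param max_deletion_fraction Sites where the fraction of spanning reads
#'   deleting the position exceeds this are filtered (default 0.5, "up to
#'   50% deletions").
#' @param heterozygosity Prior probability theta of heterozygosity; genotype
#'   priors are `(1 - 3 theta / 2, theta, theta / 2)` for
#'   (hom-ref, het, hom-alt).
#' @param call_confidence Minimum PHRED-scaled confidence (QUAL) for
#'   emitting a polymorphic call.
#' @param min_depth Minimum retained depth below which a site is a
#'   LOW_DEPTH no-call.
#' @return A `genotyper_config` list.
#' @export
genotyper_config <- function(min_base_quality = 10L,
                             max_deletion_fraction = 0.5,
                             heterozygosity = 1e-3, call_confidence = 30,
                             min_depth = 1L) {
  assert_that(min_base_quality >= 0 && call_confidence >= 0,
              "thresholds must be non-negative")
  assert_that(max_deletion_fraction > 0 && max_deletion_fraction <= 1,
              "max_deletion_fraction must lie in (0, 1]")
  assert_that(heterozygosity > 0 && heterozygosity <= 0.01,
              "heterozygosity must lie in (0, 0.01]")
  structure(list(min_base_quality = as.integer(min_base_quality),
                 max_deletion_fraction = max_deletion_fraction,
                 heterozygosity = heterozygosity,
                 call_confidence = call_confidence,
                 min_depth = as.integer(min_depth)),
            class = "genotyper_config")
}

#' Build a pileup column at one reference position
#'
#' Reads whose alignment places an M op over the position contribute
#' (base, quality, strand) entries; reads whose alignment deletes the
#' position are counted in `n_deletion_reads` and excluded from entries.
#' Inserted bases never contribute entries (they are examined separately by
#' [hidden_allele_scan()]).
#'
#' @param events Event table from [alignment_events()].
#' @param contig Reference name.
#' @param pos 1-based position.
#' @return A `pileup_column` list: `contig`, `pos`, `entries` (tibble
#'   `qname`, `base`, `qual`, `strand`), `n_deletion_reads`.
#' @export
build_pileup <- function(events, contig, pos) {
  at <- events[events$rname == contig & events$ref_pos == pos &
                 events$event != "INSERTION", ]
  dels <- at$event == "DELETION"
  structure(list(
    contig = contig, pos = pos,
    entries = tibble(qname = at$qname[!dels], base = at$read_base[!dels],
                     qual = at$qual[!dels], strand = at$strand[!dels]),
    n_deletion_reads = sum(dels)
  ), class = "pileup_column")
}

#' Diploid genotype log-likelihoods for one column
#'
#' Bases with quality below `min_base_quality`, and bases other than ref or
#' alt, are dropped. For each retained base with error probability
#' `e = 10^(-Q/10)`: `P(b | a) = 1 - e` if `b == a`, else `e / 3`; a diploid
#' genotype averages its two alleles, `P(b | a1 a2) = (P(b|a1) + P(b|a2))/2`.
#' Log-likelihoods are sums over retained bases.
#'
#' @param bases,quals Base calls and PHRED qualities of the column.
#' @param ref,alt Reference and alternate alleles.
#' @param config A [genotyper_config()].
#' @return List with `ll` (natural-log likelihood triple named `hom_ref`,
#'   `het`, `hom_alt`) and `depth_used`.
#' @export
genotype_likelihoods <- function(bases, quals, ref, alt,
                                 config = genotyper_config()) {
  keep <- quals >= config$min_base_quality & bases %in% c(ref, alt)
  bases <- bases[keep]; quals <- quals[keep]
  if (length(bases) == 0L) {
    return(list(ll = c(hom_ref = NA_real_, het = NA_real_, hom_alt = NA_real_),
                depth_used = 0L))
  }
  e <- phred_to_error(quals)
  p_ref <- ifelse(bases == ref, 1 - e, e / 3)
  p_alt <- ifelse(bases == alt, 1 - e, e / 3)
  ll <- c(hom_ref = sum(log(p_ref)),
          het = sum(log((p_ref + p_alt) / 2)),
          hom_alt = sum(log(p_alt)))
  list(ll = ll, depth_used = length(bases))
}

genotype_priors <- function(theta) {
  c(hom_ref = 1 - 3 * theta / 2, het = theta, hom_alt = theta / 2)
}

#' Call a diploid genotype at one site
#'
#' Applies the deletion-fraction site filter, combines the likelihood triple
#' with the diploid genotype prior, and reports the maximum-posterior
#' genotype with PHRED-scaled 0-normalised likelihoods (PL) and
#' `QUAL = -10 log10 P(hom_ref | data)`. A site is polymorphic when
#' `QUAL >= call_confidence`.
#'
#' @param column A `pileup_column`.
#' @param alt Alternate allele to test.
#' @param ref Reference base at the site.
#' @param config A [genotyper_config()].
#' @return One-row tibble: `contig`, `pos`, `ref`, `alt`, `genotype`,
#'   `pl_hom_ref`, `pl_het`, `pl_hom_alt`, `qual`, `depth_used`,
#'   `n_deletion_reads`, `filter`, `polymorphic`.
#' @export
call_site <- function(column, alt, ref, config = genotyper_config()) {
  n_span <- nrow(column$entries) + column$n_deletion_reads
  base <- tibble(contig = column$contig, pos = column$pos, ref = ref,
                 alt = alt, genotype = NA_character_, pl_hom_ref = NA_real_,
                 pl_het = NA_real_, pl_hom_alt = NA_real_, qual = NA_real_,
                 depth_used = 0L, n_deletion_reads = column$n_deletion_reads,
                 filter = "PASS", polymorphic = FALSE)
  if (n_span > 0 &&
      column$n_deletion_reads / n_span > config$max_deletion_fraction) {
    base$filter <- "DELETION_FRACTION"
    return(base)
  }
  gl <- genotype_likelihoods(column$entries$base, column$entries$qual, ref,
                             alt, config)
  if (gl$depth_used < config$min_depth) {
    base$filter <- "LOW_DEPTH"
    return(base)
  }
  ll <- gl$ll
  log_post <- ll + log(genotype_priors(config$heterozygosity))
  log_post <- log_post - max(log_post)
  post <- exp(log_post) / sum(exp(log_post))
  pl <- -10 / log(10) * (ll - max(ll))
  site_qual <- -10 * log10(max(post[["hom_ref"]], 1e-300))
  gt <- names(post)[which.max(post)]
  base |>
    mutate(genotype = .env$gt,
           pl_hom_ref = pl[["hom_ref"]], pl_het = pl[["het"]],
           pl_hom_alt = pl[["hom_alt"]], qual = .env$site_qual,
           depth_used = gl$depth_used,
           polymorphic = .env$gt != "hom_ref" &
             .env$site_qual >= config$call_confidence)
}

# Vectorised genotyping engine over a set of (contig, pos, ref, alt) sites.
# Produces the same rows as call_site(), one per requested site, without
# rebuilding a pileup per site.
genotype_positions <- function(events, sites, config = genotyper_config()) {
  empty <- tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), genotype = character(),
                  pl_hom_ref = double(), pl_het = double(),
                  pl_hom_alt = double(), qual = double(),
                  depth_used = integer(), n_deletion_reads = integer(),
                  filter = character(), polymorphic = logical())
  if (nrow(sites) == 0L) return(empty)
  site_tbl <- sites |>
    select(rname = "contig", ref_pos = "pos", site_ref = "ref",
           site_alt = "alt")
  ev <- events |>
    filter(.data$event != "INSERTION") |>
    dplyr::inner_join(site_tbl, by = c("rname", "ref_pos"))
  stats <- ev |>
    mutate(
      retained = .data$event != "DELETION" &
        !is.na(.data$qual) & .data$qual >= config$min_base_quality &
        (.data$read_base == .data$site_ref | .data$read_base == .data$site_alt),
      e = phred_to_error(.data$qual),
      p_ref = if_else(.data$read_base == .data$site_ref, 1 - .data$e, .data$e / 3),
      p_alt = if_else(.data$read_base == .data$site_alt, 1 - .data$e, .data$e / 3)
    ) |>
    group_by(contig = .data$rname, pos = .data$ref_pos,
             ref = .data$site_ref, alt = .data$site_alt) |>
    summarise(
      n_entries = sum(.data$event != "DELETION"),
      n_deletion_reads = sum(.data$event == "DELETION"),
      depth_used = sum(.data$retained),
      ll_hom_ref = sum(log(.data$p_ref[.data$retained])),
      ll_het = sum(log((.data$p_ref[.data$retained] +
                          .data$p_alt[.data$retained]) / 2)),
      ll_hom_alt = sum(log(.data$p_alt[.data$retained])),
      .groups = "drop"
    )
  # carry sites with no spanning reads at all
  stats <- site_tbl |>
    rename(contig = "rname", pos = "ref_pos", ref = "site_ref",
           alt = "site_alt") |>
    left_join(stats, by = c("contig", "pos", "ref", "alt")) |>
    mutate(across(c("n_entries", "n_deletion_reads", "depth_used"),
                  ~ dplyr::coalesce(.x, 0L)),
           across(c("ll_hom_ref", "ll_het", "ll_hom_alt"),
                  ~ dplyr::coalesce(.x, 0)))

  prior <- log(genotype_priors(config$heterozygosity))
  lp <- cbind(stats$ll_hom_ref + prior[1], stats$ll_het + prior[2],
              stats$ll_hom_alt + prior[3])
  lp_max <- apply(lp, 1, max)
  post <- exp(lp - lp_max)
  post <- post / rowSums(post)
  ll <- cbind(stats$ll_hom_ref, stats$ll_het, stats$ll_hom_alt)
  pl <- -10 / log(10) * (ll - apply(ll, 1, max))
  gt_names <- c("hom_ref", "het", "hom_alt")

  n_span <- stats$n_entries + stats$n_deletion_reads
  del_filtered <- n_span > 0 &
    stats$n_deletion_reads / pmax(n_span, 1L) > config$max_deletion_fraction
  low_depth <- !del_filtered & stats$depth_used < config$min_depth
  callable <- !del_filtered & !low_depth

  out <- stats |>
    mutate(
      genotype = if_else(callable, gt_names[max.col(post, ties.method = "first")],
                         NA_character_),
      pl_hom_ref = if_else(callable, pl[, 1], NA_real_),
      pl_het = if_else(callable, pl[, 2], NA_real_),
      pl_hom_alt = if_else(callable, pl[, 3], NA_real_),
      qual = if_else(callable, -10 * log10(pmax(post[, 1], 1e-300)), NA_real_),
      depth_used = if_else(callable, .data$depth_used, 0L),
      filter = dplyr::case_when(del_filtered ~ "DELETION_FRACTION",
                                low_depth ~ "LOW_DEPTH",
                                TRUE ~ "PASS"),
      polymorphic = callable & .data$genotype != "hom_ref" &
        .data$qual >= config$call_confidence
    ) |>
    select(dplyr::all_of(names(empty)))
  out
}

#' Discovery-mode genotyping over whole references
#'
#' Considers every reference position carrying at least one quality-filtered
#' non-reference base, tests the most frequent non-reference base as the
#' alternate allele, and returns the polymorphic calls.
#'
#' @param aln Alignment tibble.
#' @param refs Reference tibble.
#' @param config A [genotyper_config()].
#' @param events Precomputed event table.
#' @param all_calls Return every evaluated site, not only polymorphic ones.
#' @return Tibble of calls (see [call_site()]), polymorphic rows only by
#'   default.
#' @export
call_region <- function(aln, refs, config = genotyper_config(),
                        events = if (nrow(aln)) alignment_events(aln, refs),
                        all_calls = FALSE) {
  if (nrow(aln) == 0L) {
    return(genotype_positions(tibble(), tibble(contig = character(),
                                               pos = integer(),
                                               ref = character(),
                                               alt = character()), config))
  }
  cand <- events |>
    filter(.data$event == "MISMATCH",
           !is.na(.data$qual), .data$qual >= config$min_base_quality) |>
    count(.data$rname, .data$ref_pos, .data$ref_base, .data$read_base) |>
    group_by(.data$rname, .data$ref_pos) |>
    slice(which.max(.data$n)) |>
    ungroup() |>
    select(contig = "rname", pos = "ref_pos", ref = "ref_base",
           alt = "read_base")
  calls <- genotype_positions(events, cand, config)
  if (all_calls) calls else calls |> filter(.data$polymorphic)
}
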