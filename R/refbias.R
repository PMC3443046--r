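# Alignment-induced reference bias: alternate-allele balance at heterozygous
# sites, and recovery of alternate alleles hidden inside insertions.
#
# Because the gap-open penalty sits below the mismatch penalty, a gapped path
# can tie or beat the mismatch path at a true SNP, letting the aligner place
# the alternate base inside an insertion while the pileup shows the
# reference base. The base is not lost — it sits in an insertion anchored
# near the site — so it can be recovered by scanning insertions around the
# site.

#' Allele balance at heterozygous sites
#'
#' Pileup-based reference/alternate counts per site after minimum-quality
#' filtering, with the across-site median alternate fraction. At an unbiased
#' heterozygous site the expected alternate fraction is 0.5; reference bias
#' pulls the median below it.
#'
#' @param aln Alignment tibble.
#' @param refs Reference tibble.
#' @param het_sites Variant tibble of heterozygous sites (`contig`, `pos`,
#'   `ref`, `alt`).
#' @param min_base_quality Minimum PHRED quality for counted bases.
#' @param events Precomputed event table.
#' @return An `allele_balance` list: `sites` (tibble with `n_ref`, `n_alt`,
#'   `n_other`, `alt_fraction` per site), `median_alt_fraction`,
#'   `frac_below_half`.
#' @export
allele_balance <- function(aln, refs, het_sites, min_base_quality = 10L,
                           events = alignment_events(aln, refs)) {
  assert_that(nrow(het_sites) > 0L, "no heterozygous sites supplied")
  site_tbl <- het_sites |>
    select(rname = "contig", ref_pos = "pos", site_ref = "ref",
           site_alt = "alt")
  counts <- events |>
    filter(.data$event %in% c("MATCH", "MISMATCH"),
           !is.na(.data$qual), .data$qual >= min_base_quality) |>
    dplyr::inner_join(site_tbl, by = c("rname", "ref_pos")) |>
    group_by(contig = .data$rname, pos = .data$ref_pos,
             ref = .data$site_ref, alt = .data$site_alt) |>
    summarise(n_ref = sum(.data$read_base == .data$site_ref),
              n_alt = sum(.data$read_base == .data$site_alt),
              n_other = sum(.data$read_base != .data$site_ref &
                              .data$read_base != .data$site_alt),
              .groups = "drop")
  sites <- het_sites |>
    select("contig", "pos", "ref", "alt") |>
    left_join(counts, by = c("contig", "pos", "ref", "alt")) |>
    mutate(across(c("n_ref", "n_alt", "n_other"), ~ dplyr::coalesce(.x, 0L)),
           alt_fraction = .data$n_alt / pmax(.data$n_ref + .data$n_alt, 1L))
  structure(list(
    sites = sites,
    median_alt_fraction = median(sites$alt_fraction),
    frac_below_half = mean(sites$alt_fraction < 0.5)
  ), class = "allele_balance")
}

#' @export
tidy.allele_balance <- function(x, ...) x$sites

#' @export
glance.allele_balance <- function(x, ...) {
  tibble(n_sites = nrow(x$sites),
         median_alt_fraction = x$median_alt_fraction,
         frac_below_half = x$frac_below_half)
}

#' @export
autoplot.allele_balance <- function(object, ...) {
  ggplot2::ggplot(object$sites, ggplot2::aes(x = .data$alt_fraction)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$median_alt_fraction,
                        colour = "firebrick") +
    ggplot2::labs(x = "alternate-allele fraction", y = "heterozygous sites") +
    ggplot2::theme_minimal()
}

#' Scan for alternate alleles hidden inside insertions
#'
#' For every read spanning the site: VISIBLE if the pileup base at the site
#' equals the alternate allele; HIDDEN if the read's alignment deletes the
#' site while an insertion whose reference anchor lies within `k` bases
#' contains the alternate base (the gapped rendering that hides a true SNP
#' always removes the site base in favour of an insertion nearby); otherwise
#' ABSENT. Reads not spanning the site are excluded.
#'
#' @param aln Alignment tibble.
#' @param refs Reference tibble.
#' @param contig,pos Site coordinates.
#' @param alt Alternate allele.
#' @param k Anchor window in bases.
#' @param events Precomputed event table.
#' @return Tibble with one row per spanning read: `qname`, `label`
#'   (`VISIBLE`/`HIDDEN`/`ABSENT`).
#' @export
hidden_allele_scan <- function(aln, refs, contig, pos, alt, k = 5L,
                               events = alignment_events(aln, refs)) {
  site_rows <- events |>
    filter(.data$rname == contig, .data$ref_pos == pos,
           .data$event != "INSERTION")
  if (nrow(site_rows) == 0L) {
    return(tibble(qname = character(), label = character()))
  }
  ins_near <- events |>
    filter(.data$rname == contig, .data$event == "INSERTION",
           abs(.data$ref_pos - pos) <= k, .data$read_base == alt) |>
    pull(.data$qname)
  site_rows |>
    mutate(label = dplyr::case_when(
      .data$event != "DELETION" & .data$read_base == alt ~ "VISIBLE",
      .data$event == "DELETION" & .data$qname %in% ins_near ~ "HIDDEN",
      TRUE ~ "ABSENT"
    )) |>
    select("qname", "label")
}

#' Summarise hidden-allele recovery across heterozygous sites
#'
#' Runs [hidden_allele_scan()] at each site and reports visible, hidden and
#' recombined (visible + hidden) alternate fractions.
#'
#' @inheritParams allele_balance
#' @param k Anchor window in bases.
#' @return Tibble with one row per site: `n_visible`, `n_hidden`,
#'   `n_spanning`, `alt_fraction_visible`, `alt_fraction_recovered`.
#' @export
hidden_allele_summary <- function(aln, refs, het_sites, k = 5L,
                                  events = alignment_events(aln, refs)) {
  purrr::pmap_dfr(
    het_sites[, c("contig", "pos", "alt")],
    function(contig, pos, alt) {
      labels <- hidden_allele_scan(aln, refs, contig, pos, alt, k,
                                   events = events)
      tibble(
        contig = contig, pos = pos, alt = alt,
        n_visible = sum(labels$label == "VISIBLE"),
        n_hidden = sum(labels$label == "HIDDEN"),
        n_spanning = nrow(labels)
      )
    }
  ) |>
    mutate(
      alt_fraction_visible = .data$n_visible / pmax(.data$n_spanning, 1L),
      alt_fraction_recovered = (.data$n_visible + .data$n_hidden) /
        pmax(.data$n_spanning, 1L)
    )
}
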