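# Covariate-based empirical base-quality recalibration.
#
# Counts are accumulated at four hierarchy levels — read group; read group x
# reported quality; read group x reported quality x cycle; read group x
# reported quality x dinucleotide — and empirical qualities are composed as
# the read-group baseline plus per-covariate deltas.

#' Empirical PHRED quality from observation/mismatch counts
#'
#' `Q = -10 * log10((m + 1) / (n + 2))`, capped at 60. The additive
#' smoothing keeps the estimate finite for error-free bins and returns the
#' uninformative ~3.01 for empty ones.
#'
#' @param n Observations (vectorised).
#' @param m Mismatches (vectorised, `0 <= m <= n`).
#' @return Numeric PHRED qualities.
#' @export
empirical_quality <- function(n, m) {
  assert_that(all(n >= 0) && all(m >= 0) && all(m <= n),
              "need 0 <= m <= n")
  pmin(-10 * log10((m + 1) / (n + 2)), 60)
}

# sequencing-orientation base (and its predecessor) for each event row
seq_orientation_bases <- function(events, aln) {
  orig <- ifelse(aln$strand == "-", revcomp(aln$seq), aln$seq)
  orig_chars <- unlist(seq_chars(orig), use.names = FALSE)
  offsets <- setNames(cumsum(c(0L, nchar(orig)))[seq_len(nrow(aln))], aln$qname)
  off <- offsets[events$qname]
  cur <- orig_chars[off + events$cycle]
  prev <- ifelse(events$cycle > 1L, orig_chars[off + events$cycle - 1L], "N")
  list(cur = cur, prev = prev)
}

#' Build a recalibration table from aligned reads
#'
#' Every aligned (M-op) base not overlapping a known variant site contributes
#' one observation; a base differing from the reference contributes one
#' mismatch. Inserted and deleted bases are excluded — the error signal is
#' mismatch-only. Counts are kept per read group, per reported quality, per
#' cycle and per dinucleotide (previous sequencing-orientation base, current
#' base; sentinel `N` at cycle 1).
#'
#' @param aln Alignment tibble with `qual` (reported PHRED values) and
#'   optionally `read_group`; records without one fall into `"default"`.
#' @param refs Reference tibble.
#' @param known_sites Variant tibble (`contig`, `pos`) of sites to mask.
#' @param events Precomputed event table.
#' @return A `recal_table`: list of tibbles `read_group`, `reported_quality`,
#'   `cycle`, `dinucleotide`, each with columns `n`, `m`, `q_emp`.
#' @export
build_recal_table <- function(aln, refs, known_sites = NULL,
                              events = alignment_events(aln, refs)) {
  rg <- if ("read_group" %in% names(aln)) aln$read_group else rep("default", nrow(aln))
  rg_by_read <- setNames(rg, aln$qname)

  ev <- events |> filter(.data$event %in% c("MATCH", "MISMATCH"))
  if (!is.null(known_sites) && nrow(known_sites)) {
    key <- paste(ev$rname, ev$ref_pos)
    ev <- ev[!(key %in% paste(known_sites$contig, known_sites$pos)), ]
  }
  assert_that(nrow(ev) > 0L, "no usable aligned bases")
  sob <- seq_orientation_bases(ev, aln)
  ev <- ev |>
    mutate(read_group = unname(rg_by_read[.data$qname]),
           reported_quality = .data$qual,
           dinucleotide = paste0(sob$prev, sob$cur),
           is_mismatch = .data$event == "MISMATCH")

  level <- function(...) {
    ev |>
      group_by(across(c(...))) |>
      summarise(n = n(), m = sum(.data$is_mismatch), .groups = "drop") |>
      mutate(q_emp = empirical_quality(.data$n, .data$m))
  }
  structure(list(
    read_group = level("read_group"),
    reported_quality = level("read_group", "reported_quality"),
    cycle = level("read_group", "reported_quality", "cycle"),
    dinucleotide = level("read_group", "reported_quality", "dinucleotide")
  ), class = "recal_table")
}

#' @export
tidy.recal_table <- function(x, ...) {
  bind_rows(
    x$read_group |> mutate(level = "read_group"),
    x$reported_quality |> mutate(level = "reported_quality"),
    x$cycle |> mutate(level = "cycle", cycle = as.integer(.data$cycle)),
    x$dinucleotide |> mutate(level = "dinucleotide")
  ) |>
    select("level", dplyr::everything())
}

#' @export
glance.recal_table <- function(x, ...) {
  tibble(n_read_groups = nrow(x$read_group),
         n_observations = sum(x$read_group$n),
         n_mismatches = sum(x$read_group$m),
         mean_empirical_quality = weighted.mean(x$read_group$q_emp,
                                                x$read_group$n))
}

#' Recalibrate read qualities from a covariate table
#'
#' Per base, the recalibrated quality is the read-group empirical quality
#' plus the reported-quality, cycle and dinucleotide deltas (each level's
#' empirical quality minus its parent's), where a delta is applied only if
#' its bin holds at least `min_obs` observations. The result is clamped to
#' `[2, 60]` and rounded to the nearest integer.
#'
#' @param reads Read tibble (`name`, `seq`, `qual`, optional `read_group`).
#' @param table A `recal_table` from [build_recal_table()].
#' @param min_obs Minimum observations for a covariate bin to contribute.
#' @return `reads` with `qual` replaced by recalibrated values.
#' @export
recalibrate_reads <- function(reads, table, min_obs = 100L) {
  rg <- if ("read_group" %in% names(reads)) reads$read_group else rep("default", nrow(reads))
  lens <- nchar(reads$seq)
  per_base <- tibble(
    read_idx = rep.int(seq_len(nrow(reads)), lens),
    read_group = rep.int(rg, lens),
    cycle = unlist(lapply(lens, seq_len), use.names = FALSE),
    reported_quality = unlist(reads$qual, use.names = FALSE)
  )
  chars <- unlist(seq_chars(reads$seq), use.names = FALSE)
  prev <- c("N", chars[-length(chars)])
  prev[per_base$cycle == 1L] <- "N"
  per_base$dinucleotide <- paste0(prev, chars)

  gate <- function(tbl) tbl |> filter(.data$n >= min_obs)
  q_rg <- table$read_group |> select("read_group", q_rg = "q_emp")
  q_q <- gate(table$reported_quality) |>
    select("read_group", "reported_quality", q_q = "q_emp")
  q_cy <- gate(table$cycle) |>
    select("read_group", "reported_quality", "cycle", q_cy = "q_emp")
  q_di <- gate(table$dinucleotide) |>
    select("read_group", "reported_quality", "dinucleotide", q_di = "q_emp")

  scored <- per_base |>
    left_join(q_rg, by = "read_group") |>
    left_join(q_q, by = c("read_group", "reported_quality")) |>
    left_join(q_cy, by = c("read_group", "reported_quality", "cycle")) |>
    left_join(q_di, by = c("read_group", "reported_quality", "dinucleotide")) |>
    mutate(
      q_q = dplyr::coalesce(.data$q_q, .data$q_rg),
      new_q = .data$q_rg +
        (.data$q_q - .data$q_rg) +
        dplyr::coalesce(.data$q_cy - .data$q_q, 0) +
        dplyr::coalesce(.data$q_di - .data$q_q, 0),
      new_q = as.integer(round(pmin(pmax(.data$new_q, 2), 60)))
    )
  reads$qual <- split(scored$new_q, scored$read_idx)[as.character(seq_len(nrow(reads)))]
  names(reads$qual) <- NULL
  reads
}
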