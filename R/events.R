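# Per-base event decomposition of alignments: the workhorse table behind the
# error profiler, the recalibrator, the pileup engine and the reference-bias
# diagnostics.

#' Decompose alignments into per-base events
#'
#' Walks every CIGAR against read and reference and labels each read base
#' MATCH, MISMATCH or INSERTION; deleted reference bases become DELETION rows
#' attached to the preceding read base. Read positions are reported both in
#' aligned orientation (`read_pos`) and sequencing orientation (`cycle`;
#' reverse-strand alignments are re-indexed from the read's 3' reference
#' end). For insertions, `ref_pos` is the anchor: the last reference base
#' consumed before the insertion.
#'
#' @param aln Alignment tibble (`qname`, `rname`, `start`, `strand`, `cigar`,
#'   `seq`, optional `qual`).
#' @param refs Reference tibble (`name`, `seq`).
#' @return Tibble with one row per event: `qname`, `rname`, `strand`,
#'   `read_len`, `read_pos`, `cycle`, `ref_pos`, `event`, `read_base`,
#'   `ref_base`, `qual`.
#' @export
alignment_events <- function(aln, refs) {
  validate_alignments(aln)
  assert_that(nrow(aln) > 0L, "no alignments to decompose")
  ops_list <- parse_cigar(aln$cigar)
  n_ops <- vapply(ops_list, nrow, integer(1))
  ops <- bind_rows(ops_list)
  ops$aln_id <- rep.int(seq_len(nrow(aln)), n_ops)

  # one row per base-level unit
  unit_aln <- rep.int(ops$aln_id, ops$len)
  unit_op <- rep.int(ops$op, ops$len)
  consumes_read <- unit_op %in% c("M", "I", "S")
  consumes_ref <- unit_op %in% c("M", "D")

  grp_sizes <- tabulate(unit_aln, nbins = nrow(aln))
  grp_cum <- function(x) {
    cs <- cumsum(x)
    prev <- c(0, cs[cumsum(grp_sizes)])[unit_aln]
    cs - prev
  }
  read_pos <- grp_cum(consumes_read)
  ref_off <- grp_cum(consumes_ref)
  ref_pos <- aln$start[unit_aln] - 1L + ref_off

  read_chars <- unlist(seq_chars(aln$seq), use.names = FALSE)
  read_lens <- nchar(aln$seq)
  read_offset <- cumsum(c(0L, read_lens))[unit_aln]
  read_base <- read_chars[read_offset + pmax(read_pos, 1L)]
  read_base[unit_op == "D" | read_pos == 0L] <- NA_character_

  ref_chars_all <- unlist(seq_chars(refs$seq), use.names = FALSE)
  ref_offset_by_name <- setNames(cumsum(c(0L, nchar(refs$seq)))[seq_len(nrow(refs))],
                                 refs$name)
  # pmax guards the zero anchor of a read-leading insertion; those rows are
  # masked to NA below anyway (only M/D rows carry a reference base)
  ref_base <- ref_chars_all[ref_offset_by_name[aln$rname[unit_aln]] +
                              pmax(ref_pos, 1L)]
  ref_base[!consumes_ref] <- NA_character_

  event <- character(length(unit_op))
  event[unit_op == "I"] <- "INSERTION"
  event[unit_op == "D"] <- "DELETION"
  is_m <- unit_op == "M"
  event[is_m] <- ifelse(read_base[is_m] == ref_base[is_m], "MATCH", "MISMATCH")

  qual <- if ("qual" %in% names(aln)) {
    qv <- unlist(aln$qual, use.names = FALSE)
    if (length(qv) == sum(read_lens)) {
      q <- qv[read_offset + pmax(read_pos, 1L)]
      q[unit_op == "D" | read_pos == 0L] <- NA_integer_
      q
    } else {
      rep(NA_integer_, length(unit_op))
    }
  } else {
    rep(NA_integer_, length(unit_op))
  }

  read_len <- read_lens[unit_aln]
  strand <- aln$strand[unit_aln]
  cycle <- ifelse(strand == "-", read_len - read_pos + 1L, read_pos)
  cycle[read_pos == 0L] <- NA_integer_

  keep <- unit_op != "S"
  tibble(
    qname = aln$qname[unit_aln], rname = aln$rname[unit_aln],
    strand = strand, read_len = read_len, read_pos = read_pos,
    cycle = as.integer(cycle), ref_pos = as.integer(ref_pos), event = event,
    read_base = read_base, ref_base = ref_base, qual = qual
  )[keep, ]
}

#' Classify the events of a single alignment
#'
#' Convenience wrapper over [alignment_events()] for one record.
#'
#' @param aln One-row alignment tibble.
#' @param refs Reference tibble.
#' @return Per-base event tibble for that read.
#' @export
classify_events <- function(aln, refs) {
  assert_that(nrow(aln) == 1L, "classify_events() takes a single alignment")
  alignment_events(aln, refs)
}
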