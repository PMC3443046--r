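# Minimal SAM dialect: mandatory columns plus optional NM tag. Alignment
# tables are tibbles with columns
#   qname, rname, start (1-based leftmost reference position), strand
#   ("+"/"-"), cigar (ops M/I/D/S), seq (aligned orientation), qual (list of
#   integer PHRED values, aligned orientation), score, nm.
# SAM stores the reverse-complemented sequence for reverse-strand records, as
# the format requires; internal tables use the same (aligned) orientation, so
# serialisation is direct.

#' Parse a CIGAR string
#'
#' @param cigar Character vector of CIGAR strings (ops `M`, `I`, `D`, `S`).
#' @return A list of tibbles, one per input, with columns `op` and `len`.
#' @export
parse_cigar <- function(cigar) {
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDS])")
  bad <- vapply(seq_along(m), function(i) {
    paste0(m[[i]][, 2], m[[i]][, 3], collapse = "") != cigar[i]
  }, logical(1))
  if (any(bad)) abort(paste0("invalid CIGAR: ", cigar[which(bad)[1]]))
  lapply(m, function(x) tibble(op = x[, 3], len = as.integer(x[, 2])))
}

#' Read/reference lengths consumed by a CIGAR
#'
#' `M`, `I` and `S` consume read bases; `M` and `D` consume reference bases.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of consumed lengths.
#' @export
cigar_read_len <- function(cigar) {
  vapply(parse_cigar(cigar), function(x) sum(x$len[x$op %in% c("M", "I", "S")]),
         integer(1))
}

#' @rdname cigar_read_len
#' @export
cigar_ref_len <- function(cigar) {
  vapply(parse_cigar(cigar), function(x) sum(x$len[x$op %in% c("M", "D")]),
         integer(1))
}

validate_alignments <- function(aln) {
  if (nrow(aln) == 0L) return(invisible(aln))
  rl <- cigar_read_len(aln$cigar)
  bad <- rl != nchar(aln$seq)
  if (any(bad)) {
    abort(paste0("CIGAR/read length mismatch for read '",
                 aln$qname[which(bad)[1]], "': CIGAR consumes ",
                 rl[which(bad)[1]], ", sequence has ",
                 nchar(aln$seq[which(bad)[1]]), " bases"))
  }
  invisible(aln)
}

#' Write alignments to a SAM file
#'
#' Emits `@HD`/`@SQ` headers from the reference table and one line per
#' alignment with mandatory fields plus `NM` and `AS` tags. Positions are the
#' 1-based leftmost reference coordinates used throughout the package.
#'
#' @param aln Alignment tibble (see package conventions).
#' @param refs Reference tibble with `name`, `seq` (for `@SQ` lengths).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, refs, path) {
  validate_alignments(aln)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", refs$name, "\tLN:", nchar(refs$seq)))
  if (nrow(aln) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  flag <- ifelse(aln$strand == "-", 16L, 0L)
  qual_str <- if (!("qual" %in% names(aln))) {
    "*"
  } else {
    vapply(aln$qual, function(q) {
      if (is.null(q) || length(q) == 0L) "*" else intToUtf8(q + 33L)
    }, character(1))
  }
  nm <- if ("nm" %in% names(aln)) aln$nm else 0L
  score <- if ("score" %in% names(aln)) aln$score else 0L
  body <- paste(aln$qname, flag, aln$rname, aln$start, 60L, aln$cigar, "*", 0L,
                0L, aln$seq, qual_str, paste0("NM:i:", nm),
                paste0("AS:i:", score), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into an alignment tibble
#'
#' Unmapped records (flag 0x4) are dropped. Only the fields of the package's
#' alignment dialect are retained.
#'
#' @param path Path to a SAM file.
#' @return Alignment tibble.
#' @export
read_sam <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0L) {
    return(tibble(qname = character(), rname = character(), start = integer(),
                  strand = character(), cigar = character(), seq = character(),
                  qual = list(), score = integer(), nm = integer()))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- vapply(f, length, integer(1))
  if (any(nf < 11L)) {
    abort(paste0("malformed SAM line ", which(nf < 11L)[1] +
                   sum(startsWith(lines, "@"))))
  }
  flag <- as.integer(vapply(f, `[[`, character(1), 2))
  tag_int <- function(fields, tag) {
    hit <- grep(paste0("^", tag, ":i:"), fields, value = TRUE)
    if (length(hit)) as.integer(sub(paste0(tag, ":i:"), "", hit[1])) else NA_integer_
  }
  out <- tibble(
    qname = vapply(f, `[[`, character(1), 1),
    rname = vapply(f, `[[`, character(1), 3),
    start = as.integer(vapply(f, `[[`, character(1), 4)),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    cigar = vapply(f, `[[`, character(1), 6),
    seq = vapply(f, `[[`, character(1), 10),
    qual = lapply(f, function(x) {
      if (x[[11]] == "*") integer() else utf8ToInt(x[[11]]) - 33L
    }),
    score = vapply(f, tag_int, integer(1), "AS"),
    nm = vapply(f, tag_int, integer(1), "NM")
  )
  out <- out[bitwAnd(flag, 4L) == 0L, ]
  validate_alignments(out)
  out
}
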