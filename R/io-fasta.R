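# FASTA/FASTQ input and output, tibble-first, backed by Biostrings.
#
# A sequence table has columns `name` (unique identifier) and `seq`
# (uppercase bases over {A,C,G,T,N}); read tables additionally carry `qual`,
# a list column of integer PHRED qualities (0-60), one per base.

#' Read a FASTA file into a sequence tibble
#'
#' Sequences are case-normalised to uppercase; one row per record.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `name` and `seq`.
#' @export
read_fasta <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) abort(paste0("malformed FASTA '", path, "': ", conditionMessage(e)))
  )
  if (any(Biostrings::width(set) == 0L)) {
    abort(paste0("malformed FASTA '", path, "': empty sequence for record '",
                 names(set)[which(Biostrings::width(set) == 0L)[1]], "'"))
  }
  tibble(
    name = sub("\\s.*$", "", names(set)),
    seq = unname(toupper(as.character(set)))
  )
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `name`, `seq`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(setNames(toupper(seqs$seq), seqs$name))
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path Path to a FASTQ file (PHRED+33 qualities).
#' @return A tibble with columns `name`, `seq` and list column `qual`
#'   (integer PHRED values per base).
#' @export
read_fastq <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  if (file.size(path) == 0L) {
    return(tibble(name = character(), seq = character(), qual = list()))
  }
  # Biostrings warns about dropping (empty) metadata columns on conversion
  set <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred")
  )
  quals <- as(Biostrings::quality(set), "IntegerList")
  tibble(
    name = sub("\\s.*$", "", names(set)),
    seq = unname(toupper(as.character(set))),
    qual = unname(as.list(quals))
  )
}

#' Write a read tibble to FASTQ
#'
#' Qualities are encoded PHRED+33; values outside 0-60 are rejected so the
#' encoding stays inside the printable Sanger range used throughout.
#'
#' @param reads Tibble with columns `name`, `seq`, `qual` (list of integers).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  assert_that(!is.null(reads$qual), "reads must carry qualities for FASTQ output")
  qv <- unlist(reads$qual, use.names = FALSE)
  if (any(qv < 0L | qv > 60L)) {
    abort("PHRED qualities must lie in [0, 60] for FASTQ encoding")
  }
  lens <- vapply(reads$qual, length, integer(1))
  assert_that(all(lens == nchar(reads$seq)),
              "quality length must equal sequence length")
  qual_str <- vapply(reads$qual, function(q) intToUtf8(q + 33L), character(1))
  out <- character(4L * nrow(reads))
  out[seq(1, length(out), by = 4)] <- paste0("@", reads$name)
  out[seq(2, length(out), by = 4)] <- reads$seq
  out[seq(3, length(out), by = 4)] <- "+"
  out[seq(4, length(out), by = 4)] <- qual_str
  writeLines(out, path)
  invisible(path)
}
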