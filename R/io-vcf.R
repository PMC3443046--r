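# SNP-only VCF dialect for truth sets and call sets.
#
# A variant table is a tibble with columns
#   contig, pos (1-based), ref, alt (single bases), status (TRUE_DE_NOVO /
#   ARTIFACT / UNKNOWN), zygosity (HET / HOM_ALT / NA).
# Truth status is serialised as INFO key STATUS; zygosity as a GT sample field.

TRUTH_STATUSES <- c("TRUE_DE_NOVO", "ARTIFACT", "UNKNOWN")

validate_variants <- function(variants) {
  if (nrow(variants) == 0L) return(invisible(variants))
  assert_that(all(nchar(variants$ref) == 1L & nchar(variants$alt) == 1L),
              "only single-base (SNP) alleles are supported")
  assert_that(all(variants$ref != variants$alt),
              "ref and alt alleles must differ")
  assert_that(all(variants$status %in% TRUTH_STATUSES),
              "unknown truth status value")
  key <- order(variants$contig, variants$pos)
  assert_that(identical(key, seq_len(nrow(variants))),
              "variants must be sorted by (contig, pos)")
  invisible(variants)
}

#' Write a SNP variant table to VCF
#'
#' Serialises truth status in `INFO/STATUS` and zygosity as the `GT` field
#' (`0/1` for HET, `1/1` for HOM_ALT, `./.` when unknown). Input must be
#' sorted by contig then position.
#'
#' @param variants Variant tibble (`contig`, `pos`, `ref`, `alt`, `status`,
#'   optionally `zygosity` and `qual`).
#' @param path Output path.
#' @param refs Optional reference tibble used to emit `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, refs = NULL) {
  validate_variants(variants)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=STATUS,Number=1,Type=String,Description=\"Truth status of the site\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  if (!is.null(refs)) {
    hdr <- c(hdr, paste0("##contig=<ID=", refs$name, ",length=", nchar(refs$seq), ">"))
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "SAMPLE", sep = "\t"))
  if (nrow(variants) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  zyg <- if ("zygosity" %in% names(variants)) variants$zygosity else rep(NA_character_, nrow(variants))
  gt <- dplyr::case_when(zyg == "HET" ~ "0/1", zyg == "HOM_ALT" ~ "1/1",
                         TRUE ~ "./.")
  qual <- if ("qual" %in% names(variants)) format(variants$qual, trim = TRUE) else "."
  body <- paste(variants$contig, variants$pos, ".", variants$ref, variants$alt,
                qual, ".", paste0("STATUS=", variants$status), "GT", gt,
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SNP VCF into a variant table
#'
#' Multi-base alleles are rejected (SNP-only scope). Missing `STATUS` INFO
#' keys become `UNKNOWN`.
#'
#' @param path Path to a VCF file.
#' @return Variant tibble.
#' @export
read_vcf <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), status = character(),
                  zygosity = character()))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  info <- get(8)
  status <- ifelse(grepl("STATUS=", info),
                   sub(".*STATUS=([A-Z_]+).*", "\\1", info), "UNKNOWN")
  gt <- vapply(f, function(x) if (length(x) >= 10L) x[[10]] else "./.", character(1))
  out <- tibble(
    contig = get(1),
    pos = as.integer(get(2)),
    ref = toupper(get(4)),
    alt = toupper(get(5)),
    status = status,
    zygosity = dplyr::case_when(gt == "0/1" | gt == "1/0" ~ "HET",
                                gt == "1/1" ~ "HOM_ALT",
                                TRUE ~ NA_character_)
  )
  validate_variants(out)
  out
}
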