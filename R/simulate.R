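# Diploid amplicon panel construction and long-read simulation.
#
# Event strings record, per emitted or skipped template base, one of
#   M (match), X (mismatch), I (inserted base), D (deleted template base),
# in the orientation of the alignment against the forward reference, so the
# string plus the haplotype reconstructs the read exactly.

#' Generate a diploid amplicon panel with truth-status SNP sites
#'
#' Builds random amplicon references (optionally at target GC fractions),
#' plants `n_true_sites` TRUE_DE_NOVO variants as heterozygous sites on one
#' haplotype each, and records `n_artifact_sites` ARTIFACT variants in the
#' truth set only — artifact sites are absent from the DNA, so a correct
#' caller sees them as monomorphic. Sites are separated by at least 10 bases
#' and kept 20 bases from amplicon ends.
#'
#' @param config A [sim_config()].
#' @param n_amplicons Number of amplicons.
#' @param amplicon_len Amplicon length(s) in bases (recycled), each >= 500.
#' @param gc Target GC fraction(s) (recycled).
#' @return A `sim_panel` list with elements `panel` (tibble `name`, `seq`,
#'   `gc`), `variants` (truth table with `contig`, `pos`, `ref`, `alt`,
#'   `status`, `zygosity`, `hap`), and `haplotypes` (tibble `amplicon`,
#'   `hap1`, `hap2`).
#' @export
make_panel <- function(config, n_amplicons = 4L, amplicon_len = 2000L,
                       gc = 0.5) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  assert_that(all(amplicon_len >= 500L), "amplicon length must be >= 500")
  lens <- rep_len(as.integer(amplicon_len), n_amplicons)
  gcs <- rep_len(gc, n_amplicons)
  set.seed(stage_seed(config$seed, "panel"))

  seqs <- vapply(seq_len(n_amplicons), function(i) {
    p <- c(A = (1 - gcs[i]) / 2, C = gcs[i] / 2, G = gcs[i] / 2,
           T = (1 - gcs[i]) / 2)
    paste(sample(DNA_BASES, lens[i], replace = TRUE, prob = p), collapse = "")
  }, character(1))
  panel <- tibble(name = sprintf("amp%02d", seq_len(n_amplicons)),
                  seq = seqs, gc = gcs)

  n_sites <- config$n_true_sites + config$n_artifact_sites
  min_gap <- 10L; margin <- 20L
  # spread sites across amplicons proportionally to length
  alloc <- diff(round(cumsum(c(0, lens)) / sum(lens) * n_sites))
  capacity <- (lens - 2L * margin) %/% min_gap
  if (any(alloc > capacity)) {
    abort("amplicons too short to host the requested number of sites")
  }
  site_rows <- purrr::map_dfr(seq_len(n_amplicons), function(i) {
    k <- alloc[i]
    if (k == 0L) return(tibble(contig = character(), pos = integer()))
    span <- lens[i] - 2L * margin - (k - 1L) * min_gap
    raw <- sort(sample.int(span, k))
    tibble(contig = panel$name[i],
           pos = margin + raw + (seq_len(k) - 1L) * min_gap)
  })
  status <- sample(rep(c("TRUE_DE_NOVO", "ARTIFACT"),
                       c(config$n_true_sites, config$n_artifact_sites)))
  ref_chars <- seq_chars(panel$seq)
  names(ref_chars) <- panel$name
  variants <- site_rows |>
    mutate(
      ref = purrr::map2_chr(.data$contig, .data$pos, ~ ref_chars[[.x]][.y]),
      alt = vapply(.data$ref, function(r) sample(setdiff(DNA_BASES, r), 1L),
                   character(1), USE.NAMES = FALSE),
      status = status,
      zygosity = if_else(status == "TRUE_DE_NOVO", "HET", NA_character_),
      hap = if_else(status == "TRUE_DE_NOVO", sample(1:2, n(), replace = TRUE),
                    NA_integer_)
    ) |>
    arrange(.data$contig, .data$pos)

  haplotypes <- purrr::map_dfr(seq_len(n_amplicons), function(i) {
    h1 <- ref_chars[[panel$name[i]]]
    h2 <- h1
    v <- variants |> filter(.data$contig == panel$name[i],
                            .data$status == "TRUE_DE_NOVO")
    if (nrow(v)) {
      one <- v$hap == 1L
      h1[v$pos[one]] <- v$alt[one]
      h2[v$pos[!one]] <- v$alt[!one]
    }
    tibble(amplicon = panel$name[i], hap1 = paste(h1, collapse = ""),
           hap2 = paste(h2, collapse = ""))
  })

  structure(list(panel = panel, variants = variants, haplotypes = haplotypes,
                 config = config), class = "sim_panel")
}

# Generate one read's event string and bases from an oriented template.
# Returns NULL if fewer than min_len bases could be emitted.
walk_template <- function(template_chars, start, target_len, config,
                          min_len = 50L) {
  p_ins <- config$p_ins; p_del <- config$p_del; p_mis <- config$p_mis
  L <- length(template_chars)
  avail <- L - start + 1L
  tpl <- template_chars[start:L]
  del <- runif(avail) < p_del
  mis <- runif(avail) < p_mis
  k <- rgeom(avail, prob = 1 - p_ins)       # inserted bases after each emission

  g <- ifelse(del, 1L, 1L + k)              # events contributed per template base
  total <- sum(g)
  ev <- rep("I", total)
  starts <- cumsum(g) - g + 1L
  ev[starts[del]] <- "D"
  ev[starts[!del]] <- ifelse(mis[!del], "X", "M")

  # late-cycle mismatch inflation (off under default config)
  if (is.finite(config$late_cycle_start) &&
      config$late_cycle_mismatch_multiplier != 1) {
    cyc <- cumsum(ev != "D")
    extra <- (config$late_cycle_mismatch_multiplier - 1) * p_mis / (1 - p_mis)
    late_m <- which(ev == "M" & cyc > config$late_cycle_start)
    flip <- late_m[runif(length(late_m)) < extra]
    ev[flip] <- "X"
  }

  emit_idx <- which(ev != "D")
  if (length(emit_idx) < 1L) return(NULL)
  n_emit <- min(length(emit_idx), target_len)
  if (n_emit < min_len) return(NULL)
  cut <- emit_idx[n_emit]                   # last kept event is an emission
  ev <- ev[seq_len(cut)]
  n_lead <- 0L
  while (length(ev) > n_lead && ev[n_lead + 1L] == "D") {
    n_lead <- n_lead + 1L                   # leading deletion = later start
  }
  if (n_lead > 0L) {
    ev <- ev[-seq_len(n_lead)]
    start <- start + n_lead
  }

  consumes_ref <- ev %in% c("M", "X", "D")
  tpl_pos <- n_lead + cumsum(consumes_ref)  # template offset per event
  read_chars <- character(length(ev))
  m_idx <- ev == "M"
  x_idx <- ev == "X"
  i_idx <- ev == "I"
  read_chars[m_idx] <- tpl[tpl_pos[m_idx]]
  if (any(x_idx)) {
    orig <- tpl[tpl_pos[x_idx]]
    shift <- sample.int(3L, sum(x_idx), replace = TRUE)
    read_chars[x_idx] <- DNA_BASES[(match(orig, DNA_BASES) + shift - 1L) %% 4L + 1L]
  }
  if (any(i_idx)) {
    read_chars[i_idx] <- sample(DNA_BASES, sum(i_idx), replace = TRUE)
  }
  list(events = paste(ev, collapse = ""),
       seq = paste(read_chars[!consumes_ref | m_idx | x_idx], collapse = ""),
       start = start, end = start + sum(consumes_ref) - 1L)
}

events_to_cigar <- function(events) {
  r <- rle(chartr("X", "M", strsplit(events, "", fixed = TRUE)[[1]]))
  paste0(r$lengths, r$values, collapse = "")
}

#' Simulate long reads from a diploid amplicon panel
#'
#' For each read: the amplicon is chosen in proportion to its length (reads
#' accumulate per amplicon until the emitted bases reach `depth` times the
#' amplicon length, so the configured depth is the realised mean fold
#' coverage), the haplotype and strand uniformly, and the start uniformly
#' along the template. The template is then walked base by base: each template base is
#' deleted with probability `p_del`, otherwise emitted (mismatched to a
#' uniformly chosen different base with probability `p_mis`), and each
#' emitted base is followed by a geometric run of uniform inserted bases with
#' per-base continuation probability `p_ins`. Event rates do not depend on
#' read position. Reported base qualities are flat (`config$base_quality`,
#' default Q20).
#'
#' @param sim A `sim_panel` from [make_panel()].
#' @param config A [sim_config()]; defaults to the one stored in `sim`.
#' @return A list with `reads` (tibble `name`, `seq`, `qual`) and `truth`
#'   (true-alignment tibble: `qname`, `rname`, `start`, `strand`, `cigar`,
#'   `seq` and `qual` in aligned orientation, `nm`, `events`, `hap`).
#' @export
simulate_reads <- function(sim, config = sim$config) {
  assert_that(inherits(sim, "sim_panel"), "sim must come from make_panel()")
  assert_that(nrow(sim$panel) > 0L, "empty amplicon panel")
  set.seed(stage_seed(config$seed, "reads"))
  lp <- lognormal_length_params(config$mean_len, config$frac_gt_2500)

  hap_chars <- list()
  for (i in seq_len(nrow(sim$haplotypes))) {
    amp <- sim$haplotypes$amplicon[i]
    hap_chars[[amp]] <- list(
      "+" = list(seq_chars(sim$haplotypes$hap1[i])[[1]],
                 seq_chars(sim$haplotypes$hap2[i])[[1]]),
      "-" = list(seq_chars(revcomp(sim$haplotypes$hap1[i]))[[1]],
                 seq_chars(revcomp(sim$haplotypes$hap2[i]))[[1]])
    )
  }

  out <- vector("list", nrow(sim$panel))
  for (i in seq_len(nrow(sim$panel))) {
    amp <- sim$panel$name[i]
    L <- nchar(sim$panel$seq[i])
    # depth is mean fold coverage: accumulate reads until the emitted bases
    # reach depth x L (read lengths are truncated by the template, so a
    # fixed count at the length law's mean would under-deliver coverage)
    target_bases <- round(config$depth * L)
    n_draw <- max(20L, ceiling(2.5 * config$depth * L / config$mean_len))
    lens <- sample_read_length(n_draw, lp)
    haps <- sample(1:2, n_draw, replace = TRUE)
    strands <- sample(c("+", "-"), n_draw, replace = TRUE)
    starts <- sample.int(L, n_draw, replace = TRUE)
    reads <- vector("list", n_draw)
    emitted <- 0
    for (r in seq_len(n_draw)) {
      if (emitted >= target_bases) break
      tpl <- hap_chars[[amp]][[strands[r]]][[haps[r]]]
      w <- walk_template(tpl, starts[r], lens[r], config)
      if (is.null(w)) next
      emitted <- emitted + nchar(w$seq)
      # map oriented template coordinates to forward reference coordinates
      if (strands[r] == "+") {
        fwd_start <- w$start; fwd_end <- w$end
        aligned_seq <- w$seq
        fwd_events <- w$events
      } else {
        fwd_start <- L - w$end + 1L; fwd_end <- L - w$start + 1L
        fwd_events <- paste(rev(strsplit(w$events, "", fixed = TRUE)[[1]]),
                            collapse = "")
        aligned_seq <- revcomp(w$seq)
      }
      ev <- if (strands[r] == "+") w$events else fwd_events
      reads[[r]] <- tibble(
        qname = sprintf("%s_r%05d", amp, r),
        rname = amp, start = fwd_start, strand = strands[r],
        cigar = events_to_cigar(ev),
        seq = aligned_seq,
        nm = sum(strsplit(ev, "", fixed = TRUE)[[1]] != "M"),
        events = ev, hap = haps[r],
        read_seq = w$seq
      )
    }
    out[[i]] <- bind_rows(reads)
  }
  truth <- bind_rows(out)
  if (nrow(truth) == 0L) {
    abort("simulation produced no reads; increase depth or amplicon length")
  }
  qual <- lapply(nchar(truth$seq), function(n) rep(config$base_quality, n))
  truth$qual <- qual
  truth$score <- NA_integer_
  reads <- tibble(name = truth$qname, seq = truth$read_seq, qual = qual)
  truth$read_seq <- NULL
  list(reads = reads,
       truth = truth[, c("qname", "rname", "start", "strand", "cigar", "seq",
                         "qual", "score", "nm", "events", "hap")])
}
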