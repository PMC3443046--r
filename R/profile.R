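# Error-mode profiling, per-position error rates, read-length statistics and
# GC-bias relative-coverage curves.

#' Profile error modes of aligned reads
#'
#' Aggregates [alignment_events()] over a read set into per-mode counts and
#' rates plus a per-cycle (sequencing-orientation position) error table. The
#' denominator for all three mode rates is the number of aligned read bases
#' (insertions included), so the mode rates sum to the total rate. By
#' default every base is counted, including those over known variant sites;
#' set `exclude_known_sites = TRUE` to drop them.
#'
#' @param aln Alignment tibble.
#' @param refs Reference tibble (`name`, `seq`).
#' @param known_sites Optional variant tibble (`contig`, `pos`) marking known
#'   sites.
#' @param exclude_known_sites Drop events over `known_sites` before counting.
#' @param max_position Truncate the per-position table at this cycle.
#' @param events Precomputed event table (defaults to
#'   `alignment_events(aln, refs)`).
#' @return An `error_profile` object: list with `rates` (tibble `mode`,
#'   `count`, `rate`), `n_aligned_bases`, `per_position` (tibble `cycle`,
#'   `observations`, `events`, `rate`), `mean_read_length`,
#'   `frac_reads_gt_2500`.
#' @export
profile_errors <- function(aln, refs, known_sites = NULL,
                           exclude_known_sites = FALSE, max_position = 1000L,
                           events = alignment_events(aln, refs)) {
  assert_that(nrow(events) > 0L, "no aligned reads to profile")
  if (exclude_known_sites && !is.null(known_sites) && nrow(known_sites)) {
    key <- paste(events$rname, events$ref_pos)
    events <- events[!(key %in% paste(known_sites$contig, known_sites$pos)), ]
  }
  n_aligned <- sum(events$event != "DELETION")
  counts <- c(
    mismatch = sum(events$event == "MISMATCH"),
    insertion = sum(events$event == "INSERTION"),
    deletion = sum(events$event == "DELETION")
  )
  rates_tbl <- tibble(mode = names(counts), count = as.integer(counts),
                      rate = as.numeric(counts) / n_aligned)

  per_pos <- events |>
    filter(!is.na(.data$cycle), .data$cycle <= max_position) |>
    group_by(cycle = .data$cycle) |>
    summarise(observations = sum(.data$event != "DELETION"),
              events = sum(.data$event != "MATCH"), .groups = "drop") |>
    mutate(rate = .data$events / pmax(.data$observations, 1L))

  read_lens <- nchar(aln$seq)
  structure(list(
    rates = rates_tbl, n_aligned_bases = n_aligned, per_position = per_pos,
    mean_read_length = mean(read_lens),
    frac_reads_gt_2500 = mean(read_lens > 2500)
  ), class = "error_profile")
}

#' Slope of error rate against read position
#'
#' Weighted least-squares slope of the per-cycle error rate on cycle, with
#' observation counts as weights. Under a position-independent error model
#' the slope is indistinguishable from zero.
#'
#' @param profile An `error_profile`.
#' @return Numeric slope (rate change per base).
#' @export
error_position_slope <- function(profile) {
  pp <- profile$per_position
  assert_that(nrow(pp) > 2L, "too few positions for a slope")
  unname(coef(lm(rate ~ cycle, data = pp, weights = pp$observations))[2])
}

#' @export
tidy.error_profile <- function(x, ...) x$rates

#' @export
glance.error_profile <- function(x, ...) {
  tibble(
    n_aligned_bases = x$n_aligned_bases,
    mismatch_rate = x$rates$rate[x$rates$mode == "mismatch"],
    insertion_rate = x$rates$rate[x$rates$mode == "insertion"],
    deletion_rate = x$rates$rate[x$rates$mode == "deletion"],
    total_rate = sum(x$rates$rate),
    mean_read_length = x$mean_read_length,
    frac_reads_gt_2500 = x$frac_reads_gt_2500
  )
}

#' @export
autoplot.error_profile <- function(object, ...) {
  ggplot2::ggplot(object$per_position,
                  ggplot2::aes(x = .data$cycle, y = .data$rate)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.4) +
    ggplot2::labs(x = "read position (sequencing orientation)",
                  y = "error rate (all modes)") +
    ggplot2::theme_minimal()
}

#' Read-length summary statistics
#'
#' @param reads Read tibble (`name`, `seq`).
#' @param hist_bin Histogram bin width in bases.
#' @return List with `mean`, `median`, `frac_gt_2500` (strictly greater
#'   than 2500) and `histogram` (tibble `bin_start`, `count`).
#' @export
read_length_stats <- function(reads, hist_bin = 100L) {
  assert_that(nrow(reads) > 0L, "no reads")
  len <- nchar(reads$seq)
  bins <- (len - 1L) %/% hist_bin * hist_bin
  hist_tbl <- tibble(bin_start = bins) |> count(.data$bin_start, name = "count")
  list(mean = mean(len), median = median(len), frac_gt_2500 = mean(len > 2500),
       histogram = hist_tbl)
}

#' GC-bias relative-coverage curve
#'
#' Partitions each reference into non-overlapping windows, computes per-window
#' fold coverage (aligned reference-consuming bases divided by window size),
#' bins windows by GC fraction and reports each bin's mean coverage relative
#' to the global mean over all windows. Bins with fewer than `min_windows`
#' windows, or with zero coverage, are flagged low-confidence.
#'
#' @param aln Alignment tibble.
#' @param refs Reference tibble (`name`, `seq`).
#' @param window_size Window size in bases.
#' @param bin_width GC-fraction bin width.
#' @param min_windows Minimum windows per bin before the bin is trusted.
#' @return A `gc_bias_curve` tibble (`gc_bin`, `n_windows`, `mean_coverage`,
#'   `relative_coverage`, `flagged`) with attributes `window_size`,
#'   `global_mean_coverage` and `windows` (the per-window table).
#' @export
gc_bias <- function(aln, refs, window_size = 100L, bin_width = 0.05,
                    min_windows = 5L) {
  assert_that(all(window_size <= nchar(refs$seq)),
              "window_size exceeds a contig length")
  windows <- purrr::map_dfr(seq_len(nrow(refs)), function(i) {
    L <- nchar(refs$seq[i])
    n_win <- L %/% window_size           # drop any incomplete tail window
    chars <- seq_chars(refs$seq[i])[[1]]
    cov <- numeric(L)
    a <- aln[aln$rname == refs$name[i], ]
    if (nrow(a)) {
      ends <- a$start + cigar_ref_len(a$cigar) - 1L
      delta <- numeric(L + 1L)
      for (k in seq_len(nrow(a))) {
        delta[a$start[k]] <- delta[a$start[k]] + 1
        delta[min(ends[k], L) + 1L] <- delta[min(ends[k], L) + 1L] - 1
      }
      cov <- cumsum(delta)[seq_len(L)]
    }
    win_id <- rep(seq_len(n_win), each = window_size)
    idx <- seq_len(n_win * window_size)
    tibble(
      contig = refs$name[i],
      window = seq_len(n_win),
      gc = as.numeric(tapply(chars[idx] %in% c("G", "C"), win_id, mean)),
      coverage = as.numeric(tapply(cov[idx], win_id, sum)) / window_size
    )
  })
  global_mean <- mean(windows$coverage)
  curve <- windows |>
    mutate(gc_bin = floor(.data$gc / bin_width) * bin_width) |>
    group_by(.data$gc_bin) |>
    summarise(n_windows = n(), mean_coverage = mean(.data$coverage),
              .groups = "drop") |>
    mutate(relative_coverage = .data$mean_coverage / global_mean,
           flagged = .data$n_windows < min_windows | .data$mean_coverage == 0)
  structure(curve, class = c("gc_bias_curve", class(curve)),
            window_size = window_size, global_mean_coverage = global_mean,
            windows = windows)
}

#' @export
autoplot.gc_bias_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$gc_bin,
                                       y = .data$relative_coverage)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_windows,
                                     shape = .data$flagged)) +
    ggplot2::geom_line() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(x = "window GC fraction", y = "relative coverage") +
    ggplot2::theme_minimal()
}
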