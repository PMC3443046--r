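# Event classification, aggregate/positional error rates, read-length
# statistics and GC-bias curves.

test_that("classify_events labels mismatches and indels from the CIGAR", {
  refs <- tibble::tibble(name = "r", seq = "ACGTACGTACGTA")
  aln <- tibble::tibble(qname = "x", rname = "r", start = 1L, strand = "+",
                        cigar = "10M", seq = "ACGTACGTTC",
                        qual = list(rep(20L, 10)))
  ev <- classify_events(aln, refs)
  expect_equal(sum(ev$event == "MATCH"), 9L)
  expect_equal(sum(ev$event == "MISMATCH"), 1L)
  expect_equal(ev$ref_pos[ev$event == "MISMATCH"], 9L)

  aln2 <- tibble::tibble(qname = "y", rname = "r", start = 1L, strand = "+",
                         cigar = "4M2I4M1D2M", seq = "ACGTTTACGTGT",
                         qual = list(rep(20L, 12)))
  ev2 <- classify_events(aln2, refs)
  expect_equal(sum(ev2$event == "INSERTION"), 2L)
  expect_equal(sum(ev2$event == "DELETION"), 1L)
  # the deletion is attached to the preceding read base
  expect_equal(ev2$read_pos[ev2$event == "DELETION"], 10)
  # insertion anchor: last reference base consumed before the insertion
  expect_equal(unique(ev2$ref_pos[ev2$event == "INSERTION"]), 4L)
})

test_that("reverse-strand cycles are indexed from the read 3' end", {
  refs <- tibble::tibble(name = "r", seq = "ACGTACGT")
  aln <- tibble::tibble(qname = "x", rname = "r", start = 1L, strand = "-",
                        cigar = "8M", seq = "ACGTACGT",
                        qual = list(1:8))
  ev <- classify_events(aln, refs)
  expect_equal(ev$cycle, 8:1)
  expect_equal(ev$read_pos, 1:8)
})

test_that("profiled rates match truth event counts exactly on truth input", {
  fx <- profiled_sim()
  truth_ev <- alignment_events(fx$truth, fx$sim$panel)
  # per-read comparison of simulator event labels and CIGAR-derived labels
  sim_counts <- table(truth_ev$event)
  ev_chars <- unlist(strsplit(fx$truth$events, ""))
  expect_equal(unname(sim_counts[["INSERTION"]]), sum(ev_chars == "I"))
  expect_equal(unname(sim_counts[["DELETION"]]), sum(ev_chars == "D"))
  expect_equal(unname(sim_counts[["MISMATCH"]]), sum(ev_chars == "X"))
})

test_that("aligned-data profile recovers the configured rates", {
  fx <- profiled_sim()
  pr <- profile_errors(fx$aln, fx$sim$panel, events = fx$events)
  expect_gt(pr$n_aligned_bases, 1e5 / 2)
  g <- glance(pr)
  expect_lt(abs(g$insertion_rate - 0.12), 0.005)
  expect_lt(abs(g$deletion_rate - 0.02), 0.005)
  expect_lt(abs(g$mismatch_rate - 0.01), 0.005)
  expect_equal(g$total_rate,
               g$insertion_rate + g$deletion_rate + g$mismatch_rate)
  # positional event sums equal the aggregate counts (within the table range)
  pp <- pr$per_position
  expect_equal(sum(pp$observations),
               sum(fx$events$event != "DELETION" &
                     fx$events$cycle <= 1000))
})

test_that("error-free alignments profile to zero rates", {
  cfg <- sim_config(seed = 6, p_ins = 0, p_del = 0, p_mis = 0, depth = 6,
                    n_true_sites = 0, n_artifact_sites = 0)
  sim <- make_panel(cfg, 1, 800)
  rr <- simulate_reads(sim, cfg)
  aln <- align_reads(rr$reads, sim$panel)
  pr <- profile_errors(aln, sim$panel)
  expect_equal(glance(pr)$total_rate, 0)
  # profile on aligner output equals profile on true alignments
  pr_truth <- profile_errors(rr$truth, sim$panel)
  expect_equal(pr$rates, pr_truth$rates)
})

test_that("known-site exclusion switch removes planted-variant mismatches", {
  cfg <- sim_config(seed = 17, depth = 25, p_ins = 0, p_del = 0)
  sim <- make_panel(cfg, 1, 2000)
  rr <- simulate_reads(sim, cfg)
  with_sites <- profile_errors(rr$truth, sim$panel)
  without_sites <- profile_errors(rr$truth, sim$panel,
                                  known_sites = sim$variants,
                                  exclude_known_sites = TRUE)
  m_with <- glance(with_sites)$mismatch_rate
  m_without <- glance(without_sites)$mismatch_rate
  expect_gt(m_with, m_without)        # the default keeps every sequenced base
  expect_lt(abs(m_without - 0.01), 0.005)
})

test_that("read-length statistics report exact summaries", {
  reads <- tibble::tibble(name = c("a", "b", "c"),
                          seq = strrep("A", c(700, 700, 700)))
  st <- read_length_stats(reads)
  expect_equal(st$mean, 700)
  expect_equal(st$frac_gt_2500, 0)

  single <- tibble::tibble(name = "a", seq = strrep("A", 2501))
  expect_equal(read_length_stats(single)$frac_gt_2500, 1)  # strict >
  expect_equal(read_length_stats(tibble::tibble(
    name = "a", seq = strrep("A", 2500)))$frac_gt_2500, 0)
  expect_error(read_length_stats(reads[0, ]), "no reads")
})

test_that("the length law reproduces the 700-base mean and 5% tail", {
  withr::local_seed(55)
  lens <- sample_read_length(1e4, lognormal_length_params(700, 0.05))
  reads <- tibble::tibble(name = as.character(seq_along(lens)),
                          seq = strrep("A", lens))
  st <- read_length_stats(reads)
  expect_lt(abs(st$mean - 700) / 700, 0.05)
  expect_lt(abs(st$frac_gt_2500 - 0.05), 0.01)
})

test_that("GC-bias curve is flat under uniform coverage and normalised", {
  withr::local_seed(77)
  refs <- tibble::tibble(name = "g", seq = random_seq(8000))
  # exact uniform coverage: seven window-aligned passes of 100-base reads
  starts <- rep(seq(1L, 7901L, by = 100L), each = 7L)
  aln <- tibble::tibble(
    qname = paste0("t", seq_along(starts)), rname = "g", start = starts,
    strand = "+", cigar = "100M",
    seq = substring(refs$seq, starts, starts + 99L),
    qual = replicate(length(starts), rep(20L, 100), simplify = FALSE)
  )
  curve <- gc_bias(aln, refs, window_size = 100)
  expect_true(all(abs(curve$relative_coverage - 1) < 0.05))
  w <- attr(curve, "windows")
  expect_lt(abs(weighted.mean(curve$relative_coverage, curve$n_windows) - 1),
            1e-9)
  expect_error(gc_bias(aln, refs, window_size = 10000), "exceeds")
})

test_that("constructed GC-dependent thinning is recovered by the curve", {
  withr::local_seed(88)
  # genome with alternating GC composition so bins are populated widely
  blocks <- vapply(1:40, function(i) {
    gc <- runif(1, 0.2, 0.8)
    paste(sample(c("A", "C", "G", "T"), 200, TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }, character(1))
  refs <- tibble::tibble(name = "g", seq = paste(blocks, collapse = ""))
  # window-aligned reads, six passes, so each read sits in exactly one window
  base_starts <- seq(1L, nchar(refs$seq) - 99L, by = 100L)
  starts <- rep(base_starts, each = 6L)
  aln <- tibble::tibble(
    qname = paste0("t", seq_along(starts)), rname = "g", start = starts,
    strand = "+", cigar = "100M",
    seq = substring(refs$seq, starts, starts + 99L),
    qual = replicate(length(starts), rep(20L, 100), simplify = FALSE)
  )
  chars <- strsplit(refs$seq, "")[[1]]
  win_gc <- vapply(starts, function(s) {
    mean(chars[s:(s + 99)] %in% c("G", "C"))
  }, numeric(1))
  pass <- rep(1:6, times = length(base_starts))
  thinned <- aln[!(win_gc > 0.6 & pass <= 3L), ]   # 50% thinning above GC 0.6
  curve <- gc_bias(thinned, refs, window_size = 100)
  high <- curve[curve$gc_bin >= 0.65 & !curve$flagged, ]
  low <- curve[curve$gc_bin <= 0.55 & curve$gc_bin >= 0.35 & !curve$flagged, ]
  expect_gt(nrow(high), 0)
  ratio <- weighted.mean(high$mean_coverage, high$n_windows) /
    weighted.mean(low$mean_coverage, low$n_windows)
  expect_lt(abs(ratio - 0.5), 0.05)
})
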