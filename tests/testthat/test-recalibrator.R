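# Empirical quality estimation and covariate-based recalibration.

test_that("empirical quality follows its smoothed closed form", {
  expect_equal(empirical_quality(98, 0), 20)  # error prob 1/100
  expect_equal(empirical_quality(998, 9), 20)
  expect_equal(empirical_quality(0, 0), -10 * log10(0.5), tolerance = 1e-10)
  expect_equal(empirical_quality(1e8, 0), 60)   # cap
  expect_error(empirical_quality(5, 6), "m <= n")
})

test_that("empirical quality is monotone in the mismatch count", {
  for (n in c(10, 100, 1000)) {
    q <- empirical_quality(rep(n, n + 1), 0:n)
    expect_true(all(diff(q) <= 0))
  }
})

test_that("flat-Q20 reads at 1% mismatch recalibrate to about Q20", {
  # mismatch-only simulation profiled from truth alignments
  cfg <- sim_config(seed = 10, depth = 60, p_ins = 0, p_del = 0,
                    n_true_sites = 0, n_artifact_sites = 0)
  sim <- make_panel(cfg, 2, 2000)
  rr <- simulate_reads(sim, cfg)
  tab <- build_recal_table(rr$truth, sim$panel, known_sites = sim$variants)
  expect_gt(sum(tab$read_group$n), 1e5)
  expect_lt(abs(tab$read_group$q_emp - 20), 0.5)

  # counts nest: children sum to parents at every level
  expect_equal(sum(tab$reported_quality$n), sum(tab$read_group$n))
  expect_equal(sum(tab$cycle$n), sum(tab$read_group$n))
  expect_equal(sum(tab$dinucleotide$n), sum(tab$read_group$n))
  expect_equal(sum(tab$cycle$m), sum(tab$read_group$m))
})

test_that("known heterozygous sites are masked out of the counts", {
  cfg <- sim_config(seed = 14, depth = 40, p_ins = 0, p_del = 0)
  sim <- make_panel(cfg, 1, 2000)
  rr <- simulate_reads(sim, cfg)
  masked <- build_recal_table(rr$truth, sim$panel, known_sites = sim$variants)
  unmasked <- build_recal_table(rr$truth, sim$panel)
  # the planted het alt bases inflate the mismatch count only when unmasked
  expect_gt(masked$read_group$q_emp, unmasked$read_group$q_emp)
  expect_lt(abs(masked$read_group$q_emp - 20), 0.5)
  # masking removes exactly the bases over the known sites
  n_site_bases <- sum(unmasked$read_group$n) - sum(masked$read_group$n)
  ev <- alignment_events(rr$truth, sim$panel)
  expect_equal(n_site_bases,
               sum(ev$event %in% c("MATCH", "MISMATCH") &
                     paste(ev$rname, ev$ref_pos) %in%
                       paste(sim$variants$contig, sim$variants$pos)))
})

test_that("covariate-free data recalibrates close to the group value", {
  fx <- big_truth_sim()
  tab <- build_recal_table(fx$truth, fx$sim$panel)
  # min_obs chosen for this data size: sparse per-cycle bins fall back to
  # their parent, so with no simulated covariate structure every base lands
  # at the read-group value up to well-populated-bin noise
  recal <- recalibrate_reads(fx$reads, tab, min_obs = 5000)
  q <- unlist(recal$qual)
  expect_lt(abs(mean(q) - tab$read_group$q_emp), 0.6)
  expect_true(all(abs(q - tab$read_group$q_emp) <= 1.5))
})

test_that("doubled late-cycle error appears as a ~3-point cycle delta", {
  cfg <- sim_config(seed = 15, depth = 230, p_ins = 0, p_del = 0,
                    n_true_sites = 0, n_artifact_sites = 0,
                    late_cycle_start = 300,
                    late_cycle_mismatch_multiplier = 2)
  sim <- make_panel(cfg, 3, 2000)
  rr <- simulate_reads(sim, cfg)
  tab <- build_recal_table(rr$truth, sim$panel)
  cyc <- tab$cycle[tab$cycle$n >= 500, ]
  early <- weighted.mean(cyc$q_emp[cyc$cycle <= 300], cyc$n[cyc$cycle <= 300])
  late <- weighted.mean(cyc$q_emp[cyc$cycle > 300 & cyc$cycle <= 700],
                        cyc$n[cyc$cycle > 300 & cyc$cycle <= 700])
  expect_lt(abs((early - late) - 10 * log10(2)), 0.7)

  # and recalibrated per-base qualities reflect the same split
  recal <- recalibrate_reads(rr$reads, tab)
  per_base <- tibble::tibble(
    cycle = unlist(lapply(nchar(recal$seq), seq_len)),
    q = unlist(recal$qual)
  )
  d <- mean(per_base$q[per_base$cycle <= 300]) -
    mean(per_base$q[per_base$cycle > 300 & per_base$cycle <= 700])
  expect_gt(d, 1.8)
})

test_that("sparse covariate bins fall back to their parent estimate", {
  # one read group, tiny data: cycle/dinucleotide bins all fall under
  # min_obs, so recalibrated qualities equal the group value exactly
  refs <- tibble::tibble(name = "r", seq = random_seq(400))
  reads <- tibble::tibble(name = "x", seq = substr(refs$seq, 1, 200),
                          qual = list(rep(20L, 200)))
  aln <- tibble::tibble(qname = "x", rname = "r", start = 1L, strand = "+",
                        cigar = "200M", seq = reads$seq,
                        qual = reads$qual)
  tab <- build_recal_table(aln, refs)
  recal <- recalibrate_reads(reads, tab, min_obs = 100)
  expect_true(all(unlist(recal$qual) ==
                    as.integer(round(tab$read_group$q_emp))))
})

test_that("recalibrated qualities are calibrated against observed error", {
  fx <- big_truth_sim()
  tab <- build_recal_table(fx$truth, fx$sim$panel)
  recal <- recalibrate_reads(fx$reads, tab, min_obs = 5000)
  recal_qual <- setNames(recal$qual, recal$name)
  aln <- fx$truth
  aln$qual <- purrr::map2(aln$qname, aln$strand, function(q, s) {
    v <- recal_qual[[q]]
    if (s == "-") rev(v) else v
  })
  ev <- alignment_events(aln, fx$sim$panel)
  ev <- ev[ev$event %in% c("MATCH", "MISMATCH"), ]
  by_q <- dplyr::count(ev, qual, wt = NULL)
  for (qv in by_q$qual[by_q$n >= 1e4]) {
    r <- mean(ev$event[ev$qual == qv] == "MISMATCH")
    # 1 PHRED of statistical tolerance plus 0.5 for integer quantisation of
    # the reported quality
    expect_lt(abs(-10 * log10(r) - qv), 1.5)
  }
})

test_that("rebuilding the table from recalibrated data is a fixed point", {
  fx <- big_truth_sim()
  tab <- build_recal_table(fx$truth, fx$sim$panel)
  recal <- recalibrate_reads(fx$reads, tab)
  recal_qual <- setNames(recal$qual, recal$name)
  aln <- fx$truth
  aln$qual <- purrr::map2(aln$qname, aln$strand, function(q, s) {
    v <- recal_qual[[q]]
    if (s == "-") rev(v) else v
  })
  tab2 <- build_recal_table(aln, fx$sim$panel)
  expect_lt(abs(tab2$read_group$q_emp - tab$read_group$q_emp), 1)
})
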