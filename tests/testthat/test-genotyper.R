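# Bayesian diploid genotype likelihoods, site filters and discovery calling.

test_that("likelihoods follow the closed form on pure columns", {
  gl <- genotype_likelihoods(rep("A", 10), rep(20L, 10), "A", "G")
  expect_equal(gl$ll[["hom_ref"]], 10 * log(0.99), tolerance = 1e-12)
  expect_equal(gl$depth_used, 10L)
  expect_true(which.max(gl$ll) == 1L)

  mixed <- genotype_likelihoods(rep(c("A", "G"), each = 5), rep(20L, 10),
                                "A", "G")
  expect_equal(names(which.max(mixed$ll)), "het")
  expect_equal(mixed$ll,
               oracle_genotype_ll(rep(c("A", "G"), each = 5), rep(20L, 10),
                                  "A", "G"),
               tolerance = 1e-12)
})

test_that("bases below the quality floor are excluded (Q10 default)", {
  gl <- genotype_likelihoods("A", 9L, "A", "G")
  expect_equal(gl$depth_used, 0L)
  expect_true(all(is.na(gl$ll)))
  gl10 <- genotype_likelihoods("A", 10L, "A", "G")
  expect_equal(gl10$depth_used, 1L)
})

test_that("likelihood triples match the brute-force oracle", {
  withr::local_seed(500)
  for (k in 1:300) {
    depth <- sample(1:30, 1)
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    bases <- sample(c(ref, alt, setdiff(c("A", "C", "G", "T"), c(ref, alt))),
                    depth, replace = TRUE, prob = c(0.5, 0.4, 0.05, 0.05))
    quals <- sample(10:45, depth, replace = TRUE)
    got <- genotype_likelihoods(bases, quals, ref, alt)
    keep <- bases %in% c(ref, alt)
    if (!any(keep)) next
    want <- oracle_genotype_ll(bases[keep], quals[keep], ref, alt)
    expect_equal(got$ll, want, tolerance = 1e-10)
  }
})

test_that("the posterior is invariant to base ordering", {
  withr::local_seed(501)
  bases <- sample(rep(c("A", "G"), c(12, 8)))
  quals <- sample(10:40, 20, replace = TRUE)
  o <- sample(20)
  a <- genotype_likelihoods(bases, quals, "A", "G")
  b <- genotype_likelihoods(bases[o], quals[o], "A", "G")
  expect_equal(a$ll, b$ll, tolerance = 1e-12)
})

test_that("raising the quality floor never increases retained depth", {
  withr::local_seed(502)
  bases <- sample(c("A", "G"), 50, replace = TRUE)
  quals <- sample(0:40, 50, replace = TRUE)
  depths <- vapply(c(0, 10, 20, 30), function(mbq) {
    genotype_likelihoods(bases, quals, "A", "G",
                         genotyper_config(min_base_quality = mbq))$depth_used
  }, integer(1))
  expect_true(all(diff(depths) <= 0))
})

test_that("the deletion-fraction site filter suppresses calls", {
  col <- structure(list(
    contig = "c", pos = 10L,
    entries = tibble::tibble(qname = paste0("r", 1:4),
                             base = rep("A", 4), qual = rep(20L, 4),
                             strand = "+"),
    n_deletion_reads = 6L
  ), class = "pileup_column")
  call <- call_site(col, "G", "A")          # 6/10 deleted > 0.5
  expect_equal(call$filter, "DELETION_FRACTION")
  expect_false(call$polymorphic)

  col$n_deletion_reads <- 4L                 # 4/8... 4/(4+4) = 0.5, not above
  call2 <- call_site(col, "G", "A")
  expect_equal(call2$filter, "PASS")
  expect_equal(call2$genotype, "hom_ref")
  expect_false(call2$polymorphic)
  expect_equal(call2$pl_hom_ref, 0)
})

test_that("a 70x heterozygous column is called het with high confidence", {
  withr::local_seed(503)
  bases <- sample(rep(c("A", "G"), c(38, 32)))
  call <- call_site(structure(list(
    contig = "c", pos = 5L,
    entries = tibble::tibble(qname = paste0("r", 1:70), base = bases,
                             qual = rep(20L, 70), strand = "+"),
    n_deletion_reads = 2L
  ), class = "pileup_column"), "G", "A")
  expect_equal(call$genotype, "het")
  expect_true(call$polymorphic)
  expect_gte(call$qual, 30)
  expect_equal(min(call$pl_hom_ref, call$pl_het, call$pl_hom_alt), 0)
})

test_that("sufficient data overcomes a near-zero heterozygosity prior", {
  cfg <- genotyper_config(heterozygosity = 1e-6)
  bases <- rep(c("A", "G"), each = 35)
  call <- call_site(structure(list(
    contig = "c", pos = 5L,
    entries = tibble::tibble(qname = paste0("r", 1:70), base = bases,
                             qual = rep(20L, 70), strand = "+"),
    n_deletion_reads = 0L
  ), class = "pileup_column"), "G", "A", config = cfg)
  expect_equal(call$genotype, "het")
})

test_that("pileups separate entries from deletion-spanning reads", {
  refs <- tibble::tibble(name = "r", seq = "ACGTACGTACGT")
  aln <- tibble::tibble(
    qname = c("a", "b"), rname = "r", start = 1L, strand = "+",
    cigar = c("12M", "5M2D5M"),
    seq = c("ACGTACGTACGT", "ACGTATACGT"),
    qual = list(rep(20L, 12), rep(20L, 10))
  )
  ev <- alignment_events(aln, refs)
  col <- build_pileup(ev, "r", 7L)          # inside read b's deletion
  expect_equal(nrow(col$entries), 1L)
  expect_equal(col$n_deletion_reads, 1L)
  col2 <- build_pileup(ev, "r", 2L)
  expect_equal(nrow(col2$entries), 2L)
  expect_equal(col2$n_deletion_reads, 0L)
})

test_that("error-free discovery calls exactly the planted het sites", {
  cfg <- sim_config(seed = 23, p_ins = 0, p_del = 0, p_mis = 0, depth = 100,
                    n_true_sites = 12, n_artifact_sites = 10)
  sim <- make_panel(cfg, 1, 1500)
  rr <- simulate_reads(sim, cfg)
  aln <- align_reads(rr$reads, sim$panel)
  calls <- call_region(aln, sim$panel)
  planted <- sim$variants[sim$variants$status == "TRUE_DE_NOVO", ]
  expect_equal(nrow(calls), nrow(planted))
  expect_equal(calls$pos, planted$pos)
  expect_equal(calls$alt, planted$alt)
  expect_true(all(calls$genotype == "het"))

  # empty input produces an empty call set
  empty <- call_region(aln[0, ], sim$panel)
  expect_equal(nrow(empty), 0L)
})

test_that("pileups from aligner output equal pileups from truth alignments
           on error-free data", {
  cfg <- sim_config(seed = 24, p_ins = 0, p_del = 0, p_mis = 0, depth = 10,
                    n_true_sites = 0, n_artifact_sites = 0)
  sim <- make_panel(cfg, 1, 900)
  rr <- simulate_reads(sim, cfg)
  aln <- align_reads(rr$reads, sim$panel)
  ev_a <- alignment_events(aln, sim$panel)
  ev_t <- alignment_events(rr$truth, sim$panel)
  for (pos in c(100L, 450L, 800L)) {
    ca <- build_pileup(ev_a, sim$panel$name[1], pos)
    ct <- build_pileup(ev_t, sim$panel$name[1], pos)
    expect_equal(dplyr::arrange(ca$entries, qname),
                 dplyr::arrange(ct$entries, qname))
    expect_equal(ca$n_deletion_reads, ct$n_deletion_reads)
  }
})
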