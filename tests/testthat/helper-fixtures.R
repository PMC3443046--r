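# Shared simulation fixtures, computed once per test run. The end-to-end
# validation experiment (98 truth sites at ~70x with the full error model)
# is the expensive one; several test files interrogate different aspects of
# the same run, so it is memoised.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# Full validation design: 38 true het / 60 artifact sites, mean 70x,
# insertion/deletion/mismatch rates 12/2/1%.
e2e_validation <- function() {
  memoise_fixture("e2e_validation", function() {
    cfg <- pipeline_config(sim = sim_config(seed = 42), n_amplicons = 4,
                           amplicon_len = 2000, seed = 42)
    run_validation_experiment(cfg)
  })
}

# Small variant-free simulation aligned with the DP aligner: error-model
# recovery checks (>= 100k aligned bases).
profiled_sim <- function() {
  memoise_fixture("profiled_sim", function() {
    cfg <- sim_config(seed = 5, depth = 45, n_true_sites = 0,
                      n_artifact_sites = 0)
    sim <- make_panel(cfg, n_amplicons = 2, amplicon_len = 2000)
    rr <- simulate_reads(sim, cfg)
    aln <- align_reads(rr$reads, sim$panel)
    list(cfg = cfg, sim = sim, reads = rr$reads, truth = rr$truth, aln = aln,
         events = alignment_events(aln, sim$panel))
  })
}

# Large truth-alignment-only simulation (~1e6 bases, no DP alignment):
# positional properties and recalibration statistics.
big_truth_sim <- function() {
  memoise_fixture("big_truth_sim", function() {
    cfg <- sim_config(seed = 9, depth = 310, n_true_sites = 0,
                      n_artifact_sites = 0)
    sim <- make_panel(cfg, n_amplicons = 3, amplicon_len = 2000)
    rr <- simulate_reads(sim, cfg)
    list(cfg = cfg, sim = sim, truth = rr$truth, reads = rr$reads,
         events = alignment_events(rr$truth, sim$panel))
  })
}
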