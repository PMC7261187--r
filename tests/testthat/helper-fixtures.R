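# Shared mixing-experiment fixture at the full study scale (500 + 500 cells,
# 5% cross-genotype doublets, 500 empty drops). Computed once per test run
# and reused by the end-to-end suites.

MIXING_SEED <- 101L

mixing_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- make_mixing_config(seed = MIXING_SEED)
      dir <- file.path(tempdir(), "haircutr-mixing-fixture")
      sim <- simulate_experiment(cfg, outdir = dir)
      res <- run_count(file.path(dir, "R1.fastq"), file.path(dir, "R2.fastq"),
                       cfg$substrates, sim$whitelist, cells = sim$cells,
                       outdir = file.path(dir, "out"))
      truth <- setNames(sim$truth$cells$label, sim$truth$cells$barcode)
      cache <<- list(cfg = cfg, sim = sim, res = res, truth = truth,
                     dir = dir)
    }
    cache
  }
})

mixing_genotype_calls <- function(res) {
  call_genotypes(site_counts(res$matrix, "uracilA:45"),
                 site_counts(res$matrix, "riboG:44"))
}
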