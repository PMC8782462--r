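# Shared computations reused across test files (computed once per run).
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .test_cache)) assign(key, fn(), envir = .test_cache)
  get(key, envir = .test_cache)
}

# Stochastic benchmark at the in-silico study scale: 100 cells, the five
# half-life bins, 6 genes per bin to average the TF-affinity draw.
study_benchmark <- function() cached("study_benchmark", function()
  ensemble_benchmark(rep(c(20, 100, 500, 1000, 2000), each = 6),
                     n_cells = 100, seed = 101))

# Deterministic (noiseless ODE) benchmark on the same half-life layout.
study_benchmark_det <- function() cached("study_benchmark_det", function()
  ensemble_benchmark(rep(c(20, 100, 500, 1000, 2000), each = 6),
                     mode = "deterministic", seed = 101))

# Per-seed end-to-end fixture recovery: quantify -> TFA -> cosinor for the
# planted rhythmic TF (TF1, peak 6 h) and a planted flat TF (TF5).
fixture_recovery <- function(seeds = 1:20) cached("fixture_recovery", function() {
  do.call(rbind, lapply(seeds, function(s) {
    fx <- generate_fixture(fixture_config(seed = s))
    cd <- SummarizedExperiment::colData(fx$counts)
    ci <- average_replicates(cpm(fx$counts, "intron"), cd$time)
    ce <- average_replicates(cpm(fx$counts, "exon"), cd$time)
    times <- unique(cd$time)
    hi <- has_intron(fx$counts)
    res <- lapply(c("TF1", "TF5"), function(tf) {
      tg <- filter_regulon(fx$regulons, tf)
      ai <- suppressWarnings(tfa_mean(ci, tg, hi, tf = tf))
      ae <- suppressWarnings(tfa_mean(ce, tg, hi, tf = tf))
      ri <- cosinor_test(ai, times, period = 24)
      re <- cosinor_test(ae, times, period = 24)
      planted <- fx$surrogate$value
      data.frame(seed = s, tf = tf,
                 class = classify_tf(ri, re),
                 phase_intron = ri$phase, phase_exon = re$phase,
                 phase_diff = phase_difference(re$phase, ri$phase, 24),
                 corr_intron = if (tf == "TF1") cor(ai, planted) else NA,
                 corr_exon = if (tf == "TF1") cor(ae, planted) else NA)
    })
    do.call(rbind, res)
  }))
})

# Clustering recovery: two anti-phase rhythmic TF modules, 20 seeds.
module_config <- function(seed) {
  fixture_config(
    tf_specs = data.frame(tf = paste0("TF", 1:4),
                          rhythmic = TRUE,
                          phase = c(6, 6, 18, 18),
                          module = c(1, 1, 2, 2)),
    n_offtarget_genes = 20, seed = seed)
}
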