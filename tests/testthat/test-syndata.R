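test_that("config validation names the offending field", {
  expect_error(syn_config(frac_up = 1.2), "frac_up")
  expect_error(syn_config(fs = 0), "fs")
  expect_error(syn_config(graph_n = 2), "graph_n")
  expect_error(syn_config(gtcs_prob = c(WT = 1.5, DUP = 0.5)), "gtcs_prob")
  expect_error(syn_config(set_sizes = c(5000), n_genes_universe = 4000),
               "set_sizes")
})

test_that("generators are deterministic given the seed", {
  cfg <- syn_config(seed = 7, n_proteins = 50, n_rois = 5,
                    duration_s = 30, graph_n = 20)
  expect_identical(gen_quant_table(cfg), gen_quant_table(cfg))
  expect_identical(gen_gene_universe(cfg), gen_gene_universe(cfg))
  expect_identical(igraph::as_edgelist(gen_ppi_graph(cfg)$graph),
                   igraph::as_edgelist(gen_ppi_graph(cfg)$graph))
  expect_identical(gen_traces(cfg)$traces$traces,
                   gen_traces(cfg)$traces$traces)
  expect_identical(gen_seizure_cohort(cfg), gen_seizure_cohort(cfg))
  expect_identical(gen_spectral_counts(cfg), gen_spectral_counts(cfg))
})

test_that("quant table plants the configured truth labels", {
  cfg <- syn_config(seed = 1, n_proteins = 1000, frac_up = 0.05,
                    frac_down = 0.02)
  g <- gen_quant_table(cfg)
  expect_equal(sum(g$truth$label == "up"), 50)
  expect_equal(sum(g$truth$label == "down"), 20)
  cfg0 <- syn_config(seed = 1, effect_log2fc = 0, frac_up = 0,
                     frac_down = 0)
  expect_true(all(gen_quant_table(cfg0)$truth$label == "null"))
  # no duplicate (protein, replicate) cells
  key <- paste(g$table$protein_id, g$table$replicate_id)
  expect_false(anyDuplicated(key) > 0)
})

test_that("planted gene-set overlap matches the closed-form expectation", {
  cfg <- syn_config(set_sizes = 100L, query_size = 200L,
                    n_genes_universe = 4000L,
                    planted_enrichment_fold = 3)
  # closed form: fold * K * n / N
  expect_equal(gen_gene_universe(cfg)$truth$expected_overlap, 15)
  # mean realized overlap over seeds concentrates on the expectation
  ovs <- vapply(1:40, function(s) {
    cfg$seed <- s
    gen_gene_universe(cfg)$truth$realized_overlap
  }, numeric(1))
  se <- sqrt(15 * (1 - 15 / 100) / 40)
  expect_lt(abs(mean(ovs) - 15), 4 * se)
  # null design: fold 1 -> overlap at chance (5)
  cfg1 <- syn_config(set_sizes = 100L, query_size = 200L,
                     n_genes_universe = 4000L,
                     planted_enrichment_fold = 1)
  ovs1 <- vapply(1:40, function(s) {
    cfg1$seed <- s
    gen_gene_universe(cfg1)$truth$realized_overlap
  }, numeric(1))
  expect_lt(abs(mean(ovs1) - 5), 4 * sqrt(5 / 40))
  expect_error(gen_gene_universe(
    syn_config(planted_enrichment_fold = 50, query_size = 200L,
               n_genes_universe = 4000L)), "infeasible")
})

test_that("planted hub dominates the degree distribution", {
  # star graph from an edgeless base
  cfg <- syn_config(graph_n = 10, graph_m = 0, hub_extra_degree = 9)
  g <- gen_ppi_graph(cfg)
  deg <- igraph::degree(g$graph)
  expect_equal(sort(unname(deg), decreasing = TRUE),
               c(9, rep(1, 9)))
  expect_equal(unname(deg[g$hub]), 9)
  # hub has maximal degree in >= 95% of seeds at extra >= 2 * mean degree
  cfg2 <- syn_config(graph_n = 60, graph_m = 2, hub_extra_degree = 8)
  top <- vapply(1:100, function(s) {
    cfg2$seed <- s
    gg <- gen_ppi_graph(cfg2)
    d <- igraph::degree(gg$graph)
    d[gg$hub] == max(d)
  }, logical(1))
  expect_gte(mean(top), 0.95)
  # simple graph, no self loops
  expect_false(igraph::any_multiple(g$graph))
  expect_equal(sum(igraph::which_loop(g$graph)), 0)
})

test_that("trace generator plants recoverable transients", {
  # noise-free single transient recovers the configured amplitude
  cfg <- syn_config(seed = 11, n_rois = 1, duration_s = 120, fs = 10,
                    trace_noise_sd = 0, drift_frac = 0,
                    network_rate_hz = 0, event_rate_hz = 0.05,
                    coactive_fraction = 0, transient_amplitude = 0.5,
                    transient_halfwidth_s = 1)
  g <- gen_traces(cfg)
  expect_gt(sum(g$truth_raster), 0)
  dff <- normalize_dff(g$traces, baseline_window_s = 40)
  pk <- detect_peaks(dff)
  expect_true(all(abs(pk$events$amplitude - 0.5) / 0.5 < 0.01))
  # amplitude 0 -> baseline + noise only
  cfg0 <- syn_config(seed = 11, n_rois = 2, duration_s = 60, fs = 2,
                     transient_amplitude = 0, drift_frac = 0,
                     trace_noise_sd = 0)
  g0 <- gen_traces(cfg0)
  expect_true(all(abs(g0$traces$traces - cfg0$baseline_f0) < 1e-9))
  # coactive_fraction 0 -> no network-locked transients
  cfgc <- syn_config(seed = 12, n_rois = 20, duration_s = 60,
                     coactive_fraction = 0)
  expect_false(any(gen_traces(cfgc)$events$network))
})

test_that("seizure cohort honors incidence and censoring", {
  cfg1 <- syn_config(cohort_sizes = c(WT = 50L), gtcs_prob = c(WT = 1))
  coh1 <- gen_seizure_cohort(cfg1)
  expect_true(all(coh1$gtcs))
  expect_true(all(coh1$gtcs_latency_s < cfg1$observation_s))
  cfg0 <- syn_config(cohort_sizes = c(WT = 50L), gtcs_prob = c(WT = 0))
  coh0 <- gen_seizure_cohort(cfg0)
  expect_true(all(!coh0$gtcs))
  expect_true(all(coh0$gtcs_latency_s == cfg0$observation_s))
  # binomial concentration at large n
  cfgB <- syn_config(seed = 5, cohort_sizes = c(DUP = 10000L),
                     gtcs_prob = c(DUP = 0.8))
  expect_lt(abs(mean(gen_seizure_cohort(cfgB)$gtcs) - 0.8), 0.01)
  # score 7 implies death
  coh <- gen_seizure_cohort(syn_config(seed = 2))
  expect_true(all(coh$died == (coh$racine_1h == 7)))
})

test_that("spectral-count table separates interactors from background", {
  cfg <- syn_config(seed = 3)
  g <- gen_spectral_counts(cfg)
  expect_equal(nrow(g$counts), cfg$n_true_interactors + cfg$n_background)
  bait <- rowMeans(g$counts[paste0("bait_", 1:3)])
  igg <- rowMeans(g$counts[paste0("igg_", 1:3)])
  is_int <- g$truth$label == "interactor"
  expect_gt(mean(bait[is_int]), 2 * mean(igg[is_int]))
  # zero-count control cells exist among true interactors
  expect_true(any(igg[is_int] == 0))
  # equal means -> all background truth
  cfg0 <- syn_config(bait_mean = 2, igg_mean = 2, n_true_interactors = 0L)
  expect_true(all(gen_spectral_counts(cfg0)$truth$label == "background"))
  expect_error(gen_spectral_counts(syn_config(bait_mean = -1)), "bait_mean")
})
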