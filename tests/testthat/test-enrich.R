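test_that("background restriction intersects sets and flags empties", {
  coll <- restrict_to_background(
    list(s1 = c("A", "B", "C"), s2 = c("X", "Y"), s3 = c("A", "B")),
    universe = c("A", "B"))
  expect_equal(coll$sets$s1, c("A", "B"))
  expect_equal(coll$sets$s3, c("A", "B"))
  expect_equal(attr(coll, "empty_sets"), "s2")
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  # paper-scale margins: fold reported as 1.9
  u <- paste0("g", 1:4447)
  query <- paste0("g", 1:208)
  target <- paste0("g", c(1:150, 1000:2532))  # overlap 150, size 1683
  e <- hypergeom_enrich(query, target, u)
  expect_equal(e$k, 150)
  expect_equal(e$fold, 150 / (208 * 1683 / 4447))
  expect_equal(round(e$fold, 1), 1.9)
  # extreme draw: k = K = n = 10 in N = 20 -> p = 1/C(20,10)
  u20 <- paste0("x", 1:20)
  e2 <- hypergeom_enrich(u20[1:10], u20[1:10], u20)
  expect_equal(e2$p, 1 / choose(20, 10), tolerance = 1e-12)
  # k exactly at expectation -> fold 1, pct 0
  e3 <- hypergeom_enrich(u20[1:10], u20[6:15], u20)
  expect_equal(e3$fold, 1)
  expect_equal(e3$pct_enrichment, 0)
  expect_error(hypergeom_enrich(character(0), u20[1:3], u20), "empty")
})

test_that("hypergeometric p equals the exhaustive oracle for N <= 20", {
  cases <- expand.grid(N = c(8, 12, 16, 20), K = c(3, 5), n = c(4, 7))
  for (i in seq_len(nrow(cases))) {
    N <- cases$N[i]; K <- cases$K[i]; n <- cases$n[i]
    u <- paste0("g", seq_len(N))
    for (k in 1:min(K, n)) {
      # build query/target realizing exactly overlap k
      target <- u[seq_len(K)]
      query <- c(u[seq_len(k)],
                 if (n > k) u[(K + 1):(K + n - k)])
      e <- hypergeom_enrich(query, target, u)
      expect_equal(e$p, oracle_hyper_upper(k, K, N, n),
                   tolerance = 1e-10,
                   info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
    }
  }
})

test_that("p is monotone decreasing in the overlap at fixed margins", {
  u <- paste0("g", 1:200)
  target <- u[1:50]
  ps <- vapply(1:30, function(k) {
    query <- c(u[seq_len(k)], u[51:(50 + 30 - k)])
    hypergeom_enrich(query, target, u)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("disease profile applies BH within direction and ranks planted sets", {
  # BH closed form
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  cfg <- syn_config(seed = 41, set_sizes = rep(100L, 4),
                    planted_enrichment_fold = c(3, 1, 1, 1))
  first <- vapply(1:100, function(s) {
    cfg$seed <- s
    g <- gen_gene_universe(cfg)
    prof <- disease_profile(g$query, character(0), g$collection,
                            alternative = "greater")
    prof$set_name[which.min(prof$p)] == "SET01"
  }, logical(1))
  expect_gte(mean(first), 0.95)
  # BH invariants on a profile run
  g <- gen_gene_universe(cfg)
  prof <- disease_profile(g$query, character(0), g$collection)
  expect_true(all(prof$p_adj >= prof$p))
  ord <- order(prof$p)
  expect_true(all(diff(prof$p_adj[ord]) >= -1e-12))
  expect_error(disease_profile(c("A", "B"), c("B"), g$collection),
               "disjoint")
})

test_that("null gene-set profiles yield uniform-ish p-values", {
  # overlap expectation ~22 keeps the discrete p lattice fine enough for
  # a meaningful KS comparison against the uniform
  cfg <- syn_config(set_sizes = 300L, planted_enrichment_fold = 1,
                    n_genes_universe = 4000L, query_size = 300L)
  ps <- vapply(1:200, function(s) {
    cfg$seed <- s
    g <- gen_gene_universe(cfg)
    hypergeom_enrich(g$query, g$collection$sets$SET01,
                     g$collection$universe)$p
  }, numeric(1))
  # discreteness makes hypergeometric p conservative; KS should still
  # not reject wildly at alpha = 0.01
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("interactome calling applies the fold and t-test rules", {
  counts <- data.frame(
    protein_id = c("called", "flat", "no_ctrl", "weak"),
    bait_1 = c(10, 3, 5, 3), bait_2 = c(12, 3, 6, 4),
    bait_3 = c(11, 3, 7, 3),
    igg_1 = c(2, 3, 0, 2), igg_2 = c(1, 3, 0, 2), igg_3 = c(2, 3, 0, 2))
  out <- call_interactome(counts)
  expect_true(out$called[out$protein_id == "called"])
  # direct check: fold 6.6 and one-tailed Welch t
  expect_equal(out$fold[1], mean(c(10, 12, 11)) / mean(c(2, 1, 2)))
  expect_equal(out$p[1],
               t.test(c(10, 12, 11), c(2, 1, 2),
                      alternative = "greater")$p.value)
  expect_false(out$called[out$protein_id == "flat"])  # fold 1
  # absent in control: fold criterion passes by convention
  expect_true(out$not_in_control[out$protein_id == "no_ctrl"])
  expect_true(out$called[out$protein_id == "no_ctrl"])
  expect_error(call_interactome(transform(counts, bait_1 = bait_1 + 0.5)),
               "integer")
})

test_that("cross-dataset overlap reports enrichment and effect correlation", {
  u <- paste0("g", 1:500)
  a <- u[1:50]; b <- u[26:75]
  ea <- setNames(rnorm(50), a)
  # identical lists give maximal fold N/K and R2 = 1
  same <- cross_dataset_overlap(a, a, u, effects_a = ea, effects_b = ea)
  expect_equal(same$enrichment$fold, 500 / 50)
  expect_equal(same$correlation$r2, 1, tolerance = 1e-12)
  # small overlap skips the correlation with a flag
  tiny <- cross_dataset_overlap(u[1:3], u[3:6], u,
                                effects_a = setNames(rnorm(3), u[1:3]),
                                effects_b = setNames(rnorm(4), u[3:6]))
  expect_equal(tiny$correlation$flag, "overlap_too_small")
  # removing planted cis-correlated locus genes drops significance
  set.seed(5)
  locus <- u[26:35]  # inside the overlap of the two lists
  eff_a <- setNames(rnorm(50), a)
  eff_b <- setNames(rnorm(50), b)
  shared <- intersect(a, b)
  eff_b[locus[locus %in% shared]] <- eff_a[locus[locus %in% shared]] * 2
  with_locus <- cross_dataset_overlap(a, b, u, eff_a, eff_b)
  without <- cross_dataset_overlap(a, b, u, eff_a, eff_b,
                                   exclude = locus)
  expect_lt(abs(without$correlation$r), abs(with_locus$correlation$r))
})

test_that("GMT round-trips and agrees with the fgsea reader", {
  sets <- list(alpha = c("A", "B", "C"), beta = c("D", "E"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_equal(back$alpha, sets$alpha)
  expect_equal(back$beta, sets$beta)
  skip_if_not_installed("fgsea")
  via_fgsea <- fgsea::gmtPathways(f)
  expect_equal(via_fgsea, setNames(sets, names(sets)),
               ignore_attr = TRUE)
})
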