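#' Synthetic-data configuration
#'
#' Builds and validates the configuration object consumed by every
#' `gen_*()` generator. Defaults reproduce the study conditions the
#' downstream modules assume: 5+5 biological replicates of ~1000 membrane
#' proteins with a 1 log2-unit planted genotype effect, a 4000-gene
#' universe with one 3-fold-enriched planted set, a scale-free interaction
#' graph with a planted hub, 10-minute recordings at 2 frames/s with
#' network events recruiting 60% of ROIs, and kainate cohorts with
#' genotype-dependent GTCS incidence.
#'
#' @param seed integer RNG seed; every generator is a pure function of
#'   `(cfg, cfg$seed)`.
#' @param n_proteins number of proteins in the quantification table.
#' @param n_replicates_per_genotype biological replicates per genotype.
#' @param effect_log2fc planted log2 fold-change applied to perturbed
#'   proteins in DUP replicates only.
#' @param frac_up,frac_down proportions of proteins planted up/down.
#' @param noise_sd replicate measurement noise, log2 units.
#' @param protein_sd between-protein spread of baseline log2 ratios.
#' @param outlier_rate per-cell probability of a gross outlier.
#' @param outlier_shift log2 magnitude of a gross outlier.
#' @param missing_rate per-cell probability that a measurement is missing.
#' @param r2_low_rate proportion of entries given a sub-0.5 peptide-fit r2.
#' @param n_genes_universe size of the gene background universe.
#' @param set_sizes integer vector of planted gene-set sizes.
#' @param query_size size of the query gene list.
#' @param planted_enrichment_fold fold enrichment (>= 1) of each set's
#'   overlap with the query over chance; recycled along `set_sizes`.
#' @param graph_n,graph_m preferential-attachment graph size parameters
#'   (`graph_m` edges added per vertex; 0 gives an edgeless base).
#' @param hub_extra_degree extra edges attached to the planted hub.
#' @param n_rois number of regions of interest (neurons).
#' @param duration_s,fs recording duration (s) and frame rate (frames/s).
#' @param transient_amplitude calcium-transient amplitude, dF/F0 units.
#' @param transient_halfwidth_s transient full width at half maximum (s).
#' @param event_rate_hz per-ROI independent transient rate (events/s).
#' @param network_rate_hz network (population) event rate (events/s).
#' @param coactive_fraction fraction of ROIs recruited per network event.
#' @param jitter_s SD of per-ROI onset jitter inside a network event (s).
#' @param baseline_f0 raw baseline fluorescence level (a.u.).
#' @param drift_frac amplitude of the slow sinusoidal baseline drift,
#'   as a fraction of `baseline_f0`.
#' @param trace_noise_sd white noise SD on traces, dF/F0 units.
#' @param cohort_sizes named integer vector of animals per genotype.
#' @param gtcs_prob named numeric vector of GTCS probabilities per
#'   genotype (names must cover `cohort_sizes`).
#' @param latency_scale_s Weibull scale of GTCS latency (s).
#' @param latency_shape Weibull shape of GTCS latency.
#' @param observation_s observation window; latencies censored here (s).
#' @param n_true_interactors,n_background spectral-count table composition.
#' @param bait_mean,igg_mean mean spectral counts for true interactors
#'   (bait arm) and for the IgG/background level.
#'
#' @return a list of class `"syn_config"`.
#' @export
syn_config <- function(seed = 1L,
                       n_proteins = 1000L,
                       n_replicates_per_genotype = 5L,
                       effect_log2fc = 1,
                       frac_up = 0.05,
                       frac_down = 0.05,
                       noise_sd = 0.2,
                       protein_sd = 1,
                       outlier_rate = 0.01,
                       outlier_shift = 5,
                       missing_rate = 0.05,
                       r2_low_rate = 0.1,
                       n_genes_universe = 4000L,
                       set_sizes = c(100L, 100L, 100L),
                       query_size = 200L,
                       planted_enrichment_fold = c(3, 1, 1),
                       graph_n = 100L,
                       graph_m = 2L,
                       hub_extra_degree = 20L,
                       n_rois = 150L,
                       duration_s = 600,
                       fs = 2,
                       transient_amplitude = 0.5,
                       transient_halfwidth_s = 1,
                       event_rate_hz = 0.01,
                       network_rate_hz = 0.05,
                       coactive_fraction = 0.6,
                       jitter_s = 0.2,
                       baseline_f0 = 100,
                       drift_frac = 0.02,
                       trace_noise_sd = 0.05,
                       cohort_sizes = c(WT = 16L, DUP = 17L),
                       gtcs_prob = c(WT = 0.44, DUP = 0.82),
                       latency_scale_s = 1800,
                       latency_shape = 2,
                       observation_s = 7200,
                       n_true_interactors = 30L,
                       n_background = 300L,
                       bait_mean = 10,
                       igg_mean = 2) {
  cfg <- as.list(environment())

  chk_count <- function(x, nm, min = 1) {
    if (length(x) < 1 || any(is.na(x)) || any(x < min) || any(x != round(x)))
      stop("syn_config: invalid '", nm, "' (expected integer >= ", min, ")",
           call. = FALSE)
  }
  chk_prop <- function(x, nm) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1))
      stop("syn_config: invalid '", nm, "' (expected proportion in [0,1])",
           call. = FALSE)
  }
  chk_pos <- function(x, nm, strict = TRUE) {
    if (any(is.na(x)) || any(if (strict) x <= 0 else x < 0))
      stop("syn_config: invalid '", nm, "' (expected ",
           if (strict) "positive" else "non-negative", ")", call. = FALSE)
  }

  chk_count(seed, "seed", min = -Inf)
  chk_count(n_proteins, "n_proteins")
  chk_count(n_replicates_per_genotype, "n_replicates_per_genotype")
  chk_count(n_genes_universe, "n_genes_universe")
  chk_count(set_sizes, "set_sizes")
  chk_count(query_size, "query_size")
  chk_count(graph_n, "graph_n", min = 3)
  chk_count(graph_m, "graph_m", min = 0)
  chk_count(hub_extra_degree, "hub_extra_degree", min = 0)
  chk_count(n_rois, "n_rois")
  chk_count(cohort_sizes, "cohort_sizes")
  for (nm in c("frac_up", "frac_down", "outlier_rate", "missing_rate",
               "r2_low_rate", "coactive_fraction", "drift_frac"))
    chk_prop(cfg[[nm]], nm)
  chk_prop(gtcs_prob, "gtcs_prob")
  if (frac_up + frac_down > 1)
    stop("syn_config: invalid 'frac_up'/'frac_down' (sum exceeds 1)",
         call. = FALSE)
  chk_pos(fs, "fs")
  chk_pos(duration_s, "duration_s")
  chk_pos(noise_sd, "noise_sd", strict = FALSE)
  chk_pos(protein_sd, "protein_sd", strict = FALSE)
  chk_pos(transient_amplitude, "transient_amplitude", strict = FALSE)
  chk_pos(transient_halfwidth_s, "transient_halfwidth_s")
  chk_pos(event_rate_hz, "event_rate_hz", strict = FALSE)
  chk_pos(network_rate_hz, "network_rate_hz", strict = FALSE)
  chk_pos(jitter_s, "jitter_s", strict = FALSE)
  chk_pos(trace_noise_sd, "trace_noise_sd", strict = FALSE)
  chk_pos(baseline_f0, "baseline_f0")
  chk_pos(latency_scale_s, "latency_scale_s")
  chk_pos(latency_shape, "latency_shape")
  chk_pos(observation_s, "observation_s")
  chk_pos(bait_mean, "bait_mean", strict = FALSE)
  chk_pos(igg_mean, "igg_mean", strict = FALSE)
  chk_count(n_true_interactors, "n_true_interactors", min = 0)
  chk_count(n_background, "n_background", min = 0)
  if (any(planted_enrichment_fold < 1) || any(is.na(planted_enrichment_fold)))
    stop("syn_config: invalid 'planted_enrichment_fold' (expected >= 1)",
         call. = FALSE)
  if (any(set_sizes > n_genes_universe))
    stop("syn_config: invalid 'set_sizes' (a set exceeds the universe)",
         call. = FALSE)
  if (is.null(names(cohort_sizes)) || is.null(names(gtcs_prob)) ||
      !all(names(cohort_sizes) %in% names(gtcs_prob)))
    stop("syn_config: invalid 'gtcs_prob' (names must cover cohort_sizes)",
         call. = FALSE)
  if (duration_s * fs < 10)
    stop("syn_config: invalid 'duration_s'/'fs' (need >= 10 frames)",
         call. = FALSE)

  structure(cfg, class = "syn_config")
}

# Fixed sub-stream offsets so later draws never reshuffle earlier ones.
.seed_offsets <- c(quant = 101L, genesets = 202L, graph = 303L,
                   traces = 404L, cohort = 505L, counts = 606L)

#' Generate a synthetic protein quantification table
#'
#' Emulates a light/heavy (14N/15N) ratio table: per-protein log2 baseline
#' ratios spread across the proteome, replicate noise, a planted genotype
#' effect restricted to DUP replicates, gross outliers, sub-threshold
#' peptide-fit r2 values, and missing cells (missing completely at random,
#' realised as absent rows).
#'
#' @param cfg a [syn_config()] object.
#' @return list with `table` (long data.frame: protein_id, replicate_id,
#'   genotype, ratio, r2) and `truth` (protein_id, label in up/down/null,
#'   true_log2fc).
#' @export
gen_quant_table <- function(cfg) {
  stopifnot(inherits(cfg, "syn_config"))
  withr::local_seed(cfg$seed + .seed_offsets[["quant"]])

  np <- cfg$n_proteins
  nr <- cfg$n_replicates_per_genotype
  proteins <- sprintf("PROT%05d", seq_len(np))
  n_up <- round(cfg$frac_up * np)
  n_down <- round(cfg$frac_down * np)
  label <- rep("null", np)
  if (n_up > 0) label[seq_len(n_up)] <- "up"
  if (n_down > 0) label[n_up + seq_len(n_down)] <- "down"
  effect <- ifelse(label == "up", cfg$effect_log2fc,
                   ifelse(label == "down", -cfg$effect_log2fc, 0))

  reps <- c(sprintf("WT_%d", seq_len(nr)), sprintf("DUP_%d", seq_len(nr)))
  geno <- rep(c("WT", "DUP"), each = nr)

  baseline <- stats::rnorm(np, 0, cfg$protein_sd)
  tab <- expand.grid(protein_id = proteins, replicate_id = reps,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$genotype <- geno[match(tab$replicate_id, reps)]
  l2 <- baseline[match(tab$protein_id, proteins)] +
    ifelse(tab$genotype == "DUP", effect[match(tab$protein_id, proteins)], 0) +
    stats::rnorm(nrow(tab), 0, cfg$noise_sd)
  out <- stats::runif(nrow(tab)) < cfg$outlier_rate
  l2[out] <- l2[out] + sample(c(-1, 1), sum(out), TRUE) * cfg$outlier_shift
  tab$ratio <- 2^l2
  tab$r2 <- stats::runif(nrow(tab), 0.5, 1)
  low <- stats::runif(nrow(tab)) < cfg$r2_low_rate
  tab$r2[low] <- stats::runif(sum(low), 0, 0.5)
  tab <- tab[stats::runif(nrow(tab)) >= cfg$missing_rate, , drop = FALSE]
  rownames(tab) <- NULL

  list(table = tab,
       truth = data.frame(protein_id = proteins, label = label,
                          true_log2fc = effect, stringsAsFactors = FALSE))
}

#' Generate a gene universe with planted query-set enrichment
#'
#' Builds disjoint gene sets over a universe and a query list whose
#' expected overlap with set `j` is `planted_enrichment_fold[j]` times the
#' chance expectation `query_size * K_j / N`. In-set membership of query
#' genes is Bernoulli with probability `fold_j * query_size / N`; the
#' remaining query genes are drawn uniformly outside all sets, so the
#' planted expectation is exact.
#'
#' @param cfg a [syn_config()] object.
#' @return list with `collection` (a [gene_set_collection()]), `query`
#'   (character vector) and `truth` (set, size, fold, expected_overlap,
#'   realized_overlap).
#' @export
gen_gene_universe <- function(cfg) {
  stopifnot(inherits(cfg, "syn_config"))
  withr::local_seed(cfg$seed + .seed_offsets[["genesets"]])

  N <- cfg$n_genes_universe
  sizes <- as.integer(cfg$set_sizes)
  folds <- rep_len(cfg$planted_enrichment_fold, length(sizes))
  if (sum(sizes) > N)
    stop("gen_gene_universe: set sizes exceed the universe", call. = FALSE)
  if (any(folds * cfg$query_size > N))
    stop("gen_gene_universe: infeasible planted_enrichment_fold ",
         "(required overlap exceeds set size)", call. = FALSE)

  universe <- sprintf("G%05d", seq_len(N))
  pool <- sample(universe)
  sets <- list()
  at <- 0L
  for (j in seq_along(sizes)) {
    sets[[sprintf("SET%02d", j)]] <- sort(pool[at + seq_len(sizes[j])])
    at <- at + sizes[j]
  }
  outside <- pool[(at + 1L):N]

  query <- character(0)
  for (j in seq_along(sizes)) {
    p_in <- folds[j] * cfg$query_size / N
    hit <- stats::runif(sizes[j]) < p_in
    query <- c(query, sets[[j]][hit])
  }
  n_fill <- max(0L, cfg$query_size - length(query))
  query <- c(query, sample(outside, min(n_fill, length(outside))))

  truth <- data.frame(
    set = names(sets), size = sizes, fold = folds,
    expected_overlap = folds * sizes * cfg$query_size / N,
    realized_overlap = vapply(sets, function(s)
      length(intersect(s, query)), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  list(collection = gene_set_collection(sets, universe),
       query = query, truth = truth)
}

#' Generate a scale-free interaction graph with a planted hub
#'
#' A preferential-attachment (Barabasi-Albert) base graph (`graph_m` edges
#' per new vertex; 0 gives an edgeless base) plus `hub_extra_degree`
#' additional edges from one designated hub to distinct non-neighbours.
#' No self-loops or multi-edges.
#'
#' @param cfg a [syn_config()] object.
#' @return list with `graph` (igraph, vertex names "P####") and `hub`
#'   (name of the planted hub).
#' @export
gen_ppi_graph <- function(cfg) {
  stopifnot(inherits(cfg, "syn_config"))
  withr::local_seed(cfg$seed + .seed_offsets[["graph"]])

  n <- cfg$graph_n
  g <- if (cfg$graph_m >= 1) {
    igraph::sample_pa(n, m = cfg$graph_m, directed = FALSE)
  } else {
    igraph::make_empty_graph(n, directed = FALSE)
  }
  igraph::V(g)$name <- sprintf("P%04d", seq_len(n))
  # plant the hub on the node that already leads the degree distribution
  # so the extra edges reinforce, not fight, the scale-free tail
  hub <- igraph::V(g)$name[which.max(igraph::degree(g))]
  nbr <- igraph::V(g)$name[as.integer(
    igraph::neighbors(g, hub))]
  candidates <- setdiff(igraph::V(g)$name, c(hub, nbr))
  extra <- min(cfg$hub_extra_degree, length(candidates))
  if (extra > 0) {
    new <- sample(candidates, extra)
    g <- igraph::add_edges(g, as.vector(rbind(hub, new)))
  }
  g <- igraph::simplify(g)
  list(graph = g, hub = hub)
}

# Instantaneous-rise, exponential-decay transient whose width at half
# maximum equals halfwidth_s: tau = halfwidth_s / ln 2.
.transient_template <- function(n_frames, onset_frame, amplitude,
                                halfwidth_s, fs) {
  tau <- halfwidth_s / log(2)
  t <- (seq_len(n_frames) - onset_frame) / fs
  y <- numeric(n_frames)
  on <- t >= 0
  y[on] <- amplitude * exp(-t[on] / tau)
  y
}

#' Generate synthetic fluorescence traces with planted network events
#'
#' Raw traces are `F0(t) * (1 + dFF(t) + noise)` where `F0(t)` is a
#' constant baseline with a slow sinusoidal drift and `dFF(t)` sums
#' instantaneous-rise/exponential-decay transients (FWHM =
#' `transient_halfwidth_s`). Network events occur as a Poisson process at
#' `network_rate_hz`, each recruiting `ceiling(coactive_fraction*n_rois)`
#' ROIs with Gaussian onset jitter; each ROI additionally fires
#' independent transients at `event_rate_hz`. Per-ROI RNG sub-streams are
#' derived by fixed offsets, so adding ROIs does not reshuffle the draws
#' of earlier ones.
#'
#' @param cfg a [syn_config()] object.
#' @return list with `traces` (a raw [trace_matrix()]), `truth_raster`
#'   (binary ROI x frame matrix of planted transient onsets),
#'   `network_event_frames` (integer vector) and `events` (data.frame
#'   roi, frame, network flag).
#' @export
gen_traces <- function(cfg) {
  stopifnot(inherits(cfg, "syn_config"))
  if (cfg$fs <= 0) stop("gen_traces: fs must be positive", call. = FALSE)
  n_frames <- round(cfg$duration_s * cfg$fs)
  if (n_frames < 10)
    stop("gen_traces: need at least 10 frames", call. = FALSE)
  n_rois <- cfg$n_rois
  base_seed <- cfg$seed + .seed_offsets[["traces"]]

  # network schedule on its own stream
  withr::with_seed(base_seed, {
    n_net <- stats::rpois(1, cfg$network_rate_hz * cfg$duration_s)
    net_frames <- sort(sample.int(n_frames, min(n_net, n_frames)))
    n_recruit <- ceiling(cfg$coactive_fraction * n_rois)
    recruits <- lapply(net_frames, function(f)
      if (n_recruit > 0) sample.int(n_rois, n_recruit) else integer(0))
  })

  traces <- matrix(0, n_rois, n_frames)
  raster <- matrix(0L, n_rois, n_frames)
  ev_roi <- list()
  tt <- seq_len(n_frames) / cfg$fs
  for (r in seq_len(n_rois)) {
    withr::with_seed(base_seed + 1000L + r, {
      onsets <- integer(0)
      is_net <- logical(0)
      for (j in seq_along(net_frames)) {
        if (r %in% recruits[[j]]) {
          f <- net_frames[j] +
            round(stats::rnorm(1, 0, cfg$jitter_s) * cfg$fs)
          if (f >= 1 && f <= n_frames) {
            onsets <- c(onsets, f); is_net <- c(is_net, TRUE)
          }
        }
      }
      n_ind <- stats::rpois(1, cfg$event_rate_hz * cfg$duration_s)
      if (n_ind > 0) {
        fi <- sample.int(n_frames, min(n_ind, n_frames))
        onsets <- c(onsets, fi); is_net <- c(is_net, rep(FALSE, length(fi)))
      }
      dff <- numeric(n_frames)
      for (f in onsets)
        dff <- dff + .transient_template(n_frames, f, cfg$transient_amplitude,
                                         cfg$transient_halfwidth_s, cfg$fs)
      noise <- stats::rnorm(n_frames, 0, cfg$trace_noise_sd)
      phase <- stats::runif(1, 0, 2 * pi)
      f0 <- cfg$baseline_f0 *
        (1 + cfg$drift_frac * sin(2 * pi * tt / cfg$duration_s + phase))
      traces[r, ] <- f0 * (1 + dff + noise)
      raster[r, onsets] <- 1L
      if (length(onsets))
        ev_roi[[length(ev_roi) + 1L]] <-
          data.frame(roi = r, frame = onsets, network = is_net)
    })
  }
  events <- if (length(ev_roi)) do.call(rbind, ev_roi) else
    data.frame(roi = integer(0), frame = integer(0), network = logical(0))

  list(traces = trace_matrix(traces, cfg$fs, kind = "calcium_culture"),
       truth_raster = raster,
       network_event_frames = net_frames,
       events = events)
}

#' Generate a synthetic seizure cohort
#'
#' Per animal: GTCS ~ Bernoulli(`gtcs_prob[genotype]`); GTCS latency drawn
#' from a Weibull (shape `latency_shape`) truncated to the observation
#' window; animals without GTCS are censored at `observation_s`. Racine
#' scores (1-7) are tied to GTCS status (6-7 with GTCS, 1-5 without) and
#' score 7 implies death.
#'
#' @param cfg a [syn_config()] object.
#' @return data.frame: id, genotype, gtcs, gtcs_latency_s, gtcs_observed,
#'   racine_1h, died, death_time_s.
#' @export
gen_seizure_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "syn_config"))
  withr::local_seed(cfg$seed + .seed_offsets[["cohort"]])

  rows <- list()
  for (g in names(cfg$cohort_sizes)) {
    n <- cfg$cohort_sizes[[g]]
    p <- cfg$gtcs_prob[[g]]
    gtcs <- stats::runif(n) < p
    # truncated Weibull via inverse CDF
    pmax_ <- stats::pweibull(cfg$observation_s, cfg$latency_shape,
                             cfg$latency_scale_s)
    lat <- ifelse(gtcs,
                  stats::qweibull(stats::runif(n, 0, pmax_),
                                  cfg$latency_shape, cfg$latency_scale_s),
                  cfg$observation_s)
    racine <- ifelse(gtcs, sample(6:7, n, TRUE, prob = c(0.5, 0.5)),
                     sample(1:5, n, TRUE))
    died <- racine == 7
    death <- ifelse(died, pmin(lat + stats::rexp(n, 1 / 600),
                               cfg$observation_s - 1),
                    cfg$observation_s)
    rows[[g]] <- data.frame(
      id = sprintf("%s_%03d", g, seq_len(n)), genotype = g,
      gtcs = gtcs, gtcs_latency_s = lat, gtcs_observed = gtcs,
      racine_1h = racine, died = died, death_time_s = death,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic bait-vs-IgG spectral-count table
#'
#' True interactors receive Poisson bait counts with mean at least twice
#' the IgG mean (per-protein bait means uniform in `[2, 8] * igg_mean`,
#' or `[2, 8] * bait_mean/2` when `igg_mean = 0`); a third of true
#' interactors have IgG mean 0 (absent in control). Background proteins
#' have equal means in both arms. Three replicates per arm.
#'
#' @param cfg a [syn_config()] object.
#' @return list with `counts` (data.frame protein_id, bait_1..3,
#'   igg_1..3) and `truth` (protein_id, label in interactor/background).
#' @export
gen_spectral_counts <- function(cfg) {
  stopifnot(inherits(cfg, "syn_config"))
  if (cfg$bait_mean < 0 || cfg$igg_mean < 0)
    stop("gen_spectral_counts: negative means", call. = FALSE)
  withr::local_seed(cfg$seed + .seed_offsets[["counts"]])

  nt <- cfg$n_true_interactors
  nb <- cfg$n_background
  n <- nt + nb
  ids <- sprintf("INT%04d", seq_len(n))
  label <- c(rep("interactor", nt), rep("background", nb))

  ref <- if (cfg$igg_mean > 0) cfg$igg_mean else cfg$bait_mean / 2
  bait_mu <- c(stats::runif(nt, 2, 8) * ref, rep(cfg$igg_mean, nb))
  igg_mu <- c(rep(cfg$igg_mean, nt), rep(cfg$igg_mean, nb))
  if (nt > 0) {
    zero_ctrl <- seq_len(nt) <= ceiling(nt / 3)
    igg_mu[seq_len(nt)][zero_ctrl] <- 0
  }

  bait <- matrix(stats::rpois(3 * n, rep(bait_mu, each = 3)), n, 3,
                 byrow = TRUE)
  igg <- matrix(stats::rpois(3 * n, rep(igg_mu, each = 3)), n, 3,
                byrow = TRUE)
  counts <- data.frame(protein_id = ids, bait, igg,
                       stringsAsFactors = FALSE)
  names(counts) <- c("protein_id", paste0("bait_", 1:3),
                     paste0("igg_", 1:3))
  list(counts = counts,
       truth = data.frame(protein_id = ids, label = label,
                          stringsAsFactors = FALSE))
}
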