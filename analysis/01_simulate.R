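#!/usr/bin/env Rscript
# Generates every synthetic input used by the downstream analyses under
# one seed, and writes them (plus the planted ground truth) to results/.
# The defaults of syn_config() encode the study conditions: 5+5
# biological replicates of ~1000 membrane proteins, a 4000-gene universe
# with one 3-fold-enriched planted set, a scale-free interaction graph
# with a reinforced hub, 10-minute recordings at 2 frames/s, and
# WT/DUP kainate cohorts at 44%/82% GTCS incidence.

suppressMessages(library(membranet))
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)
cfg <- syn_config(seed = 20260919L)

quant <- gen_quant_table(cfg)
write.csv(quant$table, "results/sim/quant_table.csv", row.names = FALSE)
write.csv(quant$truth, "results/sim/quant_truth.csv", row.names = FALSE)

genes <- gen_gene_universe(cfg)
write_gmt(genes$collection$sets, "results/sim/gene_sets.gmt")
writeLines(genes$collection$universe, "results/sim/universe.txt")
writeLines(genes$query, "results/sim/query_genes.txt")
write.csv(genes$truth, "results/sim/geneset_truth.csv", row.names = FALSE)

ppi <- gen_ppi_graph(cfg)
el <- igraph::as_data_frame(ppi$graph, "edges")
write_sif(data.frame(from = el$from, to = el$to),
          "results/sim/ppi_edges.sif")
writeLines(ppi$hub, "results/sim/planted_hub.txt")

traces <- gen_traces(cfg)
write_traces_csv(traces$traces, "results/sim/traces.csv")
write.csv(traces$events, "results/sim/trace_truth_events.csv",
          row.names = FALSE)
writeLines(as.character(traces$network_event_frames),
           "results/sim/network_event_frames.txt")

cohort <- gen_seizure_cohort(cfg)
write.csv(cohort, "results/sim/seizure_cohort.csv", row.names = FALSE)

counts <- gen_spectral_counts(cfg)
write.csv(counts$counts, "results/sim/spectral_counts.csv",
          row.names = FALSE)
write.csv(counts$truth, "results/sim/interactor_truth.csv",
          row.names = FALSE)

cat("Simulated inputs written to results/sim/:\n")
cat(sprintf("  %d quantification rows, %d genes, %d-node graph,\n",
            nrow(quant$table), cfg$n_genes_universe,
            igraph::vcount(ppi$graph)))
cat(sprintf("  %d ROIs x %d frames, %d animals, %d bait/IgG proteins\n",
            nrow(traces$traces$traces), ncol(traces$traces$traces),
            nrow(cohort), nrow(counts$counts)))
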