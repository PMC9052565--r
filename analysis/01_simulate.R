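#!/usr/bin/env Rscript
# Step 1: simulate the default synthetic CRPC cohort.
#
# Generates one 660-patient cohort (seed 1) from the calibrated default
# configuration, together with its planted dependency graph and variable
# dictionary, and writes the baseline/outcome summary — the cohort-level
# table the downstream network and survival analyses start from.
#
# Outputs (results/):
#   cohort.csv, cohort_dictionary.json  - the simulated registry table
#   planted_graph.tsv / .graphml        - ground-truth dependency edges
#   cohort_summary_*.tsv                - marginal summaries (the twin of
#                                         a baseline-characteristics table)

suppressPackageStartupMessages(library(crpcnet))

dir.create("results", showWarnings = FALSE)
cfg <- default_config()
sim <- generate_cohort(cfg, seed = 1)

write_cohort(sim$cohort, sim$dictionary, "results/cohort.csv")
write_planted_graph(sim$graph, "results/planted_graph")

s <- summarize_cohort(sim$cohort)
utils::write.table(s$continuous, "results/cohort_summary_continuous.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
utils::write.table(s$binary, "results/cohort_summary_binary.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
utils::write.table(s$km, "results/cohort_summary_km.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)

cat("cohort:", nrow(sim$cohort), "patients,",
    ncol(sim$cohort), "columns;", nrow(sim$graph), "planted edges\n")
cat(sprintf("KM median OS %s days, TTF %s days\n",
            s$km$median[s$km$endpoint == "OS"],
            s$km$median[s$km$endpoint == "TTF"]))
cat(sprintf("neutropenia %.1f%%, grade>=3 %.1f%%, febrile %.1f%%\n",
            s$binary$percent[s$binary$variable == "neutropenia"],
            s$binary$percent[s$binary$variable == "grade3_neutropenia"],
            s$binary$percent[s$binary$variable == "febrile_neutropenia"]))
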