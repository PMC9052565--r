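#!/usr/bin/env Rscript
# Step 3: seven-model consensus clustering of the association networks.
#
# Builds the association graph (stability frequency > 0.5, weights =
# frequencies) for each alpha level from step 2, partitions it with the
# seven community-detection models, counts factor-response
# co-clusterings, and reports the factors associated with OS / TTF in at
# least four of the seven models together with the positive-causality
# call (>= 80% positive direction across the stable tests).

suppressPackageStartupMessages(library(crpcnet))
suppressPackageStartupMessages(library(igraph))

ccfg <- consensus_config(min_models = 4, causality_threshold = 0.8,
                         seed = 11)

for (tag in c("005", "001")) {
  st <- utils::read.delim(sprintf("results/stability_a%s.tsv", tag))
  keep <- st[st$frequency > 0.5, ]
  if (nrow(keep) == 0) { cat("alpha", tag, ": empty graph, skipped\n"); next }
  g <- graph_from_data_frame(
    data.frame(from = keep$var1, to = keep$var2, weight = keep$frequency),
    directed = FALSE)
  parts <- partition_all(g, ccfg)
  responses <- intersect(c("OS", "TTF"), V(g)$name)
  factors <- V(g)$name # a response may appear as a factor for the other
  tab <- cocluster_counts(parts, factors, responses)
  utils::write.table(tab, sprintf("results/consensus_a%s.tsv", tag),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  assoc <- consensus_factors(tab, ccfg)
  # attach the causality call for pairs that are themselves stable edges
  key <- paste(pmin(keep$var1, keep$var2), pmax(keep$var1, keep$var2))
  akey <- paste(pmin(assoc$factor, assoc$response),
                pmax(assoc$factor, assoc$response))
  hit <- match(akey, key)
  assoc$causality <- ""
  ok <- !is.na(hit)
  if (any(ok))
    assoc$causality[ok] <- causality_call(keep$positive_fraction[hit[ok]],
                                          ccfg)
  utils::write.table(assoc, sprintf("results/associated_a%s.tsv", tag),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cat("alpha", tag, ": graph", vcount(g), "nodes /", ecount(g),
      "edges;", nrow(assoc), "consensus factor-response pairs\n")
  print(assoc, row.names = FALSE)
}
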