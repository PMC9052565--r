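#' Consensus configuration for the network-clustering stage
#'
#' @param min_models Minimum number of the seven clustering models that
#'   must co-cluster a factor with a response for it to be reported
#'   associated. The default 4 follows the reported result tables (which
#'   list count-4 factors as findings); set 5 for a strict
#'   "more than four" reading.
#' @param causality_threshold A factor-response association is judged
#'   positive when its positive-direction frequency is at least this
#'   value (inclusive boundary).
#' @param seed Seed for the stochastic clustering models.
#' @return A `consensus_config` list.
#' @export
consensus_config <- function(min_models = 4L, causality_threshold = 0.8,
                             seed = 1L) {
  stopifnot(min_models >= 1, min_models <= 7,
            causality_threshold > 0, causality_threshold <= 1)
  structure(list(min_models = as.integer(min_models),
                 causality_threshold = causality_threshold,
                 seed = as.integer(seed)),
            class = "consensus_config")
}

#' Association graph from a stability result
#'
#' Nodes are all variables incident to at least one retained edge; edges
#' are the pairs with stability frequency strictly above 0.5, weighted by
#' that frequency.
#'
#' @param result A `stability_result`.
#' @param config The [analysis_config()] of the run (used for metadata).
#' @return An [igraph][igraph::igraph-package] undirected weighted graph;
#'   empty (zero nodes, with a warning) when no edge survives.
#' @export
build_association_graph <- function(result, config = NULL) {
  stopifnot(inherits(result, "stability_result"))
  freq <- result$selection_count / result$B
  keep <- which(freq > 0.5 & upper.tri(freq), arr.ind = TRUE)
  if (nrow(keep) == 0) {
    warning("no edge exceeds stability frequency 0.5; graph is empty")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  nodes <- result$nodes
  el <- data.frame(from = nodes[keep[, 1L]], to = nodes[keep[, 2L]],
                   weight = freq[keep], stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(el, directed = FALSE)
}

#' Names of the seven consensus clustering models
#'
#' The descriptive model names used in the clinical machine-learning
#' literature, mapped in [partition_all()] onto the canonical igraph
#' community-detection algorithms.
#'
#' @return Character vector of length 7.
#' @export
consensus_model_names <- function() {
  c("edge_betweenness", "leading_eigenvector", "fast_greedy",
    "louvain", "label_propagation", "walktrap", "infomap")
}

#' Partition an association graph with seven clustering models
#'
#' Applies the seven classical community-detection algorithms — edge
#' betweenness, leading eigenvector, fast-greedy modularity, Louvain
#' (fast unfolding), label propagation, walktrap (random walks) and
#' infomap (map equation) — to the weighted graph. Edge weights enter
#' every model as affinities (for stability frequencies in (0.5, 1] the
#' distance distortion inside edge betweenness is immaterial, and using
#' one weight vector keeps its maximum-modularity cut consistent).
#' Dendrogram-producing models (edge betweenness, fast greedy, walktrap)
#' are cut explicitly at maximum modularity. Node order
#' is canonicalised lexicographically and the stochastic models are
#' seeded from `config$seed`, so results are reproducible and invariant
#' to input node order. A model that fails on a degenerate graph falls
#' back to the connected-component partition, with a note.
#'
#' @param graph An undirected weighted igraph graph.
#' @param config A [consensus_config()].
#' @return A named list of seven integer membership vectors (one per
#'   model, names = node names), with attribute `"notes"` logging any
#'   fallbacks.
#' @export
partition_all <- function(graph, config = consensus_config()) {
  if (igraph::vcount(graph) == 0) stop("cannot partition an empty graph")
  # canonical lexicographic node order
  g <- igraph::permute(graph, match(igraph::V(graph)$name,
                                    sort(igraph::V(graph)$name)))
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  models <- list(
    edge_betweenness = function()
      igraph::cluster_edge_betweenness(g, weights = w),
    leading_eigenvector = function()
      igraph::cluster_leading_eigen(g, weights = w),
    fast_greedy = function() igraph::cluster_fast_greedy(g, weights = w),
    louvain = function() igraph::cluster_louvain(g, weights = w),
    label_propagation = function()
      igraph::cluster_label_prop(g, weights = w),
    walktrap = function() igraph::cluster_walktrap(g, weights = w),
    infomap = function() igraph::cluster_infomap(g, e.weights = w)
  )
  notes <- character()
  out <- vector("list", length(models))
  names(out) <- names(models)
  for (k in seq_along(models)) {
    set.seed(config$seed + k)
    cm <- tryCatch(suppressWarnings(models[[k]]()), error = function(e) e)
    if (inherits(cm, "error")) {
      notes <- c(notes, sprintf(
        "%s failed (%s); using connected components", names(models)[k],
        conditionMessage(cm)))
      memb <- igraph::components(g)$membership
    } else if (names(models)[k] %in%
                 c("edge_betweenness", "fast_greedy", "walktrap")) {
      # dendrogram-producing model: cut explicitly at maximum modularity
      memb <- igraph::cut_at(cm, steps = which.max(cm$modularity) - 1L)
    } else {
      memb <- igraph::membership(cm)
    }
    memb <- as.integer(memb)
    names(memb) <- igraph::V(g)$name
    out[[k]] <- memb
  }
  attr(out, "notes") <- notes
  out
}

#' Co-clustering counts of factors with response variables
#'
#' For each (factor, response) pair, the number of the seven partitions
#' in which the two share a community. A factor or response absent from
#' the graph contributes count 0 (noted).
#'
#' @param partitions A list of membership vectors from [partition_all()].
#' @param factors Character vector of factor (explanatory) node names.
#' @param responses Character vector of response node names.
#' @return A `consensus_table` data frame: `factor`, `response`, `count`
#'   (0..number of partitions), with attribute `"notes"`.
#' @export
cocluster_counts <- function(partitions, factors, responses) {
  stopifnot(length(partitions) >= 1)
  nodes <- names(partitions[[1L]])
  notes <- character()
  absent <- setdiff(c(factors, responses), nodes)
  if (length(absent))
    notes <- c(notes, paste("absent from graph:",
                            paste(absent, collapse = ", ")))
  grid <- expand.grid(factor = factors, response = responses,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$factor != grid$response, ]
  grid$count <- vapply(seq_len(nrow(grid)), function(r) {
    f <- grid$factor[r]; y <- grid$response[r]
    if (!(f %in% nodes) || !(y %in% nodes)) return(0L)
    sum(vapply(partitions, function(m) m[[f]] == m[[y]], logical(1)))
  }, integer(1))
  rownames(grid) <- NULL
  attr(grid, "notes") <- notes
  class(grid) <- c("consensus_table", "data.frame")
  grid
}

#' Factors associated with each response by the consensus vote
#'
#' A factor is reported associated with a response when it co-clusters
#' with it in at least `config$min_models` of the seven models. Output is
#' ordered by count (descending) then factor name.
#'
#' @param table A `consensus_table` from [cocluster_counts()].
#' @param config A [consensus_config()].
#' @return A data frame `response`, `factor`, `count`, restricted to the
#'   associated pairs.
#' @export
consensus_factors <- function(table, config = consensus_config()) {
  out <- table[table$count >= config$min_models, , drop = FALSE]
  out <- out[order(out$response, -out$count, out$factor), ]
  out <- data.frame(response = out$response, factor = out$factor,
                    count = out$count, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Causality call from a positive-direction frequency
#'
#' @param positive_frequency Fraction in `[0, 1]` of tests in which the
#'   association was positive.
#' @param config A [consensus_config()]; the boundary
#'   `causality_threshold` is inclusive.
#' @return `"positive"` or `"not-positive"`.
#' @export
causality_call <- function(positive_frequency,
                           config = consensus_config()) {
  stopifnot(all(positive_frequency >= 0), all(positive_frequency <= 1))
  ifelse(positive_frequency >= config$causality_threshold,
         "positive", "not-positive")
}
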