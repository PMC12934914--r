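#' Node centrality table for a partial-correlation network
#'
#' Computes the four standard psychometric-network centrality metrics:
#' strength (sum of absolute edge weights), expected influence (sum of signed
#' edge weights), harmonic closeness, and shortest-path betweenness, the
#' latter two on the distance transform `1/|w|` (the qgraph convention) with
#' fractional credit for tied geodesics. Harmonic closeness (sum of
#' reciprocal distances) keeps disconnected graphs well-defined: isolated
#' nodes score 0. Each metric is also standardized as its proportional
#' deviation (%) from the network mean; deviations are `NA` when the mean of
#' a metric is 0 (the standardization is undefined there).
#'
#' @param net a `ggm_network` with at least 2 nodes.
#' @return object of class `centrality_table`: data frame with one row per
#'   node and columns `node`, `strength`, `expected_influence`, `closeness`,
#'   `betweenness` plus `<metric>_dev` percentage columns.
#' @export
centrality <- function(net) {
  W <- net$weights
  p <- nrow(W)
  if (p < 2) stop("centrality needs at least 2 nodes")
  strength <- rowSums(abs(W))
  ei <- rowSums(W)
  if (all(W == 0)) {
    closeness <- betweenness <- rep(0, p)
  } else {
    A <- abs(W)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    d <- 1 / igraph::E(g)$weight
    closeness <- igraph::harmonic_centrality(g, weights = d,
                                             normalized = FALSE)
    betweenness <- igraph::betweenness(g, weights = d, directed = FALSE)
  }
  dev <- function(v) {
    m <- mean(v)
    if (abs(m) < 1e-12) rep(NA_real_, length(v)) else 100 * (v - m) / m
  }
  out <- data.frame(
    node = net$nodes,
    strength = strength, expected_influence = ei,
    closeness = as.numeric(closeness), betweenness = as.numeric(betweenness),
    strength_dev = dev(strength), expected_influence_dev = dev(ei),
    closeness_dev = dev(as.numeric(closeness)),
    betweenness_dev = dev(as.numeric(betweenness)),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("centrality_table", "data.frame")
  attr(out, "distance") <- "1/|w|"
  attr(out, "closeness_form") <- "harmonic"
  out
}

#' Proportional deviation from the mean, in percent
#'
#' The standardization used to report centrality: `100 * (v - mean) / mean`.
#'
#' @param values numeric vector with nonzero mean.
#' @return percentages averaging exactly 0 across the input.
#' @export
proportional_deviation <- function(values) {
  m <- mean(values)
  if (abs(m) < .Machine$double.eps * 100)
    stop("proportional deviation is undefined for values with zero mean")
  100 * (values - m) / m
}

#' Edges bridging the suicidal-ideation node
#'
#' Extracts every edge incident to the `SUI` node of a suicide-augmented
#' network, attaches bootstrap confidence intervals, and flags the
#' FDR-significant bridges. The FDR correction is applied within the family
#' of suicide-incident edges (the edges under evaluation here), so the
#' reported `p_fdr` can be smaller than the whole-network `p_fdr` of
#' [bootstrap_edge_ci()].
#'
#' @param net a `ggm_network` containing a `SUI` node.
#' @param inference optional `edge_inference` from [bootstrap_edge_ci()] run
#'   on the same node set.
#' @param alpha FDR significance level for flagging (default 0.05).
#' @return object of class `bridge_report`: data frame with columns `target`,
#'   `weight`, `lower`, `upper`, `p_fdr`, `significant`, ordered by
#'   decreasing absolute weight.
#' @export
bridge_report <- function(net, inference = NULL, alpha = 0.05) {
  if (!("SUI" %in% net$nodes))
    stop("network has no SUI node; bridge report undefined")
  others <- setdiff(net$nodes, "SUI")
  out <- data.frame(target = others,
                    weight = net$weights[others, "SUI"],
                    lower = NA_real_, upper = NA_real_, p_fdr = NA_real_,
                    significant = NA, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!is.null(inference)) {
    hit <- inference$node_a == "SUI" | inference$node_b == "SUI"
    inf_sui <- inference[hit, , drop = FALSE]
    inf_sui$target <- ifelse(inf_sui$node_a == "SUI", inf_sui$node_b,
                             inf_sui$node_a)
    inf_sui$p_fdr_family <- stats::p.adjust(inf_sui$p_raw, method = "BH")
    m <- match(out$target, inf_sui$target)
    out$lower <- inf_sui$lower[m]
    out$upper <- inf_sui$upper[m]
    out$p_fdr <- inf_sui$p_fdr_family[m]
    out$significant <- !is.na(out$p_fdr) & out$p_fdr < alpha
  }
  out <- out[order(-abs(out$weight)), ]
  row.names(out) <- NULL
  class(out) <- c("bridge_report", "data.frame")
  out
}

#' Convergent-evidence ranking of candidate intervention domains
#'
#' Makes the narrative notion of "convergent network evidence" reproducible:
#' each domain scores one point per member item whose strength or expected
#' influence sits above the network average, two points for an
#' FDR-significant bridge from the domain's summary node to the ideation
#' node (bridge significance is the strongest evidence, so it counts double),
#' and one point for a positive bridge edge sign. Ties are broken
#' alphabetically.
#'
#' @param item_centrality `centrality_table` of the item-level network.
#' @param cluster_centrality `centrality_table` of the cluster-level network
#'   (reported in the evidence columns for audit).
#' @param bridge a `bridge_report` from the cluster-level suicide network.
#' @param catalog an `item_catalog`.
#' @return data frame with one row per domain: `domain`, `score`, `rank`, and
#'   the evidence columns `n_items_above_avg`, `bridge_significant`,
#'   `bridge_positive`, `bridge_weight`, `cluster_strength_dev`.
#' @export
select_targets <- function(item_centrality, cluster_centrality, bridge,
                           catalog = panss_catalog()) {
  domains <- sort(unique(catalog$domain_of))
  rows <- lapply(domains, function(d) {
    mem <- domain_items(catalog, d)
    ic <- item_centrality[item_centrality$node %in% mem, ]
    above <- (!is.na(ic$strength_dev) & ic$strength_dev > 0) |
      (!is.na(ic$expected_influence_dev) & ic$expected_influence_dev > 0)
    b <- bridge[bridge$target == d, ]
    bsig <- nrow(b) == 1 && isTRUE(b$significant)
    bpos <- nrow(b) == 1 && b$weight > 0
    bw <- if (nrow(b) == 1) b$weight else NA_real_
    cs <- cluster_centrality$strength_dev[cluster_centrality$node == d]
    data.frame(domain = d,
               score = sum(above) + 2 * bsig + bpos,
               n_items_above_avg = sum(above),
               bridge_significant = bsig, bridge_positive = bpos,
               bridge_weight = bw,
               cluster_strength_dev = if (length(cs)) cs else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$domain), ]
  out$rank <- seq_len(nrow(out))
  row.names(out) <- NULL
  out
}
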