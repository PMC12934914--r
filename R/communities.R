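#' Walktrap community detection on an estimated network
#'
#' Random-walk (walktrap) community detection on the graph weighted by
#' absolute partial correlations, the detection step of exploratory graph
#' analysis. Isolated nodes become singleton communities. When a catalog is
#' supplied, each community is labeled by the modal domain of its member
#' items.
#'
#' @param net a `ggm_network`.
#' @param steps walktrap random-walk length (default 4).
#' @param catalog optional `item_catalog` used to label communities.
#' @return object of class `community_partition`: list with `assignment`
#'   (named integer vector, item to community id), `labels` (community id to
#'   domain label; generic `C<k>` labels if no catalog is given), and
#'   `modularity` of the partition on the absolute-weight graph.
#' @export
detect_communities <- function(net, steps = 4, catalog = NULL) {
  W <- abs(net$weights)
  if (all(W == 0))
    stop("no edges; communities undefined")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  deg <- igraph::degree(g)
  isolated <- which(deg == 0)
  gc <- if (length(isolated)) igraph::delete_vertices(g, isolated) else g
  wt <- igraph::cluster_walktrap(gc, weights = igraph::E(gc)$weight,
                                 steps = steps)
  member <- integer(length(net$nodes))
  names(member) <- net$nodes
  member[match(igraph::V(gc)$name, net$nodes)] <-
    as.integer(igraph::membership(wt))
  k <- max(member)
  for (v in isolated) {
    k <- k + 1L
    member[v] <- k
  }
  mod <- igraph::modularity(g, member, weights = igraph::E(g)$weight)
  labels <- label_communities(member, catalog)
  structure(list(assignment = member, labels = labels, modularity = mod),
            class = "community_partition")
}

# Label communities by the modal domain among member items (ties and repeats
# disambiguated by suffixing); nodes outside the catalog (e.g. SUI) are
# ignored for labeling.
label_communities <- function(member, catalog) {
  ids <- sort(unique(member))
  if (is.null(catalog))
    return(stats::setNames(paste0("C", seq_along(ids)), ids))
  labels <- character(length(ids))
  for (i in seq_along(ids)) {
    mem <- names(member)[member == ids[i]]
    doms <- catalog$domain_of[intersect(mem, catalog$codes)]
    labels[i] <- if (length(doms) == 0) paste0("C", ids[i]) else
      names(sort(table(doms), decreasing = TRUE))[1]
  }
  dup <- duplicated(labels)
  labels[dup] <- paste0(labels[dup], ".", seq_len(sum(dup)))
  stats::setNames(labels, ids)
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community partition: %d communities, modularity %.3f\n",
              length(x$labels), x$modularity))
  for (id in names(x$labels))
    cat(sprintf("  %s: %s\n", x$labels[[id]],
                paste(names(x$assignment)[x$assignment == as.integer(id)],
                      collapse = " ")))
  invisible(x)
}

#' Aggregate items into per-domain cluster scores
#'
#' Per participant and community, the arithmetic mean of the member item
#' scores (the standard convention for domain severity scores, which keeps
#' domains with different item counts comparable).
#'
#' @param cohort a `synthetic_cohort` (or any list with an `items` matrix and
#'   an `ideation` vector).
#' @param partition a `community_partition` covering all item columns.
#' @param include_ideation append the ideation outcome as a final `SUI`
#'   column.
#' @return numeric matrix n x K (or n x (K+1)) with domain-labeled columns.
#' @export
aggregate_clusters <- function(cohort, partition, include_ideation = FALSE) {
  items <- cohort$items
  miss <- setdiff(colnames(items), names(partition$assignment))
  if (length(miss))
    stop("partition does not cover items: ", paste(miss, collapse = ", "))
  ids <- names(partition$labels)
  scores <- sapply(ids, function(id) {
    mem <- names(partition$assignment)[partition$assignment == as.integer(id)]
    mem <- intersect(mem, colnames(items))
    rowMeans(items[, mem, drop = FALSE])
  })
  colnames(scores) <- unname(partition$labels[ids])
  scores <- scores[, order(colnames(scores)), drop = FALSE]
  if (include_ideation) {
    if (is.null(cohort$ideation))
      stop("ideation column requested but cohort has no ideation outcome")
    scores <- cbind(scores, SUI = as.numeric(cohort$ideation))
  }
  scores
}

#' Cluster-level network with the suicidal-ideation node
#'
#' EBIC-glasso partial-correlation network over the K domain summary scores
#' plus the ideation outcome (treated as numeric), labeled `SUI` and placed
#' last.
#'
#' @param cluster_scores matrix from [aggregate_clusters()] with
#'   `include_ideation = TRUE` (the `SUI` column must be present).
#' @param config a [glasso_config()].
#' @return a `ggm_network` over K+1 nodes with `SUI` last.
#' @export
suicide_network <- function(cluster_scores, config = glasso_config()) {
  if (!("SUI" %in% colnames(cluster_scores)))
    stop("cluster scores must contain the ideation column SUI")
  ord <- c(setdiff(colnames(cluster_scores), "SUI"), "SUI")
  estimate_network(cluster_scores[, ord, drop = FALSE], config)
}

#' PERMANOVA validation of an item partition
#'
#' Treats items as observations with dissimilarity `1 - |r|` and tests
#' whether the community partition separates them: a pseudo-F from
#' among/within sums of squared dissimilarities, with the permutation null
#' obtained by shuffling item labels. Communities of size 1 are excluded with
#' a warning. The p-value uses the add-one convention.
#'
#' @param correlation item correlation matrix (p x p).
#' @param partition a `community_partition` over the items.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return list with `F` (observed pseudo-F), `p`, `n_perm`, and `groups`
#'   (the labels actually used).
#' @export
permanova_clusters <- function(correlation, partition, n_perm = 9999,
                               seed = 1) {
  nodes <- colnames(correlation)
  groups <- partition$assignment[nodes]
  if (anyNA(groups))
    stop("partition does not cover all items in the correlation matrix")
  sizes <- table(groups)
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons)) {
    warning("excluding size-1 communities: ",
            paste(partition$labels[singletons], collapse = ", "))
    keep <- !(groups %in% as.integer(singletons))
    correlation <- correlation[keep, keep, drop = FALSE]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2)
    stop("PERMANOVA needs at least 2 communities with >= 2 members")
  D2 <- (1 - abs(correlation))^2
  diag(D2) <- 0
  N <- length(groups)
  a <- length(unique(groups))
  ss_total <- sum(D2[upper.tri(D2)]) / N
  pseudo_f <- function(g) {
    ss_within <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      ss_within <- ss_within +
        sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
    }
    ((ss_total - ss_within) / (a - 1)) / (ss_within / (N - a))
  }
  f_obs <- pseudo_f(groups)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm))
    if (pseudo_f(sample(groups)) >= f_obs) exceed <- exceed + 1L
  list(F = f_obs, p = (1 + exceed) / (1 + n_perm), n_perm = n_perm,
       groups = groups)
}
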