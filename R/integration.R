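# Consensus integration of per-cohort diagnostic networks: an overlap
# statistic over combinations of networks, and the consensus graph of genes
# and edges supported by at least k cohorts.

#' Overlapping rate of a combination of networks
#'
#' `100 * G / (sum of network sizes - G)` where `G` is the number of genes
#' common to all networks in the combination.  The denominator is this
#' literal sum-minus-common form, not the union size: two identical
#' networks score 100, but n identical networks score `100 / (n - 1)`, and
#' disjoint networks score 0.
#'
#' @param node_sets list (length >= 2) of character vectors of gene symbols,
#'   or of interaction networks.
#' @return the overlapping rate as a percentage.
#' @export
overlapping_rate <- function(node_sets) {
  node_sets <- lapply(node_sets, as_node_set)
  if (length(node_sets) < 2L) stop("need at least 2 networks")
  common <- length(Reduce(intersect, node_sets))
  sizes <- sum(lengths(node_sets))
  if (sizes == 0) return(0)
  100 * common / (sizes - common)
}

as_node_set <- function(x) {
  if (inherits(x, "igraph")) unique(igraph::V(x)$name)
  else if (inherits(x, "diagnostic_network")) x$nodes
  else unique(toupper(as.character(x)))
}

#' Overlap profile across combination sizes
#'
#' Enumerates every combination of `sizes` networks and summarises the
#' overlapping rate and the common-gene count per combination size.
#'
#' @param node_sets list of node sets or networks.
#' @param sizes combination sizes to profile (default 2 to the number of
#'   networks).
#' @return data frame with one row per size: `size`, `n_combinations`,
#'   mean/min/max overlapping rate, mean/min/max common-gene count.
#' @export
overlap_profile <- function(node_sets, sizes = 2:length(node_sets)) {
  node_sets <- lapply(node_sets, as_node_set)
  if (length(node_sets) < 2L) stop("need at least 2 networks")
  rows <- lapply(sizes, function(k) {
    combs <- utils::combn(length(node_sets), k, simplify = FALSE)
    ov <- vapply(combs, function(ix) overlapping_rate(node_sets[ix]),
                 numeric(1))
    cm <- vapply(combs, function(ix)
      length(Reduce(intersect, node_sets[ix])), numeric(1))
    data.frame(size = k, n_combinations = length(combs),
               mean_overlap = mean(ov), min_overlap = min(ov),
               max_overlap = max(ov),
               mean_common = mean(cm), min_common = min(cm),
               max_common = max(cm))
  })
  do.call(rbind, rows)
}

#' Consensus network of recurrently supported genes and edges
#'
#' A gene is kept when it appears in at least `k` of the input networks; an
#' edge is kept when it appears (as an unordered pair) in at least `k`
#' networks and both endpoints are kept.  Support counts are attached as
#' vertex and edge attributes.  With `k = 1` this is the union graph, with
#' `k = length(networks)` the intersection graph.  Genes kept by support but
#' left with no surviving edge are dropped unless `keep_isolated` is set.
#'
#' @param networks list of interaction networks (or `diagnostic_network`s).
#' @param k minimum number of supporting networks (default 3).
#' @param keep_isolated retain supported genes of degree 0?
#' @return an interaction network with `support` vertex/edge attributes and
#'   graph attribute `k`.
#' @export
consensus_network <- function(networks, k = 3, keep_isolated = FALSE) {
  stopifnot(k >= 1)
  nets <- lapply(networks, function(x)
    if (inherits(x, "diagnostic_network")) x$network else x)
  node_support <- table(unlist(lapply(nets, function(g)
    unique(igraph::V(g)$name))))
  edge_keys <- lapply(nets, function(g) {
    el <- igraph::as_edgelist(g)
    if (!nrow(el)) return(character())
    unique(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|"))
  })
  edge_support <- table(unlist(edge_keys))
  keep_nodes <- names(node_support)[node_support >= k]
  ek <- names(edge_support)[edge_support >= k]
  pairs <- do.call(rbind, strsplit(ek, "|", fixed = TRUE))
  if (is.null(pairs)) pairs <- matrix(character(), ncol = 2)
  keep_edge <- pairs[, 1] %in% keep_nodes & pairs[, 2] %in% keep_nodes
  pairs <- pairs[keep_edge, , drop = FALSE]
  g <- as_interaction_network(pairs,
                              nodes = if (keep_isolated) keep_nodes)
  if (igraph::vcount(g)) {
    igraph::V(g)$support <-
      as.integer(node_support[igraph::V(g)$name])
    if (igraph::ecount(g)) {
      el <- igraph::as_edgelist(g)
      keys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]),
                    sep = "|")
      igraph::E(g)$support <- as.integer(edge_support[keys])
    }
  }
  igraph::graph_attr(g, "k") <- as.integer(k)
  g
}

#' Write a consensus network with support columns
#'
#' TSV with columns `gene_a`, `gene_b`, `edge_support`, `support_a`,
#' `support_b`.
#'
#' @param net consensus network from [consensus_network()].
#' @param path output TSV.
#' @export
write_consensus <- function(net, path) {
  el <- igraph::as_edgelist(net)
  sup <- stats::setNames(igraph::V(net)$support, igraph::V(net)$name)
  out <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                    edge_support = if (igraph::ecount(net))
                      igraph::E(net)$support else integer(),
                    support_a = sup[el[, 1]], support_b = sup[el[, 2]],
                    row.names = NULL)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_consensus
#' @export
read_consensus <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  g <- as_interaction_network(tab[, c("gene_a", "gene_b")])
  if (igraph::ecount(g)) {
    el <- igraph::as_edgelist(g)
    key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|")
    tk <- paste(pmin(toupper(tab$gene_a), toupper(tab$gene_b)),
                pmax(toupper(tab$gene_a), toupper(tab$gene_b)), sep = "|")
    igraph::E(g)$support <- tab$edge_support[match(key, tk)]
    sup <- c(stats::setNames(tab$support_a, toupper(tab$gene_a)),
             stats::setNames(tab$support_b, toupper(tab$gene_b)))
    igraph::V(g)$support <- sup[igraph::V(g)$name]
  }
  g
}
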