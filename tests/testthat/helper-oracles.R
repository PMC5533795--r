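# Independent oracles and shared fixtures for the test suite.  Every
# oracle is a deliberately naive reimplementation (brute force, literal
# definitions) kept separate from the package's code paths.

# literal step-up definition: for sorted p(i), adj(i) = min over j >= i of
# min(1, p(j) * m / j), returned in input order
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(vapply(i:m, function(j) min(1, ps[j] * m / j), numeric(1)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# hypergeometric upper tail as an explicit sum of point masses
hyper_tail_bruteforce <- function(ov, q, t, bg) {
  ks <- ov:min(q, t)
  sum(choose(t, ks) * choose(bg - t, q - ks)) / choose(bg, q)
}

# textbook Welch statistic
welch_oracle <- function(x1, x2) {
  unname(stats::t.test(x1, x2)$statistic)
}

# enumerate every connected vertex subset containing `seed` (indices into
# the adjacency list); standard branch-and-exclude enumeration
enumerate_connected <- function(adj, seed) {
  out <- list()
  rec <- function(S, ext, excl) {
    out[[length(out) + 1L]] <<- S
    while (length(ext)) {
      v <- ext[1]
      ext <- ext[-1]
      nb <- setdiff(adj[[v]], c(S, v, ext, excl))
      rec(c(S, v), c(ext, nb), excl)
      excl <- c(excl, v)
    }
  }
  rec(seed, setdiff(adj[[seed]], seed), integer())
  out
}

# maximum norm_agg score over all connected subgraphs containing the seed
exhaustive_best_score <- function(net, scores, seed) {
  vn <- igraph::V(net)$name
  adj <- lapply(igraph::as_adj_list(net), as.integer)
  subsets <- enumerate_connected(adj, match(seed, vn))
  max(vapply(subsets, function(ix)
    sum(abs(scores[vn[ix]])) / sqrt(length(ix)), numeric(1)))
}

# same, for the plain-sum score
exhaustive_best_score_sum <- function(net, scores, seed) {
  vn <- igraph::V(net)$name
  adj <- lapply(igraph::as_adj_list(net), as.integer)
  subsets <- enumerate_connected(adj, match(seed, vn))
  max(vapply(subsets, function(ix) sum(abs(scores[vn[ix]])), numeric(1)))
}

# naive KNN: plain majority vote, NA on vote ties (ties are exercised by
# dedicated deterministic tests)
knn_oracle <- function(train, labels, x, k) {
  d <- apply(train, 1, function(r) sqrt(sum((r - x)^2)))
  nn <- order(d)[seq_len(k)]
  v <- table(labels[nn])
  top <- names(v)[v == max(v)]
  if (length(top) > 1L) NA_character_ else top
}

# tiny deterministic graphs used across files
toy_star <- function(leaves = 4) {
  as_interaction_network(cbind("HUB", paste0("L", seq_len(leaves))))
}
toy_path <- function(genes = c("A", "B", "C")) {
  as_interaction_network(cbind(genes[-length(genes)], genes[-1]))
}

# small synthetic instance shared by recovery-style tests
small_sim <- function(seed, ...) {
  cfg <- sim_config(rng_seed = seed, ...)
  gen <- generate_network(cfg)
  list(cfg = cfg, net = gen$network, truth = gen$truth,
       data = generate_expression(gen$network, gen$truth, cfg))
}

# run scoring -> induction -> iterated search for one cohort
cohort_diagnostic <- function(net, dataset, alpha = 0.05,
                              config = search_config()) {
  tab <- score_genes(dataset)
  sel <- select_diagnostic_genes(tab, alpha)
  sub <- induce_subnetwork(net, sel)
  if (igraph::vcount(sub) == 0L) return(character())
  sc <- stats::setNames(tab$t, tab$gene)
  sc[is.na(sc)] <- 0
  iterate_search(sub, sc, config)$nodes
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# full recovery run: per-cohort diagnostic networks, consensus, EC ranking
recovery_run <- function(seed) {
  sim <- small_sim(seed)
  nets <- lapply(sim$data, function(d)
    induce_subnetwork(sim$net, cohort_diagnostic(sim$net, d),
                      drop_isolated = FALSE))
  cons <- consensus_network(nets, k = 3)
  ec <- connectivity_enrichment(degree_table(cons), degree_table(sim$net))
  list(truth = sim$truth,
       consensus = cons,
       jaccard = jaccard(igraph::V(cons)$name, sim$truth$planted_module),
       top4_hits = sum(ec$gene[seq_len(min(4, nrow(ec)))] %in%
                         sim$truth$pivotal_genes))
}
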