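test_that("module_score evaluates the three methods as defined", {
  sc <- c(A = 3, B = -3, C = 3, D = 0)
  expect_equal(module_score("A", sc, "sum"), 3)
  expect_equal(module_score("A", sc, "norm_agg"), 3)
  expect_equal(module_score(c("A", "B", "C"), sc, "norm_agg"), 9 / sqrt(3))
  expect_equal(module_score(c("A", "B", "C"), sc, "sum"), 9)
  # adding a zero-score node lowers the size-penalized aggregate
  expect_lt(module_score(c("A", "B", "C", "D"), sc, "norm_agg"),
            module_score(c("A", "B", "C"), sc, "norm_agg"))
  expect_error(module_score(character(), sc), "non-empty")
  expect_error(module_score("Z", sc), "missing score")
  # operational MI score: computable, non-negative, zero with no frontier
  path <- toy_path(c("A", "B", "C"))
  expect_gte(module_score(c("A", "B"), sc, "mi", net = path), 0)
  expect_equal(module_score(c("A", "B", "C"), sc, "mi", net = path), 0)
})

test_that("greedy expansion follows the strict-increase rule", {
  # isolated seed: empty frontier
  lone <- as_interaction_network(cbind("A", "B"), nodes = "Z")
  m <- greedy_expand(lone, c(A = 1, B = 1, Z = 5), "Z")
  expect_identical(m$nodes, "Z")
  # path a-b-c with weak middle: adding b lowers the aggregate => stop at {a}
  path <- toy_path(c("A", "B", "C"))
  sc <- c(A = 3, B = 0.1, C = 3)
  m <- greedy_expand(path, sc, "A")
  expect_identical(m$nodes, "A")
  expect_equal(m$score, 3)
  # sum scoring on a star absorbs everything
  star <- toy_star(4)
  sc2 <- c(HUB = 5, L1 = 4, L2 = 4, L3 = 4, L4 = 4)
  m2 <- greedy_expand(star, sc2, "HUB", search_config(method = "sum"))
  expect_setequal(m2$nodes, names(sc2))
  expect_equal(m2$score, 5 + 4 * 4)
  expect_error(greedy_expand(star, sc2, "NOPE"), "seed not in network")
  # reported score always equals the recomputed module score
  expect_equal(m2$score, module_score(m2$nodes, sc2, "sum"))
})

test_that("greedy never beats the exhaustive connected-subgraph optimum", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(5:10, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.25, 0.6))
    igraph::V(g)$name <- LETTERS[seq_len(n)]
    sc <- stats::setNames(rnorm(n, sd = 2), LETTERS[seq_len(n)])
    seed <- sample(LETTERS[seq_len(n)], 1)
    got <- greedy_expand(g, sc, seed)$score
    best <- exhaustive_best_score(g, sc, seed)
    expect_lte(got, best + 1e-9)
  }
  # equality on fixtures where greedy is optimal
  star <- toy_star(3)
  sc <- c(HUB = 5, L1 = 4, L2 = 4, L3 = 4)
  expect_equal(greedy_expand(star, sc, "HUB", search_config("sum"))$score,
               max(vapply(enumerate_connected(
                 lapply(igraph::as_adj_list(star), as.integer),
                 match("HUB", igraph::V(star)$name)),
                 function(ix) sum(sc[igraph::V(star)$name[ix]]), numeric(1))))
})

test_that("search rounds are deterministic and merge the top modules", {
  sim <- small_sim(9, n_genes = 120, module_size = 15)
  tab <- score_genes(sim$data[[1]])
  sc <- stats::setNames(tab$t, tab$gene); sc[is.na(sc)] <- 0
  sub <- induce_subnetwork(sim$net, select_diagnostic_genes(tab))
  u1 <- search_round(sub, sc)
  u2 <- search_round(sub, sc)
  expect_identical(u1, u2)
  # top_k = number of nodes: union of all greedy results
  all_cfg <- search_config(top_k = igraph::vcount(sub))
  u_all <- search_round(sub, sc, all_cfg)
  every <- sort(unique(unlist(lapply(igraph::V(sub)$name, function(s)
    greedy_expand(sub, sc, s)$nodes))))
  expect_identical(u_all, every)
  # dominant planted component is recovered
  expect_gte(mean(intersect(sim$truth$planted_module,
                            igraph::V(sub)$name) %in% u1), 0.9)
})

test_that("iterated search shrinks monotonically and is idempotent", {
  sim <- small_sim(10)
  nodes <- cohort_diagnostic(sim$net, sim$data[[1]])
  tab <- score_genes(sim$data[[1]])
  sc <- stats::setNames(tab$t, tab$gene); sc[is.na(sc)] <- 0
  sub <- induce_subnetwork(sim$net, select_diagnostic_genes(tab))
  dn <- iterate_search(sub, sc)
  expect_identical(dn$nodes, nodes)
  if (nrow(dn$rounds) > 1)
    expect_true(all(diff(dn$rounds$n_nodes) <= 0))
  expect_lte(length(dn$nodes), 55)
  # idempotence: searching the result again returns it unchanged
  again <- iterate_search(dn$network, sc)
  expect_identical(again$nodes, dn$nodes)
  # a network already at stopping size is returned unchanged
  tiny <- induce_subnetwork(sim$net, sim$truth$planted_module)
  dn2 <- iterate_search(tiny, sc)
  expect_identical(dn2$nodes, sort(igraph::V(tiny)$name))
  expect_equal(nrow(dn2$rounds), 0)
})

test_that("planted-module recovery does not degrade as effect size grows", {
  med_jac <- vapply(c(0, 1, 2), function(es) {
    jac <- vapply(1:5, function(s) {
      sim <- small_sim(s, n_cohorts = 1, effect_size = es)
      nodes <- cohort_diagnostic(sim$net, sim$data[[1]])
      if (!length(nodes)) return(0)
      jaccard(nodes, sim$truth$planted_module)
    }, numeric(1))
    stats::median(jac)
  }, numeric(1))
  expect_true(all(diff(med_jac) >= -0.05))
  expect_gt(med_jac[3], med_jac[1])
})
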