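# dataset with an informative 4-gene panel at evaluation-cohort scale
eval_sim <- function(seed, n_tumor = 250) {
  small_sim(seed, n_tumor = n_tumor, n_normal = 10, n_cohorts = 1)
}

test_that("knn_predict votes deterministically with the stated tie rules", {
  expect_identical(knn_predict(rbind(c(0, 0)), "a", c(5, 5), 1), "a")
  # vote tie at k = 2: nearest neighbour among tied classes wins
  train <- rbind(c(0, 0), c(2, 0))
  expect_identical(knn_predict(train, c("a", "b"), c(0.5, 0), 2), "a")
  expect_identical(knn_predict(train, c("a", "b"), c(1.6, 0), 2), "b")
  # exact distance tie: training order breaks it
  expect_identical(knn_predict(rbind(c(-1, 0), c(1, 0)), c("a", "b"),
                               c(0, 0), 1), "a")
  expect_error(knn_predict(train, c("a", "b"), c(0, 0), 0), "at least 1")
  expect_error(knn_predict(train, c("a", "b"), c(0, 0), 3), "exceeds")
})

test_that("knn_predict agrees with a brute-force oracle on random instances", {
  set.seed(55)
  mismatches <- 0
  for (i in 1:200) {
    n <- sample(8:25, 1); p <- sample(2:5, 1)
    train <- matrix(rnorm(n * p), n)
    labels <- sample(letters[1:3], n, replace = TRUE)
    x <- rnorm(p)
    k <- sample(1:min(7, n), 1)
    want <- knn_oracle(train, labels, x, k)
    if (!is.na(want))
      mismatches <- mismatches + (knn_predict(train, labels, x, k) != want)
  }
  expect_equal(mismatches, 0)
})

test_that("well-separated clusters are classified almost perfectly", {
  accs <- vapply(1:5, function(s) {
    set.seed(s)
    x <- rbind(matrix(rnorm(40, 0), ncol = 2),
               matrix(rnorm(40, 6), ncol = 2))
    y <- rep(c("a", "b"), each = 20)
    pred <- vapply(seq_len(nrow(x)), function(i)
      knn_predict(x[-i, ], y[-i], x[i, ], 10), character(1))
    mean(pred == y)
  }, numeric(1))
  expect_gte(mean(accs), 0.99)
})

test_that("cross-validation reports coherent statistics and collapses deterministic LOO", {
  sim <- eval_sim(1, n_tumor = 80)
  panel <- sim$truth$pivotal_genes
  rep <- cross_validate(sim$data[[1]], panel, "kfold10", knn_classifier(10),
                        repeats = 8, seed = 2)
  expect_true(rep$min <= rep$median && rep$median <= rep$max)
  expect_true(rep$mean >= rep$min && rep$mean <= rep$max)
  expect_true(all(rep$accuracies >= 0 & rep$accuracies <= 1))
  loo <- cross_validate(sim$data[[1]], panel, "loo", knn_classifier(10),
                        repeats = 100)
  expect_true(loo$collapsed)
  expect_equal(loo$repeats, 1L)
  expect_equal(loo$min, loo$max)
  expect_error(cross_validate(sim$data[[1]], c("NOPE"), "kfold10"),
               "absent")
})

test_that("stratified folds preserve class proportions within one sample", {
  set.seed(8)
  y <- sample(c("a", "b", "c", "d"), 120, replace = TRUE,
              prob = c(0.45, 0.2, 0.15, 0.2))
  fold <- diagnet:::stratified_folds(y, 10)
  for (cl in unique(y)) {
    per_fold <- table(factor(fold[y == cl], levels = 1:10))
    expect_lte(diff(range(per_fold)), 1)
  }
})

test_that("label permutation drops accuracy to the chance rate", {
  sim <- eval_sim(2)
  d <- sim$data[[1]]
  tum <- d$samples$group == "tumor"
  set.seed(99)
  d$samples$subtype[tum] <- sample(d$samples$subtype[tum])
  rep <- cross_validate(d, sim$truth$pivotal_genes, "kfold10",
                        knn_classifier(10), repeats = 5, seed = 1)
  chance <- max(table(d$samples$subtype[tum])) / sum(tum)
  expect_lt(abs(rep$mean - chance), 0.05)
})

test_that("trajectory grows through the informative panel then plateaus", {
  sim <- eval_sim(3)
  d <- sim$data[[1]]
  noise <- setdiff(rownames(d$expr), sim$truth$diff_genes)[1:3]
  ranked <- c(sim$truth$pivotal_genes, noise)
  tr <- panel_trajectory(d, ranked, "kfold10", knn_classifier(10),
                         repeats = 4, seed = 5)
  expect_equal(nrow(tr), length(ranked))
  expect_gte(tr$mean_accuracy[4], tr$mean_accuracy[1])
  expect_lte(max(tr$mean_accuracy[5:7]), tr$mean_accuracy[4] + 0.05)
  # single-gene prefix equals a direct cross-validation of that gene
  direct <- cross_validate(d, ranked[1], "kfold10", knn_classifier(10),
                           repeats = 4, seed = 5 + 1)$mean
  expect_equal(tr$mean_accuracy[1], direct)
})

test_that("stratification t-tests split the planted subtype axes", {
  sim <- eval_sim(4, n_tumor = 120)
  d <- sim$data[[1]]
  er_gene <- sim$truth$pivotal_genes[1]    # ER-axis pattern
  tng_gene <- sim$truth$pivotal_genes[3]   # TNG marker pattern
  ps <- vapply(1:10, function(s) {
    sim_s <- eval_sim(s + 10, n_tumor = 120)
    stratify_t(sim_s$data[[1]], sim_s$truth$pivotal_genes[1], "ER")$p
  }, numeric(1))
  expect_gte(mean(ps < 1e-6), 0.95)
  res <- stratify_t(d, tng_gene, "TNG")
  expect_lt(res$p, 1e-6)
  # identical groups: t near 0, sign flips under group swap
  flat <- d
  flat$expr[er_gene, ] <- 1:ncol(flat$expr) * 0 + rnorm(ncol(flat$expr))
  r0 <- stratify_t(flat, er_gene, "ER")
  expect_gt(r0$p, 0.001)
  swapped <- d
  tum <- d$samples$group == "tumor"
  swapped$samples$ER[tum] <- ifelse(d$samples$ER[tum] == "positive",
                                    "negative", "positive")
  expect_equal(stratify_t(swapped, er_gene, "ER")$t,
               -stratify_t(d, er_gene, "ER")$t)
})

test_that("cluster order groups separated classes contiguously", {
  set.seed(12)
  expr <- cbind(matrix(rnorm(4 * 10, 0), 4), matrix(rnorm(4 * 10, 8), 4))
  rownames(expr) <- paste0("P", 1:4)
  colnames(expr) <- paste0("S", 1:20)
  ds <- structure(list(expr = expr,
                       samples = data.frame(sample = colnames(expr),
                                            group = "tumor")),
                  class = "expression_dataset")
  for (link in c("average", "complete", "ward")) {
    ord <- cluster_order(ds, paste0("P", 1:4), "euclidean", link)$order
    cls <- as.integer(sub("S", "", ord)) > 10
    expect_equal(sum(diff(cls) != 0), 1)   # one block boundary
  }
  two <- structure(list(expr = expr[, 1:2],
                        samples = ds$samples[1:2, ]),
                   class = "expression_dataset")
  expect_setequal(cluster_order(two, paste0("P", 1:4))$order,
                  c("S1", "S2"))
  # deterministic
  expect_identical(cluster_order(ds, paste0("P", 1:4), "correlation")$order,
                   cluster_order(ds, paste0("P", 1:4), "correlation")$order)
})
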