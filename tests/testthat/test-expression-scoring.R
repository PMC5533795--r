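test_that("welch_t reproduces hand-computed values and symmetries", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(welch_t(c(1, 2, 3), c(4, 5, 6)), -3 / sqrt(2 / 3))
  x <- rnorm(8); y <- rnorm(5)
  expect_equal(welch_t(y, x), -welch_t(x, y))
  expect_equal(welch_t(3 * x, 3 * y), welch_t(x, y))          # scale invariant
  shifts <- seq(0, 2, by = 0.5)
  ts <- vapply(shifts, function(s) welch_t(x + s, y), numeric(1))
  expect_true(all(diff(ts) > 0))                              # monotone in shift
  expect_error(welch_t(1, c(1, 2)), "at least 2")
  expect_error(welch_t(c(1, 1, 1), c(2, 2, 2)), "undefined")
})

test_that("welch_t matches the textbook oracle on random pairs", {
  set.seed(42)
  err <- replicate(1000, {
    x <- rnorm(sample(2:20, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(2:20, 1), mean = runif(1, -2, 2))
    abs(welch_t(x, y) - welch_oracle(x, y))
  })
  expect_lt(max(err), 1e-12)
})

test_that("t_to_p follows the Welch-Satterthwaite t reference distribution", {
  expect_equal(t_to_p(0, 5, 5), 1)
  expect_equal(t_to_p(2.2, 6, 9, 1.3, 0.4), t_to_p(-2.2, 6, 9, 1.3, 0.4))
  # equal variances, n1 = n2 = 3 => df = 4; oracle = numeric integration of
  # the t(4) density over the upper tail
  tv <- 3 / sqrt(2 / 3)
  upper <- stats::integrate(function(u) stats::dt(u, 4), tv, Inf)$value
  expect_equal(t_to_p(-tv, 3, 3), 2 * upper, tolerance = 1e-9)
  # agrees with the full Welch test p on random data
  set.seed(1)
  for (i in 1:25) {
    x <- rnorm(sample(3:15, 1), sd = runif(1, 0.5, 2)); y <- rnorm(sample(3:15, 1))
    tt <- stats::t.test(x, y)
    expect_equal(t_to_p(welch_t(x, y), length(x), length(y),
                        stats::var(x), stats::var(y)),
                 tt$p.value, tolerance = 1e-12)
  }
  expect_error(t_to_p(Inf, 3, 3), "finite")
})

test_that("bh_adjust implements the step-up definition", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(99)
  for (i in 1:1000) {
    p <- runif(sample(1:12, 1))
    a <- bh_adjust(p)
    expect_equal(a, bh_bruteforce(p), tolerance = 1e-14)
    expect_true(all(a >= p - 1e-15) && all(a <= 1))
  }
})

test_that("score_genes produces a complete, coherent table", {
  sim <- small_sim(5, n_cohorts = 1)
  tab <- score_genes(sim$data[[1]])
  expect_s3_class(tab, "gene_score_table")
  expect_equal(nrow(tab), nrow(sim$data[[1]]$expr))
  expect_true(all(tab$p >= 0 & tab$p <= 1, na.rm = TRUE))
  expect_true(all(tab$p_adj >= tab$p - 1e-15, na.rm = TRUE))
  ord <- order(tab$p)
  expect_true(all(diff(tab$p_adj[ord]) >= -1e-15))
  expect_identical(unique(tab$n_tumor), 30L)
  # missing candidates are reported, not fatal
  expect_warning(t2 <- score_genes(sim$data[[1]], c("G0001", "NOPE")),
                 "absent")
  expect_identical(attr(t2, "missing_genes"), "NOPE")
  # degenerate cohort rejected
  tiny <- sim$data[[1]]
  keep <- c(which(tiny$samples$group == "tumor")[1],
            which(tiny$samples$group == "normal"))
  tiny$expr <- tiny$expr[, keep]; tiny$samples <- tiny$samples[keep, ]
  expect_error(score_genes(tiny), "fewer than 2")
})

test_that("planted signal is detected and lost under label permutation", {
  sim <- small_sim(8, n_cohorts = 1)
  tab <- score_genes(sim$data[[1]])
  sel <- select_diagnostic_genes(tab)
  expect_gte(mean(sim$truth$diff_genes %in% sel), 0.9)
  expect_gte(jaccard(sel, sim$truth$diff_genes), 0.8)
  # alpha boundaries
  expect_setequal(select_diagnostic_genes(tab, 1.0), tab$gene)
  expect_length(select_diagnostic_genes(tab, 0), 0)
  # ranking is by |t| descending
  expect_true(all(diff(abs(tab$t[match(sel, tab$gene)])) <= 1e-12))
  # permuting group labels destroys the signal
  set.seed(1)
  med_t <- vapply(1:20, function(i) {
    perm <- sim$data[[1]]
    perm$samples$group <- sample(perm$samples$group)
    pt <- score_genes(perm, sim$truth$diff_genes)
    stats::median(abs(pt$t))
  }, numeric(1))
  expect_lt(stats::median(med_t), 1)
})

test_that("zero-variance genes are flagged rather than dropped", {
  sim <- small_sim(2, n_cohorts = 1, n_genes = 50, module_size = 6)
  d <- sim$data[[1]]
  d$expr["G0001", ] <- ifelse(d$samples$group == "tumor", 5, 3)
  d$expr["G0002", ] <- 4
  tab <- score_genes(d)
  expect_identical(tab$flag[tab$gene == "G0001"], "zero_variance")
  expect_true(is.na(tab$t[tab$gene == "G0001"]))
  expect_identical(tab$t[tab$gene == "G0002"], 0)   # equal constant groups
  expect_identical(tab$p[tab$gene == "G0002"], 1)
})

test_that("score tables round-trip through TSV", {
  sim <- small_sim(4, n_cohorts = 1, n_genes = 50, module_size = 6)
  tab <- score_genes(sim$data[[1]])
  p <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(tab, p)
  back <- read_score_table(p)
  expect_equal(back$t, tab$t, tolerance = 1e-9)
  expect_identical(back$gene, tab$gene)
})
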