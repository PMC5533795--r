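# Synthetic multi-cohort breast-cancer-like data with planted ground truth.
# Networks are preferential-attachment graphs (hub-dominated, like curated
# PPI databases); a connected "diagnostic module" is grown by BFS and its
# members receive a tumor-vs-normal expression shift; a handful of pivotal
# genes inside the module are rewired to be densely connected within the
# module while keeping a modest global degree, and additionally carry
# subtype-specific shifts.

SUBTYPE_LEVELS <- c("ERpos_HER2neg", "ERpos_HER2pos", "ERneg_HER2pos", "TNG")

# one shift pattern column per subtype class, one row per pivotal gene
# (recycled); an ER axis, a HER2 axis, a TNG marker and an ER-negative
# marker so ER-splitting and TNG-splitting genes both exist
PIVOTAL_PATTERNS <- matrix(
  c(1, 1, 0, 0,
    0, 1, 1, 0,
    0, 0, 0, 1,
    0, 0, 1, 1),
  nrow = 4, byrow = TRUE,
  dimnames = list(NULL, SUBTYPE_LEVELS))

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator.  The
#' defaults describe the reference simulation used throughout the package's
#' tests: 6 cohorts of 30 tumor + 30 normal samples over 400 genes, a
#' 40-gene planted diagnostic module with a 2-SD tumor shift, 4 pivotal
#' genes with 2.5-SD subtype shifts, unit Gaussian noise and a 0.3-SD
#' per-cohort batch offset.
#'
#' @param n_genes number of genes (network nodes).
#' @param attachment preferential-attachment parameter: edges added per new
#'   node while growing the graph.
#' @param n_cohorts number of expression cohorts to simulate.
#' @param n_tumor,n_normal samples per group per cohort.
#' @param module_size number of genes in the planted connected module.
#' @param n_pivotal number of pivotal genes inside the module.
#' @param effect_size tumor-vs-normal shift of differential genes, in units
#'   of `noise_sd`.
#' @param subtype_effect_size magnitude of per-subtype shifts of pivotal
#'   genes, in units of `noise_sd`.
#' @param noise_sd standard deviation of i.i.d. Gaussian measurement noise.
#' @param batch_sd standard deviation of the per-cohort, per-gene batch
#'   offset.
#' @param frac_outside_diff fraction of genes outside the module that also
#'   receive the tumor shift (the module is enriched for, not exclusive of,
#'   differential genes).
#' @param down_frac fraction of differential genes shifted downwards in
#'   tumors rather than upwards.
#' @param subtype_probs length-4 probability vector over the subtype classes
#'   `[ER+|PR+]HER2-`, `[ER+|PR+]HER2+`, `[ER-|PR-]HER2+`, TNG.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline
#'   log-expression, shared across cohorts.
#' @param rng_seed integer seed; identical configurations yield bit-identical
#'   networks and matrices.
#' @return a validated object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 400, attachment = 2, n_cohorts = 6,
                       n_tumor = 30, n_normal = 30, module_size = 40,
                       n_pivotal = 4, effect_size = 2,
                       subtype_effect_size = 2.5, noise_sd = 1,
                       batch_sd = 0.3, frac_outside_diff = 0.05,
                       down_frac = 0,
                       subtype_probs = c(0.45, 0.20, 0.15, 0.20),
                       baseline_mean = 7, baseline_sd = 1, rng_seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              attachment = as.integer(attachment),
              n_cohorts = as.integer(n_cohorts),
              n_tumor = as.integer(n_tumor),
              n_normal = as.integer(n_normal),
              module_size = as.integer(module_size),
              n_pivotal = as.integer(n_pivotal),
              effect_size = effect_size,
              subtype_effect_size = subtype_effect_size,
              noise_sd = noise_sd, batch_sd = batch_sd,
              frac_outside_diff = frac_outside_diff,
              down_frac = down_frac,
              subtype_probs = subtype_probs / sum(subtype_probs),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              rng_seed = as.integer(rng_seed))
  counts <- c("n_genes", "attachment", "n_cohorts", "n_tumor", "n_normal",
              "module_size", "n_pivotal")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("invalid config: ", f, " must be a count >= 1")
  if (cfg$module_size > cfg$n_genes)
    stop("invalid config: module_size exceeds n_genes")
  if (cfg$n_pivotal > cfg$module_size)
    stop("invalid config: n_pivotal exceeds module_size")
  if (cfg$effect_size < 0 || cfg$noise_sd <= 0)
    stop("invalid config: effect_size must be >= 0 and noise_sd > 0")
  if (length(cfg$subtype_probs) != 4L || any(cfg$subtype_probs < 0))
    stop("invalid config: subtype_probs must be 4 non-negative weights")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a scale-free interaction network with a planted module
#'
#' Grows a preferential-attachment graph, plants one connected module by
#' breadth-first growth from a random node, rewires `n_pivotal` low-degree
#' module members so that all of their interactions stay inside the module
#' (high within-module connectivity at modest global degree), and guarantees
#' every other module member at least one interaction outside the module.
#' Differential genes are the module members plus a random
#' `frac_outside_diff` share of outside genes.
#'
#' @param config a [sim_config()].
#' @return a list with elements `network` (interaction network) and `truth`,
#'   a `ground_truth` list holding `diff_genes`, `planted_module`,
#'   `pivotal_genes` and `effect_table` (per-gene tumor shift and per-subtype
#'   pivotal shifts, both in SD units).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  n <- config$n_genes
  g <- igraph::sample_pa(n, power = 1, m = config$attachment,
                         directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("G%04d", seq_len(n))

  root <- sample(igraph::V(g)$name, 1)
  bfs_order <- igraph::bfs(g, root, order = TRUE)$order
  module <- igraph::V(g)$name[as.integer(bfs_order)[seq_len(config$module_size)]]
  module <- sort(module)

  # pivotal genes: module members of smallest global degree, rewired inward
  deg <- igraph::degree(g)[module]
  pivotal <- module[order(deg, module)][seq_len(config$n_pivotal)]
  for (pg in pivotal) {
    inc <- igraph::incident(g, pg)
    if (length(inc)) g <- igraph::delete_edges(g, inc)
  }
  k_within <- min(8L, config$module_size - 1L)
  for (pg in pivotal) {
    partners <- setdiff(pivotal, pg)
    pool <- setdiff(module, c(pg, partners))
    partners <- c(partners, sample(pool, max(0L, k_within - length(partners))))
    g <- igraph::add_edges(g, rbind(pg, partners))
  }
  g <- igraph::simplify(g)

  # ordinary module members must keep a foothold outside the module
  outside <- setdiff(igraph::V(g)$name, module)
  for (mg in setdiff(module, pivotal)) {
    nb <- igraph::neighbors(g, mg)$name
    if (!length(setdiff(nb, module)))
      g <- igraph::add_edges(g, c(mg, sample(outside, 1)))
  }
  g <- igraph::simplify(g)

  n_out <- round(config$frac_outside_diff * length(outside))
  diff_genes <- sort(c(module, sample(outside, n_out)))

  sign <- ifelse(stats::runif(length(diff_genes)) < config$down_frac, -1, 1)
  tumor_shift <- stats::setNames(sign * config$effect_size, diff_genes)
  patt <- PIVOTAL_PATTERNS[rep_len(seq_len(nrow(PIVOTAL_PATTERNS)),
                                   config$n_pivotal), , drop = FALSE]
  subtype_shift <- patt * config$subtype_effect_size
  rownames(subtype_shift) <- pivotal

  truth <- structure(list(diff_genes = diff_genes,
                          planted_module = module,
                          pivotal_genes = pivotal,
                          effect_table = list(tumor_shift = tumor_shift,
                                              subtype_shift = subtype_shift)),
                     class = "ground_truth")
  list(network = g, truth = truth)
}

#' Generate multi-cohort expression data for a simulated network
#'
#' Each cohort is an independent case/control dataset over the network's
#' genes: entries are gene baseline + per-cohort batch offset + (for tumor
#' samples) tumor shift and pivotal subtype shift + i.i.d. Gaussian noise.
#' Tumor samples carry ER/PR/HER2 labels implied by their subtype class;
#' normal samples are labelled `normal`.
#'
#' @param network interaction network from [generate_network()].
#' @param truth matching `ground_truth`.
#' @param config the [sim_config()] used to generate them.
#' @return a list of `expression_dataset` objects, one per cohort, each a
#'   list with `expr` (genes x samples matrix), `samples` (data frame with
#'   `sample`, `group`, `ER`, `PR`, `HER2`, `subtype`) and `cohort`.
#' @export
generate_expression <- function(network, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  genes <- igraph::V(network)$name
  if (!all(truth$diff_genes %in% genes))
    stop("ground truth refers to genes absent from the network")
  if (config$n_tumor < 1L || config$n_normal < 1L)
    stop("invalid config: zero samples in a group")
  set.seed(config$rng_seed + 1L)
  baseline <- stats::rnorm(length(genes), config$baseline_mean,
                           config$baseline_sd)
  names(baseline) <- genes
  shift <- numeric(length(genes))
  names(shift) <- genes
  shift[names(truth$effect_table$tumor_shift)] <-
    truth$effect_table$tumor_shift * config$noise_sd
  sub_shift <- matrix(0, length(genes), 4,
                      dimnames = list(genes, SUBTYPE_LEVELS))
  ss <- truth$effect_table$subtype_shift
  sub_shift[rownames(ss), ] <- ss * config$noise_sd

  lapply(seq_len(config$n_cohorts), function(co) {
    batch <- stats::rnorm(length(genes), 0, config$batch_sd)
    n_t <- config$n_tumor; n_n <- config$n_normal
    subtype <- sample(SUBTYPE_LEVELS, n_t, replace = TRUE,
                      prob = config$subtype_probs)
    ids <- sprintf("C%02d_%s%02d", co,
                   rep(c("T", "N"), c(n_t, n_n)),
                   c(seq_len(n_t), seq_len(n_n)))
    mu <- matrix(baseline + batch, length(genes), n_t + n_n)
    mu[, seq_len(n_t)] <- mu[, seq_len(n_t)] + shift +
      sub_shift[, match(subtype, SUBTYPE_LEVELS)]
    expr <- mu + matrix(stats::rnorm(length(mu), 0, config$noise_sd),
                        nrow(mu))
    dimnames(expr) <- list(genes, ids)
    er <- c(ERpos_HER2neg = "positive", ERpos_HER2pos = "positive",
            ERneg_HER2pos = "negative", TNG = "negative")
    her2 <- c(ERpos_HER2neg = "negative", ERpos_HER2pos = "positive",
              ERneg_HER2pos = "positive", TNG = "negative")
    samples <- data.frame(
      sample = ids,
      group = rep(c("tumor", "normal"), c(n_t, n_n)),
      ER = c(er[subtype], rep(NA_character_, n_n)),
      PR = c(er[subtype], rep(NA_character_, n_n)),  # concordant by design
      HER2 = c(her2[subtype], rep(NA_character_, n_n)),
      subtype = c(subtype, rep(NA_character_, n_n)),
      stringsAsFactors = FALSE)
    structure(list(expr = expr, samples = samples, cohort = co),
              class = "expression_dataset")
  })
}

#' Read and write expression datasets and ground truth
#'
#' Expression is stored as TSV with genes in rows and a header of sample
#' IDs; sample annotations as TSV with columns `sample`, `group`, `ER`,
#' `PR`, `HER2`, `subtype`; ground truth as JSON.
#'
#' @param dataset an `expression_dataset`.
#' @param expr_path,annot_path TSV paths.
#' @param truth a `ground_truth`; `path` its JSON file.
#' @name expression_io
#' @export
write_expression <- function(dataset, expr_path, annot_path) {
  utils::write.table(dataset$expr, expr_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(dataset$samples, annot_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expr_path, annot_path))
}

#' @rdname expression_io
#' @export
read_expression <- function(expr_path, annot_path, cohort = NA) {
  expr <- as.matrix(utils::read.delim(expr_path, row.names = 1,
                                      check.names = FALSE))
  samples <- utils::read.delim(annot_path, stringsAsFactors = FALSE)
  if (!all(samples$sample == colnames(expr)))
    stop("annotation sample order does not match expression columns")
  structure(list(expr = expr, samples = samples, cohort = cohort),
            class = "expression_dataset")
}

#' @rdname expression_io
#' @export
write_truth <- function(truth, path) {
  out <- list(diff_genes = truth$diff_genes,
              planted_module = truth$planted_module,
              pivotal_genes = truth$pivotal_genes,
              tumor_shift = as.list(truth$effect_table$tumor_shift),
              subtype_shift = apply(truth$effect_table$subtype_shift, 1,
                                    as.list, simplify = FALSE))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname expression_io
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ss <- do.call(rbind, lapply(raw$subtype_shift, unlist))
  structure(list(diff_genes = raw$diff_genes,
                 planted_module = raw$planted_module,
                 pivotal_genes = raw$pivotal_genes,
                 effect_table = list(tumor_shift = unlist(raw$tumor_shift),
                                     subtype_shift = ss)),
            class = "ground_truth")
}
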