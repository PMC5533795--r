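# End-to-end orchestration: score -> induce -> search (per cohort) ->
# integrate -> pivotal -> enrich -> evaluate, with a manifest recording
# every output file, its checksum, the seeds and the configuration hash, so
# a rerun with the same configuration is bit-identical.

#' Pipeline configuration
#'
#' Either point the pipeline at existing inputs (`expression` +
#' `annotation` TSV path pairs, a `network` edge list, optionally a `gmt`
#' library) or set `simulate = TRUE` to generate inputs with
#' [sim_config()]/[generate_network()]/[generate_expression()] first.  All
#' randomness flows from the single `seed`, split per stage.
#'
#' @param expression,annotation character vectors of per-cohort TSV paths
#'   (ignored when `simulate = TRUE`).
#' @param network path to a plain two-column TSV edge list (ignored when
#'   simulating).
#' @param gmt optional GMT library path for the enrichment stage.
#' @param simulate generate synthetic inputs?
#' @param sim arguments passed to [sim_config()] when simulating.
#' @param alpha adjusted-p cutoff defining per-cohort diagnostic genes.
#' @param search arguments passed to [search_config()].
#' @param k_support consensus support threshold (default 3).
#' @param B permutations for the degree-enrichment null (default 1000).
#' @param panel_size genes taken from the top of the EC ranking for
#'   evaluation when break-point panels are unavailable (default 4).
#' @param cv_repeats repeats for the 10-fold cross-validation stage.
#' @param seed master integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(expression = NULL, annotation = NULL,
                            network = NULL, gmt = NULL, simulate = FALSE,
                            sim = list(), alpha = 0.05, search = list(),
                            k_support = 3, B = 1000, panel_size = 4,
                            cv_repeats = 50, seed = 1) {
  cfg <- list(expression = expression, annotation = annotation,
              network = network, gmt = gmt, simulate = isTRUE(simulate),
              sim = sim, alpha = alpha, search = search,
              k_support = k_support, B = B, panel_size = panel_size,
              cv_repeats = cv_repeats, seed = as.integer(seed))
  if (!cfg$simulate) {
    if (is.null(cfg$expression) || is.null(cfg$annotation) ||
        is.null(cfg$network))
      stop("expression, annotation and network paths are required unless ",
           "simulate = TRUE")
    if (length(cfg$expression) != length(cfg$annotation))
      stop("expression and annotation path lists differ in length")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file with the fields of [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

pipeline_stages <- c("simulate", "score", "search", "integrate", "pivotal",
                     "enrich", "evaluate")

#' Run the full diagnostic-network pipeline
#'
#' Executes the stages in order, writing every intermediate table under
#' `outdir` and a `manifest.json` listing the stages run, all output files
#' with MD5 checksums, the seeds and the configuration hash.  A cohort
#' signal too weak to build a consensus network is not an error: the run
#' completes with `status = "no_signal"` and the downstream stages are
#' skipped.  Any genuine stage failure aborts with the stage name, after
#' writing a machine-readable `error.json`.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with `status` (`"ok"` or `"no_signal"`),
#'   `manifest`, and the in-memory stage results.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stages = list(), seed = config$seed,
                   config_hash = config_hash(config))
  res <- list()
  stage <- function(name, fun) {
    out <- tryCatch(fun(), error = function(e) {
      rec <- list(stage = name, error = conditionMessage(e))
      jsonlite::write_json(rec, file.path(outdir, "error.json"),
                           auto_unbox = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(name = name, files = out$files)
    out$value
  }

  # --- inputs -------------------------------------------------------------
  if (config$simulate) {
    sim_args <- config$sim
    sim_args$rng_seed <- config$seed
    scfg <- do.call(sim_config, sim_args)
    res$sim <- stage("simulate", function() {
      gen <- generate_network(scfg)
      datasets <- generate_expression(gen$network, gen$truth, scfg)
      files <- c(
        net = file.path(outdir, "network.tsv"),
        truth = file.path(outdir, "truth.json"))
      write_edge_list(gen$network, files[["net"]])
      write_truth(gen$truth, files[["truth"]])
      for (i in seq_along(datasets)) {
        ep <- file.path(outdir, sprintf("cohort%02d_expr.tsv", i))
        ap <- file.path(outdir, sprintf("cohort%02d_samples.tsv", i))
        write_expression(datasets[[i]], ep, ap)
        files <- c(files, ep, ap)
      }
      list(value = list(network = gen$network, truth = gen$truth,
                        datasets = datasets), files = unname(files))
    })
    network <- res$sim$network
    datasets <- res$sim$datasets
  } else {
    network <- read_edge_list(config$network, "plain")
    datasets <- Map(read_expression, config$expression, config$annotation,
                    seq_along(config$expression))
    manifest$stages[[1L]] <- list(name = "load", files = character())
  }

  # --- score --------------------------------------------------------------
  res$scores <- stage("score", function() {
    tables <- lapply(datasets, score_genes)
    files <- vapply(seq_along(tables), function(i) {
      p <- file.path(outdir, sprintf("cohort%02d_scores.tsv", i))
      write_score_table(tables[[i]], p)
      p
    }, character(1))
    list(value = tables, files = files)
  })

  # --- per-cohort diagnostic networks --------------------------------------
  srch <- do.call(search_config, config$search)
  res$diagnostic <- stage("search", function() {
    nets <- lapply(seq_along(res$scores), function(i) {
      tab <- res$scores[[i]]
      diag_genes <- select_diagnostic_genes(tab, config$alpha)
      sub <- induce_subnetwork(network, diag_genes)
      if (igraph::vcount(sub) == 0L)
        return(structure(list(network = sub, nodes = character(),
                              score = NA_real_,
                              rounds = data.frame()),
                         class = "diagnostic_network"))
      scores <- stats::setNames(tab$t, tab$gene)
      scores[is.na(scores)] <- 0
      iterate_search(sub, scores, srch)
    })
    files <- vapply(seq_along(nets), function(i) {
      p <- file.path(outdir, sprintf("cohort%02d_diagnostic.tsv", i))
      write_edge_list(nets[[i]]$network, p)
      p
    }, character(1))
    list(value = nets, files = files)
  })

  # --- integrate ----------------------------------------------------------
  res$consensus <- stage("integrate", function() {
    nonempty <- Filter(function(n) length(n$nodes) > 0, res$diagnostic)
    files <- character()
    if (length(nonempty) >= 2L) {
      prof <- overlap_profile(nonempty)
      pp <- file.path(outdir, "overlap_profile.tsv")
      utils::write.table(prof, pp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- pp
    }
    cons <- if (length(nonempty))
      consensus_network(nonempty, k = config$k_support)
    else as_interaction_network(matrix(character(), ncol = 2))
    cp <- file.path(outdir, "consensus.tsv")
    write_consensus(cons, cp)
    list(value = cons, files = c(files, cp))
  })

  if (igraph::vcount(res$consensus) < 4L) {
    manifest$status <- "no_signal"
    manifest <- write_manifest(manifest, outdir)
    warning("consensus network empty or near-empty; downstream stages ",
            "skipped (status: no_signal)")
    return(invisible(list(status = "no_signal", manifest = manifest,
                          results = res)))
  }

  # --- pivotal ------------------------------------------------------------
  res$pivotal <- stage("pivotal", function() {
    bg <- degree_table(network)
    genes <- igraph::V(res$consensus)$name
    cuts <- degree_quantile_cutoffs(genes, bg)
    per <- per_level_representation(genes, bg, cuts)
    perm <- permutation_test_top_level(genes, bg, cuts, B = config$B,
                                       seed = config$seed + 101L)
    ec <- connectivity_enrichment(degree_table(res$consensus), bg)
    bp <- rank_breakpoints(ec)
    files <- c(file.path(outdir, "per_levels.tsv"),
               file.path(outdir, "ec_table.tsv"),
               file.path(outdir, "panels.json"))
    utils::write.table(per, files[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(bp$ranked, files[2], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_panels(list(permutation_p = perm$p, breakpoints = bp$breakpoints,
                      panels = bp$panels), files[3])
    list(value = list(cutoffs = cuts, per = per, permutation = perm,
                      ec = ec, breakpoints = bp), files = files)
  })

  # --- enrich -------------------------------------------------------------
  if (!is.null(config$gmt)) {
    res$enrichment <- stage("enrich", function() {
      lib <- read_gmt(config$gmt)
      er <- enrich(igraph::V(res$consensus)$name, lib,
                   seed = config$seed + 202L)
      p <- file.path(outdir, "enrichment.tsv")
      write_enrichment(er, p)
      list(value = er, files = p)
    })
  }

  # --- evaluate -----------------------------------------------------------
  res$evaluation <- stage("evaluate", function() {
    panel <- res$pivotal$ec$gene[seq_len(min(config$panel_size,
                                             nrow(res$pivotal$ec)))]
    eligible <- vapply(datasets, function(d) {
      y <- d$samples$subtype[d$samples$group == "tumor"]
      !any(is.na(y)) && all(table(y) >= 2L)
    }, logical(1))
    if (!all(eligible))
      warning(sum(!eligible), " cohort(s) skipped in evaluation: ",
              "a subtype class has fewer than 2 tumor samples")
    if (!any(eligible)) stop("no cohort eligible for cross-validation")
    reports <- lapply(which(eligible), function(i)
      cross_validate(datasets[[i]], panel, "kfold10",
                     knn_classifier(10), repeats = config$cv_repeats,
                     seed = config$seed + 303L + i))
    names(reports) <- sprintf("cohort%02d", which(eligible))
    p <- file.path(outdir, "cv_report.tsv")
    write_cv_table(reports, p)
    list(value = list(panel = panel, reports = reports), files = p)
  })

  manifest$status <- "ok"
  manifest <- write_manifest(manifest, outdir)
  invisible(list(status = "ok", manifest = manifest, results = res))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(manifest, outdir) {
  files <- unique(unlist(lapply(manifest$stages, `[[`, "files")))
  files <- files[file.exists(files)]
  manifest$files <- lapply(files, function(f)
    list(path = basename(f), md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
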