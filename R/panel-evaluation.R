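# Candidate-panel evaluation: a k-nearest-neighbour classifier with fully
# specified tie handling, leave-one-out and repeated stratified 10-fold
# cross-validation of subtype prediction, panel-growth trajectories,
# pooled-variance stratification t-tests, and agglomerative clustering of
# samples on the panel.

#' k-nearest-neighbour prediction
#'
#' Euclidean distance on the panel features; the predicted label is the
#' majority vote of the `k` nearest training samples.  Vote ties are broken
#' in favour of the tied class owning the single nearest neighbour;
#' distance ties are broken by training-sample order.  Both rules make the
#' prediction deterministic.
#'
#' @param train_matrix numeric matrix, samples in rows.
#' @param train_labels labels, one per training row.
#' @param test_vector numeric vector (one test sample) or matrix of test
#'   samples in rows.
#' @param k neighbourhood size, `1 <= k <= nrow(train_matrix)`.
#' @return predicted label(s).
#' @export
knn_predict <- function(train_matrix, train_labels, test_vector, k) {
  if (k < 1) stop("k must be at least 1")
  train_matrix <- as.matrix(train_matrix)
  if (k > nrow(train_matrix)) stop("k exceeds the number of training samples")
  train_labels <- as.character(train_labels)
  test <- if (is.matrix(test_vector)) test_vector else rbind(test_vector)
  unname(apply(test, 1, function(x) {
    d <- sqrt(rowSums(sweep(train_matrix, 2, x)^2))
    nn <- order(d)[seq_len(k)]          # order() is stable: sample order
    votes <- table(train_labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) return(top)
    for (i in nn) if (train_labels[i] %in% top) return(train_labels[i])
  }))
}

#' Classifier interfaces for cross-validation
#'
#' A classifier is a list with `fit(x, y)` returning a model and
#' `predict(model, newx)` returning labels, plus a `deterministic` flag
#' used to collapse repeats when resampling is the only source of
#' variation.  `knn_classifier()` wraps the package's [knn_predict()]
#' (the reference classifier); `svm_classifier()` wraps
#' \code{e1071::svm} when that package is available.
#'
#' @param k neighbourhood size (default 10).
#' @param ... passed to \code{e1071::svm}.
#' @return a `panel_classifier` list.
#' @export
knn_classifier <- function(k = 10) {
  structure(list(
    name = sprintf("knn%d", k),
    fit = function(x, y) list(x = as.matrix(x), y = y, k = k),
    predict = function(model, newx)
      knn_predict(model$x, model$y, as.matrix(newx),
                  min(model$k, nrow(model$x))),
    deterministic = TRUE), class = "panel_classifier")
}

#' @rdname knn_classifier
#' @export
svm_classifier <- function(...) {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("svm_classifier requires the e1071 package")
  structure(list(
    name = "svm",
    fit = function(x, y) e1071::svm(as.matrix(x), factor(y), ...),
    predict = function(model, newx)
      as.character(stats::predict(model, as.matrix(newx))),
    deterministic = TRUE), class = "panel_classifier")
}

# tumor-sample feature matrix (samples x panel) and subtype labels
panel_features <- function(dataset, panel) {
  panel <- toupper(panel)
  if (!all(panel %in% rownames(dataset$expr)))
    stop("panel gene(s) absent from dataset: ",
         paste(setdiff(panel, rownames(dataset$expr)), collapse = ", "))
  tum <- dataset$samples$group == "tumor"
  if (any(is.na(dataset$samples$subtype[tum])))
    stop("subtype labels undefined for some tumor samples")
  list(x = t(dataset$expr[panel, tum, drop = FALSE]),
       y = dataset$samples$subtype[tum])
}

# stratified fold assignment: within each class, shuffled cyclic fold ids,
# so class proportions per fold differ by at most one sample
stratified_folds <- function(y, nfold) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    ix <- which(y == cl)
    fold[ix] <- sample(rep_len(seq_len(nfold), length(ix)))
  }
  fold
}

#' Cross-validate a gene panel for subtype classification
#'
#' Tumor samples are classified into the four ER/PR/HER2 subtype classes
#' using only the panel genes.  `"loo"` leaves one sample out at a time;
#' `"kfold10"` uses stratified 10-fold splits, reshuffled on every repeat.
#' With a deterministic classifier, leave-one-out has no source of
#' variation, so the repeats collapse to a single run (recorded in the
#' report).
#'
#' @param dataset an `expression_dataset` with subtype labels.
#' @param panel character vector of panel genes.
#' @param scheme `"kfold10"` or `"loo"`.
#' @param classifier a `panel_classifier` (default [knn_classifier()] with
#'   k = 10).
#' @param repeats number of repeats (default 1000).
#' @param seed optional integer seed for the fold resampling.
#' @return a `cv_report` list: `scheme`, `classifier`, `repeats`,
#'   `collapsed` (repeats collapsed to one?), `accuracies`, and the
#'   `median`, `mean`, `max`, `min` accuracy.
#' @export
cross_validate <- function(dataset, panel, scheme = c("kfold10", "loo"),
                           classifier = knn_classifier(10), repeats = 1000,
                           seed = NULL) {
  scheme <- match.arg(scheme)
  feat <- panel_features(dataset, panel)
  x <- feat$x; y <- feat$y
  if (!is.null(seed)) set.seed(seed)
  collapsed <- FALSE
  if (scheme == "loo") {
    if (isTRUE(classifier$deterministic) && repeats > 1) {
      repeats <- 1L
      collapsed <- TRUE
    }
    acc <- vapply(seq_len(repeats), function(r) {
      pred <- vapply(seq_len(nrow(x)), function(i) {
        model <- classifier$fit(x[-i, , drop = FALSE], y[-i])
        classifier$predict(model, x[i, , drop = FALSE])[1]
      }, character(1))
      mean(pred == y)
    }, numeric(1))
  } else {
    nfold <- 10L
    if (any(table(y) < 2L))
      stop("a subtype class has fewer than 2 samples; ",
           "stratified 10-fold undefined")
    acc <- vapply(seq_len(repeats), function(r) {
      fold <- stratified_folds(y, nfold)
      pred <- character(length(y))
      for (f in seq_len(nfold)) {
        te <- fold == f
        if (!any(te)) next
        model <- classifier$fit(x[!te, , drop = FALSE], y[!te])
        pred[te] <- classifier$predict(model, x[te, , drop = FALSE])
      }
      mean(pred == y)
    }, numeric(1))
  }
  structure(list(scheme = scheme, classifier = classifier$name,
                 repeats = repeats, collapsed = collapsed,
                 accuracies = acc, median = stats::median(acc),
                 mean = mean(acc), max = max(acc), min = min(acc)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cross-validation (%s, %s, %d repeat%s%s)\n", x$scheme,
              x$classifier, x$repeats, if (x$repeats > 1) "s" else "",
              if (x$collapsed) ", collapsed: deterministic" else ""))
  cat(sprintf("  accuracy median %.3f mean %.3f max %.3f min %.3f\n",
              x$median, x$mean, x$max, x$min))
  invisible(x)
}

#' Prediction-power trajectory over growing panels
#'
#' Evaluates every prefix of a ranked gene list (one gene added at a time)
#' with [cross_validate()] and reports the mean accuracy per panel size.
#'
#' @inheritParams cross_validate
#' @param ranked_genes genes in the order they join the panel.
#' @return data frame with `size`, `gene_added`, `mean_accuracy`.
#' @export
panel_trajectory <- function(dataset, ranked_genes,
                             scheme = c("kfold10", "loo"),
                             classifier = knn_classifier(10), repeats = 20,
                             seed = NULL) {
  scheme <- match.arg(scheme)
  if (!length(ranked_genes)) stop("ranked gene list is empty")
  acc <- vapply(seq_along(ranked_genes), function(s)
    cross_validate(dataset, ranked_genes[seq_len(s)], scheme, classifier,
                   repeats, seed = if (is.null(seed)) NULL else seed + s)$mean,
    numeric(1))
  data.frame(size = seq_along(ranked_genes), gene_added = ranked_genes,
             mean_accuracy = acc, stringsAsFactors = FALSE)
}

#' Subtype stratification t-test for one gene
#'
#' Pooled-variance two-sample Student t-test of the gene's tumor expression
#' between two subtype strata: `"ER"` contrasts ER-positive against
#' ER-negative tumors, `"TNG"` contrasts triple-negative tumors against the
#' rest.
#'
#' @param dataset an `expression_dataset`.
#' @param gene gene symbol.
#' @param grouping `"ER"` or `"TNG"`.
#' @return list with `t`, `p`, `n1`, `n2` (group 1 is ER-positive /
#'   triple-negative respectively).
#' @export
stratify_t <- function(dataset, gene, grouping = c("ER", "TNG")) {
  grouping <- match.arg(grouping)
  gene <- toupper(gene)
  if (!gene %in% rownames(dataset$expr)) stop("gene absent: ", gene)
  tum <- dataset$samples$group == "tumor"
  x <- dataset$expr[gene, tum]
  g1 <- if (grouping == "ER") dataset$samples$ER[tum] == "positive"
        else dataset$samples$subtype[tum] == "TNG"
  if (sum(g1) < 2L || sum(!g1) < 2L)
    stop("degenerate stratification: a group has fewer than 2 samples")
  tt <- stats::t.test(x[g1], x[!g1], var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, n1 = sum(g1),
       n2 = sum(!g1))
}

#' Agglomerative clustering of samples on a panel
#'
#' Hierarchical clustering of all samples restricted to the panel genes,
#' with Euclidean or correlation distance and average, complete or Ward
#' linkage.  Returns the leaf order (the heatmap column order) and the
#' merge tree.
#'
#' @param dataset an `expression_dataset`.
#' @param panel panel genes.
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @param linkage `"average"`, `"complete"` or `"ward"`.
#' @return list with `order` (sample IDs in leaf order), `merge`, and the
#'   underlying `hclust` object.
#' @export
cluster_order <- function(dataset, panel,
                          distance = c("euclidean", "correlation"),
                          linkage = c("average", "complete", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  panel <- toupper(panel)
  x <- t(dataset$expr[panel, , drop = FALSE])
  if (nrow(x) < 2L) stop("need at least 2 samples")
  d <- if (distance == "euclidean") stats::dist(x)
       else stats::as.dist(1 - stats::cor(t(x)))
  hc <- stats::hclust(d, method = if (linkage == "ward") "ward.D2"
                                  else linkage)
  list(order = rownames(x)[hc$order], merge = hc$merge, hclust = hc)
}

#' Write a cross-validation report table
#'
#' One row per (panel, dataset, scheme, classifier) with the four summary
#' statistics, mirroring the layout panel-evaluation tables use.
#'
#' @param reports named list of `cv_report`s (names label the rows).
#' @param path output TSV.
#' @export
write_cv_table <- function(reports, path) {
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(panel = nm, scheme = r$scheme, classifier = r$classifier,
               repeats = r$repeats, median = r$median, mean = r$mean,
               max = r$max, min = r$min)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
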