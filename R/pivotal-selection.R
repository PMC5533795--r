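# Pivotal-gene selection from the consensus network: degree-quantile
# representation against the background interaction graph, a permutation
# null for the top quantile, per-gene connectivity enrichment (consensus
# degree over background degree), and break-point detection on the ranked
# enrichment profile to propose candidate panels.

#' Degree-quantile cutoffs for a selected gene set
#'
#' Splits the degree range into four contiguous integer intervals at the
#' quartiles (type-1, i.e. order-statistic quantiles) of the background
#' degrees of the selected genes, covering `[min degree, Inf)`.
#'
#' @param selected_genes genes whose background degrees define the
#'   quartiles (at least 4).
#' @param background_degrees named integer vector, gene -> degree in the
#'   background graph (see [degree_table()]).
#' @return data frame with columns `level` (1-4), `lower`, `upper`
#'   (`upper = Inf` for the top level).
#' @export
degree_quantile_cutoffs <- function(selected_genes, background_degrees) {
  selected_genes <- toupper(selected_genes)
  if (!all(selected_genes %in% names(background_degrees)))
    stop("selected genes missing from the background degree table")
  d <- background_degrees[selected_genes]
  if (length(d) < 4L) stop("need at least 4 selected genes")
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), type = 1, names = FALSE)
  q <- as.integer(q)
  if (length(unique(q)) < 3L || any(diff(q) <= 0))
    stop("degenerate quartiles: selected degrees do not separate into 4 levels")
  lower <- c(min(min(d), 1L), q + 1L)
  upper <- c(q, Inf)
  if (any(lower[-1] > upper[-1]))
    stop("degenerate quartiles: selected degrees do not separate into 4 levels")
  data.frame(level = 1:4, lower = lower, upper = upper)
}

# level index (1..4 or NA) of each degree under the interval table
degree_level <- function(degrees, intervals) {
  lev <- rep(NA_integer_, length(degrees))
  for (i in seq_len(nrow(intervals))) {
    hit <- degrees >= intervals$lower[i] & degrees <= intervals$upper[i]
    lev[hit & is.na(lev)] <- intervals$level[i]
  }
  lev
}

#' Per-level representation of a gene set in the background
#'
#' For each degree level, the fraction of background genes in that level
#' that belong to the selected set: `Per_i = N_selected,i / N_background,i`.
#' An empty background level yields `NA` with a warning.
#'
#' @param selected selected gene symbols.
#' @param background_degrees named background degree vector.
#' @param intervals interval table from [degree_quantile_cutoffs()].
#' @return data frame with `level`, `lower`, `upper`, `n_selected`,
#'   `n_background`, `per` (fraction).
#' @export
per_level_representation <- function(selected, background_degrees,
                                     intervals) {
  selected <- toupper(selected)
  lev_bg <- degree_level(background_degrees, intervals)
  lev_sel <- lev_bg[names(background_degrees) %in% selected]
  n_bg <- vapply(intervals$level, function(l) sum(lev_bg == l, na.rm = TRUE),
                 numeric(1))
  n_sel <- vapply(intervals$level, function(l)
    sum(lev_sel == l, na.rm = TRUE), numeric(1))
  per <- ifelse(n_bg > 0, n_sel / n_bg, NA_real_)
  if (any(n_bg == 0)) warning("empty background level; Per undefined there")
  cbind(intervals, n_selected = n_sel, n_background = n_bg, per = per)
}

#' Permutation test for top-level degree enrichment
#'
#' Tests whether the representation of the selected set in the most highly
#' connected level (level 4, the top degree quartile) could arise by chance:
#' `B` random gene sets of the same size are drawn from the background
#' without replacement, the top-level `Per` statistic is recomputed for
#' each, and `p = (1 + #{permuted >= observed}) / (B + 1)` (the add-one
#' estimator, so p is never exactly 0).  The statistic depends only on the
#' degree multiset, so the test is invariant to gene relabelling.
#'
#' @param selected selected gene symbols.
#' @param background_degrees named background degree vector.
#' @param intervals interval table from [degree_quantile_cutoffs()].
#' @param B number of permutations (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @return list with `p`, `observed` (top-level Per), `B`, and
#'   `perm_mean`.
#' @export
permutation_test_top_level <- function(selected, background_degrees,
                                       intervals, B = 1000, seed = NULL) {
  stopifnot(B >= 1)
  selected <- toupper(selected)
  if (length(selected) > length(background_degrees))
    stop("selected set larger than background")
  if (!is.null(seed)) set.seed(seed)
  lev_bg <- degree_level(background_degrees, intervals)
  top <- max(intervals$level)
  n_bg_top <- sum(lev_bg == top, na.rm = TRUE)
  if (n_bg_top == 0) stop("no background genes in the top level")
  in_top <- !is.na(lev_bg) & lev_bg == top
  observed <- sum(in_top[names(background_degrees) %in% selected]) / n_bg_top
  m <- length(selected)
  perm <- vapply(seq_len(B), function(b)
    sum(in_top[sample.int(length(in_top), m)]) / n_bg_top, numeric(1))
  list(p = (1 + sum(perm >= observed)) / (B + 1), observed = observed,
       B = B, perm_mean = mean(perm))
}

#' Connectivity enrichment of consensus-network genes
#'
#' `EC_j = (degree of gene j in the consensus network) / (degree of gene j
#' in the background graph)`.  Because the consensus network is a
#' restriction of the background, EC never exceeds 1; hub genes that keep
#' only a sliver of their interactions score low, genes whose interactions
#' are concentrated in the consensus network score high.
#'
#' @param subnet_degrees named degree vector of the consensus network (see
#'   [degree_table()]), or the network itself.
#' @param background_degrees named background degree vector, or network.
#' @return data frame sorted by descending `ec` (ties by descending
#'   consensus degree, then lexicographic): `gene`, `degree_subnet`,
#'   `degree_background`, `ec`.
#' @export
connectivity_enrichment <- function(subnet_degrees, background_degrees) {
  if (inherits(subnet_degrees, "igraph"))
    subnet_degrees <- degree_table(subnet_degrees)
  if (inherits(background_degrees, "igraph"))
    background_degrees <- degree_table(background_degrees)
  genes <- names(subnet_degrees)
  if (!all(genes %in% names(background_degrees)))
    stop("consensus gene(s) missing from the background: ",
         paste(setdiff(genes, names(background_degrees)), collapse = ", "))
  bg <- background_degrees[genes]
  if (any(bg == 0))
    stop("background degree 0 for: ",
         paste(genes[bg == 0], collapse = ", "))
  ec <- as.numeric(subnet_degrees) / as.numeric(bg)
  out <- data.frame(gene = genes,
                    degree_subnet = as.integer(subnet_degrees),
                    degree_background = as.integer(bg), ec = ec,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$ec, -out$degree_subnet, out$gene), , drop = FALSE]
}

#' Break points on the ranked connectivity-enrichment profile
#'
#' Genes are ranked by descending EC; the drop score at position i is
#' `(EC_i - EC_{i+1}) / EC_i`, the relative fall to the next gene.  The
#' `n_breakpoints` positions with the largest drops are the candidate panel
#' boundaries; each defines a top-`b` panel, and when the gene at a boundary
#' ties in EC with its predecessor the shorter top-`b-1` panel is added as
#' well (tied genes cannot themselves be separated by a break).
#'
#' @param ec_table output of [connectivity_enrichment()] (at least 3 genes).
#' @param n_breakpoints number of boundaries to report (default 2).
#' @return list with `ranked` (the table plus `rank` and `drop` columns),
#'   `breakpoints` (positions), and `panels` (list of
#'   `list(size, genes, drop_score)` sorted by decreasing size).
#' @export
rank_breakpoints <- function(ec_table, n_breakpoints = 2) {
  if (nrow(ec_table) < 3L) stop("need at least 3 genes")
  tab <- ec_table[order(-ec_table$ec, -ec_table$degree_subnet,
                        ec_table$gene), , drop = FALSE]
  n <- nrow(tab)
  drop <- c((tab$ec[-n] - tab$ec[-1]) / tab$ec[-n], NA)
  tab$rank <- seq_len(n)
  tab$drop <- drop
  ord <- order(-drop[-n], seq_len(n - 1))
  bp <- sort(ord[seq_len(min(n_breakpoints, n - 1))])
  sizes <- integer()
  for (b in bp) {
    sizes <- c(sizes, b)
    if (b > 1 && tab$ec[b] == tab$ec[b - 1]) sizes <- c(sizes, b - 1L)
  }
  sizes <- sort(unique(sizes), decreasing = TRUE)
  panels <- lapply(sizes, function(s)
    list(size = s, genes = tab$gene[seq_len(s)],
         drop_score = tab$drop[s]))
  list(ranked = tab, breakpoints = bp, panels = panels)
}

#' Write pivotal-selection outputs
#'
#' The EC and Per tables as TSV, candidate panels as JSON.
#'
#' @param x table or panel list.
#' @param path output file.
#' @name pivotal_io
#' @export
write_panels <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
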