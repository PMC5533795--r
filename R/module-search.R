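# Greedy active-subnetwork search.  Each gene carries a differential
# t-score; starting from a seed node the module grows by repeatedly adding
# the frontier node that most increases the module score, and stops when no
# addition strictly increases it.  One greedy run per seed gene, the
# node sets of the top-scoring modules are merged, and the search is
# iterated on the shrinking induced subgraph until the node count reaches
# the stopping size (about 50 by default).

#' Search configuration
#'
#' @param method module scoring method: `"norm_agg"` (default,
#'   `sum(|t|)/sqrt(k)` -- the classic size-penalized active-module
#'   aggregate), `"sum"` (plain `sum(|t|)`, which can never favour a smaller
#'   module), or `"mi"` (histogram mutual information between module and
#'   frontier score distributions; see [module_score()]).
#' @param top_k number of top-ranked modules whose node sets are merged per
#'   round (default 10).
#' @param stop_size,stop_slack iteration stops once the merged node count is
#'   at most `stop_size + stop_slack` (defaults 50 + 5, i.e. "approximately
#'   50"), or once it stops shrinking.
#' @param mi_bins number of equal-width bins for the `"mi"` method.
#' @return a `search_config` list.
#' @export
search_config <- function(method = c("norm_agg", "sum", "mi"), top_k = 10,
                          stop_size = 50, stop_slack = 5, mi_bins = 8) {
  method <- match.arg(method)
  stopifnot(top_k >= 1, stop_size >= 1, stop_slack >= 0, mi_bins >= 2)
  structure(list(method = method, top_k = as.integer(top_k),
                 stop_size = as.integer(stop_size),
                 stop_slack = as.integer(stop_slack),
                 mi_bins = as.integer(mi_bins)),
            class = "search_config")
}

#' Score a candidate module
#'
#' `sum` is the accumulated absolute t-score; `norm_agg` divides it by
#' `sqrt(k)` so that adding weak nodes is penalized; `mi` is an operational
#' mutual-information score: |t| values of module members and of the
#' frontier (non-member neighbours) are pooled into `mi_bins` equal-width
#' bins and the score is the mutual information between bin membership and
#' module-vs-frontier membership.  A per-node scalar does not define the
#' joint density a textbook MI would need, so `mi` is an interpretation, and
#' `norm_agg` is the default.
#'
#' @param nodes character vector of module genes (non-empty).
#' @param scores named numeric vector of per-gene t-scores.
#' @param method `"sum"`, `"norm_agg"` or `"mi"`.
#' @param net interaction network; required for `"mi"` (defines the
#'   frontier), ignored otherwise.
#' @param mi_bins bin count for `"mi"`.
#' @return the module score.
#' @export
module_score <- function(nodes, scores, method = "norm_agg", net = NULL,
                         mi_bins = 8) {
  if (!length(nodes)) stop("module must be non-empty")
  if (!all(nodes %in% names(scores)))
    stop("missing score for: ",
         paste(setdiff(nodes, names(scores)), collapse = ", "))
  a <- abs(scores[nodes])
  switch(method,
    sum = sum(a),
    norm_agg = sum(a) / sqrt(length(nodes)),
    mi = {
      if (is.null(net)) stop("method 'mi' requires the network")
      frontier <- setdiff(
        unique(unlist(lapply(nodes, function(v)
          igraph::neighbors(net, v)$name))), nodes)
      mi_membership(abs(scores[nodes]), abs(scores[frontier]), mi_bins)
    },
    stop("unknown scoring method: ", method))
}

# MI between bin index and set membership for two score samples
mi_membership <- function(x, y, bins) {
  if (!length(y)) return(0)
  all <- c(x, y)
  if (diff(range(all)) == 0) return(0)   # one occupied bin carries no MI
  br <- seq(min(all), max(all), length.out = bins + 1)
  br[1] <- br[1] - 1e-9; br[length(br)] <- br[length(br)] + 1e-9
  cx <- tabulate(cut(x, br, labels = FALSE), bins)
  cy <- tabulate(cut(y, br, labels = FALSE), bins)
  joint <- rbind(cx, cy) / (length(x) + length(y))
  px <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (i in 1:2) for (j in seq_len(bins))
    if (joint[i, j] > 0)
      mi <- mi + joint[i, j] * log(joint[i, j] / (px[i] * py[j]))
  mi
}

# adjacency list of integer neighbour indices, named by vertex
adjacency_index <- function(net) {
  adj <- igraph::as_adj_list(net)
  lapply(adj, as.integer)
}

#' Greedy seed expansion
#'
#' Starts from `{seed}` and repeatedly adds the frontier node yielding the
#' largest strict increase of the module score, stopping when no candidate
#' increases it.  Ties in candidate gain are broken by lexicographic gene
#' symbol, making the search fully deterministic.  The result is always a
#' connected subgraph containing the seed.
#'
#' @param net interaction network.
#' @param scores named numeric vector of per-gene t-scores covering the
#'   network's nodes.
#' @param seed seed gene symbol.
#' @param config a [search_config()].
#' @return a `scored_module` list: `nodes`, `score`, `method`, `seed`.
#' @export
greedy_expand <- function(net, scores, seed, config = search_config()) {
  vn <- igraph::V(net)$name
  if (!seed %in% vn) stop("seed not in network: ", seed)
  if (!all(vn %in% names(scores)))
    stop("scores missing for some network nodes")
  adj <- adjacency_index(net)
  s_abs <- abs(scores[vn])
  idx <- match(seed, vn)
  in_mod <- logical(length(vn))
  in_mod[idx] <- TRUE
  members <- idx
  cur_sum <- s_abs[idx]
  slow <- config$method == "mi"
  score <- if (slow)
    module_score(vn[members], scores, config$method, net, config$mi_bins)
  else module_score(vn[members], scores, config$method)
  frontier <- setdiff(adj[[idx]], members)
  while (length(frontier)) {
    if (slow) {
      gains <- vapply(frontier, function(f)
        module_score(vn[c(members, f)], scores, "mi", net, config$mi_bins),
        numeric(1))
    } else if (config$method == "sum") {
      gains <- cur_sum + s_abs[frontier]
    } else {
      gains <- (cur_sum + s_abs[frontier]) / sqrt(length(members) + 1)
    }
    ord <- order(-gains, vn[frontier])
    best <- ord[1]
    if (gains[best] <= score) break
    add <- frontier[best]
    score <- gains[best]
    cur_sum <- cur_sum + s_abs[add]
    members <- c(members, add)
    in_mod[add] <- TRUE
    frontier <- union(frontier[-best], setdiff(adj[[add]], members))
    frontier <- frontier[!in_mod[frontier]]
  }
  structure(list(nodes = sort(vn[members]), score = unname(score),
                 method = config$method, seed = seed),
            class = "scored_module")
}

#' One search round: expand from every seed, merge the top modules
#'
#' Runs [greedy_expand()] once with each network node as the seed, ranks the
#' resulting modules by score (ties by seed symbol), and returns the union
#' of the node sets of the `top_k` best modules.  Deterministic.
#'
#' @inheritParams greedy_expand
#' @return sorted character vector of merged node symbols.
#' @export
search_round <- function(net, scores, config = search_config()) {
  vn <- sort(igraph::V(net)$name)
  if (!length(vn)) stop("network is empty")
  mods <- lapply(vn, function(s) greedy_expand(net, scores, s, config))
  sc <- vapply(mods, `[[`, numeric(1), "score")
  ord <- order(-sc, vn)
  top <- mods[ord[seq_len(min(config$top_k, length(mods)))]]
  sort(unique(unlist(lapply(top, `[[`, "nodes"))))
}

#' Iterated merge-and-shrink search
#'
#' Round r searches the subgraph induced by round r-1's merged node set, so
#' the node count is non-increasing.  Iteration stops once the count is at
#' most `stop_size + stop_slack` or once it stops shrinking; the final node
#' set with its induced edges is the cohort's diagnostic network.
#'
#' @inheritParams greedy_expand
#' @return a `diagnostic_network` list: `network` (induced graph), `nodes`,
#'   `score` (module score of the final node set), `rounds` (data frame of
#'   round, node count, best module score).
#' @export
iterate_search <- function(net, scores, config = search_config()) {
  sub <- net
  n_prev <- Inf
  rounds <- list()
  r <- 0L
  nodes <- sort(igraph::V(net)$name)
  repeat {
    n_cur <- igraph::vcount(sub)
    if (n_cur == 0L) break
    if (n_cur <= config$stop_size + config$stop_slack || n_cur >= n_prev)
      break
    r <- r + 1L
    nodes <- search_round(sub, scores, config)
    n_prev <- n_cur
    sub <- igraph::induced_subgraph(sub, nodes)
    best <- if (config$method == "mi")
      module_score(nodes, scores, "mi", sub, config$mi_bins)
    else module_score(nodes, scores, config$method)
    rounds[[r]] <- data.frame(round = r, n_nodes = length(nodes),
                              score = best)
  }
  nodes <- sort(igraph::V(sub)$name)
  score <- if (!length(nodes)) NA_real_
    else if (config$method == "mi")
      module_score(nodes, scores, "mi", sub, config$mi_bins)
    else module_score(nodes, scores, config$method)
  structure(list(network = sub, nodes = nodes, score = score,
                 rounds = if (length(rounds)) do.call(rbind, rounds)
                          else data.frame(round = integer(),
                                          n_nodes = integer(),
                                          score = numeric())),
            class = "diagnostic_network")
}
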