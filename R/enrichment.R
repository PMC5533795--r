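# Gene-set enrichment of the consensus-network genes over GMT libraries:
# one-sided Fisher exact (hypergeometric) over-representation p, BH
# adjustment across terms, a rank-deviation Z against random query lists,
# and the combined score C = log10(p) * Z.

#' Read and write GMT gene-set libraries
#'
#' One term per line: name, description, then member genes, tab-separated.
#' Symbols are upper-cased on read.
#'
#' @param path GMT file.
#' @param library named list of character vectors (term -> genes).
#' @name gmt_io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t")
  bad <- lengths(fields) < 3L
  if (any(bad)) warning(sum(bad), " malformed GMT line(s) skipped")
  fields <- fields[!bad]
  if (!length(fields)) stop("no terms parsed from ", path)
  lib <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(lib) <- vapply(fields, `[[`, character(1), 1)
  lib
}

#' @rdname gmt_io
#' @export
write_gmt <- function(library, path) {
  lines <- vapply(names(library), function(nm)
    paste(c(nm, nm, library[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Fisher exact over-representation p-value
#'
#' The upper hypergeometric tail `P(X >= overlap)` for drawing `query_size`
#' genes from a background of `background_size` of which `term_size` belong
#' to the term.
#'
#' @param overlap observed overlap count.
#' @param query_size number of query genes.
#' @param term_size number of term genes.
#' @param background_size size of the gene universe.
#' @return p in (0, 1].
#' @export
fisher_p <- function(overlap, query_size, term_size, background_size) {
  if (overlap < 0 || overlap > min(query_size, term_size) ||
      term_size > background_size || query_size > background_size ||
      overlap < query_size + term_size - background_size)
    stop("inconsistent contingency counts")
  stats::phyper(overlap - 1, term_size, background_size - term_size,
                query_size, lower.tail = FALSE)
}

# Fisher p of every term for one query, given precomputed term sizes
term_pvalues <- function(query, library, term_sizes, background_size) {
  q <- length(query)
  vapply(seq_along(library), function(i) {
    ov <- sum(library[[i]] %in% query)
    fisher_p(ov, q, term_sizes[i], background_size)
  }, numeric(1))
}

#' Rank-deviation Z-score for one term
#'
#' The library's terms are ranked by Fisher p for the observed query and
#' for `n_random` random queries of the same size drawn from the
#' background; Z is the observed rank's deviation from the null mean rank
#' in null standard-deviation units.  Enrichment improves (lowers) the
#' observed rank, so enriched terms have negative Z.
#'
#' @param term term name (must exist in `library`).
#' @param query character vector of query genes.
#' @param library named list of term gene sets.
#' @param background_size gene universe size (default: distinct genes in
#'   the library).
#' @param n_random number of random query lists (default 200).
#' @param seed optional integer seed.
#' @return Z, or `NA` (with a warning) when the null rank variance is zero.
#' @export
rank_z <- function(term, query, library, background_size = NULL,
                   n_random = 200, seed = NULL) {
  z <- enrich(query, library, background_size = background_size,
              n_random = n_random, seed = seed)
  z$z[match(term, z$term)]
}

#' Combined enrichment score
#'
#' `C = log10(p) * Z`; with an enriched term both factors are negative, so
#' large positive C marks strong enrichment, and `p = 1` gives C = 0.
#'
#' @param p Fisher p-value in (0, 1].
#' @param z rank-deviation Z.
#' @return the combined score.
#' @export
c_score <- function(p, z) {
  if (any(p <= 0)) stop("p must be positive")
  log10(p) * z
}

#' Gene-set enrichment over a GMT library
#'
#' For each term: the overlap with the query, the Fisher exact p, the BH
#' adjusted p across the library's terms, the rank-deviation Z (one shared
#' set of `n_random` random queries ranks every term), and the combined
#' score.  Results are sorted by descending C.
#'
#' @param query_genes character vector of query gene symbols (non-empty).
#' @param library named list of term gene sets, as from [read_gmt()].
#' @param background_size gene universe size; defaults to the number of
#'   distinct genes in the library and must be at least that.
#' @param n_random random query lists behind Z (default 200).
#' @param seed optional integer seed; fixing it makes results reproducible.
#' @return an `enrichment_result` data frame: `term`, `overlap`, `p`,
#'   `p_adj`, `z`, `c`, `genes` (semicolon-joined overlap genes).
#' @export
enrich <- function(query_genes, library, background_size = NULL,
                   n_random = 200, seed = NULL) {
  if (!length(query_genes)) stop("empty query")
  if (!length(library)) stop("empty library")
  query_genes <- unique(toupper(query_genes))
  universe <- unique(unlist(library))
  if (is.null(background_size)) background_size <- length(universe)
  if (background_size < length(universe))
    stop("background smaller than the library's gene universe")
  term_sizes <- lengths(library)
  # query genes outside the universe cannot overlap any term; the draw size
  # is the in-universe part of the query
  q_in <- intersect(query_genes, universe)
  q_eff <- max(length(q_in), 1L)
  p <- term_pvalues(q_in, library, term_sizes, background_size)
  obs_rank <- rank(p, ties.method = "average")
  if (!is.null(seed)) set.seed(seed)
  null_ranks <- matrix(NA_real_, n_random, length(library))
  for (r in seq_len(n_random)) {
    rq <- sample(universe, min(q_eff, length(universe)))
    null_ranks[r, ] <- rank(term_pvalues(rq, library, term_sizes,
                                         background_size),
                            ties.method = "average")
  }
  mu <- colMeans(null_ranks)
  sd <- apply(null_ranks, 2, stats::sd)
  z <- ifelse(sd > 0, (obs_rank - mu) / sd, NA_real_)
  if (any(sd == 0)) warning("zero null rank variance for some term(s); ",
                            "Z undefined there")
  ov <- vapply(library, function(g) sum(g %in% q_in), integer(1))
  genes <- vapply(library, function(g)
    paste(sort(intersect(g, q_in)), collapse = ";"), character(1))
  out <- data.frame(term = names(library), overlap = ov, p = p,
                    p_adj = bh_adjust(p), z = z, c = log10(p) * z,
                    genes = genes, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(-ifelse(is.na(out$c), -Inf, out$c), out$term), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @rdname gmt_io
#' @param result an `enrichment_result`.
#' @export
write_enrichment <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
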