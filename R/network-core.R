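#' @importFrom igraph graph_from_edgelist simplify V E degree induced_subgraph
#'   delete_vertices vcount ecount as_edgelist vertex_attr edge_attr
#'   make_empty_graph add_vertices neighbors gsize
NULL

#' Build an interaction network from a two-column edge matrix
#'
#' Constructs the package's canonical undirected interaction network: gene
#' symbols are upper-cased, self-loops are removed, and duplicate edges are
#' collapsed.  The result is a plain \pkg{igraph} object; all network
#' operations in the package accept and return this representation.
#'
#' @param edges character matrix (or data frame) with two columns of gene
#'   symbols, one row per interaction.
#' @param nodes optional character vector of additional node names to include
#'   even when they carry no edge.
#' @return an undirected, simple \pkg{igraph} graph with named vertices.
#' @export
as_interaction_network <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  if (length(edges) == 0L) {
    el <- matrix(character(), ncol = 2)
  } else {
    el <- cbind(toupper(as.character(edges[, 1])),
                toupper(as.character(edges[, 2])))
  }
  keep <- el[, 1] != el[, 2]          # self-loops out
  el <- el[keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (!is.null(nodes)) {
    nodes <- setdiff(toupper(nodes), igraph::V(g)$name)
    if (length(nodes)) g <- igraph::add_vertices(g, length(nodes), name = nodes)
  }
  g
}

#' Read an interaction network from disk
#'
#' Two dialects are supported.  `"plain"` expects a headerless (or
#' `#`-commented) two-column TSV of gene symbols.  `"biogrid-tab3"` parses a
#' BioGRID TAB3 export: rows are kept when both interactor organisms match
#' `organism` and the experimental system type equals `system_type`, genes are
#' taken from the Official Symbol columns, and symbols are upper-cased.
#' Self-loops and duplicate pairs are dropped in both dialects.  Malformed
#' rows are skipped with a warning and counted in the parse report attached as
#' the graph attribute `parse_report` (`total`, `kept`, `skipped`,
#' `filtered`); `kept + skipped + filtered` equals the input row count.
#'
#' @param path file path.
#' @param dialect `"plain"` or `"biogrid-tab3"`.
#' @param organism organism identifier both interactors must carry
#'   (BioGRID numeric taxon id as character; default human, `"9606"`).
#' @param system_type experimental system type to keep (default
#'   `"physical"`).
#' @return an interaction network (see [as_interaction_network()]).
#' @export
read_edge_list <- function(path, dialect = c("plain", "biogrid-tab3"),
                           organism = "9606", system_type = "physical") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "plain") {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    total <- length(lines)
    fields <- strsplit(lines, "\t| +")
    ok <- vapply(fields, function(f) length(f) >= 2L && all(nzchar(f[1:2])),
                 logical(1))
    if (any(!ok))
      warning(sum(!ok), " malformed row(s) skipped in ", path)
    el <- do.call(rbind, lapply(fields[ok], function(f) f[1:2]))
    if (is.null(el)) stop("no edges parsed from ", path)
    net <- as_interaction_network(el)
    report <- list(total = total, kept = sum(ok), skipped = sum(!ok),
                   filtered = 0L)
  } else {
    tab <- utils::read.delim(path, check.names = TRUE,
                             colClasses = "character", comment.char = "")
    total <- nrow(tab)
    col <- function(patterns) {
      for (p in patterns) {
        hit <- grep(p, names(tab), ignore.case = TRUE)
        if (length(hit)) return(hit[1])
      }
      stop("required column matching ", patterns[1], " absent in ", path)
    }
    a  <- col("Official.?Symbol.*A")
    b  <- col("Official.?Symbol.*B")
    oa <- col(c("Organism.?ID.*A", "Organism.*A"))
    ob <- col(c("Organism.?ID.*B", "Organism.*B"))
    st <- col("Experimental.?System.?Type")
    bad <- !nzchar(tab[[a]]) | !nzchar(tab[[b]]) | tab[[a]] == "-" |
      tab[[b]] == "-"
    if (any(bad)) warning(sum(bad), " malformed row(s) skipped in ", path)
    pass <- !bad & tab[[oa]] == organism & tab[[ob]] == organism &
      tolower(tab[[st]]) == tolower(system_type)
    if (!any(pass)) stop("no interactions pass the filters in ", path)
    net <- as_interaction_network(cbind(tab[[a]][pass], tab[[b]][pass]))
    report <- list(total = total, kept = sum(pass), skipped = sum(bad),
                   filtered = sum(!pass & !bad))
  }
  igraph::graph_attr(net, "parse_report") <- report
  net
}

#' Induce a subnetwork on a gene set
#'
#' Keeps the edges of `net` with both endpoints in `genes`.  Members of
#' `genes` left without any edge are removed when `drop_isolated` is `TRUE`
#' (the default), matching the convention that a protein network node must
#' interact with something.
#'
#' @param net interaction network.
#' @param genes character vector of gene symbols (case-insensitive).
#' @param drop_isolated drop degree-0 members of `genes`?
#' @return induced interaction network.
#' @export
induce_subnetwork <- function(net, genes, drop_isolated = TRUE) {
  genes <- intersect(toupper(genes), igraph::V(net)$name)
  sub <- igraph::induced_subgraph(net, genes)
  if (drop_isolated) {
    iso <- igraph::V(sub)[igraph::degree(sub) == 0]
    if (length(iso)) sub <- igraph::delete_vertices(sub, iso)
  }
  sub
}

#' Node degree lookups
#'
#' `net_degree()` returns the number of edges incident to one gene and errors
#' on unknown genes; `degree_table()` returns the full named gene-to-degree
#' mapping.
#'
#' @param net interaction network.
#' @param gene single gene symbol.
#' @return integer degree, or a named integer vector for `degree_table()`.
#' @export
net_degree <- function(net, gene) {
  gene <- toupper(gene)
  if (!gene %in% igraph::V(net)$name) stop("gene not in network: ", gene)
  unname(igraph::degree(net, gene))
}

#' @rdname net_degree
#' @export
degree_table <- function(net) {
  d <- igraph::degree(net)
  stats::setNames(as.integer(d), igraph::V(net)$name)
}

#' Write a network as a two-column TSV edge list or SIF
#'
#' Isolated nodes are preserved in SIF output as single-column rows, the
#' Cytoscape convention; the plain edge list keeps edges only.
#'
#' @param net interaction network.
#' @param path output file.
#' @param interaction SIF interaction type label.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_sif <- function(net, path, interaction = "pp") {
  el <- igraph::as_edgelist(net)
  lines <- character(0)
  if (nrow(el)) lines <- paste(el[, 1], interaction, el[, 2], sep = "\t")
  iso <- setdiff(igraph::V(net)$name, unique(c(el)))
  writeLines(c(lines, iso), path)
  invisible(path)
}
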