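# Per-cohort differential scoring: Welch-type t statistic over tumor vs
# normal groups, two-sided p from the t reference distribution with
# Welch-Satterthwaite degrees of freedom, and Benjamini-Hochberg adjustment
# within the candidate gene universe.

#' Welch two-sample t statistic
#'
#' `t = (mean(x1) - mean(x2)) / sqrt(var(x1)/n1 + var(x2)/n2)` with sample
#' variances on the n-1 denominator.  By the package's sign convention group
#' 1 is tumor and group 2 normal, so positive t means higher expression in
#' tumors.
#'
#' @param x1,x2 numeric vectors, each of length >= 2.
#' @return the t statistic.
#' @export
welch_t <- function(x1, x2) {
  if (length(x1) < 2L || length(x2) < 2L)
    stop("each group needs at least 2 samples")
  v1 <- stats::var(x1); v2 <- stats::var(x2)
  se2 <- v1 / length(x1) + v2 / length(x2)
  if (se2 == 0) {
    if (mean(x1) == mean(x2)) return(0)
    stop("undefined statistic: both group variances are zero")
  }
  (mean(x1) - mean(x2)) / sqrt(se2)
}

#' Two-sided p-value for a Welch t statistic
#'
#' Uses the t reference distribution with Welch-Satterthwaite degrees of
#' freedom computed from the group variances; with the default unit
#' variances the df reduce to the equal-variance value.
#'
#' @param t statistic.
#' @param n1,n2 group sizes.
#' @param var1,var2 group sample variances (default 1 each).
#' @return two-sided p in (0, 1]; symmetric in the sign of `t`.
#' @export
t_to_p <- function(t, n1, n2, var1 = 1, var2 = 1) {
  if (!is.finite(t)) stop("t must be finite")
  a <- var1 / n1; b <- var2 / n2
  df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  2 * stats::pt(-abs(t), df)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input and applies the BH step-up procedure; adjusted values
#' are returned in input order, are pointwise >= the input and capped at 1,
#' and are non-decreasing in p.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Score candidate genes in one cohort
#'
#' Computes, for every candidate gene, the Welch t statistic contrasting
#' tumor against normal samples, its two-sided p-value, and the BH-adjusted
#' p-value across the candidate set (the adjustment universe is the
#' candidate list, not the whole genome).  Genes with zero variance in both
#' groups and unequal means are flagged (`flag = "zero_variance"`, t and p
#' set to `NA`) rather than dropped; candidates absent from the matrix are
#' reported via a warning and the `missing_genes` attribute.
#'
#' @param dataset an `expression_dataset`.
#' @param candidate_genes gene symbols to score (default: all rows).
#' @return a `gene_score_table` data frame with columns `gene`, `t`, `p`,
#'   `p_adj`, `mean_tumor`, `mean_normal`, `var_tumor`, `var_normal`,
#'   `n_tumor`, `n_normal`, `flag`.
#' @export
score_genes <- function(dataset, candidate_genes = rownames(dataset$expr)) {
  stopifnot(inherits(dataset, "expression_dataset"))
  candidate_genes <- toupper(candidate_genes)
  missing <- setdiff(candidate_genes, rownames(dataset$expr))
  if (length(missing)) {
    warning(length(missing), " candidate gene(s) absent from the matrix, ",
            "skipped")
    candidate_genes <- setdiff(candidate_genes, missing)
  }
  is_t <- dataset$samples$group == "tumor"
  is_n <- dataset$samples$group == "normal"
  n1 <- sum(is_t); n2 <- sum(is_n)
  if (n1 < 2L || n2 < 2L)
    stop("cohort rejected: fewer than 2 samples in a group")
  xt <- dataset$expr[candidate_genes, is_t, drop = FALSE]
  xn <- dataset$expr[candidate_genes, is_n, drop = FALSE]
  m1 <- rowMeans(xt); m2 <- rowMeans(xn)
  v1 <- apply(xt, 1, stats::var); v2 <- apply(xn, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), ifelse(m1 == m2, 0, NA))
  flag <- ifelse(is.na(t), "zero_variance", "")
  df <- (v1 / n1 + v2 / n2)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- ifelse(is.na(t), NA, 2 * stats::pt(-abs(t), ifelse(is.na(df), 1, df)))
  p[!is.na(t) & t == 0 & se2 == 0] <- 1
  p_adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_adj[ok] <- bh_adjust(p[ok])
  out <- data.frame(gene = candidate_genes, t = t, p = p, p_adj = p_adj,
                    mean_tumor = m1, mean_normal = m2,
                    var_tumor = v1, var_normal = v2,
                    n_tumor = n1, n_normal = n2, flag = flag,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "missing_genes") <- missing
  class(out) <- c("gene_score_table", "data.frame")
  out
}

#' Select diagnostic genes from a score table
#'
#' Diagnostic genes are the candidates whose BH-adjusted p-value falls below
#' `alpha`; they are returned sorted by descending `|t|` (the magnitude of
#' the statistic is the diagnostic-value ranking, so strongly down-regulated
#' genes rank alongside up-regulated ones).
#'
#' @param table a `gene_score_table`.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return character vector of gene symbols.
#' @export
select_diagnostic_genes <- function(table, alpha = 0.05) {
  keep <- !is.na(table$p_adj) & table$p_adj < alpha
  sel <- table[keep, , drop = FALSE]
  sel$gene[order(-abs(sel$t), sel$gene)]
}

#' Read and write gene score tables
#'
#' Plain TSV with one row per gene and the `gene_score_table` columns.
#'
#' @param table a `gene_score_table`; `path` the TSV file.
#' @name score_table_io
#' @export
write_score_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname score_table_io
#' @export
read_score_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  out$flag[is.na(out$flag)] <- ""
  class(out) <- c("gene_score_table", "data.frame")
  out
}
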