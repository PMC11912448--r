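#' Ratio-of-max normalization of an expression matrix
#'
#' Divides each gene's expression vector by its maximum across cell types,
#' so every retained row has maximum 1. All-zero rows are dropped with a
#' warning. Idempotent.
#'
#' @param expr tibble with a `gene` column and one numeric column per cell
#'   type, or a numeric matrix with gene rownames.
#' @return tibble of the same shape with rows scaled to max 1.
#' @examples
#' ratio_of_max(tibble::tibble(gene = "g", a = 2, b = 4, d = 8))
#' @export
ratio_of_max <- function(expr) {
  e <- expr_to_matrix(expr)
  if (any(e < 0)) abort("expression values must be nonnegative")
  mx <- apply(e, 1, max)
  zero <- mx == 0
  if (any(zero)) {
    warn(sprintf("dropping %d all-zero gene(s)", sum(zero)))
    e <- e[!zero, , drop = FALSE]
    mx <- mx[!zero]
  }
  out <- e / mx
  matrix_to_expr(out)
}

expr_to_matrix <- function(expr) {
  if (is.matrix(expr)) return(expr)
  expr <- as_tibble(expr)
  stopifnot("gene" %in% names(expr))
  if (anyDuplicated(expr$gene)) abort("gene labels must be unique")
  m <- as.matrix(expr[setdiff(names(expr), "gene")])
  rownames(m) <- expr$gene
  m
}

matrix_to_expr <- function(m) {
  bind_cols(tibble(gene = rownames(m)),
            as_tibble(m, .name_repair = "minimal"))
}

#' Lineage-specific genes by the fold rule
#'
#' A gene is specific to its top cell type when its expression there is at
#' least `fold` times its expression in *every* other cell type. A tie at
#' the maximum therefore fails the rule (ratio 1), while a gene expressed
#' only in one cell type passes it.
#'
#' @param expr expression tibble or matrix (raw or ratio-of-max normalized;
#'   the rule is scale-invariant per gene).
#' @param fold specificity fold (default 5).
#' @return tibble: gene, top_tissue, fold_over_next (top / second-highest;
#'   Inf when all others are 0), specific (logical).
#' @examples
#' specific_genes(tibble::tibble(gene = "g", a = 10, b = 2, d = 1))
#' @export
specific_genes <- function(expr, fold = 5) {
  e <- expr_to_matrix(expr)
  if (ncol(e) < 2) abort("need at least two cell types")
  top_i <- max.col(e, ties.method = "first")
  top <- e[cbind(seq_len(nrow(e)), top_i)]
  second <- vapply(seq_len(nrow(e)), function(i) max(e[i, -top_i[i]]),
                   numeric(1))
  tibble(
    gene = rownames(e),
    top_tissue = colnames(e)[top_i],
    fold_over_next = ifelse(second > 0, top / second, Inf),
    specific = top >= fold * second & top > 0
  )
}

#' UPGMA clustering of normalized expression profiles
#'
#' Average-linkage (UPGMA) hierarchical clustering of genes on distances
#' between their ratio-of-max rows. The default metric is Euclidean;
#' correlation distance (1 - Pearson r) is available. Leaf order is
#' deterministic for a fixed input (ties broken by input order).
#'
#' @param normalized ratio-of-max expression tibble or matrix.
#' @param distance "euclidean" or "correlation".
#' @return list of class `rb_upgma`: `hclust` object, `order` (gene labels
#'   in dendrogram order), `merges` (tibble of merge heights).
#' @export
upgma_cluster <- function(normalized, distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  e <- expr_to_matrix(normalized)
  if (nrow(e) < 2) abort("need at least two genes to cluster")
  d <- if (distance == "euclidean") {
    dist(e)
  } else {
    as.dist(1 - stats::cor(t(e)))
  }
  hc <- hclust(d, method = "average")
  structure(list(
    hclust = hc,
    order = rownames(e)[hc$order],
    merges = tibble(step = seq_along(hc$height), height = hc$height)
  ), class = "rb_upgma")
}

#' RG enrichment in a lineage-specific gene set
#'
#' Delegates to [gene_set_test()] on a phenotype-restricted subcohort: the
#' observed count is the number of RGs in the set among `samples`, and the
#' cohort size is the subset size.
#'
#' @param model an [fit_expected_model()] object.
#' @param rg RG tibble for the whole cohort.
#' @param genes lineage-specific gene set (character).
#' @param samples probands forming the subcohort (default: whole cohort,
#'   reducing exactly to [gene_set_test()]).
#' @param n subcohort size; defaults to `length(samples)` or the model's n.
#' @param set_name label.
#' @return one-row `rb_enrichment` tibble.
#' @export
lineage_set_enrichment <- function(model, rg, genes, samples = NULL,
                                   n = NULL, set_name = "lineage_set") {
  if (!is.null(samples)) {
    rg <- filter(rg, .data$sample %in% samples)
    n <- n %||% length(samples)
  }
  gene_set_test(model, genes, observed = rg, n = n, set_name = set_name)
}
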