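# Expression-pattern analysis: FPKM filtering and log transform,
# hierarchical clustering (Euclidean distance, average linkage),
# cross-tabulation of expression groups against subfamily subsets,
# ortholog expression correlation, and qPCR 2^-ddCt fold changes.

#' Filter all-zero genes and log-transform an FPKM matrix
#'
#' Removes genes (rows) whose FPKM is zero in every sample, then returns
#' `log2(FPKM + 1)`. The +1 pseudocount keeps zeros at 0 and FPKM 1 at
#' exactly 1.
#'
#' @param mat Numeric matrix, genes x samples, FPKM (non-negative);
#'   rownames are gene ids, colnames sample labels (unique).
#' @return The log2 matrix of retained genes, in the input gene order,
#'   with attributes `removed_genes` (character vector) and `n_removed`.
#' @export
filter_and_transform <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (any(mat < 0)) stop("FPKM values must be non-negative", call. = FALSE)
  if (anyDuplicated(colnames(mat))) {
    stop("sample labels must be unique", call. = FALSE)
  }
  all_zero <- rowSums(mat) == 0
  out <- log2(mat[!all_zero, , drop = FALSE] + 1)
  attr(out, "removed_genes") <- rownames(mat)[all_zero]
  attr(out, "n_removed") <- sum(all_zero)
  out
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering with Euclidean distances and average (UPGMA)
#' linkage, cut into `k` groups. Group ids are renumbered by descending
#' group size (1 = largest) so labels are stable across row
#' permutations up to relabelling.
#'
#' @param logmat Numeric matrix of log-transformed expression, genes x
#'   samples.
#' @param k Number of groups to cut the tree into.
#' @return list with `tree` (an `hclust`, NULL for a single gene) and
#'   `groups`, a named integer vector of group ids per gene.
#' @export
cluster_expression <- function(logmat, k) {
  stopifnot(is.matrix(logmat), k >= 1L)
  n <- nrow(logmat)
  if (k > n) stop("k exceeds the number of genes", call. = FALSE)
  if (n == 1L) {
    return(list(tree = NULL,
                groups = stats::setNames(1L, rownames(logmat))))
  }
  tree <- stats::hclust(stats::dist(logmat, method = "euclidean"),
                        method = "average")
  raw <- stats::cutree(tree, k = k)
  sizes <- sort(table(raw), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sizes), names(sizes))
  groups <- stats::setNames(as.integer(remap[as.character(raw)]), names(raw))
  list(tree = tree, groups = groups)
}

#' Cross-tabulate expression groups against subfamily subsets
#'
#' @param groups Named integer vector of expression group ids (genes).
#' @param subsets Named character vector of subset labels (genes).
#' @return list with `counts` (matrix group x subset), `percent`
#'   (column percentages over each subset), and `dropped`, the gene ids
#'   present in only one of the two inputs (excluded, reported).
#' @export
expression_by_subset <- function(groups, subsets) {
  shared <- intersect(names(groups), names(subsets))
  dropped <- setdiff(union(names(groups), names(subsets)), shared)
  if (length(shared) == 0L) {
    warning("no genes shared between group and subset labels",
            call. = FALSE)
  }
  if (length(dropped) > 0L) {
    message(sprintf("expression_by_subset: %d genes missing a label, excluded",
                    length(dropped)))
  }
  tab <- table(group = groups[shared],
               subset = factor(subsets[shared], levels = SUBSET_LEVELS))
  counts <- matrix(as.integer(tab), nrow = nrow(tab), ncol = ncol(tab),
                   dimnames = dimnames(tab))
  csum <- colSums(counts)
  percent <- sweep(counts, 2L, ifelse(csum == 0, 1, csum), "/") * 100
  list(counts = counts, percent = percent, dropped = dropped)
}

#' Expression correlation between ortholog pairs
#'
#' Per pair, the Pearson correlation of the two genes' expression over
#' the shared tissues; in aggregate, the Pearson correlation between the
#' per-gene tissue sums across all usable pairs.
#'
#' @param pairs data.frame with columns `id_a`, `id_b`.
#' @param mat_a,mat_b Expression matrices (genes x tissues) for the two
#'   species; rownames are gene ids.
#' @param tissues Character vector of shared tissue labels (columns of
#'   both matrices).
#' @return list with `per_pair` (data.frame `id_a`, `id_b`, `r`; `r` is
#'   NA for zero-variance profiles), `aggregate_r`, `n_pairs`, and
#'   `n_high`, the number of pairs with `r > 0.8`.
#' @export
ortholog_expression_correlation <- function(pairs, mat_a, mat_b, tissues) {
  stopifnot(all(tissues %in% colnames(mat_a)),
            all(tissues %in% colnames(mat_b)))
  keep <- pairs$id_a %in% rownames(mat_a) & pairs$id_b %in% rownames(mat_b)
  if (any(!keep)) {
    message(sprintf("ortholog_expression_correlation: %d pairs skipped %s",
                    sum(!keep), "(gene missing from a matrix)"))
  }
  p <- pairs[keep, , drop = FALSE]
  va <- mat_a[p$id_a, tissues, drop = FALSE]
  vb <- mat_b[p$id_b, tissues, drop = FALSE]
  r <- vapply(seq_len(nrow(p)), function(i) {
    a <- va[i, ]; b <- vb[i, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  sums_a <- rowSums(va)
  sums_b <- rowSums(vb)
  aggregate_r <- if (nrow(p) >= 2L && stats::sd(sums_a) > 0 &&
                     stats::sd(sums_b) > 0) {
    stats::cor(sums_a, sums_b)
  } else NA_real_
  list(per_pair = data.frame(id_a = p$id_a, id_b = p$id_b, r = r,
                             stringsAsFactors = FALSE),
       aggregate_r = aggregate_r,
       n_pairs = nrow(p),
       n_high = sum(r > 0.8, na.rm = TRUE))
}

#' qPCR relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are averaged per (gene, condition, timepoint);
#' `dCt = mean(Ct_target) - mean(Ct_reference)`;
#' `ddCt = dCt_treated - dCt_control` at the same gene and timepoint;
#' `fold = 2^(-ddCt)`.
#'
#' @param table data.frame with columns `gene`, `condition`, `timepoint`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @param control The control condition label (e.g. `"CK"`).
#' @return data.frame `gene`, `condition`, `timepoint`, `fold_change` for
#'   every non-control condition.
#' @export
ddct_fold_change <- function(table, control) {
  need <- c("gene", "condition", "timepoint", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(table)))
  if (any(is.na(table$ct_reference))) {
    stop("missing reference Ct value", call. = FALSE)
  }
  if (any(table$ct_target <= 0 | table$ct_reference <= 0)) {
    stop("Ct values must be positive", call. = FALSE)
  }
  agg <- stats::aggregate(cbind(ct_target, ct_reference) ~
                            gene + condition + timepoint,
                          data = table, FUN = mean)
  agg$dct <- agg$ct_target - agg$ct_reference
  ctrl <- agg[agg$condition == control, , drop = FALSE]
  trt <- agg[agg$condition != control, , drop = FALSE]
  key <- function(d) paste(d$gene, d$timepoint)
  m <- match(key(trt), key(ctrl))
  if (any(is.na(m))) {
    stop("control condition missing for some (gene, timepoint)",
         call. = FALSE)
  }
  trt$fold_change <- 2^(-(trt$dct - ctrl$dct[m]))
  out <- trt[, c("gene", "condition", "timepoint", "fold_change")]
  out <- out[order(out$gene, out$condition, out$timepoint), , drop = FALSE]
  rownames(out) <- NULL
  out
}
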