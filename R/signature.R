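# Signature derivation: screen each tumor/normal study for upregulated
# genes (Welch t-test on log2 values, BH-adjusted), then intersect the
# upregulated sets across studies and with the hallmark hypoxia set.

#' Gene-wise differential expression between tumor and normal samples
#'
#' Per gene: Welch two-sample t-test (unequal variances, two-sided) on the
#' log2-scale values, log2 fold change as the difference of group means
#' (tumor minus normal), and Benjamini-Hochberg adjustment across all tested
#' genes. A gene whose values are constant within both groups has an
#' undefined t statistic and is assigned p = 1 so it can never pass a
#' significance filter, whatever its mean difference.
#'
#' @param mat Expression matrix (log2 scale), genes x samples.
#' @param groups Per-sample group labels with exactly two levels; vector
#'   aligned with the matrix columns (or named by sample id).
#' @param case Label of the tumor/case level (default "tumor"); the other
#'   level is the reference.
#' @return data.frame with columns gene_id, log2_fold_change, fold_change,
#'   p_value, adjusted_p; one row per gene, input gene order.
#' @export
differential_expression <- function(mat, groups, case = "tumor") {
  mat <- validate_expression(mat)
  if (!is.null(names(groups))) {
    if (!all(colnames(mat) %in% names(groups)))
      stop_input("`groups` names do not cover all matrix samples")
    groups <- groups[colnames(mat)]
  }
  if (length(groups) != ncol(mat))
    stop_input("`groups` must have one label per sample")
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2L)
    stop_input("`groups` must have exactly 2 levels, got: %s",
               paste(lev, collapse = ", "))
  if (!case %in% lev)
    stop_input("case level '%s' not present in `groups`", case)
  is_case <- groups == case
  if (sum(is_case) < 2L || sum(!is_case) < 2L)
    stop_input("each group needs at least 2 samples")

  case_mat <- mat[, is_case, drop = FALSE]
  ctrl_mat <- mat[, !is_case, drop = FALSE]
  lfc <- rowMeans(case_mat) - rowMeans(ctrl_mat)
  pvals <- vapply(seq_len(nrow(mat)), function(i) {
    x <- case_mat[i, ]
    y <- ctrl_mat[i, ]
    if (stats::var(x) == 0 && stats::var(y) == 0) return(1)
    stats::t.test(x, y, var.equal = FALSE)$p.value
  }, numeric(1))
  data.frame(gene_id = rownames(mat),
             log2_fold_change = unname(lfc),
             fold_change = unname(2^lfc),
             p_value = pvals,
             adjusted_p = stats::p.adjust(pvals, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Select upregulated genes from a differential-expression table
#'
#' Keeps genes with fold change strictly greater than `fc_threshold` and
#' BH-adjusted p strictly less than `adj_p_threshold` (a gene at exactly the
#' fold-change cutoff is excluded).
#'
#' @param de_table Output of [differential_expression()].
#' @param fc_threshold Fold-change cutoff (linear scale, default 2).
#' @param adj_p_threshold Adjusted-p cutoff (default 0.05).
#' @param name Name given to the resulting gene set.
#' @return A [gene_set] of the selected genes (input order); NULL when no
#'   gene passes.
#' @export
filter_upregulated <- function(de_table, fc_threshold = 2,
                               adj_p_threshold = 0.05,
                               name = "upregulated") {
  check_number(fc_threshold, "fc_threshold", min = 0, strict_min = TRUE)
  check_number(adj_p_threshold, "adj_p_threshold", min = 0, max = 1,
               strict_min = TRUE)
  keep <- de_table$fold_change > fc_threshold &
    de_table$adjusted_p < adj_p_threshold
  genes <- de_table$gene_id[keep]
  if (length(genes) == 0L) {
    hx_log("filter_upregulated: no gene passed the thresholds", "warn")
    return(NULL)
  }
  gene_set(name, genes)
}

#' Intersect upregulated gene sets with the hallmark set
#'
#' The derived signature: genes upregulated in every study that are also
#' members of the hallmark hypoxia set. Output is sorted by gene identifier
#' so the signature is deterministic regardless of input order. An empty
#' intersection is allowed (logged), not an error.
#'
#' @param upregulated_sets List of [gene_set]s (or character vectors), one
#'   per study; NULL entries (studies with no hits) yield an empty signature.
#' @param hallmark The hallmark [gene_set].
#' @param name Name of the derived signature set.
#' @return A [gene_set] (possibly constructed over zero genes is not
#'   representable, so an empty result returns NULL with a warning log).
#' @export
intersect_signature <- function(upregulated_sets, hallmark,
                                name = "hypoxia_signature") {
  if (inherits(upregulated_sets, "gene_set") ||
      is.character(upregulated_sets))
    upregulated_sets <- list(upregulated_sets)
  if (length(upregulated_sets) < 1L)
    stop_input("at least one upregulated gene set is required")
  if (any(vapply(upregulated_sets, is.null, logical(1)))) {
    hx_log("intersect_signature: a study contributed no upregulated genes; empty signature",
           "warn")
    return(NULL)
  }
  sets <- lapply(upregulated_sets, as_gene_ids)
  shared <- Reduce(intersect, sets, accumulate = FALSE)
  shared <- sort(intersect(shared, as_gene_ids(hallmark)))
  if (length(shared) == 0L) {
    hx_log("intersect_signature: empty signature", "warn")
    return(NULL)
  }
  gene_set(name, shared, description = "derived hypoxia signature")
}
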