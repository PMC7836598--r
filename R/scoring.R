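# The signature score. For each signature gene, a sample in the top half of
# that gene's expression across the cohort contributes +1, the bottom half
# -1; the per-sample score is the sum over signature genes. The score only
# sees ranks, so it is invariant to any strictly increasing per-gene
# transformation of the expression values (log scale, quantile
# normalisation, ...).

#' Dichotomize one gene's expression at the cohort median
#'
#' +1 for samples strictly above the median of the vector, -1 otherwise.
#' With even n and distinct values this gives exactly n/2 of each sign; with
#' odd n the median sample falls to -1. A constant gene is uninformative:
#' every sample gets -1 and a warning is logged.
#'
#' @param values Numeric per-sample expression vector (length >= 2).
#' @return Integer vector in {-1, +1}, same names/length as input.
#' @examples
#' binarize_gene(c(1, 2, 3, 4))   # -1 -1 +1 +1
#' @export
binarize_gene <- function(values) {
  if (!is.numeric(values) || length(values) < 2L)
    stop_input("binarize_gene needs a numeric vector of length >= 2")
  if (any(!is.finite(values)))
    stop_input("binarize_gene: non-finite values")
  if (length(unique(values)) == 1L) {
    hx_log("binarize_gene: constant gene, all samples scored -1", "warn")
    return(stats::setNames(rep(-1L, length(values)), names(values)))
  }
  out <- ifelse(values > stats::median(values), 1L, -1L)
  stats::setNames(as.integer(out), names(values))
}

#' Per-sample signature score
#'
#' Sums [binarize_gene()] over the signature genes present in the matrix.
#' Missing signature genes are dropped (logged), never imputed, and the
#' score is a raw sum, not rescaled by the number of genes used. Group
#' labels (high/low, strictly-above-median split of the scores) are
#' attached; when every sample ends up with the same score no stratification
#' exists and the group is NA with a warning.
#'
#' @param mat Expression matrix, genes x samples.
#' @param signature A [gene_set] or character vector of signature genes.
#' @return data.frame (class `score_table`) with columns sample_id, score,
#'   n_genes_used, group.
#' @examples
#' m <- rbind(g1 = 1:4, g2 = 4:1)
#' colnames(m) <- paste0("s", 1:4)
#' signature_score(m, c("g1", "g2"))$score  # all zero
#' @export
signature_score <- function(mat, signature) {
  mat <- validate_expression(mat)
  genes <- as_gene_ids(signature)
  present <- intersect(genes, rownames(mat))
  if (length(present) == 0L)
    stop_input("no signature gene is present in the expression matrix")
  n_missing <- length(genes) - length(present)
  if (n_missing > 0L)
    hx_log(sprintf("signature_score: %d signature gene(s) absent from the matrix",
                   n_missing), "warn")
  contrib <- vapply(present, function(g) binarize_gene(mat[g, ]),
                    integer(ncol(mat)))
  scores <- as.integer(rowSums(contrib))
  group <- tryCatch(assign_groups(scores), error = function(e) {
    warning("all scores identical; high/low group undefined (NA)",
            call. = FALSE)
    rep(NA_character_, length(scores))
  })
  structure(data.frame(sample_id = colnames(mat),
                       score = scores,
                       n_genes_used = length(present),
                       group = group,
                       stringsAsFactors = FALSE),
            class = c("score_table", "data.frame"))
}

#' Split samples into high/low score groups
#'
#' "high" for scores strictly greater than the cohort median score, "low"
#' otherwise. Errors when all scores are identical (no stratification
#' possible).
#'
#' @param scores Integer per-sample scores (length >= 2).
#' @return Character vector in {"high", "low"}.
#' @examples
#' assign_groups(c(-3, -1, 1, 3))
#' @export
assign_groups <- function(scores) {
  if (length(scores) < 2L)
    stop_input("assign_groups needs at least 2 samples")
  if (length(unique(scores)) == 1L)
    stop_input("all scores are identical; cannot assign high/low groups")
  ifelse(scores > stats::median(scores), "high", "low")
}

#' Screen genes correlated with a signature score
#'
#' Gene-wise Pearson correlation against the per-sample score with its
#' two-sided p-value; returns the genes passing r >= `r_threshold` (signed,
#' one-sided: strong negative correlates are excluded) and p <
#' `p_threshold`, sorted by descending r. Constant genes have undefined r
#' and are excluded with a logged warning.
#'
#' @param mat Expression matrix, genes x samples.
#' @param scores A `score_table` from [signature_score()] or a numeric
#'   vector named by sample.
#' @param r_threshold Minimum Pearson r (default 0.05).
#' @param p_threshold Maximum two-sided p (default 0.05).
#' @return data.frame with columns gene_id, r, p for the passing genes.
#' @export
correlate_genes_with_score <- function(mat, scores, r_threshold = 0.05,
                                       p_threshold = 0.05) {
  mat <- validate_expression(mat)
  if (inherits(scores, "score_table"))
    scores <- stats::setNames(scores$score, scores$sample_id)
  if (!is.null(names(scores))) {
    if (!all(colnames(mat) %in% names(scores)))
      stop_input("score names do not cover all matrix samples")
    scores <- scores[colnames(mat)]
  }
  if (length(scores) != ncol(mat))
    stop_input("scores must align with the matrix samples")
  if (stats::var(scores) == 0)
    stop_input("score vector is constant; correlation undefined")
  constant <- apply(mat, 1L, function(v) stats::var(v) == 0)
  if (any(constant))
    hx_log(sprintf("correlate_genes_with_score: excluded %d constant gene(s)",
                   sum(constant)), "warn")
  keep_mat <- mat[!constant, , drop = FALSE]
  res <- vapply(seq_len(nrow(keep_mat)), function(i) {
    ct <- stats::cor.test(keep_mat[i, ], scores, method = "pearson")
    c(unname(ct$estimate), ct$p.value)
  }, numeric(2))
  out <- data.frame(gene_id = rownames(keep_mat),
                    r = res[1L, ], p = res[2L, ],
                    stringsAsFactors = FALSE)
  out <- out[out$r >= r_threshold & out$p < p_threshold, , drop = FALSE]
  out <- out[order(-out$r), , drop = FALSE]
  rownames(out) <- NULL
  out
}
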