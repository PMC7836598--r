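#' Construct a gene set
#'
#' A named collection of unique gene identifiers, the in-memory form of one
#' GMT line (hallmark hypoxia, hallmark EMT, or a derived signature).
#'
#' @param name Set name.
#' @param genes Character vector of gene identifiers; duplicates are removed
#'   with a warning, order of first appearance is kept.
#' @param description Free-text description (second GMT field).
#' @return An object of class `gene_set`.
#' @examples
#' gene_set("SIG", c("VEGFA", "CA9", "LDHA"))
#' @export
gene_set <- function(name, genes, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_input("gene set `name` must be a non-empty string")
  genes <- as.character(genes)
  if (length(genes) == 0L)
    stop_input("gene set '%s' is empty", name)
  if (anyNA(genes) || any(!nzchar(genes)))
    stop_input("gene set '%s' contains missing/blank identifiers", name)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning(sprintf("gene set '%s': removed %d duplicated identifier(s) (%s)",
                    name, length(dup),
                    paste(utils::head(dup, 3L), collapse = ", ")),
            call. = FALSE)
    genes <- genes[!duplicated(genes)]
  }
  structure(list(name = name, description = description, genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes (%s%s)\n", x$name, length(x$genes),
              paste(utils::head(x$genes, 5L), collapse = ", "),
              if (length(x$genes) > 5L) ", ..." else ""))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

# Accept a gene_set or a bare character vector wherever gene ids are needed.
as_gene_ids <- function(x) {
  if (inherits(x, "gene_set")) return(x$genes)
  if (is.character(x)) return(x)
  stop_input("expected a gene_set or character vector of gene identifiers")
}

#' Validate a gene-by-sample expression matrix
#'
#' The pipeline's expression container is a plain numeric matrix of log-scale
#' values with unique gene rownames and unique sample colnames. This checks
#' those invariants and returns the matrix unchanged.
#'
#' @param mat Numeric matrix, genes in rows, samples in columns.
#' @return The validated matrix (invisibly the same object).
#' @export
validate_expression <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop_input("expression must be a numeric matrix (genes x samples)")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop_input("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(mat)))
    stop_input("duplicate gene identifiers: %s",
               paste(utils::head(unique(rownames(mat)[duplicated(rownames(mat))]), 3L),
                     collapse = ", "))
  if (anyDuplicated(colnames(mat)))
    stop_input("duplicate sample identifiers: %s",
               paste(utils::head(unique(colnames(mat)[duplicated(colnames(mat))]), 3L),
                     collapse = ", "))
  if (ncol(mat) < 2L)
    stop_input("expression matrix needs at least 2 samples")
  if (any(!is.finite(mat)))
    stop_input("expression matrix contains non-finite values")
  mat
}

.clinical_required <- c("sample_id", "os_time", "os_event",
                        "pfs_time", "pfs_event",
                        "stage", "grade", "residual", "gender")
.stage_levels <- c("I", "II", "III/IV")
.grade_levels <- c("G1", "G2", "G3/G4")

#' Validate a clinical table
#'
#' Checks the per-sample survival endpoints and covariates: unique
#' `sample_id`; non-negative `os_time`/`pfs_time`; `os_event`/`pfs_event`,
#' `residual` and `gender` in {0,1}; `stage` in I/II/III-IV and `grade` in
#' G1/G2/G3-G4 (stored as ordered-level factors). Extra columns (e.g.
#' molecular subtype labels) are carried through untouched.
#'
#' @param clinical A data.frame with at least the columns above.
#' @return The validated data.frame with stage/grade as factors.
#' @export
validate_clinical <- function(clinical) {
  if (!is.data.frame(clinical)) stop_input("clinical must be a data.frame")
  missing_cols <- setdiff(.clinical_required, names(clinical))
  if (length(missing_cols) > 0L)
    stop_input("clinical table is missing column(s): %s",
               paste(missing_cols, collapse = ", "))
  clinical$sample_id <- as.character(clinical$sample_id)
  if (anyDuplicated(clinical$sample_id))
    stop_input("duplicate sample_id in clinical table")
  for (col in c("os_time", "pfs_time")) {
    v <- clinical[[col]]
    if (!is.numeric(v) || any(v < 0, na.rm = TRUE))
      stop_input("`%s` must be numeric and non-negative", col)
  }
  for (col in c("os_event", "pfs_event", "residual", "gender")) {
    v <- clinical[[col]]
    if (!all(v %in% c(0, 1) | is.na(v)))
      stop_input("`%s` must be coded 0/1", col)
    clinical[[col]] <- as.integer(v)
  }
  clinical$stage <- factor(as.character(clinical$stage),
                           levels = .stage_levels)
  clinical$grade <- factor(as.character(clinical$grade),
                           levels = .grade_levels)
  if (anyNA(clinical$stage) || anyNA(clinical$grade))
    stop_input("stage must be one of %s and grade one of %s",
               paste(.stage_levels, collapse = "/"),
               paste(.grade_levels, collapse = "/"))
  rownames(clinical) <- NULL
  clinical
}

#' Integer-code an ordinal clinical covariate
#'
#' Maps the ordered levels of a factor (e.g. stage I < II < III/IV, grade
#' G1 < G2 < G3/G4) to consecutive integers 1..k, the coding used when an
#' ordinal covariate enters a partial correlation as a control variable.
#'
#' @param x Factor (or character coercible to one of the clinical orderings).
#' @param levels Optional explicit level order; defaults to the factor's own.
#' @return Integer vector.
#' @examples
#' encode_ordinal(factor(c("I", "II", "III/IV"), levels = c("I", "II", "III/IV")))
#' @export
encode_ordinal <- function(x, levels = NULL) {
  if (!is.factor(x)) {
    if (is.null(levels)) stop_input("`levels` required for non-factor input")
    x <- factor(as.character(x), levels = levels)
  } else if (!is.null(levels)) {
    x <- factor(as.character(x), levels = levels)
  }
  if (anyNA(x)) stop_input("ordinal covariate has values outside its levels")
  as.integer(x)
}
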