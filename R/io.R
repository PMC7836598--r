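# File formats: gene-by-sample TSV (first column gene id, sample header),
# GMT gene sets, clinical TSV. All readers validate hard and name the
# offending line; all writers round-trip exactly (fwrite emits shortest
# exact decimal representations).

#' Read a gene-by-sample expression TSV
#'
#' Expects a header row of sample identifiers whose first field names the
#' gene-id column, then one row per gene. Values must be numeric; duplicate
#' gene or sample identifiers, ragged rows and non-numeric cells are format
#' errors reporting the offending line.
#'
#' @param path File path.
#' @param log_transform_input If TRUE the values are transformed to
#'   log2(x + 1) after reading (for linear-scale inputs such as RSEM
#'   estimates).
#' @return A validated numeric matrix, genes x samples.
#' @export
read_expression <- function(path, log_transform_input = FALSE) {
  check_flag(log_transform_input, "log_transform_input")
  if (!file.exists(path)) stop_input("file not found: %s", path)
  nfields <- utils::count.fields(path, sep = "\t", quote = "",
                                 comment.char = "")
  if (length(nfields) < 2L)
    stop_input("%s: expected a header plus at least one gene row", path)
  ragged <- which(nfields != nfields[1L])
  if (length(ragged) > 0L)
    stop_input("%s: ragged row at line %d (%d fields, expected %d)",
               path, ragged[1L], nfields[ragged[1L]], nfields[1L])
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L),
                          data.table = FALSE, showProgress = FALSE)
  gene_ids <- dt[[1L]]
  vals <- dt[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1L]
      stop_input("%s: non-numeric value '%s' at line %d, sample '%s'",
                 path, vals[[j]][bad], bad + 1L, names(vals)[j])
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- gene_ids
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1L]
    stop_input("%s: duplicated gene row '%s' (line %d)",
               path, dup, max(which(gene_ids == dup)) + 1L)
  }
  if (log_transform_input) {
    if (any(mat < -1)) stop_input("%s: values < -1 cannot be log2(x+1)-transformed", path)
    mat <- log2(mat + 1)
  }
  validate_expression(mat)
}

#' Write an expression matrix as TSV
#'
#' @param mat Validated expression matrix.
#' @param path Output path.
#' @param gene_col Name of the first (gene id) column.
#' @export
write_expression <- function(mat, path, gene_col = "gene_id") {
  mat <- validate_expression(mat)
  dt <- data.table::data.table(gene_id = rownames(mat))
  data.table::setnames(dt, "gene_id", gene_col)
  # %.17g keeps the shortest exact decimal form so read_expression
  # round-trips bit-identically
  vals <- data.table::as.data.table(
    lapply(as.data.frame(mat), function(v) sprintf("%.17g", v)))
  dt <- cbind(dt, vals)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated gene identifiers.
#' Duplicate genes within a line are dropped with a warning; a line with
#' fewer than three fields is a format error.
#'
#' @param path File path.
#' @return A list of [gene_set] objects (possibly empty), named by set name.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop_input("%s: line %d has %d field(s); GMT needs name, description and >= 1 gene",
                 path, i, length(fields))
    sets[[i]] <- gene_set(fields[1L], fields[-(1:2)],
                          description = fields[2L])
  }
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A [gene_set] or list of them.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    desc <- if (nzchar(s$description)) s$description else "na"
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table TSV
#'
#' Requires columns sample_id, os_time, os_event, pfs_time, pfs_event,
#' stage, grade, residual, gender; extra columns (subtype labels) pass
#' through. Rows with a missing survival time or event indicator for both
#' endpoints are dropped with a logged count; a missing mandatory column or
#' a negative time is an error.
#'
#' @param path File path.
#' @return A validated clinical data.frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE,
                          na.strings = c("", "NA"))
  missing_cols <- setdiff(.clinical_required, names(dt))
  if (length(missing_cols) > 0L)
    stop_input("%s: missing mandatory column(s): %s", path,
               paste(missing_cols, collapse = ", "))
  incomplete <- is.na(dt$os_time) | is.na(dt$os_event) |
    is.na(dt$pfs_time) | is.na(dt$pfs_event)
  if (any(incomplete)) {
    hx_log(sprintf("read_clinical: dropped %d row(s) with missing survival data",
                   sum(incomplete)), "warn")
    dt <- dt[!incomplete, , drop = FALSE]
  }
  validate_clinical(dt)
}

#' Write a clinical table as TSV
#'
#' @param clinical Validated clinical data.frame.
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  clinical <- validate_clinical(clinical)
  out <- clinical
  out$stage <- as.character(out$stage)
  out$grade <- as.character(out$grade)
  for (col in c("os_time", "pfs_time"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Align an expression matrix and clinical table by sample identifier
#'
#' Joint analyses use the identifier intersection; samples present in only
#' one input are dropped (never imputed) and the discarded counts logged.
#'
#' @param mat Expression matrix.
#' @param clinical Clinical table.
#' @return List with `expression` and `clinical` restricted to the shared
#'   samples, in the same order.
#' @export
align_expression_clinical <- function(mat, clinical) {
  mat <- validate_expression(mat)
  clinical <- validate_clinical(clinical)
  shared <- intersect(colnames(mat), clinical$sample_id)
  if (length(shared) == 0L)
    stop_input("no shared samples between expression and clinical inputs")
  n_expr_only <- ncol(mat) - length(shared)
  n_clin_only <- nrow(clinical) - length(shared)
  if (n_expr_only + n_clin_only > 0L)
    hx_log(sprintf("sample alignment: dropped %d expression-only and %d clinical-only sample(s)",
                   n_expr_only, n_clin_only), "warn")
  list(expression = mat[, shared, drop = FALSE],
       clinical = clinical[match(shared, clinical$sample_id), , drop = FALSE])
}
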