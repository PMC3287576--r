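#' Staged expression matrix of log2 ratios
#'
#' Construct a validated genes x stages matrix of log2 expression ratios
#' relative to a designated control stage (e.g. mature pollen, "MP"). This is
#' the container consumed by the prior builder and the NCA solver: rows are
#' genes, columns are ordered developmental stages, and every value is
#' log2(expression at stage / expression at control).
#'
#' @param values numeric matrix with unique rownames (gene identifiers) and
#'   unique colnames (stage labels).
#' @param control_stage label of the control stage; must be a column of
#'   `values` unless `require_control = FALSE`.
#' @param require_control if `TRUE` (default) the control stage must be
#'   present as a column and that column must be identically zero (the ratio
#'   of the control to itself is 1, so its log2 is exactly 0).
#' @param tol tolerance used when checking that the control column is zero.
#' @return an object of class `"expression_matrix"` (a numeric matrix with a
#'   `control_stage` attribute).
#' @export
expression_matrix <- function(values, control_stage, require_control = TRUE,
                              tol = 1e-8) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene identifiers as rownames and stage labels as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate stage labels")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', stage '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (require_control) {
    if (!control_stage %in% colnames(values))
      stop("control stage '", control_stage, "' not among stage labels")
    if (max(abs(values[, control_stage])) > tol)
      stop("control stage column '", control_stage,
           "' is not zero; log2 ratios must be taken relative to the control")
    values[, control_stage] <- 0  # snap residual float noise
  }
  structure(values, control_stage = control_stage, class = c("expression_matrix", "matrix"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d stages (log2 ratios vs control '%s')\n",
              nrow(x), ncol(x), attr(x, "control_stage")))
  cat("Stages:", paste(colnames(x), collapse = ", "), "\n")
  n <- min(6L, nrow(x))
  print(round(unclass(x)[seq_len(n), , drop = FALSE], 3))
  if (nrow(x) > n) cat("...", nrow(x) - n, "more genes\n")
  invisible(x)
}

#' Control stage of an expression matrix
#' @param E an `expression_matrix`.
#' @return the control stage label.
#' @export
control_stage <- function(E) attr(E, "control_stage")

#' Read a staged expression table
#'
#' Reads a tab-delimited table whose header row holds stage labels and whose
#' first column holds gene identifiers, and validates it as an
#' [expression_matrix()]. Duplicate gene rows, non-numeric cells and a
#' missing or non-zero control column are rejected.
#'
#' @param path path to a TSV file.
#' @param control_stage label of the control stage.
#' @param require_control passed to [expression_matrix()].
#' @return an `expression_matrix`.
#' @export
read_expression <- function(path, control_stage, require_control = TRUE) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "", comment.char = "")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at gene '%s', stage '%s' in %s",
                 ids[bad[1]], colnames(num)[bad[2]], path))
  }
  expression_matrix(num, control_stage, require_control = require_control)
}

#' Write a staged expression table
#'
#' Emits the same dialect [read_expression()] consumes: UTF-8, tab-delimited,
#' header row of stage labels, first column `gene_id`.
#'
#' @param E an `expression_matrix`.
#' @param path output path.
#' @export
write_expression <- function(E, path) {
  df <- data.frame(gene_id = rownames(E),
                   apply(unclass(E), 2, function(col) format(col, digits = 15, trim = TRUE,
                                                             scientific = FALSE)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2 ratios relative to a control stage
#'
#' Converts a positive linear-scale expression matrix into log2 fold changes
#' against the control stage: `values[i, t] = log2(raw[i, t] / raw[i, control])`.
#' The control column of the result is exactly zero.
#'
#' @param raw positive numeric matrix (genes x stages) on the linear scale.
#' @param control_stage stage label, must be a column of `raw`.
#' @return an `expression_matrix` of log2 ratios.
#' @export
compute_log_ratios <- function(raw, control_stage) {
  if (!is.matrix(raw) || !is.numeric(raw)) stop("`raw` must be a numeric matrix")
  if (!control_stage %in% colnames(raw))
    stop("control stage '", control_stage, "' not among stage labels")
  if (any(raw <= 0)) {
    bad <- which(raw <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("nonpositive value at gene '%s', stage '%s': linear-scale expression must be > 0",
                 rownames(raw)[bad[1]], colnames(raw)[bad[2]]))
  }
  lr <- log2(raw / raw[, control_stage])
  lr[, control_stage] <- 0
  expression_matrix(lr, control_stage)
}

#' Differential-expression filter
#'
#' Selects genes whose absolute linear fold change exceeds `fc_threshold`
#' (i.e. `|log2 ratio| > log2(fc_threshold)`) in at least `min_stages` stages.
#' The default 1.6 is the conventional linear-scale cutoff; a gene
#' differentially expressed at a single stage already qualifies.
#'
#' @param E an `expression_matrix`.
#' @param fc_threshold linear-scale fold-change threshold, must be > 1.
#' @param min_stages minimum number of stages exceeding the threshold.
#' @param log2_scale set `TRUE` to read `fc_threshold` as a cutoff already on
#'   the log2 scale (`|log2 ratio| > fc_threshold`).
#' @return character vector of gene identifiers, in input order.
#' @export
filter_degs <- function(E, fc_threshold = 1.6, min_stages = 1L, log2_scale = FALSE) {
  if (!log2_scale && fc_threshold <= 1)
    stop("`fc_threshold` must exceed 1 on the linear scale")
  cut <- if (log2_scale) fc_threshold else log2(fc_threshold)
  hits <- rowSums(abs(unclass(E)) > cut)
  rownames(E)[hits >= min_stages]
}
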