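#' Time-course expression dataset
#'
#' Container for a genes x samples matrix of log2 expression values together
#' with a sample sheet mapping every sample (column) to a time point and a
#' replicate. The time axis is ordered and shared by all downstream stages.
#'
#' @param values Numeric matrix, genes as rows (rownames = gene ids), samples
#'   as columns (colnames = sample ids), log2 scale.
#' @param samples Data frame with columns `sample`, `time`, `replicate`;
#'   `time` is a numeric label on a strictly increasing axis.
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` (the matrix), `samples` (the sample sheet, rows ordered as the
#'   matrix columns) and `time_order` (sorted unique time labels).
#' @examples
#' x <- matrix(rnorm(12), 2, 6,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
#' sheet <- data.frame(sample = paste0("s", 1:6),
#'                     time = rep(1:3, each = 2), replicate = rep(1:2, 3))
#' ds <- expression_dataset(x, sheet)
#' @export
expression_dataset <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("`values` must have unique rownames (gene ids)")
  if (is.null(colnames(values)))
    stop("`values` must have colnames (sample ids)")
  req <- c("sample", "time", "replicate")
  if (!all(req %in% names(samples)))
    stop("`samples` must have columns sample, time, replicate")
  missing_cols <- setdiff(colnames(values), samples$sample)
  if (length(missing_cols))
    stop("samples absent from sample sheet: ",
         paste(missing_cols, collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample), , drop = FALSE]
  if (anyDuplicated(samples[, c("time", "replicate")]))
    stop("each sample must map to exactly one (time, replicate)")
  time_order <- sort(unique(samples$time))
  structure(list(values = values, samples = samples, time_order = time_order),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples, %d time points\n",
              nrow(x$values), ncol(x$values), length(x$time_order)))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

# Columns (sample ids) belonging to one time point, optionally checked for a
# minimum replicate count.
time_columns <- function(ds, time, min_rep = 0L) {
  cols <- ds$samples$sample[ds$samples$time == time]
  if (length(cols) < min_rep)
    stop(sprintf("time point %s has %d replicates (need >= %d)",
                 format(time), length(cols), min_rep))
  cols
}

# Genes x time matrix of replicate means.
replicate_means <- function(ds) {
  out <- vapply(ds$time_order, function(tt) {
    rowMeans(ds$values[, time_columns(ds, tt), drop = FALSE])
  }, numeric(nrow(ds$values)))
  colnames(out) <- as.character(ds$time_order)
  out
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
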