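#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity, as a
#' validated front end used by every enrichment and differential test in the
#' pipeline.
#'
#' @param pvalues Numeric vector of p-values in \[0,1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjust_bh <- function(pvalues) {
  if (!is.numeric(pvalues)) stop("p-values must be numeric")
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(pvalues, method = "BH")
}

# Vectorised Welch two-sample test over matrix rows.
# x, y: matrices with the same rows (genes), columns = replicates.
welch_rows <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  if (nx < 2 || ny < 2) stop("Welch test needs >= 2 replicates per group")
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tt <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- se2 == 0
  if (any(zero)) {  # both groups constant: significant iff the means differ
    p[zero] <- ifelse(mx[zero] == my[zero], 1, 0)
    tt[zero] <- ifelse(mx[zero] == my[zero], 0, Inf * sign(mx - my)[zero])
  }
  list(diff = mx - my, t = tt, df = df, p = p)
}

#' Per-time-point differential expression versus a reference
#'
#' Welch two-sample test of each gene's replicate values at every
#' non-reference time point against the reference time point, with
#' Benjamini-Hochberg adjustment across genes within each time point. A gene
#' is a DEG at a time point iff its adjusted p-value is below `alpha` and
#' its |log2 fold change| (mean difference on the log2 scale) is at least
#' `lfc_min`.
#'
#' @param data An [expression_dataset()].
#' @param reference_time Time label used as baseline (default: first).
#' @param alpha Adjusted-p significance threshold.
#' @param lfc_min Minimum |log2 fold change|.
#' @return Data frame with columns `gene`, `time`, `log2fc`, `p`, `padj`,
#'   `is_deg`.
#' @export
call_degs <- function(data, reference_time = NULL, alpha = 0.05, lfc_min = 1) {
  stopifnot(inherits(data, "expression_dataset"))
  if (is.null(reference_time)) reference_time <- data$time_order[1]
  if (!reference_time %in% data$time_order)
    stop("unknown reference_time: ", format(reference_time))
  ref <- data$values[, time_columns(data, reference_time, min_rep = 2L), drop = FALSE]
  out <- lapply(setdiff(data$time_order, reference_time), function(tt) {
    cur <- data$values[, time_columns(data, tt, min_rep = 2L), drop = FALSE]
    w <- welch_rows(cur, ref)
    padj <- adjust_bh(w$p)
    data.frame(gene = rownames(data$values), time = tt, log2fc = w$diff,
               p = w$p, padj = padj,
               is_deg = padj < alpha & abs(w$diff) >= lfc_min,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Emergent genes: first significant change in the expression gradient
#'
#' For every consecutive pair of time points, tests each gene's replicate
#' values at the later time against the earlier one (Welch test, BH across
#' genes within the pair). A gene's emergent time is the first time point at
#' which this gradient test is significant (adjusted p < `alpha` and |mean
#' difference| >= `lfc_min`); genes never significant get `NA`. In
#' `"baseline"` mode each time point is instead compared against the first.
#'
#' @inheritParams call_degs
#' @param mode `"gradient"` (consecutive differences, default) or
#'   `"baseline"`.
#' @return List with `emergent_time` (named vector of time labels, `NA` if
#'   never significant), `counts` (data frame `time`, `n_emergent`) and
#'   `table` (the per-pair long test table).
#' @export
find_emergent <- function(data, alpha = 0.05, lfc_min = 1,
                          mode = c("gradient", "baseline")) {
  stopifnot(inherits(data, "expression_dataset"))
  mode <- match.arg(mode)
  times <- data$time_order
  if (length(times) < 3) stop("need >= 3 ordered time points")
  if (anyDuplicated(times)) stop("duplicated time labels")
  genes <- rownames(data$values)
  emergent <- rep(NA_real_, length(genes))
  names(emergent) <- genes
  tabs <- vector("list", length(times) - 1L)
  for (k in 2:length(times)) {
    earlier <- if (mode == "gradient") times[k - 1] else times[1]
    a <- data$values[, time_columns(data, earlier, min_rep = 2L), drop = FALSE]
    b <- data$values[, time_columns(data, times[k], min_rep = 2L), drop = FALSE]
    w <- welch_rows(b, a)
    padj <- adjust_bh(w$p)
    sig <- padj < alpha & abs(w$diff) >= lfc_min
    newly <- sig & is.na(emergent)
    emergent[newly] <- times[k]
    tabs[[k - 1L]] <- data.frame(gene = genes, time = times[k], diff = w$diff,
                                 p = w$p, padj = padj, significant = sig,
                                 row.names = NULL)
  }
  counts <- data.frame(time = times[-1],
                       n_emergent = vapply(times[-1], function(tt)
                         sum(emergent == tt, na.rm = TRUE), numeric(1)))
  list(emergent_time = emergent, counts = counts, table = do.call(rbind, tabs))
}
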