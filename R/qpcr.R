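#' Fit a 5-parameter Richards sigmoid to a qPCR amplification curve
#'
#' Nonlinear least-squares fit of
#' \eqn{F(x) = Fb + Fmax (1 + e^{-(x-c)/b})^{-d}} to cycle/fluorescence
#' data. Starting values are taken from the data: `Fb` = minimum, `Fmax` =
#' range, `c` = first cycle at half range, `b` = 2, `d` = 1.
#'
#' @param cycles Ordered cycle numbers (>= 15 of them).
#' @param fluorescence Fluorescence readings (arbitrary units); the curve
#'   must actually amplify (max/min ratio >= 5).
#' @return List with `params` (named: `Fmax`, `b`, `c`, `d`, `Fb`),
#'   `residual` (root-mean-square, same units as fluorescence) and
#'   `fitted` values.
#' @export
fit_richards <- function(cycles, fluorescence) {
  if (length(cycles) != length(fluorescence)) stop("length mismatch")
  if (length(cycles) < 15) stop("need >= 15 cycles")
  fmin <- min(fluorescence); fmax <- max(fluorescence)
  ratio <- if (fmin > 0) fmax / fmin else Inf
  if (ratio < 5) stop("no amplification: max/min fluorescence ratio below 5")
  half <- fmin + (fmax - fmin) / 2
  start <- list(Fmax = fmax - fmin, b = 2,
                c = cycles[which(fluorescence >= half)[1]], d = 1, Fb = fmin)
  df <- data.frame(x = cycles, y = fluorescence)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Fb + Fmax * (1 + exp(-(x - c) / b))^(-d),
                      data = df, start = start,
                      lower = c(Fmax = 1e-8, b = 1e-3, c = -Inf, d = 1e-3,
                                Fb = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Richards fit did not converge: ",
                             conditionMessage(e)))
  p <- stats::coef(fit)
  res <- sqrt(mean(stats::residuals(fit)^2))
  list(params = p, residual = res, fitted = stats::fitted(fit))
}

#' Cy0 of a fitted Richards amplification curve
#'
#' The Cy0 quantification value: the x-intercept, measured from the
#' baseline `Fb`, of the tangent to the fitted curve at its inflection
#' point. For this parameterization the inflection lies at
#' \eqn{x^* = c + b \ln d}, where \eqn{F(x^*) - Fb = Fmax (1 + 1/d)^{-d}}
#' and \eqn{F'(x^*) = (Fmax / b)(1 + 1/d)^{-d-1}}, so
#' \eqn{Cy0 = x^* - (F(x^*) - Fb) / F'(x^*)}. Subtracting the baseline
#' makes the value invariant to fluorescence offsets and linear rescaling.
#'
#' @param params Named vector or list with `Fmax`, `b`, `c`, `d`, `Fb`
#'   (e.g. `fit_richards(...)$params`).
#' @return Cy0 in cycles.
#' @export
compute_cy0 <- function(params) {
  p <- as.list(params)
  if (p$Fmax <= 0 || p$b <= 0 || p$d <= 0)
    stop("invalid parameters: Fmax, b and d must be positive")
  cy0 <- richards_cy0(p$Fmax, p$b, p$c, p$d, if (is.null(p$Fb)) 0 else p$Fb)
  if (!is.finite(cy0)) stop("non-finite tangent construction")
  cy0
}

#' Cy0 quantification of a table of amplification curves
#'
#' Fits every well of a long-format curve table and reports fitted
#' parameters, fit residual and Cy0, flagging wells whose Cy0 falls outside
#' the observed cycle range.
#'
#' @param curves Data frame with columns `well`, `cycle`, `fluorescence`.
#' @return Data frame with one row per well: `well`, `Fmax`, `b`, `c`, `d`,
#'   `Fb`, `residual`, `cy0`, `in_range`.
#' @export
cy0_table <- function(curves) {
  stopifnot(all(c("well", "cycle", "fluorescence") %in% names(curves)))
  wells <- unique(curves$well)
  rows <- lapply(wells, function(w) {
    sub <- curves[curves$well == w, , drop = FALSE]
    sub <- sub[order(sub$cycle), , drop = FALSE]
    fit <- fit_richards(sub$cycle, sub$fluorescence)
    cy0 <- compute_cy0(fit$params)
    p <- fit$params
    data.frame(well = w, Fmax = p[["Fmax"]], b = p[["b"]], c = p[["c"]],
               d = p[["d"]], Fb = p[["Fb"]], residual = fit$residual,
               cy0 = cy0,
               in_range = cy0 >= min(sub$cycle) & cy0 <= max(sub$cycle))
  })
  do.call(rbind, rows)
}
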