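#' Construct a hybrid Boolean/continuous dynamical system from a GRN
#'
#' Translates a signed directed regulatory network into the standardized
#' qualitative dynamical-systems form: each node i carries an activator set
#' (incoming +1 edges) and an inhibitor set (incoming -1 edges), a sigmoid
#' gain `h` and a first-order decay rate `gamma`. Nodes may be clamped to a
#' fixed activation in \[0,1\] (knockout = 0, constitutive activation = 1).
#'
#' @param grn A [build_grn()] `regulatory_network`, or a data frame of
#'   directed edges (`regulator`, `target`, `sign`).
#' @param h Sigmoid gain (> 0).
#' @param gamma Decay rate (> 0), recycled over nodes.
#' @param clamp Named numeric vector of clamped activations in \[0,1\].
#' @return Object of class `squad_system`.
#' @export
squad_system <- function(grn, h = 10, gamma = 1, clamp = NULL) {
  edges <- if (inherits(grn, "regulatory_network")) grn$edges else grn
  stopifnot(is.data.frame(edges))
  if (!"sign" %in% names(edges)) edges$sign <- 1
  reg <- as.character(edges$regulator)
  tgt <- as.character(edges$target)
  nodes <- unique(c(reg, tgt))
  act <- inh <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    if (edges$sign[i] > 0) act[[tgt[i]]] <- union(act[[tgt[i]]], reg[i])
    else inh[[tgt[i]]] <- union(inh[[tgt[i]]], reg[i])
  }
  for (nd in nodes)
    if (length(intersect(act[[nd]], inh[[nd]])))
      stop("node ", nd, " has a regulator that both activates and inhibits it")
  if (h <= 0) stop("h must be > 0")
  gamma <- rep_len(gamma, length(nodes))
  if (any(gamma <= 0)) stop("gamma must be > 0")
  names(gamma) <- nodes
  if (!is.null(clamp)) {
    if (is.null(names(clamp)) || !all(names(clamp) %in% nodes))
      stop("clamp must be a named vector over system nodes")
    if (any(clamp < 0 | clamp > 1)) stop("clamp values must lie in [0,1]")
  }
  structure(list(nodes = nodes, act = act, inh = inh, h = h, gamma = gamma,
                 clamp = clamp),
            class = "squad_system")
}

#' @export
print.squad_system <- function(x, ...) {
  cat(sprintf("squad_system: %d nodes, h = %g, %d clamped\n",
              length(x$nodes), x$h, length(x$clamp)))
  invisible(x)
}

with_clamp <- function(system, clamp) {
  system$clamp <- clamp
  system
}

#' SQUAD sigmoid activation
#'
#' The normalized sigmoid mapping a regulatory input \eqn{\omega \in [0,1]}
#' to an activation in \[0,1\]:
#' \deqn{f(\omega) = \frac{-e^{0.5h} + e^{-h(\omega - 0.5)}}
#'   {(1 - e^{0.5h})(1 + e^{-h(\omega - 0.5)})}}
#' It is continuous, strictly increasing, and anchored at f(0) = 0,
#' f(0.5) = 0.5, f(1) = 1 for every gain h.
#'
#' @param omega Regulatory input in \[0,1\] (vectorised).
#' @param h Gain (> 0); larger values sharpen the switch.
#' @return Activation in \[0,1\].
#' @export
squad_activation <- function(omega, h = 10) {
  if (any(omega < 0 | omega > 1)) stop("omega must lie in [0,1]")
  if (h <= 0) stop("h must be > 0")
  e1 <- exp(0.5 * h)
  e2 <- exp(-h * (omega - 0.5))
  (-e1 + e2) / ((1 - e1) * (1 + e2))
}

#' Regulatory input of a node
#'
#' Saturating combination of a node's activator and inhibitor states: with
#' \eqn{S_A} the summed activator activations and \eqn{N_A} the activator
#' count (likewise B for inhibitors),
#' `act = ((1 + N_A) / N_A) * S_A / (1 + S_A)` (1 when there are no
#' activators), `inh` analogously (0 when there are no inhibitors), and
#' \eqn{\omega = act (1 - inh)}. Nodes with no regulators at all have no
#' defined input and return `NA` (the integrator treats them as decaying
#' inputs).
#'
#' @param system A [squad_system()].
#' @param node Node id.
#' @param x Named state vector of activations in \[0,1\].
#' @return The input `omega` in \[0,1\], or `NA` for unregulated nodes.
#' @export
squad_omega <- function(system, node, x) {
  if (any(x < 0 | x > 1)) stop("state values must lie in [0,1]")
  a <- system$act[[node]]
  b <- system$inh[[node]]
  if (!length(a) && !length(b)) return(NA_real_)
  act <- if (length(a)) {
    sa <- sum(x[a])
    ((1 + length(a)) / length(a)) * sa / (1 + sa)
  } else 1
  inh <- if (length(b)) {
    sb <- sum(x[b])
    ((1 + length(b)) / length(b)) * sb / (1 + sb)
  } else 0
  act * (1 - inh)
}

# Derivative field: dx_i = f(omega_i, h) - gamma_i x_i for regulated nodes,
# -gamma_i x_i for unregulated ones, 0 for clamped ones.
squad_deriv <- function(system, x) {
  dx <- numeric(length(x))
  names(dx) <- names(x)
  for (nd in system$nodes) {
    om <- squad_omega(system, nd, x)
    dx[nd] <- if (is.na(om)) -system$gamma[nd] * x[nd]
              else squad_activation(om, system$h) - system$gamma[nd] * x[nd]
  }
  dx[names(system$clamp)] <- 0
  dx
}

#' Integrate the SQUAD system
#'
#' Fixed-step fourth-order Runge-Kutta integration of
#' \eqn{dx_i/dt = f(\omega_i, h) - \gamma_i x_i}. Clamped nodes are held at
#' their clamp value; unregulated, unclamped nodes decay toward 0. The
#' integration stops early once the maximal derivative magnitude falls
#' below `tol` (steady state).
#'
#' @param system A [squad_system()].
#' @param x0 Named initial state in \[0,1\] (default: all zeros); clamp
#'   values override.
#' @param t_end Integration horizon (> 0).
#' @param dt Step size (> 0).
#' @param tol Residual tolerance for steadiness.
#' @return Object of class `squad_trajectory`: list with `time`, `x` (time
#'   x nodes activation matrix), `steady` flag, `residual`
#'   (final \eqn{\max_i |dx_i/dt|}) and `final` (last state).
#' @export
squad_integrate <- function(system, x0 = NULL, t_end = 60, dt = 0.05,
                            tol = 1e-6) {
  if (dt <= 0 || t_end <= 0) stop("dt and t_end must be > 0")
  nodes <- system$nodes
  if (is.null(x0)) x0 <- stats::setNames(rep(0, length(nodes)), nodes)
  if (is.null(names(x0)) || !all(nodes %in% names(x0)))
    stop("x0 must be a named vector covering all system nodes")
  x <- x0[nodes]
  if (any(x < 0 | x > 1)) stop("x0 must lie in [0,1]")
  if (length(system$clamp)) x[names(system$clamp)] <- system$clamp
  n_steps <- ceiling(t_end / dt)
  times <- numeric(n_steps + 1)
  traj <- matrix(NA_real_, n_steps + 1, length(nodes),
                 dimnames = list(NULL, nodes))
  traj[1, ] <- x
  steady <- FALSE
  residual <- NA_real_
  last <- 1L
  for (s in seq_len(n_steps)) {
    dx <- squad_deriv(system, x)
    residual <- max(abs(dx))
    if (is.na(residual)) stop("integration failure: residual is NaN")
    if (residual < tol) { steady <- TRUE; break }
    clip01 <- function(z) pmin(pmax(z, 0), 1)  # guard intermediate stages
    k1 <- dx
    k2 <- squad_deriv(system, clip01(x + dt / 2 * k1))
    k3 <- squad_deriv(system, clip01(x + dt / 2 * k2))
    k4 <- squad_deriv(system, clip01(x + dt * k3))
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(x < -1e-6 | x > 1 + 1e-6))
      stop("integration failure: state left [0,1] beyond numerical guard")
    x <- pmin(pmax(x, 0), 1)
    if (length(system$clamp)) x[names(system$clamp)] <- system$clamp
    last <- s + 1L
    times[last] <- s * dt
    traj[last, ] <- x
  }
  if (!steady) {
    dx <- squad_deriv(system, x)
    residual <- max(abs(dx))
    steady <- residual < tol
  }
  structure(list(time = times[seq_len(last)],
                 x = traj[seq_len(last), , drop = FALSE],
                 steady = steady, residual = residual, final = x),
            class = "squad_trajectory")
}

#' @export
print.squad_trajectory <- function(x, ...) {
  cat(sprintf("squad_trajectory: %d nodes, t = [0, %.2f], %s (residual %.2e)\n",
              ncol(x$x), max(x$time),
              if (x$steady) "steady" else "not steady", x$residual))
  invisible(x)
}

#' Boolean fixed points of the underlying logic
#'
#' Synchronous Boolean dynamics consistent with the network logic:
#' `x_i' = OR(activators) AND NOT OR(inhibitors)` for regulated nodes;
#' input nodes (no regulators) hold their value; clamped nodes are fixed at
#' the rounded clamp value. All states over the free nodes are enumerated
#' exhaustively and the fixed points returned.
#'
#' @param system A [squad_system()] with at most 20 free (unclamped) nodes.
#' @return 0/1 matrix with one fixed point per row, columns = nodes.
#' @export
boolean_attractors <- function(system) {
  nodes <- system$nodes
  clamped <- names(system$clamp)
  free <- setdiff(nodes, clamped)
  if (length(free) > 20)
    stop("more than 20 free nodes: exhaustive enumeration refused; ",
         "consider sampling initial states instead")
  fixed <- list()
  clamp_val <- if (length(clamped)) round(system$clamp) else numeric(0)
  for (code in 0:(2^length(free) - 1)) {
    x <- stats::setNames(integer(length(nodes)), nodes)
    if (length(free)) x[free] <- bitwAnd(bitwShiftR(code, seq_along(free) - 1L), 1L)
    if (length(clamped)) x[clamped] <- clamp_val
    xn <- x
    for (nd in nodes) {
      a <- system$act[[nd]]; b <- system$inh[[nd]]
      if (length(a) || length(b)) {
        on_a <- if (length(a)) any(x[a] == 1L) else TRUE
        on_b <- if (length(b)) any(x[b] == 1L) else FALSE
        xn[nd] <- as.integer(on_a && !on_b)
      }
    }
    if (length(clamped)) xn[clamped] <- clamp_val
    if (all(xn == x)) fixed[[length(fixed) + 1L]] <- x
  }
  out <- do.call(rbind, fixed)
  if (is.null(out)) out <- matrix(integer(0), 0, length(nodes),
                                  dimnames = list(NULL, nodes))
  out
}

#' Steady-state perturbation scan of one node
#'
#' Relaxes the system to steady state with `node` clamped at `value_from`,
#' then again (from the same initial state) with the node clamped at
#' `value_to`, and reports the per-node steady-state changes, sorted by
#' magnitude. Models knockout (clamp 0) and constitutive activation
#' (clamp 1) experiments.
#'
#' @param system A [squad_system()].
#' @param node Node to clamp.
#' @param value_from,value_to Clamp values in \[0,1\].
#' @param x0 Initial state passed to [squad_integrate()].
#' @param ... Further arguments to [squad_integrate()].
#' @return Data frame `node`, `from`, `to`, `delta`, sorted by `|delta|`
#'   decreasing.
#' @export
perturbation_scan <- function(system, node, value_from = 0, value_to = 1,
                              x0 = NULL, ...) {
  if (!node %in% system$nodes) stop("unknown node: ", node)
  clamp_a <- c(system$clamp[setdiff(names(system$clamp), node)],
               stats::setNames(value_from, node))
  clamp_b <- c(system$clamp[setdiff(names(system$clamp), node)],
               stats::setNames(value_to, node))
  ta <- squad_integrate(with_clamp(system, clamp_a), x0 = x0, ...)
  tb <- squad_integrate(with_clamp(system, clamp_b), x0 = x0, ...)
  if (!ta$steady || !tb$steady)
    stop(sprintf("relaxation did not reach steady state (residuals %.3e, %.3e)",
                 ta$residual, tb$residual))
  delta <- tb$final - ta$final
  out <- data.frame(node = system$nodes, from = unname(ta$final),
                    to = unname(tb$final), delta = unname(delta))
  out[order(abs(out$delta), decreasing = TRUE), , drop = FALSE]
}
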