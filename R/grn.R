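#' Shifted Hill regulation multiplier
#'
#' The regulation function used throughout the ODE system:
#' \deqn{H^s(X) = \lambda + \frac{1 - \lambda}{1 + (X/X_0)^n}.}
#' With no regulator (`X = 0`) the multiplier is 1; at saturation it
#' approaches the fold change `lambda`.  Activation uses `lambda > 1`,
#' inhibition `0 < lambda < 1`; `lambda = 1` is a neutral edge.
#'
#' @param x regulator concentration(s), `>= 0`.
#' @param x0 half-response threshold, `> 0`.
#' @param n Hill coefficient, integer `>= 1`.
#' @param lambda fold change, `> 0`.
#' @return Multiplier(s) bounded between `min(1, lambda)` and `max(1, lambda)`.
#' @export
#' @examples
#' shifted_hill(0, 50, 4, 0.1)   # 1: no regulator
#' shifted_hill(50, 50, 4, 0.01) # (1 + lambda) / 2
shifted_hill <- function(x, x0, n, lambda) {
  if (any(x0 <= 0)) stop("x0 must be positive", call. = FALSE)
  if (any(n < 1) || any(n != round(n))) {
    stop("Hill coefficient n must be a positive integer", call. = FALSE)
  }
  if (any(lambda <= 0)) stop("lambda must be positive", call. = FALSE)
  if (any(x < 0)) stop("x must be non-negative", call. = FALSE)
  lambda + (1 - lambda) / (1 + (x / x0)^n)
}

#' Parameter sampling ranges for the kinetic ensemble
#'
#' Holds the uniform sampling windows used by [sample_parameter_set()]:
#' production rate `g`, degradation rate `k`, integer Hill coefficient `n`,
#' and activation fold change `lambda` (inhibition folds are the
#' reciprocals of draws from the same window).  Edge thresholds follow the
#' half-functional rule: `X0` for any edge out of node j is uniform on
#' `[0.02 M, 1.98 M]` where `M` is the median unregulated level `g/k`
#' implied by the `g` and `k` windows.
#'
#' @param g_range production rate window (concentration/time).
#' @param k_range degradation rate window (1/time).
#' @param n_range integer Hill-coefficient bounds (inclusive).
#' @param lambda_range activation fold-change window (`>= 1`).
#' @param threshold_rule threshold scheme; only `"half_functional"` is
#'   implemented.
#' @return An object of class `sampling_ranges`.
#' @export
sampling_ranges <- function(g_range = c(1, 100), k_range = c(0.1, 1),
                            n_range = c(1L, 6L), lambda_range = c(1, 100),
                            threshold_rule = "half_functional") {
  chk <- function(r, name, lo = -Inf) {
    if (length(r) != 2 || r[1] > r[2] || r[1] <= lo) {
      stop("invalid ", name, call. = FALSE)
    }
  }
  chk(g_range, "g_range", 0)
  chk(k_range, "k_range", 0)
  chk(lambda_range, "lambda_range", 0)
  if (any(n_range < 1) || any(n_range != round(n_range)) ||
      n_range[1] > n_range[2]) {
    stop("n_range must be positive integer bounds", call. = FALSE)
  }
  threshold_rule <- match.arg(threshold_rule, "half_functional")
  structure(list(g_range = g_range, k_range = k_range,
                 n_range = as.integer(n_range), lambda_range = lambda_range,
                 threshold_rule = threshold_rule,
                 median_level = median_unregulated_level(g_range, k_range)),
            class = "sampling_ranges")
}

#' Median unregulated expression level implied by sampling windows
#'
#' The median of `g/k` with `g` and `k` independent uniform on the given
#' windows, computed by numerically inverting the exact CDF
#' `P(g/k <= m) = E_k[(min(g_max, m k) - g_min)+ / (g_max - g_min)]`.
#' Deterministic (no Monte Carlo), so threshold sampling is fully
#' reproducible from the ranges alone.
#'
#' @param g_range,k_range uniform windows for production and degradation.
#' @return The median level (scalar).
#' @export
median_unregulated_level <- function(g_range = c(1, 100),
                                     k_range = c(0.1, 1)) {
  cdf <- function(m) {
    stats::integrate(function(k) {
      pmax(pmin(g_range[2], m * k) - g_range[1], 0) / diff(g_range)
    }, k_range[1], k_range[2])$value / diff(k_range)
  }
  hi <- g_range[2] / k_range[1]
  stats::uniroot(function(m) cdf(m) - 0.5, c(g_range[1] / k_range[2], hi),
                 tol = 1e-8)$root
}

#' Construct a kinetic parameter set
#'
#' Validates and assembles the full kinetic realization of a topology:
#' per-node production and degradation rates, and per-edge regulation
#' parameters aligned with the topology's edge order.
#'
#' @param topology a [network_topology()].
#' @param g,k positive per-node production and degradation rates (named or
#'   in topology node order).
#' @param lambda per-edge fold changes; must exceed 1 on activation edges
#'   and lie in (0, 1) on inhibition edges.
#' @param n per-edge integer Hill coefficients (`>= 1`).
#' @param x0 per-edge positive thresholds.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(topology, g, k, lambda = numeric(),
                           n = integer(), x0 = numeric()) {
  stopifnot(inherits(topology, "network_topology"))
  nn <- length(topology$nodes)
  ne <- nrow(topology$edges)
  if (length(g) != nn || length(k) != nn) {
    stop("g and k need one entry per node", call. = FALSE)
  }
  if (length(lambda) != ne || length(n) != ne || length(x0) != ne) {
    stop("lambda, n and x0 need one entry per edge", call. = FALSE)
  }
  if (!is.null(names(g))) g <- g[topology$nodes]
  if (!is.null(names(k))) k <- k[topology$nodes]
  stopifnot(all(g > 0), all(k > 0), all(x0 > 0),
            all(n >= 1), all(n == round(n)), all(lambda > 0))
  act <- topology$edges$sign == "activation"
  if (any(lambda[act] < 1) || any(lambda[!act] > 1)) {
    stop("lambda must be >= 1 on activation edges and <= 1 on inhibition edges",
         call. = FALSE)
  }
  structure(list(g = stats::setNames(as.numeric(g), topology$nodes),
                 k = stats::setNames(as.numeric(k), topology$nodes),
                 lambda = as.numeric(lambda), n = as.integer(n),
                 x0 = as.numeric(x0), topology = topology),
            class = "kinetic_params")
}

#' Estimate per-node median expression levels under regulation
#'
#' The half-functional threshold rule wants each regulation to have
#' roughly even odds of being functional, so edge thresholds must track
#' the typical level of the *regulated* source gene, not its bare `g/k`.
#' For each node this Monte-Carlo estimate draws `g`, `k` and, for every
#' incoming edge, a shifted-Hill multiplier with freshly sampled kinetics
#' and a regulator level at its unregulated scale (one level of regulatory
#' context), then takes the median of the resulting level.  Strongly
#' inhibited genes (e.g. a microRNA repressed by two transcription
#' factors) thus get medians well below `g/k`, and their outgoing-edge
#' thresholds become reachable.
#'
#' Uses the ambient RNG, so results are reproducible under `set.seed()`.
#'
#' @param topology a [network_topology()].
#' @param ranges a [sampling_ranges()].
#' @param n_draws Monte-Carlo draws per node.
#' @return Named numeric vector of median levels, one per node.
#' @export
estimate_node_medians <- function(topology, ranges = sampling_ranges(),
                                  n_draws = 5000) {
  m0 <- ranges$median_level
  n <- n_draws
  med <- vapply(topology$nodes, function(node) {
    g <- stats::runif(n, ranges$g_range[1], ranges$g_range[2])
    k <- stats::runif(n, ranges$k_range[1], ranges$k_range[2])
    lev <- g / k
    for (e in which(topology$edges$target == node)) {
      fold <- stats::runif(n, ranges$lambda_range[1], ranges$lambda_range[2])
      lam <- if (topology$edges$sign[e] == "activation") fold else 1 / fold
      n_vals <- seq(ranges$n_range[1], ranges$n_range[2])
      nh <- n_vals[sample.int(length(n_vals), n, replace = TRUE)]
      x0 <- stats::runif(n, 0.02 * m0, 1.98 * m0)
      xs <- stats::runif(n, ranges$g_range[1], ranges$g_range[2]) /
        stats::runif(n, ranges$k_range[1], ranges$k_range[2])
      lev <- lev * (lam + (1 - lam) / (1 + (xs / x0)^nh))
    }
    stats::median(lev)
  }, 1)
  names(med) <- topology$nodes
  med
}

#' Sample one kinetic parameter set
#'
#' Draws a full kinetic realization for a topology: per-node production `g`
#' and degradation `k` (uniform), per-edge Hill coefficient `n` (uniform
#' integer), fold change `lambda` (activation: uniform on `lambda_range`;
#' inhibition: reciprocal of a draw from the same range, so in
#' `[1/max, 1/min]`), and threshold `X0` by the half-functional rule:
#' uniform on `[0.02 M, 1.98 M]` where `M` is the source node's median
#' regulated level from [estimate_node_medians()].  Reproducible through
#' R's RNG (`set.seed()`).
#'
#' @param topology a [network_topology()].
#' @param ranges a [sampling_ranges()].
#' @param node_medians optional named vector from
#'   [estimate_node_medians()]; estimated on the fly when `NULL`.
#'   Precompute it when sampling many sets.
#' @return An object of class `kinetic_params` with fields `g`, `k` (named
#'   per node) and `lambda`, `n`, `x0` (per edge, in topology edge order),
#'   plus the source topology.
#' @export
sample_parameter_set <- function(topology, ranges = sampling_ranges(),
                                 node_medians = NULL) {
  stopifnot(inherits(topology, "network_topology"),
            inherits(ranges, "sampling_ranges"))
  if (is.null(node_medians)) {
    node_medians <- estimate_node_medians(topology, ranges)
  }
  nn <- length(topology$nodes)
  ne <- nrow(topology$edges)
  g <- stats::runif(nn, ranges$g_range[1], ranges$g_range[2])
  k <- stats::runif(nn, ranges$k_range[1], ranges$k_range[2])
  names(g) <- names(k) <- topology$nodes
  n_vals <- seq(ranges$n_range[1], ranges$n_range[2])
  n <- if (ne) n_vals[sample.int(length(n_vals), ne, replace = TRUE)]
       else integer()
  fold <- stats::runif(ne, ranges$lambda_range[1], ranges$lambda_range[2])
  lambda <- ifelse(topology$edges$sign == "activation", fold, 1 / fold)
  m_src <- node_medians[topology$edges$source]
  x0 <- stats::runif(ne, 0.02 * m_src, 1.98 * m_src)
  structure(list(g = g, k = k, lambda = as.numeric(lambda),
                 n = as.integer(n), x0 = as.numeric(x0),
                 topology = topology),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("kinetic_params for", length(x$g), "nodes /", length(x$lambda),
      "edges\n")
  cat("g:", signif(x$g, 3), "\n")
  cat("k:", signif(x$k, 3), "\n")
  invisible(x)
}

#' Describe an over-/down-expression perturbation
#'
#' @param node node name to perturb.
#' @param mode `"over_expression"` or `"down_expression"`.
#' @param fold positive multiplier (`> 1`) applied to (over) or dividing
#'   (down) the node's production rate.
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(node, mode = c("over_expression", "down_expression"),
                         fold = 10) {
  mode <- match.arg(mode)
  if (!is.numeric(fold) || fold <= 1) stop("fold must be > 1", call. = FALSE)
  structure(list(node = node, mode = mode, fold = fold),
            class = "perturbation")
}

#' Apply a perturbation to a kinetic parameter set
#'
#' Over-expression multiplies the node's production rate `g` by `fold`;
#' down-expression divides it.  All other parameters are untouched, so the
#' perturbed set remains comparable to its parent.
#'
#' @param params a `kinetic_params` object.
#' @param pert a [perturbation()].
#' @return The modified `kinetic_params`.
#' @export
apply_perturbation <- function(params, pert) {
  stopifnot(inherits(params, "kinetic_params"), inherits(pert, "perturbation"))
  i <- node_index(params$topology, pert$node)
  params$g[i] <- switch(pert$mode,
    over_expression = params$g[i] * pert$fold,
    down_expression = params$g[i] / pert$fold
  )
  params
}

#' Time derivatives of the regulatory ODE system
#'
#' For node i, `dX_i/dt = g_i * prod_j H^s(X_j; X0_ji, n_ji, lambda_ji) -
#' k_i X_i`, where the product runs over the incoming edges of node i and
#' is 1 for unregulated nodes.
#'
#' @param state named (or topology-ordered) non-negative concentration
#'   vector.
#' @param params a `kinetic_params` object.
#' @return Named vector of time derivatives.
#' @export
ode_rhs <- function(state, params) {
  stopifnot(inherits(params, "kinetic_params"))
  topo <- params$topology
  if (length(state) != length(topo$nodes)) {
    stop("state length does not match topology", call. = FALSE)
  }
  if (!is.null(names(state))) state <- state[topo$nodes]
  if (any(state < 0)) stop("state must be non-negative", call. = FALSE)
  src <- node_index(topo, topo$edges$source)
  tgt <- node_index(topo, topo$edges$target)
  prod_h <- rep(1, length(state))
  for (e in seq_along(src)) {
    prod_h[tgt[e]] <- prod_h[tgt[e]] *
      shifted_hill(state[[src[e]]], params$x0[e], params$n[e],
                   params$lambda[e])
  }
  out <- params$g * prod_h - params$k * state
  names(out) <- topo$nodes
  out
}

# Flattened integer/double views of a parameter set for the compiled core.
params_flat <- function(params) {
  topo <- params$topology
  list(g = unname(params$g), k = unname(params$k),
       lambda = params$lambda, n = params$n, x0 = params$x0,
       src = node_index(topo, topo$edges$source) - 1L,
       tgt = node_index(topo, topo$edges$target) - 1L)
}
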