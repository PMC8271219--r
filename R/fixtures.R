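#' Degree- and sign-preserving topology randomization
#'
#' Randomizes the wiring of a signed directed network while preserving
#' every node's in- and out-degree, the total numbers of activating and
#' inhibiting edges, and self-loops as self-loops.  The move set is:
#' repeated double-edge endpoint swaps — pick edges (a, b) and (c, d) and
#' rewire to (a, d) and (c, b), rejecting moves that create duplicate
#' (source, target) pairs or new self-loops — followed by a random
#' permutation of the sign labels across edge positions.
#'
#' @param topology a [network_topology()] with at least 2 edges.
#' @param n_swaps target number of accepted endpoint swaps.
#' @param max_attempts give up (with an error) if no valid randomization
#'   differing from the input is found within this many proposals.
#' @return A randomized [network_topology()] over the same nodes.
#' @export
randomize_topology <- function(topology, n_swaps = 10 * nrow(topology$edges),
                               max_attempts = 1000) {
  e <- topology$edges
  if (nrow(e) < 2) stop("need at least 2 edges to randomize", call. = FALSE)
  loops <- e$source == e$target
  src <- e$source
  tgt <- e$target
  swappable <- which(!loops)
  accepted <- 0L
  attempts <- 0L
  key <- function() paste(src, tgt)
  while (accepted < n_swaps && attempts < max_attempts) {
    attempts <- attempts + 1L
    if (length(swappable) < 2) break
    ij <- sample(swappable, 2)
    i <- ij[1]; j <- ij[2]
    new_ti <- tgt[j]; new_tj <- tgt[i]
    if (src[i] == new_ti || src[j] == new_tj) next  # would create self-loop
    cur <- key()
    k1 <- paste(src[i], new_ti); k2 <- paste(src[j], new_tj)
    if (k1 == k2 || k1 %in% cur[-c(i, j)] || k2 %in% cur[-c(i, j)]) next
    tgt[i] <- new_ti; tgt[j] <- new_tj
    accepted <- accepted + 1L
  }
  if (accepted == 0L) {
    stop("no valid randomization found within max_attempts", call. = FALSE)
  }
  sign <- sample(e$sign)  # shuffle labels; global counts preserved
  network_topology(data.frame(source = src, target = tgt, sign = sign,
                              stringsAsFactors = FALSE),
                   nodes = topology$nodes)
}

# All stable fixed points of a symmetric-structure 2-node network by
# scanning the 1-D self-consistency map.  For a 2-node network, any fixed
# point satisfies x1 = F1(x2), x2 = F2(x1) with
# Fi(x) = (g_i / k_i) * H(x); roots of x - F1(F2(x)) found on a dense grid
# give every fixed point independent of any time integration.
roots_2node <- function(params, grid_n = 4000) {
  topo <- params$topology
  stopifnot(length(topo$nodes) == 2, nrow(topo$edges) == 2)
  ord <- order(node_index(topo, topo$edges$source))
  ed <- topo$edges[ord, ]
  lam <- params$lambda[ord]; nh <- params$n[ord]; x0 <- params$x0[ord]
  # edge 1: node1 -> node2, edge 2: node2 -> node1
  f2 <- function(x1) params$g[2] / params$k[2] *
    shifted_hill(x1, x0[1], nh[1], lam[1])
  f1 <- function(x2) params$g[1] / params$k[1] *
    shifted_hill(x2, x0[2], nh[2], lam[2])
  gmap <- function(x1) f1(f2(x1)) - x1
  hi <- params$g[1] / params$k[1] * max(1, lam[2]) * 1.01
  xs <- seq(1e-9, hi, length.out = grid_n)
  ys <- vapply(xs, gmap, 1)
  roots <- numeric()
  for (i in seq_len(grid_n - 1)) {
    if (ys[i] == 0) roots <- c(roots, xs[i])
    if (ys[i] * ys[i + 1] < 0) {
      roots <- c(roots, stats::uniroot(gmap, xs[i + (0:1)], tol = 1e-12)$root)
    }
  }
  states <- cbind(roots, vapply(roots, f2, 1))
  colnames(states) <- topo$nodes
  # stability via the Jacobian of the 2-D system
  stable <- apply(states, 1, function(x) {
    h <- 1e-6 * pmax(x, 1)
    j <- matrix(0, 2, 2)
    f0 <- ode_rhs(x, params)
    for (c in 1:2) {
      xp <- x; xp[c] <- xp[c] + h[c]
      j[, c] <- (ode_rhs(xp, params) - f0) / h[c]
    }
    all(Re(eigen(j, only.values = TRUE)$values) < 0)
  })
  list(states = states, stable = stable)
}

#' Two-node toggle-switch fixture with known attractors
#'
#' A symmetric mutual-inhibition pair with strong repression: two stable
#' states (one node high, the other low) separated by an unstable
#' symmetric saddle.  The stable states are found by an independent 1-D
#' root scan of the self-consistency map, not by time integration, so the
#' fixture can serve as an oracle for the steady-state machinery.
#'
#' @param g,k,lambda,n,x0 symmetric kinetic parameters of both nodes and
#'   both inhibition edges.
#' @return List with `topology`, `params` (`kinetic_params`) and `states`
#'   (matrix of the stable fixed points, residual below `1e-8`).
#' @export
make_toggle_fixture <- function(g = 20, k = 1, lambda = 0.05, n = 4,
                                x0 = 10) {
  topo <- network_topology(data.frame(
    source = c("A", "B"), target = c("B", "A"),
    sign = c("inhibition", "inhibition"), stringsAsFactors = FALSE
  ))
  params <- kinetic_params(topo, g = c(A = g, B = g), k = c(A = k, B = k),
                           lambda = c(lambda, lambda), n = c(n, n),
                           x0 = c(x0, x0))
  rt <- roots_2node(params)
  states <- rt$states[rt$stable, , drop = FALSE]
  if (nrow(states) != 2) {
    stop("fixture parameters do not give exactly 2 stable states",
         call. = FALSE)
  }
  resid <- apply(states, 1, function(x) max(abs(ode_rhs(x, params))))
  stopifnot(all(resid < 1e-8))
  list(topology = topo, params = params, states = states)
}

#' Synthetic score ensemble from a known Gaussian mixture
#'
#' Draws EM and resistance score pairs from specified univariate mixtures
#' so the mixture-threshold fitting and classification stages can be
#' tested against analytically known equal-posterior cutpoints.
#'
#' @param em_spec,res_spec lists with numeric vectors `weight`, `mean`,
#'   `sd` (weights must sum to 1; one entry per component).
#' @param n number of score pairs.
#' @return List with `scores` (data.frame `em_score`, `resistance_score`)
#'   and the generating `em_spec`/`res_spec` for recovery tests.
#' @export
synth_score_ensemble <- function(em_spec = list(weight = c(0.4, 0.2, 0.4),
                                                mean = c(-2, 0, 2),
                                                sd = c(0.3, 0.3, 0.3)),
                                 res_spec = list(weight = c(0.5, 0.5),
                                                 mean = c(-2, 2),
                                                 sd = c(0.5, 0.5)),
                                 n = 1000) {
  draw <- function(spec, n) {
    w <- spec$weight
    if (abs(sum(w) - 1) > 1e-8) {
      stop("mixture weights must sum to 1", call. = FALSE)
    }
    comp <- sample(seq_along(w), n, replace = TRUE, prob = w)
    stats::rnorm(n, spec$mean[comp], spec$sd[comp])
  }
  list(scores = data.frame(em_score = draw(em_spec, n),
                           resistance_score = draw(res_spec, n)),
       em_spec = em_spec, res_spec = res_spec)
}
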