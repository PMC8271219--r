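# Shared fixtures and independent oracles for the test suite.

# Single isolated node: dX/dt = g - kX, fixed point g/k.
fix_isolated <- function(g = 10, k = 1) {
  topo <- network_topology(
    data.frame(source = character(), target = character(),
               sign = character(), stringsAsFactors = FALSE),
    nodes = "A"
  )
  kinetic_params(topo, g = g, k = k)
}

# Three-node feed-forward cascade A -> B -| C (no feedback): the unique
# fixed point solves sequentially, giving a closed-form oracle.
fix_cascade <- function() {
  topo <- network_topology(data.frame(
    source = c("A", "B"), target = c("B", "C"),
    sign = c("activation", "inhibition"), stringsAsFactors = FALSE
  ))
  params <- kinetic_params(topo, g = c(A = 12, B = 30, C = 40),
                           k = c(A = 0.5, B = 1, C = 0.8),
                           lambda = c(8, 0.1), n = c(3, 2), x0 = c(20, 25))
  xa <- 12 / 0.5
  xb <- 30 / 1 * shifted_hill(xa, 20, 3, 8)
  xc <- 40 / 0.8 * shifted_hill(xb, 25, 2, 0.1)
  list(params = params, fixed_point = c(A = xa, B = xb, C = xc))
}

# Single auto-repressor: monostable for any parameters (decreasing
# production vs linear degradation cross exactly once).
fix_autorepressor <- function() {
  topo <- network_topology(data.frame(
    source = "A", target = "A", sign = "inhibition",
    stringsAsFactors = FALSE
  ))
  kinetic_params(topo, g = 50, k = 1, lambda = 0.02, n = 4, x0 = 10)
}

# Independent steady-state oracle: stiff-capable lsoda relaxation from
# deSolve, entirely separate from the compiled RK45 path.
oracle_relax <- function(params, x0, t_end = 5000) {
  f <- function(t, y, parms) list(as.numeric(ode_rhs(pmax(y, 0), params)))
  out <- deSolve::lsoda(y = as.numeric(x0), times = c(0, t_end / 2, t_end),
                        func = f, rtol = 1e-10, atol = 1e-10)
  stats::setNames(pmax(as.numeric(out[nrow(out), -1]), 0),
                  params$topology$nodes)
}

# Brute-force fixed-point search for 2-node systems: minimize |rhs|^2 by
# Nelder-Mead (log scale) from a dense grid of seeds; independent of both
# the RK45 integrator and the package's 1-D root scan.
oracle_roots_2node <- function(params, n_grid = 12) {
  hi <- params$g / params$k * 10
  seeds <- expand.grid(
    exp(seq(log(1e-3), log(hi[1]), length.out = n_grid)),
    exp(seq(log(1e-3), log(hi[2]), length.out = n_grid))
  )
  obj <- function(lx) {
    r <- ode_rhs(exp(lx), params)
    sum(r^2)
  }
  sols <- NULL
  for (i in seq_len(nrow(seeds))) {
    op <- stats::optim(log(as.numeric(seeds[i, ])), obj,
                       control = list(maxit = 2000, reltol = 1e-16))
    if (op$value < 1e-14) sols <- rbind(sols, exp(op$par))
  }
  if (is.null(sols)) return(NULL)
  # dedup on relative distance
  keep <- NULL
  for (i in seq_len(nrow(sols))) {
    dup <- FALSE
    if (!is.null(keep)) {
      for (j in seq_len(nrow(keep))) {
        if (max(abs(log(sols[i, ] / keep[j, ]))) < 0.02) dup <- TRUE
      }
    }
    if (!dup) keep <- rbind(keep, sols[i, ])
  }
  colnames(keep) <- params$topology$nodes
  keep
}

# Stability of a fixed point via finite-difference Jacobian eigenvalues.
oracle_stable <- function(params, x) {
  nn <- length(x)
  j <- matrix(0, nn, nn)
  f0 <- ode_rhs(x, params)
  h <- 1e-6 * pmax(x, 1)
  for (c in seq_len(nn)) {
    xp <- x
    xp[c] <- xp[c] + h[c]
    j[, c] <- (ode_rhs(xp, params) - f0) / h[c]
  }
  all(Re(eigen(j, only.values = TRUE)$values) < 0)
}

# Equal-posterior boundary between two Gaussian components, computed from
# known generating parameters (closed-form density equality via uniroot).
oracle_cutpoint <- function(w1, m1, s1, w2, m2, s2) {
  f <- function(x) w1 * dnorm(x, m1, s1) - w2 * dnorm(x, m2, s2)
  uniroot(f, c(m1, m2), tol = 1e-10)$root
}

# Write a temporary topo file and return its path.
write_topo_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".topo",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
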