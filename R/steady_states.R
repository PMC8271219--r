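#' Accessible concentration range of each node
#'
#' For a node with production `g`, degradation `k` and incoming fold
#' changes `lambda_j`, the reachable window is
#' `[(g/k) prod min(1, lambda_j), (g/k) prod max(1, lambda_j)]`: the
#' extremes of the production multiplier over all regulator levels.
#'
#' @param params a `kinetic_params` object.
#' @return Matrix with columns `min` and `max`, one row per node.
#' @keywords internal
node_level_range <- function(params) {
  topo <- params$topology
  base <- params$g / params$k
  lo <- hi <- rep(1, length(base))
  tgt <- node_index(topo, topo$edges$target)
  for (e in seq_along(tgt)) {
    lo[tgt[e]] <- lo[tgt[e]] * min(1, params$lambda[e])
    hi[tgt[e]] <- hi[tgt[e]] * max(1, params$lambda[e])
  }
  cbind(min = base * lo, max = base * hi)
}

#' Draw a random initial condition
#'
#' Each node's start level is log-uniform between its minimum and maximum
#' accessible levels (see [node_level_range()]); unregulated nodes collapse
#' to their fixed level `g/k`.
#'
#' @param params a `kinetic_params` object.
#' @param n number of initial conditions.
#' @return Matrix of `n` rows, one column per node.
#' @export
sample_initial_condition <- function(params, n = 1) {
  rng <- node_level_range(params)
  llo <- log(rng[, "min"])
  lhi <- log(rng[, "max"])
  nn <- nrow(rng)
  u <- matrix(stats::runif(n * nn), n, nn)
  x <- exp(sweep(sweep(u, 2, lhi - llo, `*`), 2, llo, `+`))
  colnames(x) <- params$topology$nodes
  x
}

#' Relax one initial condition to a steady state
#'
#' Integrates the ODE system with an adaptive embedded Runge-Kutta scheme
#' until the scaled residual `max |dX/dt| / max(X, 1)` falls below `tol`,
#' or `t_max` is reached (reported as non-converged, never dropped
#' silently).
#'
#' @param params a `kinetic_params` object.
#' @param x0 non-negative start vector (topology order).
#' @param tol steady-state residual tolerance.
#' @param t_max integration horizon in model time units.
#' @return List with `state` (named concentrations), `converged` (logical)
#'   and `residual`.
#' @export
integrate_to_steady_state <- function(params, x0, tol = 1e-6, t_max = 1000) {
  if (any(x0 < 0)) stop("x0 must be non-negative", call. = FALSE)
  fp <- params_flat(params)
  res <- cpp_steady_states(matrix(as.numeric(x0), nrow = 1),
                           fp$g, fp$k, fp$lambda, fp$n, fp$x0,
                           fp$src, fp$tgt, tol, t_max)
  state <- drop(res$states)
  names(state) <- params$topology$nodes
  list(state = state, converged = res$converged[1],
       residual = res$residual[1])
}

# Greedy dedup of states on log2-scale Euclidean distance.
# Returns the distinct states ordered by the first node's level.
dedup_states <- function(states, dedup_tol = 0.1) {
  if (nrow(states) == 0) return(states)
  lg <- log2(pmax(states, .Machine$double.eps))
  keep <- integer()
  for (r in seq_len(nrow(states))) {
    dup <- FALSE
    for (j in keep) {
      if (sqrt(sum((lg[r, ] - lg[j, ])^2)) < dedup_tol) {
        dup <- TRUE
        break
      }
    }
    if (!dup) keep <- c(keep, r)
  }
  out <- states[keep, , drop = FALSE]
  out[order(out[, 1]), , drop = FALSE]
}

#' Enumerate the distinct stable steady states of one parameter set
#'
#' Relaxes `n_init` random log-uniform initial conditions and deduplicates
#' the converged endpoints on log2-scale Euclidean distance below
#' `dedup_tol`.  If a new distinct state first appears in the last quarter
#' of the initial conditions, one extra batch of `n_init` conditions is run
#' (`adaptive = TRUE`), since late discovery suggests the budget had not
#' saturated.
#'
#' @param params a `kinetic_params` object.
#' @param n_init number of initial conditions (`>= 1`).
#' @param tol,t_max passed to [integrate_to_steady_state()].
#' @param dedup_tol distinct-state threshold in log2 concentration units.
#' @param adaptive double the search once when states keep appearing late.
#' @return An object of class `model_solution`: `states` (matrix, one row
#'   per distinct state, ordered by the first node's level),
#'   `n_states`, `n_nonconverged`, `n_init_used`.
#' @export
enumerate_steady_states <- function(params, n_init = 100, tol = 1e-6,
                                    t_max = 1000, dedup_tol = 0.1,
                                    adaptive = TRUE) {
  stopifnot(n_init >= 1)
  fp <- params_flat(params)
  run_batch <- function(n) {
    ics <- sample_initial_condition(params, n)
    cpp_steady_states(ics, fp$g, fp$k, fp$lambda, fp$n, fp$x0,
                      fp$src, fp$tgt, tol, t_max)
  }
  res <- run_batch(n_init)
  used <- n_init
  conv <- which(res$converged)
  states <- res$states[conv, , drop = FALSE]
  if (adaptive && length(conv) > 0) {
    # index (among converged ICs) at which each distinct state first appeared
    lg <- log2(pmax(states, .Machine$double.eps))
    first <- integer()
    for (r in seq_len(nrow(lg))) {
      new <- TRUE
      for (j in first) {
        if (sqrt(sum((lg[r, ] - lg[j, ])^2)) < dedup_tol) {
          new <- FALSE
          break
        }
      }
      if (new) first <- c(first, r)
    }
    if (length(first) && max(first) > 0.75 * nrow(lg)) {
      res2 <- run_batch(n_init)
      used <- used + n_init
      states <- rbind(states, res2$states[res2$converged, , drop = FALSE])
      conv <- c(conv, which(res2$converged))
    }
  }
  nonconv <- as.integer(used - nrow(states))
  distinct <- dedup_states(states, dedup_tol)
  colnames(distinct) <- params$topology$nodes
  structure(list(states = distinct, n_states = nrow(distinct),
                 n_nonconverged = nonconv, n_init_used = used),
            class = "model_solution")
}

#' Simulate an ensemble of kinetic models
#'
#' Samples `n_sets` kinetic parameter sets for a topology and enumerates
#' the distinct steady states of each.  This is the workhorse behind the
#' multistability census, phenotype scoring and phase tables.
#'
#' @param topology a [network_topology()].
#' @param n_sets number of parameter sets.
#' @param n_init initial conditions per set.
#' @param ranges a [sampling_ranges()].
#' @param pert optional [perturbation()] applied to every sampled set.
#' @param ... passed to [enumerate_steady_states()].
#' @return An object of class `grn_ensemble`: `states` (matrix of all
#'   distinct states, one row each), `set_id` and `state_index` (integer
#'   vectors aligned with rows), `n_states` (per set), `n_nonconverged`
#'   (per set), `topology`, and `params` (list of the sampled sets).
#' @export
simulate_ensemble <- function(topology, n_sets, n_init = 100,
                              ranges = sampling_ranges(), pert = NULL, ...) {
  stopifnot(n_sets >= 1)
  node_medians <- estimate_node_medians(topology, ranges)
  params_list <- vector("list", n_sets)
  sols <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    p <- sample_parameter_set(topology, ranges, node_medians)
    if (!is.null(pert)) p <- apply_perturbation(p, pert)
    params_list[[s]] <- p
    sols[[s]] <- enumerate_steady_states(p, n_init = n_init, ...)
  }
  n_states <- vapply(sols, function(s) s$n_states, 1L)
  states <- do.call(rbind, lapply(sols, function(s) s$states))
  structure(list(
    states = states,
    set_id = rep(seq_len(n_sets), n_states),
    state_index = unlist(lapply(n_states, seq_len), use.names = FALSE),
    n_states = n_states,
    n_nonconverged = vapply(sols, function(s) s$n_nonconverged, 1L),
    topology = topology,
    params = params_list
  ), class = "grn_ensemble")
}

#' @export
print.grn_ensemble <- function(x, ...) {
  cat("grn_ensemble:", length(x$n_states), "parameter sets,",
      nrow(x$states), "steady states\n")
  print(tabulate_multistability(x))
  invisible(x)
}

#' Multistability census of an ensemble
#'
#' Fractions of parameter sets with exactly 1, 2, 3 or 4+ distinct steady
#' states.  Sets in which every initial condition failed to converge are
#' excluded from the denominator and reported separately.
#'
#' @param ensemble a `grn_ensemble` (or integer vector of state counts).
#' @return data.frame with columns `n_states` (`"1"`, `"2"`, `"3"`,
#'   `">=4"`, `"non_converged"`), `count`, `fraction` (fractions over the
#'   converged sets; `NA` for the non-converged row).
#' @export
tabulate_multistability <- function(ensemble) {
  counts <- if (inherits(ensemble, "grn_ensemble")) ensemble$n_states
            else as.integer(ensemble)
  if (!length(counts)) stop("empty ensemble", call. = FALSE)
  empty <- sum(counts == 0)
  counts <- counts[counts > 0]
  bins <- c(sum(counts == 1), sum(counts == 2), sum(counts == 3),
            sum(counts >= 4))
  data.frame(
    n_states = c("1", "2", "3", ">=4", "non_converged"),
    count = c(bins, empty),
    fraction = c(if (sum(bins)) bins / sum(bins) else rep(NA_real_, 4), NA),
    stringsAsFactors = FALSE
  )
}

#' Phase composition of an ensemble
#'
#' A phase is the sorted multiset of phenotype labels co-existing for one
#' parameter set, e.g. `{ES, HR, MR}`.  Returns, per stability class
#' (monostable, bistable, tristable, 4+), the frequency of each phase.
#'
#' @param ensemble a `grn_ensemble`.
#' @param labels character vector of phenotype labels, one per row of
#'   `ensemble$states` (from [classify_phenotype()]).
#' @return data.frame with columns `stability`, `phase`, `count`,
#'   `frequency` (frequencies sum to 1 within each stability class).
#' @export
tabulate_phases <- function(ensemble, labels) {
  stopifnot(inherits(ensemble, "grn_ensemble"))
  if (length(labels) != nrow(ensemble$states) || anyNA(labels)) {
    stop("need one non-missing label per steady state", call. = FALSE)
  }
  phase <- vapply(split(as.character(labels), ensemble$set_id),
                  function(x) paste(sort(x), collapse = ","), "")
  nst <- ensemble$n_states[ensemble$n_states > 0]
  cls <- cut(nst, c(0, 1, 2, 3, Inf),
             labels = c("monostable", "bistable", "tristable", "4+"))
  out <- do.call(rbind, lapply(split(phase, cls), function(p) {
    if (!length(p)) return(NULL)
    tab <- sort(table(p), decreasing = TRUE)
    data.frame(phase = names(tab), count = as.integer(tab),
               frequency = as.numeric(tab) / length(p),
               stringsAsFactors = FALSE)
  }))
  out$stability <- sub("\\..*$", "", rownames(out))
  rownames(out) <- NULL
  out[, c("stability", "phase", "count", "frequency")]
}
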