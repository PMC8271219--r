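#' Simulate a noisy trajectory by Euler-Maruyama
#'
#' Discretizes the regulatory ODEs with time step `dt` and adds, per node
#' and step, a noise increment `eta * sqrt(dt) * N(0, 1)`.  The per-node
#' amplitude `eta` defaults to `noise_scale` times the node's unregulated
#' level `g/k`, so that noise is proportionate to each node's
#' concentration scale.  Negative excursions are clipped at 0.
#'
#' @param params a `kinetic_params` object.
#' @param x0 start concentrations (topology order).
#' @param dt time step.
#' @param t_total total simulated time (`>= dt`).
#' @param noise_scale scalar multiplier on `g/k` for the per-node
#'   amplitude; ignored when `eta` is given.
#' @param eta optional explicit per-node amplitude vector (0 = noise-free).
#' @param record_every record one state every this many steps.
#' @return An object of class `sde_trajectory`: `time` (vector), `x`
#'   (matrix of recorded states, columns = nodes), `dt`, `eta`.
#' @export
euler_maruyama <- function(params, x0, dt = 0.01, t_total = 100,
                           noise_scale = 0.05, eta = NULL,
                           record_every = 10) {
  stopifnot(dt > 0, t_total >= dt, record_every >= 1)
  fp <- params_flat(params)
  if (is.null(eta)) eta <- noise_scale * fp$g / fp$k
  stopifnot(length(eta) == length(fp$g), all(eta >= 0))
  n_steps <- floor(t_total / dt)
  x <- cpp_euler_maruyama(as.numeric(x0), fp$g, fp$k, fp$lambda, fp$n,
                          fp$x0, fp$src, fp$tgt, dt, n_steps,
                          as.numeric(eta), as.integer(record_every))
  colnames(x) <- params$topology$nodes
  structure(list(time = seq(0, by = dt * record_every, length.out = nrow(x)),
                 x = x, dt = dt, eta = eta),
            class = "sde_trajectory")
}

#' Score a trajectory on the EM/resistance plane
#'
#' Applies a fixed normalization (typically the deterministic ensemble's
#' [znormalize()] statistics) to the recorded states and computes EM and
#' resistance scores per time point.
#'
#' @param traj an `sde_trajectory`.
#' @param stats a `znorm_stats` object.
#' @param nodes role mapping passed to [compute_scores()].
#' @return data.frame with columns `time`, `em_score`, `resistance_score`.
#' @export
score_trajectory <- function(traj, stats,
                             nodes = list(zeb1 = "ZEB1", mir200 = "miR200",
                                          era36 = "ERa36", era66 = "ERa66")) {
  stopifnot(inherits(traj, "sde_trajectory"), inherits(stats, "znorm_stats"))
  lg <- log2(pmax(traj$x, .Machine$double.eps))
  z <- sweep(sweep(lg, 2, stats$mean), 2, stats$sd, `/`)
  cbind(time = traj$time, compute_scores(z, nodes = nodes))
}

#' Pseudo-potential landscape over the score plane
#'
#' Bins scored trajectory points on the (EM score, resistance score) plane,
#' normalizes the occupancy to a probability `P`, and sets the
#' pseudo-potential to `-log(P)`.  Empty bins have zero probability and
#' infinite potential; no pseudo-count smoothing is applied.
#'
#' @param scored one data.frame from [score_trajectory()], or a list of
#'   them (e.g. several initial conditions), all scored with the same
#'   normalization.
#' @param bins number of bins per axis.
#' @param xlim,ylim optional axis limits; default to the data range.
#' @return An object of class `score_landscape`: `em_breaks`, `res_breaks`
#'   (bin edges), `em_mid`, `res_mid` (bin centers), `p` (probability
#'   matrix, EM rows x resistance columns), `potential` (`-log(p)`).
#' @export
build_landscape <- function(scored, bins = 60, xlim = NULL, ylim = NULL) {
  if (is.data.frame(scored)) scored <- list(scored)
  em <- unlist(lapply(scored, `[[`, "em_score"), use.names = FALSE)
  rs <- unlist(lapply(scored, `[[`, "resistance_score"), use.names = FALSE)
  if (!length(em)) stop("no scored trajectory points", call. = FALSE)
  pad <- function(r) r + c(-1, 1) * max(diff(r), 1e-6) * 1e-3
  if (is.null(xlim)) xlim <- pad(range(em))
  if (is.null(ylim)) ylim <- pad(range(rs))
  bx <- seq(xlim[1], xlim[2], length.out = bins + 1)
  by <- seq(ylim[1], ylim[2], length.out = bins + 1)
  ix <- findInterval(em, bx, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(rs, by, rightmost.closed = TRUE, all.inside = TRUE)
  p <- matrix(0, bins, bins)
  for (i in seq_along(ix)) p[ix[i], iy[i]] <- p[ix[i], iy[i]] + 1
  p <- p / sum(p)
  structure(list(em_breaks = bx, res_breaks = by,
                 em_mid = (bx[-1] + bx[-length(bx)]) / 2,
                 res_mid = (by[-1] + by[-length(by)]) / 2,
                 p = p, potential = -log(p)),
            class = "score_landscape")
}

#' Local minima of a pseudo-potential landscape
#'
#' A bin is a local minimum when it is occupied and no occupied bin in its
#' 8-neighborhood has a strictly lower potential.  Used to check that
#' landscape valleys co-localize with deterministic attractors.
#'
#' @param landscape a `score_landscape`.
#' @param min_p ignore bins with probability below this mass (stray
#'   single-visit bins would otherwise each count as a minimum).
#' @return data.frame with columns `em`, `res`, `potential`, `row`, `col`.
#' @export
landscape_minima <- function(landscape, min_p = 1e-4) {
  p <- landscape$p
  pot <- landscape$potential
  n <- nrow(p)
  out <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (p[i, j] < min_p) next
      nb <- expand.grid(i + (-1:1), j + (-1:1))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= n & nb[, 2] >= 1 & nb[, 2] <= n, ]
      vals <- pot[as.matrix(nb)]
      if (all(pot[i, j] <= vals + 1e-12)) {
        out <- rbind(out, data.frame(em = landscape$em_mid[i],
                                     res = landscape$res_mid[j],
                                     potential = pot[i, j],
                                     row = i, col = j))
      }
    }
  }
  if (is.null(out)) out <- data.frame(em = numeric(), res = numeric(),
                                      potential = numeric(),
                                      row = integer(), col = integer())
  out[order(out$potential), ]
}

#' Marginal score distribution of a trajectory
#'
#' @param scored data.frame from [score_trajectory()].
#' @param axis `"em"` or `"resistance"`.
#' @param bins number of histogram bins.
#' @return data.frame with columns `mid` (bin centers) and `density`
#'   (integrates to 1 over the binned range).
#' @export
marginal_distribution <- function(scored, axis = c("em", "resistance"),
                                  bins = 60) {
  axis <- match.arg(axis)
  x <- scored[[if (axis == "em") "em_score" else "resistance_score"]]
  h <- graphics::hist(x, breaks = bins, plot = FALSE)
  data.frame(mid = h$mids, density = h$density)
}

#' Detect committed phenotype transitions along a trajectory
#'
#' Labels every recorded time point with [classify_phenotype()] and
#' debounces: a transition is committed only when the new label persists
#' for at least `dwell_min` consecutive recorded steps.  Shorter visits are
#' treated as threshold jitter and ignored.
#'
#' @param scored data.frame from [score_trajectory()].
#' @param thresholds a [fit_thresholds()] result.
#' @param dwell_min minimum dwell (recorded steps) to commit a label.
#' @return data.frame with columns `from`, `to`, `time` (time of the first
#'   step of the committed new label); zero rows if no transitions.
#' @export
detect_transitions <- function(scored, thresholds, dwell_min = 50) {
  stopifnot(dwell_min >= 1)
  labels <- as.character(classify_phenotype(scored, thresholds))
  r <- rle(labels)
  keep <- r$lengths >= dwell_min
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  lab <- r$values[keep]
  st <- starts[keep]
  # collapse consecutive identical committed labels (separated by jitter)
  if (length(lab) > 1) {
    same <- c(FALSE, lab[-1] == lab[-length(lab)])
    lab <- lab[!same]
    st <- st[!same]
  }
  if (length(lab) <= 1) {
    return(data.frame(from = character(), to = character(),
                      time = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(from = lab[-length(lab)], to = lab[-1],
             time = scored$time[st[-1]], stringsAsFactors = FALSE)
}
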