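#' Configuration for the sensitive/resistant population model
#'
#' Agent-based model of a drug-treated cell population.  Every cell
#' carries a sensitive score (drawn from `Normal(mean_s, sd^2)`) and a
#' resistant score (from `Normal(mean_r, sd^2)`), both clamped to
#' `[-6, 6]`, plus a state flag S or R selecting which score currently
#' governs drug survival.  Per step a cell escapes drug-induced death with
#' probability `exp(x) / (exp(x) + c)` of its current state's score `x`,
#' dies basally with probability `basal_death`, may switch state, and
#' divides with the logistic probability
#' `proliferation_rate * (1 - N / carrying_capacity)`.
#'
#' @param proliferation_rate per-step division probability at low density.
#' @param basal_death per-step drug-independent death probability.
#' @param carrying_capacity logistic ceiling (cells).
#' @param sigmoid_c constant `c` of the survival sigmoid.
#' @param mean_s,mean_r centers of the sensitive/resistant score
#'   distributions.
#' @param sd heterogeneity: standard deviation of both score distributions.
#' @param p_sr,p_rs per-step stochastic switch probabilities S to R and R
#'   to S.
#' @param drug_induced_psr extra per-step S-to-R probability applied only
#'   to sensitive cells that survived drug exposure that step.
#' @param met_induced_prs extra per-step R-to-S probability (an
#'   independent draw) modeling an MET-inducing signal.
#' @param initial_size starting cell count.
#' @param initial_resistant_fraction fraction of initial cells placed in
#'   the resistant state.
#' @param drug_on whether drug-induced death (and drug-induced plasticity)
#'   acts.
#' @return An object of class `pop_config`.
#' @export
pop_config <- function(proliferation_rate = 0.91, basal_death = 0.1,
                       carrying_capacity = 1e5, sigmoid_c = 0.6,
                       mean_s = -2, mean_r = 2, sd = 0,
                       p_sr = 0, p_rs = 0,
                       drug_induced_psr = 0, met_induced_prs = 0,
                       initial_size = 100,
                       initial_resistant_fraction = 0,
                       drug_on = TRUE) {
  probs <- c(proliferation_rate = proliferation_rate,
             basal_death = basal_death, p_sr = p_sr, p_rs = p_rs,
             drug_induced_psr = drug_induced_psr,
             met_induced_prs = met_induced_prs,
             initial_resistant_fraction = initial_resistant_fraction)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("probabilities out of [0, 1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  }
  stopifnot(carrying_capacity >= 1, sd >= 0, sigmoid_c > 0,
            initial_size >= 1)
  structure(as.list(environment()), class = "pop_config")
}

#' Per-step probability of escaping drug-induced death
#'
#' The sigmoid `exp(x) / (exp(x) + c)` mapping a resistance score to the
#' probability that the cell survives drug exposure in one step;
#' drug-induced death occurs with the complementary probability
#' `c / (exp(x) + c)`.  Monotone increasing in `x`: strongly resistant
#' cells (large `x`) almost always escape.
#'
#' @param x resistance score(s).
#' @param c sigmoid constant (`> 0`).
#' @return Survival probability in (0, 1).
#' @export
survival_probability <- function(x, c = 0.6) {
  if (any(c <= 0)) stop("c must be positive", call. = FALSE)
  1 / (1 + c * exp(-x))
}

#' Logistic per-step proliferation probability
#'
#' @param current_size population size at the start of the step.
#' @param config a [pop_config()].
#' @return `max(0, rate * (1 - N / K))`; identical for S and R cells.
#' @export
proliferation_probability <- function(current_size, config) {
  stopifnot(current_size >= 0)
  max(0, config$proliferation_rate *
        (1 - current_size / config$carrying_capacity))
}

# Draw clamped scores.  `truncate` forces the sign by rejection sampling
# ("negative" keeps draws < 0, "positive" keeps draws > 0), used only when
# seeding the initial population.
draw_scores <- function(n, mean, sd, truncate = c("none", "negative",
                                                  "positive")) {
  truncate <- match.arg(truncate)
  x <- stats::rnorm(n, mean, sd)
  if (truncate != "none") {
    bad <- if (truncate == "negative") x >= 0 else x <= 0
    for (i in 1:100) {
      if (!any(bad)) break
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
      bad <- if (truncate == "negative") x >= 0 else x <= 0
    }
  }
  pmin(pmax(x, -6), 6)
}

#' Create one daughter cell
#'
#' The daughter inherits the mother's current state (sensitive or
#' resistant) and redraws both scores from the configured Gaussians,
#' clamped to `[-6, 6]`; the mother keeps her own scores.  The vectorized
#' step routine performs the same operation for whole birth cohorts.
#'
#' @param cell list with elements `resistant` (logical), `s_score`,
#'   `r_score` — the mother.
#' @param config a [pop_config()].
#' @return A list of the same shape describing the daughter.
#' @export
birth <- function(cell, config) {
  list(resistant = cell$resistant,
       s_score = draw_scores(1, config$mean_s, config$sd),
       r_score = draw_scores(1, config$mean_r, config$sd))
}

#' Initialize a population of cells
#'
#' Initial sensitive-state cells must actually be sensitive (sensitive
#' score < 0) and initial resistant-state cells resistant (resistant score
#' > 0); draws violating the sign are rejected and resampled.  Scores are
#' clamped to `[-6, 6]`.
#'
#' @param config a [pop_config()].
#' @return An object of class `population`: logical `resistant` plus
#'   numeric `s_score`, `r_score` vectors, one entry per cell.
#' @export
init_population <- function(config) {
  n <- config$initial_size
  n_r <- round(n * config$initial_resistant_fraction)
  resistant <- c(rep(TRUE, n_r), rep(FALSE, n - n_r))
  s_score <- r_score <- numeric(n)
  if (n - n_r > 0) {
    s_score[!resistant] <- draw_scores(n - n_r, config$mean_s, config$sd,
                                       truncate = "negative")
    r_score[!resistant] <- draw_scores(n - n_r, config$mean_r, config$sd)
  }
  if (n_r > 0) {
    s_score[resistant] <- draw_scores(n_r, config$mean_s, config$sd)
    r_score[resistant] <- draw_scores(n_r, config$mean_r, config$sd,
                                      truncate = "positive")
  }
  structure(list(resistant = resistant, s_score = s_score,
                 r_score = r_score), class = "population")
}

#' Advance the population by one step
#'
#' Processes, in order: (1) death — an independent basal draw
#' (`basal_death`) and, with drug on, a drug draw with probability
#' `1 - survival_probability(score of the current state)`; (2)
#' drug-induced plasticity — surviving sensitive cells flip to resistant
#' with `drug_induced_psr` (only with drug on, since it is triggered by
#' surviving exposure); (3) stochastic switching — S to R with `p_sr`, R
#' to S with `p_rs`, plus an independent R-to-S draw with
#' `met_induced_prs`; (4) proliferation — survivors divide with the
#' logistic probability computed from the population size at the start of
#' the step; daughters inherit the mother's state and redraw both scores
#' (clamped, untruncated).
#'
#' @param pop a `population`.
#' @param config a [pop_config()].
#' @return The updated `population` (possibly with zero cells).
#' @export
pop_step <- function(pop, config) {
  n <- length(pop$resistant)
  if (n == 0) return(pop)
  p_div <- proliferation_probability(n, config)
  # (1) death: basal and drug exposure are independent; a single draw
  # against the combined survival probability is distributionally identical
  p_surv <- 1 - config$basal_death
  if (config$drug_on) {
    score <- pop$s_score
    score[pop$resistant] <- pop$r_score[pop$resistant]
    p_surv <- p_surv * survival_probability(score, config$sigmoid_c)
  }
  alive <- stats::runif(n) < p_surv
  resistant <- pop$resistant
  # (2) drug-induced plasticity: S cells that survived drug exposure
  if (config$drug_on && config$drug_induced_psr > 0) {
    flip <- alive & !resistant &
      stats::runif(n) < config$drug_induced_psr
    resistant[flip] <- TRUE
  }
  # (3) stochastic switching, simultaneous on the post-(2) states
  was_r <- resistant
  # stochastic and MET-induced R->S draws are independent; combine them
  p_rs_eff <- 1 - (1 - config$p_rs) * (1 - config$met_induced_prs)
  u <- stats::runif(n)
  to_r <- alive & !was_r & u < config$p_sr
  to_s <- alive & was_r & u < p_rs_eff
  resistant[to_r] <- TRUE
  resistant[to_s] <- FALSE
  # (4) proliferation of survivors
  divide <- alive & stats::runif(n) < p_div
  n_d <- sum(divide)
  keep <- which(alive)
  out <- list(resistant = c(resistant[keep], resistant[divide]),
              s_score = c(pop$s_score[keep],
                          draw_scores(n_d, config$mean_s, config$sd)),
              r_score = c(pop$r_score[keep],
                          draw_scores(n_d, config$mean_r, config$sd)))
  class(out) <- "population"
  out
}

#' Run one population trajectory
#'
#' @param config a [pop_config()].
#' @param horizon number of steps.
#' @param keep_population return the final `population` object too.
#' @return An object of class `pop_trajectory`: data.frame `counts` with
#'   columns `step` (0..horizon), `total`, `sensitive`, `resistant`
#'   (zero-padded after extinction), plus `extinct` (logical) and
#'   optionally `final_population`.
#' @export
run_population <- function(config, horizon = 100, keep_population = FALSE) {
  stopifnot(horizon >= 1)
  pop <- init_population(config)
  total <- sens <- res <- integer(horizon + 1)
  count <- function(p) c(length(p$resistant), sum(!p$resistant),
                         sum(p$resistant))
  x <- count(pop)
  total[1] <- x[1]; sens[1] <- x[2]; res[1] <- x[3]
  for (t in seq_len(horizon)) {
    if (length(pop$resistant) == 0) break  # stays zero-padded
    pop <- pop_step(pop, config)
    x <- count(pop)
    total[t + 1] <- x[1]; sens[t + 1] <- x[2]; res[t + 1] <- x[3]
  }
  out <- list(counts = data.frame(step = 0:horizon, total = total,
                                  sensitive = sens, resistant = res),
              extinct = total[horizon + 1] == 0)
  if (keep_population) out$final_population <- pop
  structure(out, class = "pop_trajectory")
}

#' Estimate the extinction probability
#'
#' Fraction of replicate simulations whose population reaches zero by the
#' horizon, with the binomial standard error
#' `sqrt(p (1 - p) / n_replicates)`.
#'
#' @param config a [pop_config()].
#' @param horizon steps per replicate.
#' @param n_replicates number of replicates (`>= 10`).
#' @return List with `probability`, `se`, `n_replicates`, `horizon`,
#'   `final_sizes` (all replicates) and `surviving_sizes` (final sizes of
#'   the non-extinct replicates).
#' @export
estimate_extinction <- function(config, horizon = 100, n_replicates = 100) {
  stopifnot(n_replicates >= 10)
  finals <- integer(n_replicates)
  for (r in seq_len(n_replicates)) {
    tr <- run_population(config, horizon = horizon)
    finals[r] <- tr$counts$total[horizon + 1]
  }
  p <- mean(finals == 0)
  list(probability = p, se = sqrt(p * (1 - p) / n_replicates),
       n_replicates = n_replicates, horizon = horizon,
       final_sizes = finals, surviving_sizes = finals[finals > 0])
}

#' Sweep the switching-probability plane
#'
#' Mean final population size at the horizon over a grid of `(P_SR, P_RS)`
#' values, averaged over replicates — the survival/extinction phase
#' portrait of the population model.
#'
#' @param config template [pop_config()]; its `p_sr`/`p_rs` are
#'   overwritten per grid cell.
#' @param p_sr_grid,p_rs_grid probability grids in `[0, 1]`.
#' @param horizon steps per run.
#' @param n_replicates replicates per grid cell.
#' @return Matrix of mean final sizes with `p_sr_grid` rows and
#'   `p_rs_grid` columns (dimnames give the grid values).
#' @export
sweep_plane <- function(config, p_sr_grid = seq(0, 1, 0.1),
                        p_rs_grid = seq(0, 1, 0.1), horizon = 100,
                        n_replicates = 5) {
  stopifnot(all(p_sr_grid >= 0 & p_sr_grid <= 1),
            all(p_rs_grid >= 0 & p_rs_grid <= 1))
  out <- matrix(NA_real_, length(p_sr_grid), length(p_rs_grid),
                dimnames = list(p_sr = p_sr_grid, p_rs = p_rs_grid))
  for (i in seq_along(p_sr_grid)) {
    for (j in seq_along(p_rs_grid)) {
      config$p_sr <- p_sr_grid[i]
      config$p_rs <- p_rs_grid[j]
      finals <- vapply(seq_len(n_replicates), function(r) {
        run_population(config, horizon = horizon)$counts$total[horizon + 1]
      }, 1L)
      out[i, j] <- mean(finals)
    }
  }
  out
}
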