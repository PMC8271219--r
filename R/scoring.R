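#' z-normalize a steady-state ensemble
#'
#' Pools all steady states (each state weighted equally, however many
#' states its parameter set has), log2-transforms the concentrations and
#' z-scores each node with the pooled mean and standard deviation.  Zero
#' concentrations are floored at machine epsilon before the log; the count
#' of floored entries is recorded.
#'
#' @param states matrix of linear-scale steady states (rows = states,
#'   columns = nodes) or a `grn_ensemble`.
#' @param stats optional pre-computed `znorm_stats` to apply (e.g. the
#'   control run's statistics when scoring a perturbed ensemble).
#' @return List with `z` (matrix of z-scores) and `stats` (class
#'   `znorm_stats`: per-node `mean`, `sd`, and `n_floored`).
#' @export
znormalize <- function(states, stats = NULL) {
  if (inherits(states, "grn_ensemble")) states <- states$states
  if (!is.matrix(states) || nrow(states) < 2) {
    stop("need a matrix of at least 2 steady states", call. = FALSE)
  }
  n_floored <- sum(states <= 0)
  if (n_floored > 0) {
    warning(n_floored, " non-positive concentration(s) floored at machine ",
            "epsilon before log2")
  }
  lg <- log2(pmax(states, .Machine$double.eps))
  if (is.null(stats)) {
    mu <- colMeans(lg)
    sd <- apply(lg, 2, stats::sd)
    if (any(sd <= 0)) stop("constant node level; cannot z-normalize",
                           call. = FALSE)
    stats <- structure(list(mean = mu, sd = sd, n_floored = n_floored),
                       class = "znorm_stats")
  } else {
    stopifnot(inherits(stats, "znorm_stats"))
  }
  z <- sweep(sweep(lg, 2, stats$mean), 2, stats$sd, `/`)
  list(z = z, stats = stats)
}

#' EM and resistance scores of z-normalized states
#'
#' The epithelial-mesenchymal (EM) score is `z(ZEB1) - z(miR200)`; the
#' tamoxifen-resistance score is `z(ERa36) - z(ERa66)`.  High EM scores
#' mark mesenchymal states, high resistance scores mark states expected to
#' tolerate anti-estrogen drugs.
#'
#' @param z matrix of z-scores with named columns (from [znormalize()]).
#' @param nodes named list mapping the four roles (`zeb1`, `mir200`,
#'   `era36`, `era66`) to column names.
#' @return data.frame with columns `em_score` and `resistance_score`.
#' @export
compute_scores <- function(z,
                           nodes = list(zeb1 = "ZEB1", mir200 = "miR200",
                                        era36 = "ERa36", era66 = "ERa66")) {
  need <- unlist(nodes)
  miss <- setdiff(need, colnames(z))
  if (length(miss)) {
    stop("node(s) missing from the ensemble: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    em_score = z[, nodes$zeb1] - z[, nodes$mir200],
    resistance_score = z[, nodes$era36] - z[, nodes$era66]
  )
}

# Equal-posterior boundary between two adjacent Gaussian components,
# searched between their means.  Falls back to the midpoint if the
# weighted densities do not cross there (can happen with very unequal
# variances).
posterior_cut <- function(w1, m1, s1, w2, m2, s2) {
  f <- function(x) {
    log(w1) + stats::dnorm(x, m1, s1, log = TRUE) -
      log(w2) - stats::dnorm(x, m2, s2, log = TRUE)
  }
  if (f(m1) > 0 && f(m2) < 0) {
    stats::uniroot(f, c(m1, m2), tol = 1e-9)$root
  } else {
    (m1 + m2) / 2
  }
}

#' Fit Gaussian-mixture thresholds for the two score axes
#'
#' EM scores are fit with a 3-component univariate normal mixture
#' (epithelial / hybrid / mesenchymal) and resistance scores with a
#' 2-component mixture (sensitive / resistant), both by EM via
#' \pkg{mclust}.  Cutpoints sit at the equal-posterior boundaries between
#' adjacent components ordered by mean.  A degenerate fit (any component
#' weight below `1e-3`, or a failed fit) falls back to quantile cutpoints
#' with a warning.
#'
#' @param scores data.frame from [compute_scores()] (needs `em_score` and
#'   `resistance_score`, at least 100 rows).
#' @return An object of class `score_thresholds`: `em_cuts` (ordered E|H
#'   and H|M cutpoints), `res_cut` (S|R cutpoint), `em_fit`/`res_fit`
#'   (mixture parameters), `degenerate` (logical flags per axis).
#' @export
fit_thresholds <- function(scores) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 100)
  fit_axis <- function(x, g) {
    # a spreadless axis cannot support a mixture at all
    if (stats::sd(x) < 1e-6 * (1 + abs(mean(x)))) return(NULL)
    fit <- tryCatch(
      mclust::Mclust(x, G = g, modelNames = "V", verbose = FALSE),
      error = function(e) NULL
    )
    if (is.null(fit) || any(fit$parameters$pro < 1e-3)) return(NULL)
    ord <- order(fit$parameters$mean)
    list(pro = fit$parameters$pro[ord],
         mean = fit$parameters$mean[ord],
         sd = sqrt(fit$parameters$variance$sigmasq)[ord])
  }
  em_fit <- fit_axis(scores$em_score, 3)
  res_fit <- fit_axis(scores$resistance_score, 2)
  degenerate <- c(em = is.null(em_fit), res = is.null(res_fit))
  if (is.null(em_fit)) {
    warning("degenerate 3-component fit on EM scores; using tercile cutpoints")
    em_cuts <- unname(stats::quantile(scores$em_score, c(1 / 3, 2 / 3)))
    # tied quantiles (spreadless axis) still need ordered cutpoints
    if (diff(em_cuts) <= 0) em_cuts[2] <- em_cuts[1] + 1e-8
  } else {
    em_cuts <- c(
      posterior_cut(em_fit$pro[1], em_fit$mean[1], em_fit$sd[1],
                    em_fit$pro[2], em_fit$mean[2], em_fit$sd[2]),
      posterior_cut(em_fit$pro[2], em_fit$mean[2], em_fit$sd[2],
                    em_fit$pro[3], em_fit$mean[3], em_fit$sd[3])
    )
  }
  if (is.null(res_fit)) {
    warning("degenerate 2-component fit on resistance scores; using median cutpoint")
    res_cut <- unname(stats::median(scores$resistance_score))
  } else {
    res_cut <- posterior_cut(res_fit$pro[1], res_fit$mean[1], res_fit$sd[1],
                             res_fit$pro[2], res_fit$mean[2], res_fit$sd[2])
  }
  if (diff(em_cuts) <= 0) stop("EM cutpoints are not ordered", call. = FALSE)
  structure(list(em_cuts = em_cuts, res_cut = res_cut,
                 em_fit = em_fit, res_fit = res_fit,
                 degenerate = degenerate),
            class = "score_thresholds")
}

#' @export
print.score_thresholds <- function(x, ...) {
  cat("score_thresholds: E|H =", signif(x$em_cuts[1], 4),
      " H|M =", signif(x$em_cuts[2], 4),
      " S|R =", signif(x$res_cut, 4), "\n")
  invisible(x)
}

#' Classify scored states into the six phenotypes
#'
#' The EM axis is discretized into epithelial (E), hybrid (H) and
#' mesenchymal (M) by the two EM cutpoints, the resistance axis into
#' sensitive (S) and resistant (R) by its cutpoint, giving labels ES, ER,
#' HS, HR, MS, MR.  A score exactly at a cutpoint falls in the lower
#' (less mesenchymal / more sensitive) class.
#'
#' @param scores data.frame from [compute_scores()].
#' @param thresholds a [fit_thresholds()] result.
#' @return Factor of labels with levels ES, ER, HS, HR, MS, MR.
#' @export
classify_phenotype <- function(scores, thresholds) {
  stopifnot(inherits(thresholds, "score_thresholds"))
  em <- ifelse(scores$em_score <= thresholds$em_cuts[1], "E",
        ifelse(scores$em_score <= thresholds$em_cuts[2], "H", "M"))
  rs <- ifelse(scores$resistance_score <= thresholds$res_cut, "S", "R")
  factor(paste0(em, rs), levels = c("ES", "ER", "HS", "HR", "MS", "MR"))
}

#' Spearman association between EM and resistance scores
#'
#' @param scores data.frame from [compute_scores()] with at least 3 rows.
#' @return List with `rho` and `p_value`.
#' @export
correlate_em_resistance <- function(scores) {
  stopifnot(nrow(scores) >= 3)
  if (stats::sd(scores$em_score) == 0 ||
      stats::sd(scores$resistance_score) == 0) {
    stop("constant score vector; correlation undefined", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(scores$em_score, scores$resistance_score,
                    method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

# Score an ensemble end to end with its own normalization; helper shared
# by the randomization control and the workflows.
score_ensemble <- function(ensemble, nodes = NULL) {
  args <- list(znormalize(ensemble)$z)
  if (!is.null(nodes)) args$nodes <- nodes
  do.call(compute_scores, args)
}

#' Randomized-topology control for the EM-resistance association
#'
#' Generates degree- and sign-preserving randomizations of a topology
#' (see [randomize_topology()]), simulates an ensemble for each, scores it
#' with its own normalization, and records the Spearman rho between EM and
#' resistance scores.  The wild-type rho and its percentile within the
#' randomized distribution quantify how specific the association is to the
#' actual wiring.
#'
#' @param topology the wild-type [network_topology()].
#' @param n_random number of randomized networks (0 gives wild type only).
#' @param n_sets,n_init ensemble size per network.
#' @param max_attempts swap attempts per randomization before skipping.
#' @return List with `rho_wildtype`, `rho_random` (numeric vector),
#'   `percentile` (of wild type within the randomized set) and `n_skipped`.
#' @export
randomization_control <- function(topology, n_random = 100, n_sets = 500,
                                  n_init = 50, max_attempts = 1000) {
  run_one <- function(topo) {
    ens <- simulate_ensemble(topo, n_sets = n_sets, n_init = n_init)
    correlate_em_resistance(score_ensemble(ens))$rho
  }
  rho_wt <- run_one(topology)
  rho_random <- numeric()
  skipped <- 0L
  for (i in seq_len(n_random)) {
    rt <- tryCatch(randomize_topology(topology, max_attempts = max_attempts),
                   error = function(e) NULL)
    if (is.null(rt)) {
      skipped <- skipped + 1L
      next
    }
    rho_random <- c(rho_random, run_one(rt))
  }
  pct <- if (length(rho_random)) mean(rho_wt >= rho_random) else NA_real_
  list(rho_wildtype = rho_wt, rho_random = rho_random,
       percentile = pct, n_skipped = skipped)
}

#' Phenotype frequency shifts under a perturbation
#'
#' Runs matched control and perturbed ensembles over `n_reps` replicates.
#' Each replicate samples a fresh control ensemble, fits normalization and
#' thresholds on it, applies the same statistics and thresholds to the
#' perturbed ensemble (so frequency shifts are not confounded by threshold
#' drift), and tabulates the six phenotype frequencies per condition.
#'
#' @param topology a [network_topology()].
#' @param pert a [perturbation()].
#' @param n_sets,n_init ensemble size per replicate.
#' @param n_reps number of replicates (`>= 3` recommended).
#' @return data.frame with columns `phenotype`, `condition`
#'   (control/perturbed), `mean_frequency`, `sd_frequency`, and
#'   `delta_mean` (perturbed minus control, repeated per condition).
#' @export
perturbation_report <- function(topology, pert, n_sets = 500, n_init = 50,
                                n_reps = 3) {
  freq <- function(labels) {
    tab <- table(labels)
    as.numeric(tab) / sum(tab)
  }
  ctrl <- pert_f <- matrix(NA_real_, n_reps, 6)
  for (r in seq_len(n_reps)) {
    ens_c <- simulate_ensemble(topology, n_sets = n_sets, n_init = n_init)
    zc <- znormalize(ens_c)
    sc <- compute_scores(zc$z)
    th <- fit_thresholds(sc)
    ctrl[r, ] <- freq(classify_phenotype(sc, th))
    ens_p <- simulate_ensemble(topology, n_sets = n_sets, n_init = n_init,
                               pert = pert)
    zp <- znormalize(ens_p, stats = zc$stats)
    sp <- compute_scores(zp$z)
    pert_f[r, ] <- freq(classify_phenotype(sp, th))
  }
  lev <- c("ES", "ER", "HS", "HR", "MS", "MR")
  delta <- colMeans(pert_f) - colMeans(ctrl)
  data.frame(
    phenotype = rep(lev, 2),
    condition = rep(c("control", "perturbed"), each = 6),
    mean_frequency = c(colMeans(ctrl), colMeans(pert_f)),
    sd_frequency = c(apply(ctrl, 2, stats::sd), apply(pert_f, 2, stats::sd)),
    delta_mean = rep(delta, 2),
    stringsAsFactors = FALSE
  )
}
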