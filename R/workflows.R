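#' Derive a child seed from a master seed
#'
#' Counter-based fan-out so each pipeline stage is independently
#' reproducible from a single master seed: `child_seed(s, k)` is a fixed
#' deterministic hash of `(s, k)` kept inside the 32-bit integer range.
#'
#' @param master master seed (integer).
#' @param stage stage counter (integer, `>= 0`).
#' @return An integer seed.
#' @export
child_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 48271 + as.numeric(stage) * 16807 +
                12345) %% 2147483647)
}

#' Full ensemble pipeline: simulate, normalize, score, classify, tabulate
#'
#' Runs the deterministic ensemble for a topology, z-normalizes the pooled
#' steady states, computes EM/resistance scores, fits mixture thresholds,
#' classifies the six phenotypes, and builds the multistability and phase
#' tables.  With a perturbation, a control ensemble is run first and its
#' normalization statistics and thresholds are reused for the perturbed
#' ensemble, so frequency shifts are directly comparable.
#'
#' @param topology a [network_topology()]; default the bundled network.
#' @param n_sets,n_init ensemble dimensions.
#' @param seed master seed.
#' @param pert optional [perturbation()].
#' @param out_dir optional directory: writes `states.tsv`, `scores.tsv`,
#'   `params.tsv`, `multistability.tsv`, `phases.tsv` and a
#'   `manifest.json` capturing the configuration.
#' @return List with `ensemble`, `znorm`, `scores`, `thresholds`,
#'   `labels`, `multistability`, `phases`, `correlation` and (with `pert`)
#'   `perturbed` holding the scored perturbed ensemble.
#' @export
run_ensemble_pipeline <- function(topology = default_topology(),
                                  n_sets = 1000, n_init = 100, seed = 1,
                                  pert = NULL, out_dir = NULL) {
  set.seed(child_seed(seed, 0))
  ens <- simulate_ensemble(topology, n_sets = n_sets, n_init = n_init)
  zn <- znormalize(ens)
  scores <- compute_scores(zn$z)
  th <- fit_thresholds(scores)
  labels <- classify_phenotype(scores, th)
  out <- list(
    ensemble = ens, znorm = zn, scores = scores, thresholds = th,
    labels = labels,
    multistability = tabulate_multistability(ens),
    phases = tabulate_phases(ens, labels),
    correlation = correlate_em_resistance(scores)
  )
  if (!is.null(pert)) {
    set.seed(child_seed(seed, 1))
    ens_p <- simulate_ensemble(topology, n_sets = n_sets, n_init = n_init,
                               pert = pert)
    zp <- znormalize(ens_p, stats = zn$stats)
    sp <- compute_scores(zp$z)
    out$perturbed <- list(ensemble = ens_p, scores = sp,
                          labels = classify_phenotype(sp, th))
  }
  if (!is.null(out_dir)) write_ensemble_outputs(out, out_dir, seed)
  out
}

write_ensemble_outputs <- function(res, out_dir, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  ens <- res$ensemble
  states <- data.frame(set_id = ens$set_id, state_index = ens$state_index,
                       log2(pmax(ens$states, .Machine$double.eps)),
                       check.names = FALSE)
  w(states, "states.tsv")
  w(cbind(states[, 1:2], res$scores, label = as.character(res$labels)),
    "scores.tsv")
  params <- do.call(rbind, lapply(seq_along(ens$params), function(i) {
    p <- ens$params[[i]]
    data.frame(set_id = i, t(c(p$g, p$k)),
               t(stats::setNames(p$lambda, paste0("lambda", seq_along(p$lambda)))),
               t(stats::setNames(p$n, paste0("n", seq_along(p$n)))),
               t(stats::setNames(p$x0, paste0("x0_", seq_along(p$x0)))),
               check.names = FALSE)
  }))
  w(params, "params.tsv")
  w(res$multistability, "multistability.tsv")
  w(res$phases, "phases.tsv")
  manifest <- list(
    seed = seed,
    n_sets = length(ens$n_states),
    thresholds = list(em_cuts = res$thresholds$em_cuts,
                      res_cut = res$thresholds$res_cut),
    znorm = list(mean = as.list(res$znorm$stats$mean),
                 sd = as.list(res$znorm$stats$sd)),
    spearman_rho = res$correlation$rho
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Landscape pipeline for one multistable parameter set
#'
#' Simulates noisy trajectories for a chosen parameter set of a previously
#' run ensemble, scores them with the ensemble's normalization, and builds
#' the pseudo-potential landscape plus the committed-transition list.
#'
#' @param pipeline a [run_ensemble_pipeline()] result.
#' @param set_id parameter-set identifier within the ensemble.
#' @param n_traj number of trajectories (initial conditions cycle through
#'   the set's deterministic steady states).
#' @param t_total,dt,noise_scale,record_every passed to
#'   [euler_maruyama()].
#' @param seed master seed.
#' @param dwell_min debounce window for [detect_transitions()].
#' @param out_dir optional directory for `trajectory.tsv` and
#'   `landscape.tsv`.
#' @return List with `scored` (list of scored trajectories), `landscape`,
#'   `transitions`.
#' @export
run_landscape_pipeline <- function(pipeline, set_id, n_traj = 3,
                                   t_total = 2000, dt = 0.01,
                                   noise_scale = 0.05, record_every = 10,
                                   seed = 1, dwell_min = 50,
                                   out_dir = NULL) {
  ens <- pipeline$ensemble
  if (set_id < 1 || set_id > length(ens$params)) {
    stop("unknown set_id: ", set_id, call. = FALSE)
  }
  params <- ens$params[[set_id]]
  states <- ens$states[ens$set_id == set_id, , drop = FALSE]
  if (nrow(states) == 0) stop("set has no converged states", call. = FALSE)
  set.seed(child_seed(seed, 2))
  scored <- lapply(seq_len(n_traj), function(i) {
    x0 <- states[(i - 1) %% nrow(states) + 1, ]
    tr <- euler_maruyama(params, x0, dt = dt, t_total = t_total,
                         noise_scale = noise_scale,
                         record_every = record_every)
    score_trajectory(tr, pipeline$znorm$stats)
  })
  land <- build_landscape(scored)
  trans <- do.call(rbind, lapply(scored, detect_transitions,
                                 thresholds = pipeline$thresholds,
                                 dwell_min = dwell_min))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(do.call(rbind, scored),
                       file.path(out_dir, "trajectory.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    grid <- expand.grid(em = land$em_mid, res = land$res_mid)
    grid$p <- as.vector(land$p)
    grid$potential <- as.vector(land$potential)
    utils::write.table(grid, file.path(out_dir, "landscape.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(scored = scored, landscape = land, transitions = trans)
}

#' Preset population-dynamics experiments
#'
#' Reproducible drivers for the population-model figures: the
#' switching-plane sweeps at two heterogeneity levels
#' (`"plane"`), the heterogeneity series of extinction estimates
#' (`"heterogeneity"`), the pre-existing-resistance series
#' (`"preexisting"`), and the drug-induced-plasticity x MET-induction
#' quadrant of trajectories (`"met"`).
#'
#' @param preset one of `"plane"`, `"heterogeneity"`, `"preexisting"`,
#'   `"met"`.
#' @param seed master seed.
#' @param horizon steps per run.
#' @param n_replicates replicates per condition.
#' @return Preset-specific list of results (sweep matrices, extinction
#'   estimates, or trajectories), each tagged with its configuration.
#' @export
run_popdyn_preset <- function(preset = c("heterogeneity", "preexisting",
                                         "plane", "met"),
                              seed = 1, horizon = 100, n_replicates = 100) {
  preset <- match.arg(preset)
  set.seed(child_seed(seed, 3))
  switch(preset,
    heterogeneity = lapply(c(0.65, 0.70, 0.75), function(s) {
      cfg <- pop_config(sd = s, p_sr = 0.5, p_rs = 1.0)
      c(list(sd = s),
        estimate_extinction(cfg, horizon = horizon,
                            n_replicates = n_replicates))
    }),
    preexisting = lapply(c(0, 0.25, 0.5), function(f) {
      cfg <- pop_config(sd = 0.8, p_sr = 0.2, p_rs = 0.2,
                        initial_resistant_fraction = f)
      c(list(initial_resistant_fraction = f),
        estimate_extinction(cfg, horizon = horizon,
                            n_replicates = n_replicates))
    }),
    plane = lapply(c(0, 1), function(s) {
      list(sd = s,
           final_sizes = sweep_plane(pop_config(sd = s), horizon = horizon,
                                     n_replicates = max(1, n_replicates %/% 20)))
    }),
    met = {
      grid <- expand.grid(drug_induced_psr = c(0, 1),
                          met_induced_prs = c(0, 1))
      lapply(seq_len(nrow(grid)), function(i) {
        cfg <- pop_config(sd = 0, p_sr = 0.2, p_rs = 0,
                          drug_induced_psr = grid$drug_induced_psr[i],
                          met_induced_prs = grid$met_induced_prs[i])
        list(drug_induced_psr = grid$drug_induced_psr[i],
             met_induced_prs = grid$met_induced_prs[i],
             trajectory = run_population(cfg, horizon = horizon)$counts)
      })
    }
  )
}
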