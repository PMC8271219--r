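test_that("survival sigmoid matches its closed form and limits", {
  expect_equal(survival_probability(0, 0.6), 0.625)
  expect_equal(survival_probability(2, 0.6), exp(2) / (exp(2) + 0.6))
  expect_equal(survival_probability(100, 0.6), 1)
  expect_equal(survival_probability(-100, 0.6), 0, tolerance = 1e-12)
  x <- seq(-6, 6, 0.1)
  expect_true(all(diff(survival_probability(x, 0.6)) > 0))
  expect_error(survival_probability(0, -1), "positive")
})

test_that("logistic proliferation probability follows the recursion term", {
  cfg <- pop_config()
  expect_equal(proliferation_probability(0, cfg), 0.91)
  expect_equal(proliferation_probability(5e4, cfg), 0.455)
  expect_equal(proliferation_probability(1e5, cfg), 0)
  expect_equal(proliferation_probability(2e5, cfg), 0)
})

test_that("config validation rejects out-of-range probabilities", {
  expect_error(pop_config(p_sr = 1.2), "p_sr")
  expect_error(pop_config(basal_death = -0.1), "basal_death")
  expect_error(pop_config(sd = -1))
})

test_that("initial scores are truncated, clamped and centered correctly", {
  set.seed(130)
  cfg <- pop_config(sd = 0.5, initial_size = 5000,
                    initial_resistant_fraction = 0.3)
  pop <- init_population(cfg)
  expect_equal(sum(pop$resistant), 1500)
  expect_true(all(pop$s_score[!pop$resistant] < 0))
  expect_true(all(pop$r_score[pop$resistant] > 0))
  expect_true(all(abs(pop$s_score) <= 6) && all(abs(pop$r_score) <= 6))
  expect_equal(mean(pop$s_score), -2, tolerance = 0.05)
  expect_equal(mean(pop$r_score), 2, tolerance = 0.05)
  # zero heterogeneity pins the scores exactly
  p0 <- init_population(pop_config(sd = 0, initial_size = 50))
  expect_true(all(p0$s_score == -2) && all(p0$r_score == 2))
})

test_that("birth yields state-inheriting daughters with fresh scores", {
  mother <- list(resistant = TRUE, s_score = -5.5, r_score = 5.5)
  cfg0 <- pop_config(sd = 0)
  d <- birth(mother, cfg0)
  expect_true(d$resistant)
  expect_equal(d$s_score, -2)
  expect_equal(d$r_score, 2)
  set.seed(135)
  cfg <- pop_config(sd = 0.5)
  ds <- replicate(10000, birth(mother, cfg)$s_score)
  expect_equal(sd(ds), 0.5, tolerance = 0.03)
  expect_equal(mean(ds), -2, tolerance = 0.02)
  expect_true(all(abs(ds) <= 6))
})

test_that("daughters inherit state and redraw scores at the set spread", {
  set.seed(140)
  # all-resistant, immortal, always dividing: doubles each step
  cfg <- pop_config(sd = 0.5, basal_death = 0, drug_on = FALSE,
                    proliferation_rate = 1, initial_size = 2000,
                    carrying_capacity = 1e9,
                    initial_resistant_fraction = 1)
  pop <- init_population(cfg)
  pop2 <- pop_step(pop, cfg)
  expect_equal(length(pop2$resistant), 4000)
  expect_true(all(pop2$resistant))
  daughters <- pop2$r_score[2001:4000]
  expect_equal(mean(daughters), 2, tolerance = 0.05)
  expect_equal(sd(daughters), 0.5, tolerance = 0.05)
})

test_that("a step with all-zero probabilities only adds births", {
  set.seed(145)
  cfg <- pop_config(sd = 0, basal_death = 0, drug_on = FALSE,
                    proliferation_rate = 0.5, initial_size = 1000)
  pop2 <- pop_step(init_population(cfg), cfg)
  n <- length(pop2$resistant)
  expect_gte(n, 1000)                      # nobody dies
  expect_equal(n - 1000, 500, tolerance = 60)  # binomial births
  expect_true(all(!pop2$resistant))        # no switching
})

test_that("homogeneous sensitive cells under drug decline to extinction", {
  set.seed(150)
  cfg <- pop_config(sd = 0, p_sr = 0, p_rs = 0)
  tr <- run_population(cfg, horizon = 100)
  expect_true(tr$extinct)
  # rapid overall decline: gone within a handful of steps
  tot <- tr$counts$total
  expect_equal(tot[length(tot)], 0)
  expect_lt(tot[6], 0.1 * tot[1])
  # trailing zeros after extinction, length horizon + 1
  expect_equal(nrow(tr$counts), 101)
})

test_that("certain S-to-R switching rescues the population under drug", {
  set.seed(155)
  cfg <- pop_config(sd = 0, p_sr = 1, p_rs = 0)
  tr <- run_population(cfg, horizon = 100)
  expect_false(tr$extinct)
  expect_gt(tr$counts$total[101], cfg$initial_size)
  # and the survivors sit in the resistant state
  expect_gt(tr$counts$resistant[101], 0.9 * tr$counts$total[101])
})

test_that("trajectories are seed-reproducible", {
  cfg <- pop_config(sd = 0.5, p_sr = 0.3, p_rs = 0.3)
  set.seed(160); a <- run_population(cfg, horizon = 40)
  set.seed(160); b <- run_population(cfg, horizon = 40)
  expect_identical(a$counts, b$counts)
})

test_that("population stays within one birth cohort of carrying capacity", {
  set.seed(165)
  cfg <- pop_config(sd = 0, drug_on = FALSE, basal_death = 0,
                    carrying_capacity = 500, initial_size = 490)
  pop <- init_population(cfg)
  for (t in 1:30) {
    n_before <- length(pop$resistant)
    pop <- pop_step(pop, cfg)
    expect_lte(length(pop$resistant), 500 + n_before)
  }
  expect_lte(length(pop$resistant), 2 * 500)
})

test_that("drug-off dynamics track the deterministic logistic recursion", {
  set.seed(170)
  cfg <- pop_config(sd = 0, drug_on = FALSE, carrying_capacity = 5000,
                    initial_size = 100)
  n_rep <- 50
  horizon <- 60
  runs <- replicate(n_rep, run_population(cfg, horizon)$counts$total)
  meanfield <- numeric(horizon + 1)
  meanfield[1] <- 100
  for (t in 1:horizon) {
    n <- meanfield[t]
    meanfield[t + 1] <- n * (1 - 0.1) * (1 + 0.91 * (1 - n / 5000))
  }
  emp <- rowMeans(runs)
  mc_se <- apply(runs, 1, sd) / sqrt(n_rep)
  ok <- abs(emp - meanfield) <= 3 * pmax(mc_se, 1e-8) + 0.02 * meanfield
  expect_gt(mean(ok), 0.95)
  # saturation close to the recursion's fixed point, not the raw capacity
  nstar <- 5000 * (1 - 0.1 / (0.9 * 0.91))
  expect_equal(mean(emp[(horizon - 9):(horizon + 1)]), nstar,
               tolerance = 0.05)
})

test_that("extinction probability responds monotonically to switching", {
  set.seed(175)
  cfg <- function(psr, prs) pop_config(sd = 0.5, p_sr = psr, p_rs = prs,
                                       initial_size = 50)
  ext <- function(psr, prs) {
    estimate_extinction(cfg(psr, prs), horizon = 40,
                        n_replicates = 40)$probability
  }
  # more S->R switching cannot hurt survival
  e_low <- ext(0.05, 0.5)
  e_high <- ext(0.8, 0.5)
  expect_gte(e_low + 0.1, e_high)
  expect_gt(e_low, e_high - 1e-9)
  # more R->S switching cannot help survival
  e_prs_low <- ext(0.3, 0.05)
  e_prs_high <- ext(0.3, 0.95)
  expect_lte(e_prs_low, e_prs_high + 0.1)
  binom <- estimate_extinction(cfg(0, 0), horizon = 60, n_replicates = 20)
  expect_equal(binom$probability, 1)
  expect_equal(binom$se, 0)
})

test_that("MET induction never grows the final population", {
  set.seed(180)
  for (psr in c(0.2, 0.6)) {
    cfg0 <- pop_config(sd = 0, p_sr = psr, p_rs = 0.1,
                       drug_induced_psr = 0, met_induced_prs = 0)
    cfg1 <- pop_config(sd = 0, p_sr = psr, p_rs = 0.1,
                       drug_induced_psr = 0, met_induced_prs = 1)
    f0 <- mean(replicate(10, run_population(cfg0, 60)$counts$total[61]))
    f1 <- mean(replicate(10, run_population(cfg1, 60)$counts$total[61]))
    expect_lte(f1, f0 + 1)
  }
})

test_that("the switching-plane sweep matches single runs at its corners", {
  set.seed(185)
  cfg <- pop_config(sd = 0, initial_size = 50)
  m <- sweep_plane(cfg, p_sr_grid = c(0, 1), p_rs_grid = c(0, 1),
                   horizon = 50, n_replicates = 3)
  expect_equal(dim(m), c(2, 2))
  expect_equal(m["0", "0"], 0)   # no switching, drug on: extinct
  expect_equal(m["0", "1"], 0)   # P_SR = 0: extinct regardless of P_RS
  expect_gt(m["1", "0"], 1000)   # P_SR >> P_RS: colony
})
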