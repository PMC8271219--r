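test_that("shifted Hill function matches its defining limits and values", {
  # no regulator and neutral edge
  expect_equal(shifted_hill(0, 50, 4, 0.1), 1)
  expect_equal(shifted_hill(c(0, 3, 90), 50, 4, 1), c(1, 1, 1))
  # at the threshold the multiplier is halfway between 1 and lambda
  expect_equal(shifted_hill(50, 50, 1, 0.01), 0.505)
  expect_equal(shifted_hill(7, 7, 3, 30), 15.5)
  # saturation approaches lambda
  expect_equal(shifted_hill(1e9, 10, 2, 0.2), 0.2, tolerance = 1e-6)
  expect_error(shifted_hill(1, -1, 2, 2), "x0")
  expect_error(shifted_hill(1, 1, 1.5, 2), "integer")
})

test_that("shifted Hill is bounded and monotone in the regulator", {
  x <- seq(0, 500, length.out = 400)
  for (lambda in c(0.01, 0.3, 1, 4, 80)) {
    h <- shifted_hill(x, 37, 3, lambda)
    expect_true(all(h >= min(1, lambda) - 1e-12))
    expect_true(all(h <= max(1, lambda) + 1e-12))
    d <- diff(h)
    if (lambda < 1) expect_true(all(d <= 1e-12))
    if (lambda > 1) expect_true(all(d >= -1e-12))
  }
})

test_that("parameter sampling respects ranges, types and the seed", {
  topo <- default_topology()
  rg <- sampling_ranges()
  set.seed(101)
  med <- estimate_node_medians(topo, rg)
  draws <- replicate(200, sample_parameter_set(topo, rg, med),
                     simplify = FALSE)
  g <- unlist(lapply(draws, `[[`, "g"))
  k <- unlist(lapply(draws, `[[`, "k"))
  n <- unlist(lapply(draws, `[[`, "n"))
  lam <- do.call(rbind, lapply(draws, `[[`, "lambda"))
  act <- topo$edges$sign == "activation"
  expect_true(all(g >= 1 & g <= 100))
  expect_true(all(k >= 0.1 & k <= 1))
  expect_true(all(n %in% 1:6))
  expect_true(all(lam[, act] >= 1 & lam[, act] <= 100))
  expect_true(all(lam[, !act] >= 0.01 & lam[, !act] <= 1))
  x0 <- do.call(rbind, lapply(draws, `[[`, "x0"))
  m_src <- med[topo$edges$source]
  for (e in seq_len(ncol(x0))) {
    expect_true(all(x0[, e] >= 0.02 * m_src[e] & x0[, e] <= 1.98 * m_src[e]))
  }
  # determinism
  set.seed(77)
  a <- sample_parameter_set(topo, rg, med)
  set.seed(77)
  b <- sample_parameter_set(topo, rg, med)
  expect_identical(a, b)
  # degenerate n range pins the Hill coefficient
  rg2 <- sampling_ranges(n_range = c(2, 2))
  set.seed(1)
  expect_true(all(sample_parameter_set(topo, rg2, med)$n == 2))
})

test_that("regulated medians sit below g/k for repressed genes", {
  set.seed(5)
  med <- estimate_node_medians(default_topology(), sampling_ranges())
  m0 <- sampling_ranges()$median_level
  # miR200 carries two incoming inhibitions; ZEB1 two activations
  expect_lt(med[["miR200"]], m0 / 3)
  expect_gt(med[["ZEB1"]], m0 * 3)
})

test_that("perturbations scale only the targeted production rate", {
  topo <- default_topology()
  set.seed(3)
  p <- sample_parameter_set(topo)
  p$g["ZEB1"] <- 10
  oe <- apply_perturbation(p, perturbation("ZEB1", "over_expression", 10))
  de <- apply_perturbation(p, perturbation("ZEB1", "down_expression", 10))
  expect_equal(unname(oe$g["ZEB1"]), 100)
  expect_equal(unname(de$g["ZEB1"]), 1)
  expect_equal(oe$g[names(oe$g) != "ZEB1"], p$g[names(p$g) != "ZEB1"])
  expect_identical(oe[c("k", "lambda", "n", "x0")],
                   p[c("k", "lambda", "n", "x0")])
  expect_error(apply_perturbation(p, perturbation("NOPE", "over_expression")),
               "unknown node")
  expect_error(perturbation("ZEB1", fold = 0.5), "fold")
})

test_that("ode_rhs matches closed forms and the compiled core", {
  iso <- fix_isolated(g = 10, k = 1)
  expect_equal(unname(ode_rhs(c(A = 10), iso)), 0)
  expect_equal(unname(ode_rhs(c(A = 0), iso)), 10)
  # R and C++ right-hand sides agree on a full network
  topo <- default_topology()
  set.seed(4)
  p <- sample_parameter_set(topo)
  for (i in 1:20) {
    x <- runif(5, 0, 200)
    fp <- emtamr:::params_flat(p)
    dx_cpp <- emtamr:::cpp_ode_rhs(x, fp$g, fp$k, fp$lambda, fp$n, fp$x0,
                                   fp$src, fp$tgt)
    expect_equal(unname(ode_rhs(x, p)), as.numeric(dx_cpp),
                 tolerance = 1e-12)
  }
  expect_error(ode_rhs(c(1, 2), p), "match")
  expect_error(ode_rhs(c(-1, 1, 1, 1, 1), p), "non-negative")
})

test_that("toggle roots found independently are zeros of the rhs", {
  fx <- make_toggle_fixture()
  roots <- oracle_roots_2node(fx$params)
  expect_gte(nrow(roots), 2)
  for (i in seq_len(nrow(roots))) {
    expect_lt(max(abs(ode_rhs(roots[i, ], fx$params))), 1e-6)
  }
})
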