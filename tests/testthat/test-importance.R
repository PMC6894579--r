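test_that("level 0 is the model conditional and nodes without data keep it", {
  m <- two_bern_model()
  id0 <- make_id0(m)
  expect_equal(id0$level, 0L)
  th <- c(dummy = 0.5)
  for (e in 1:2)
    expect_identical(id0$nodes[[e]]$params_fn(c(1, 0), th),
                     m$nodes[[e]]$params_fn(c(1, 0), th))
  # a node with no attached observation keeps its level-0 ID at level 1
  id1 <- make_id1(m)
  expect_identical(id1$nodes[[1]]$params_fn(c(1, 0), th),
                   id0$nodes[[1]]$params_fn(c(1, 0), th))
})

test_that("diagnostic level-1 ID equals the exact per-individual posterior", {
  scn <- diagnostic_scenario(P = 4)
  dat <- data.frame(individual = 1:4, y1 = c(1, 1, 0, 0), y2 = c(1, 0, 1, 0))
  bm <- build_diagnostic(scn, dat)
  ids <- bm$ids
  th <- c(p_D = 0.35, Se1 = 0.8, Se2 = 0.7, Sp1 = 0.9, Sp2 = 0.85)
  for (e in 1:4) {
    # brute-force two-point Bayes normalization
    l1 <- th[["Se1"]]^dat$y1[e] * (1 - th[["Se1"]])^(1 - dat$y1[e]) *
          th[["Se2"]]^dat$y2[e] * (1 - th[["Se2"]])^(1 - dat$y2[e])
    l0 <- (1 - th[["Sp1"]])^dat$y1[e] * th[["Sp1"]]^(1 - dat$y1[e]) *
          (1 - th[["Sp2"]])^dat$y2[e] * th[["Sp2"]]^(1 - dat$y2[e])
    zexp <- th[["p_D"]] * l1 / (th[["p_D"]] * l1 + (1 - th[["p_D"]]) * l0)
    z <- ids$nodes[[e]]$params_fn(rep(0, 4), th)$prob
    expect_equal(z, zexp, tolerance = 1e-12)
  }
  # perfect tests pin the latent state exactly
  bmp <- build_diagnostic(diagnostic_scenario(P = 2, Se = c(1, 1), Sp = c(1, 1)),
                          data.frame(individual = 1:2, y1 = c(1, 0), y2 = c(1, 0)))
  thp <- c(p_D = 0.5, Se1 = 1, Se2 = 1, Sp1 = 1, Sp2 = 1)
  expect_equal(bmp$ids$nodes[[1]]$params_fn(c(0, 0), thp)$prob, 1)
  expect_equal(bmp$ids$nodes[[2]]$params_fn(c(0, 0), thp)$prob, 0)
})

test_that("generic Bernoulli level-1 construction matches the analytic rule", {
  scn <- diagnostic_scenario(P = 3)
  bm <- build_diagnostic(scn, tiny_diag_data)
  mg <- bm$model; mg$fast <- NULL
  idg <- make_id1(mg)   # generic route: evaluates the observation terms at 0/1
  th <- c(p_D = 0.42, Se1 = 0.75, Se2 = 0.66, Sp1 = 0.88, Sp2 = 0.93)
  for (e in 1:3)
    expect_equal(idg$nodes[[e]]$params_fn(rep(0, 3), th)$prob,
                 bm$ids$nodes[[e]]$params_fn(rep(0, 3), th)$prob,
                 tolerance = 1e-10)
})

test_that("volatility level-1 ID matches fine-grid normalization of the product", {
  scn <- svt_scenario(E = 5, sigma2 = 0.0121, phi = 0.99, nu = 12, mu = -10)
  sim <- simulate_scenario(scn, seed = 31)
  bm <- build_svt(scn, sim$data)
  th <- c(mu = -10, phi = 0.99, nu = 12, sigma2 = 0.0121)
  xi <- sim$latent
  for (e in 2:5) {
    idp <- bm$ids$nodes[[e]]$params_fn(xi, th)
    # oracle: normalize prior x observation term on a dense grid
    m0 <- th[["mu"]] + th[["phi"]] * (xi[e - 1] - th[["mu"]])
    v0 <- th[["sigma2"]]
    g <- seq(m0 - 8 * sqrt(v0) - 1, m0 + 8 * sqrt(v0) + 1, length.out = 20001)
    lw <- stats::dnorm(g, m0, sqrt(v0), log = TRUE) +
      stats::dt(sim$data$y[e] * exp(-g / 2), th[["nu"]], log = TRUE) - g / 2
    w <- exp(lw - max(lw)); w <- w / sum(w)
    mean_true <- sum(g * w)
    var_true <- sum((g - mean_true)^2 * w)
    # the ID is an approximation: close but not exact
    expect_lt(abs(idp$mean - mean_true), 0.2 * sqrt(var_true))
    expect_lt(abs(idp$var / var_true - 1), 0.2)
  }
})

test_that("mixed-model level-2 ID matches quadrature on a three-node pedigree", {
  ped <- data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2),
                    generation = c(0, 0, 1))
  scn <- mixed_scenario(generations = 2, n_per_gen = 2)
  dat <- data.frame(individual = 1:3, x2 = c(0, 1, 0),
                    record = c(10.4, 12.1, 11.0))
  bm <- build_mixed(scn, ped, dat)
  th <- c(beta1 = 10, beta2 = 2, sigma_a2 = 0.6, sigma_e2 = 0.4)
  xi <- c(0.3, -0.2, 0.1)
  # node 2 (founder whose mate, node 1, precedes it): ID2 folds its own
  # record and child 3's record with child 3's breeding value integrated out
  idp <- make_id2(bm$model)$nodes[[2]]$params_fn(xi, th)
  r <- dat$record - th[["beta1"]] - th[["beta2"]] * dat$x2
  g <- seq(-6, 6, length.out = 40001)
  lw <- stats::dnorm(g, 0, sqrt(th[["sigma_a2"]]), log = TRUE) +
    stats::dnorm(r[2], g, sqrt(th[["sigma_e2"]]), log = TRUE) +
    stats::dnorm(r[3], (g + xi[1]) / 2,
                 sqrt(th[["sigma_a2"]] / 2 + th[["sigma_e2"]]), log = TRUE)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  mean_true <- sum(g * w)
  var_true <- sum((g - mean_true)^2 * w)
  expect_equal(idp$mean, mean_true, tolerance = 1e-6)
  expect_equal(idp$var, var_true, tolerance = 1e-4)
  # node without children: level 2 equals level 1
  id1 <- make_id1(bm$model)$nodes[[3]]$params_fn(xi, th)
  id2 <- make_id2(bm$model)$nodes[[3]]$params_fn(xi, th)
  expect_equal(id1, id2)
})

test_that("unsupported level requests fail informatively", {
  scn <- logistic_scenario(T = 5, M = 2)
  sim <- simulate_scenario(scn, seed = 32)
  bm <- build_logistic(scn, sim$data)
  mg <- bm$model; mg$fast <- NULL
  expect_error(make_id1(mg), "poisson")
  expect_error(make_id2(mg), "level-2")
})
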