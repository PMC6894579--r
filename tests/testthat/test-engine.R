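test_that("joint parameter proposal has the requested covariance", {
  set.seed(41)
  S <- matrix(c(2, 0.8, 0.8, 1), 2)
  ch <- chol(S)
  j <- 0.7
  th <- c(a = 1, b = -2)
  draws <- t(replicate(2e4, propose_theta(th, ch, j)))
  emp <- stats::cov(draws)
  expect_true(all(abs(emp - j^2 * S) < 0.05))
  expect_equal(colMeans(draws), th, tolerance = 0.05)
  set.seed(42); p1 <- propose_theta(th, ch, j)
  set.seed(42); p2 <- propose_theta(th, ch, j)
  expect_identical(p1, p2)
})

test_that("identical parameters regenerate the identical latent state", {
  set.seed(43)
  scn <- svt_scenario(E = 30)
  sim <- simulate_scenario(scn, seed = 44)
  bm <- build_svt(scn, sim$data)
  th <- c(mu = -10, phi = 0.95, nu = 12, sigma2 = 0.02)
  rg <- pbpmcmc:::.regen_latent(bm$model, bm$ids, th, th, sim$latent, 0.03)
  expect_equal(rg$xi_p, sim$latent, tolerance = 1e-12)
  expect_equal(rg$fid_i, rg$fid_p, tolerance = 1e-9)
})

test_that("with no data and a flat prior every in-support proposal is accepted", {
  m <- pbp_model(
    list(pbp_param("a", 0, 1, init = 0.5)),
    list(pbp_node("normal", integer(),
                  function(xi, theta) list(mean = theta[["a"]], var = 1))))
  ids <- make_id0(m)
  set.seed(45)
  st <- chain_state(m, c(a = 0.5), 0.2)
  ch <- chol(matrix(0.01, 1, 1))
  for (k in 1:50) {
    u <- pbp_update(m, ids, st, ch, 1, detail = TRUE)
    d <- attr(u, "detail")
    if (is.finite(d$log_alpha)) {
      expect_equal(d$log_alpha, 0, tolerance = 1e-10)
      expect_true(u$accepted)
    }
    st <- u$state
  }
})

test_that("level-0 acceptance reduces to the observation-prior ratio", {
  set.seed(46)
  scn <- diagnostic_scenario(P = 50)
  sim <- simulate_scenario(scn, seed = 47)
  bm <- build_diagnostic(scn, sim$data)
  ids <- make_id0(bm$model)
  th <- c(p_D = 0.5, Se1 = 0.7, Se2 = 0.7, Sp1 = 0.8, Sp2 = 0.8)
  st <- chain_state(bm$model, th, sim$latent)
  ch <- chol(diag(0.003, 5))
  for (k in 1:200) {
    u <- pbp_update(bm$model, ids, st, ch, 1, detail = TRUE)
    d <- attr(u, "detail")
    if (is.finite(d$log_alpha))
      expect_equal(d$log_alpha, d$log_alpha_mbp, tolerance = 1e-9)
    st <- u$state
  }
})

test_that("equal seeds give identical traces, different seeds different ones", {
  scn <- diagnostic_scenario(P = 15)
  sim <- simulate_scenario(scn, seed = 48)
  bm <- build_diagnostic(scn, sim$data)
  cfg <- engine_config(updates = 300, burnin = 100, seed = 49)
  t1 <- run_chain(bm$model, bm$ids, cfg)
  t2 <- run_chain(bm$model, bm$ids, cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  tr3 <- run_chain(bm$model, bm$ids, engine_config(updates = 300, burnin = 100, seed = 50))
  expect_false(identical(t1$p_D, tr3$p_D))
})

test_that("PBP and baseline samplers agree on a small enumerable posterior", {
  scn <- diagnostic_scenario(P = 3)
  bm <- build_diagnostic(scn, tiny_diag_data)
  oracle <- enum_diag_posterior(tiny_diag_data$y1, tiny_diag_data$y2)
  cfg1 <- engine_config(updates = 4e4, burnin = 4e3, seed = 51, store_latent = TRUE)
  cfg2 <- engine_config(updates = 4e4, burnin = 4e3, seed = 52, store_latent = TRUE)
  tv <- function(tr) 0.5 * sum(abs(latent_config_freq(tr, 8) - oracle$prob))
  expect_lt(tv(run_chain(bm$model, bm$ids, cfg1)), 0.02)
  expect_lt(tv(run_chain(bm$model, NULL, cfg2)), 0.02)
})

test_that("adaptation recovers the posterior covariance on a Gaussian toy", {
  # two-parameter Gaussian posterior: y ~ N(a + b, 1), z ~ N(a - b, 1)
  set.seed(53)
  n <- 50
  yv <- stats::rnorm(n, 1.5, 1); zv <- stats::rnorm(n, -0.5, 1)
  m <- pbp_model(
    list(pbp_param("a", -Inf, Inf, init = 0),
         pbp_param("b", -Inf, Inf, init = 0)),
    list(pbp_node("normal", integer(),
                  function(xi, theta) list(mean = 0, var = 1))),
    list(pbp_obs(yv, function(value, xi, theta)
           sum(stats::dnorm(value, theta[["a"]] + theta[["b"]], 1, log = TRUE)),
           depends = integer()),
         pbp_obs(zv, function(value, xi, theta)
           sum(stats::dnorm(value, theta[["a"]] - theta[["b"]], 1, log = TRUE)),
           depends = integer())))
  tr <- run_chain(m, make_id0(m),
                  engine_config(updates = 4000, burnin = 6000, seed = 54))
  # true posterior covariance of (a, b) is diag(1/(2n), 1/(2n))
  S <- attr(tr, "Sigma")
  expect_lt(abs(S[1, 1] * 2 * n - 1), 0.4)
  expect_lt(abs(S[2, 2] * 2 * n - 1), 0.4)
  expect_lt(abs(S[1, 2]) * 2 * n, 0.3)
  # sampling-phase acceptance lands near the configured target
  expect_gt(attr(tr, "accept")$pbp_rate, 0.13)
  expect_lt(attr(tr, "accept")$pbp_rate, 0.53)
})

test_that("stationary transitions between latent configurations are symmetric", {
  # empirical detailed-balance check: the joint PBP update is a single
  # reversible kernel, so stationary transition counts between latent
  # configurations must be symmetric up to Monte Carlo noise
  scn <- diagnostic_scenario(P = 2)
  bm <- build_diagnostic(scn, data.frame(individual = 1:2, y1 = c(1, 0), y2 = c(1, 0)))
  set.seed(55)
  th <- c(p_D = 0.5, Se1 = 0.7, Se2 = 0.7, Sp1 = 0.8, Sp2 = 0.8)
  # start from a draw of the exact latent conditional so the chain is
  # stationary from the first update
  burn <- run_chain(bm$model, bm$ids,
                    engine_config(updates = 1000, burnin = 2000, seed = 155))
  st <- attr(burn, "final_state")
  ch <- chol(attr(burn, "Sigma"))
  jj <- attr(burn, "j")
  n <- 3e4
  idx <- integer(n)
  for (k in seq_len(n)) {
    st <- pbp_update(bm$model, bm$ids, st, ch, jj)$state
    idx[k] <- 1 + st$xi[1] + 2 * st$xi[2]
  }
  trans <- table(factor(idx[-n], levels = 1:4), factor(idx[-1], levels = 1:4))
  for (a in 1:3) for (b in (a + 1):4) {
    nab <- trans[a, b]; nba <- trans[b, a]
    if (nab + nba > 20)
      expect_lt(abs(nab - nba), 3 * sqrt(nab + nba))
  }
})

test_that("infeasible initialization fails with guidance", {
  scn <- diagnostic_scenario(P = 2)
  bm <- build_diagnostic(scn, data.frame(individual = 1:2, y1 = c(1, 0), y2 = c(1, 0)))
  expect_error(
    run_chain(bm$model, bm$ids,
              engine_config(updates = 10, burnin = 10, seed = 56),
              init = list(theta = c(p_D = 2, Se1 = 0.7, Se2 = 0.7,
                                    Sp1 = 0.8, Sp2 = 0.8))),
    "prior")
})
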