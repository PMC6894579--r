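test_that("latent likelihood matches hand computation on small models", {
  m1 <- pbp_model(list(pbp_param("z", 0, 1, init = 0.5)),
                  list(pbp_node("poisson", integer(),
                                function(xi, theta) list(lambda = 2))))
  expect_equal(latent_loglik(m1, c(z = 0.5), 0), -2)

  m2 <- two_bern_model(z1 = 0.3, za = 0.2, zb = 0.7)
  th <- c(dummy = 0.5)
  expect_equal(latent_loglik(m2, th, c(1, 0)), log(0.3) + log(1 - 0.7))
  expect_equal(latent_loglik(m2, th, c(0, 1)), log(0.7) + log(0.2))
  expect_error(latent_loglik(m2, th, c(1, 0, 1)), "length")
})

test_that("observation likelihood matches hand computation", {
  # no observation terms
  m <- two_bern_model()
  expect_equal(obs_loglik(m, c(dummy = 0.5), c(1, 0)), 0)
  # diagnostic individual with D = 1, tests (1, 0), Se = 0.6
  scn <- diagnostic_scenario(P = 1, Se = c(0.6, 0.6), Sp = c(0.9, 0.9))
  bm <- build_diagnostic(scn, data.frame(individual = 1, y1 = 1, y2 = 0))
  mg <- bm$model; mg$fast <- NULL
  th <- c(p_D = 0.5, Se1 = 0.6, Se2 = 0.6, Sp1 = 0.9, Sp2 = 0.9)
  expect_equal(obs_loglik(mg, th, 1), log(0.6 * 0.4))
  expect_equal(obs_loglik(bm$model, th, 1), log(0.6 * 0.4))
  # binomial trap count y = 3 out of P_t = 10 at p = 0.5
  scn <- logistic_scenario(T = 3, M = 1, P0 = 10)
  bm <- build_logistic(scn, data.frame(time = 1, count = 3))
  th <- c(r_b = 0.6, mu_d = 0.3, K = 100, p = 0.5)
  expect_equal(obs_loglik(bm$model, th, c(0, 0, 0, 0)),
               log(choose(10, 3) * 0.5^10))
})

test_that("prior evaluation respects support, constraints and densities", {
  m <- pbp_model(
    list(pbp_param("a", 0, 1),
         pbp_param("b", 0, Inf,
                   log_prior = function(x) stats::dgamma(x, 2, 3, log = TRUE))),
    list(pbp_node("normal", integer(),
                  function(xi, theta) list(mean = 0, var = 1))))
  expect_equal(prior_loglik(m, c(a = 0.5, b = 1)),
               stats::dgamma(1, 2, 3, log = TRUE))
  expect_identical(prior_loglik(m, c(a = 1.5, b = 1)), -Inf)
  mc <- pbp_model(m$params, m$nodes, constraint = function(th) th[["a"]] < th[["b"]])
  expect_identical(prior_loglik(mc, c(a = 0.9, b = 0.5)), -Inf)
  expect_equal(prior_loglik(mc, c(a = 0.1, b = 0.5)),
               stats::dgamma(0.5, 2, 3, log = TRUE))
})

test_that("model construction rejects topological-order violations", {
  expect_error(
    pbp_model(list(pbp_param("z", 0, 1)),
              list(pbp_node("poisson", 2L, function(xi, theta) list(lambda = 1)),
                   pbp_node("poisson", integer(), function(xi, theta) list(lambda = 1)))),
    "topologically")
  expect_error(
    pbp_model(list(pbp_param("z", 0, 1)),
              list(pbp_node("poisson", 1L, function(xi, theta) list(lambda = 1)))),
    "topologically")
})

test_that("forward simulation is seed-reproducible and consistent with the law", {
  m <- pbp_model(list(pbp_param("z", 0, 1, init = 0.5)),
                 list(pbp_node("poisson", integer(),
                               function(xi, theta) list(lambda = 50)),
                      pbp_node("poisson", 1L,
                               function(xi, theta) list(lambda = xi[1] + 1))))
  set.seed(21); s1 <- simulate_forward(m, c(z = 0.5))
  set.seed(21); s2 <- simulate_forward(m, c(z = 0.5))
  expect_identical(s1, s2)
  set.seed(22)
  n <- 3000
  draws <- replicate(n, simulate_forward(m, c(z = 0.5))$xi[1])
  expect_lt(abs(mean(draws) - 50), 3 * sqrt(50 / n))
})

test_that("forward-simulated frequencies match the enumerated joint law", {
  set.seed(23)
  m <- two_bern_model(z1 = 0.3, za = 0.2, zb = 0.7)
  th <- c(dummy = 0.5)
  n <- 2e4
  sims <- replicate(n, simulate_forward(m, th)$xi)
  idx <- 1 + sims[1, ] + 2 * sims[2, ]
  states <- expand.grid(0:1, 0:1)
  pexp <- apply(states, 1, function(s) exp(latent_loglik(m, th, as.numeric(s))))
  ct <- tabulate(idx, nbins = 4)
  expect_gt(stats::chisq.test(ct, p = pexp)$p.value, 1e-4)
})

test_that("local delta evaluation agrees with full recomputation", {
  set.seed(24)
  scn <- svt_scenario(E = 12)
  sim <- simulate_scenario(scn, seed = 25)
  bm <- build_svt(scn, sim$data)
  mg <- bm$model; mg$fast <- NULL
  th <- c(mu = -9.5, phi = 0.9, nu = 10, sigma2 = 0.05)
  st <- chain_state(mg, th, sim$latent)
  for (k in 1:20) {
    e <- sample(12, 1)
    v <- st$xi[e] + stats::rnorm(1)
    d <- delta_loglik(mg, st, e, v)
    xi2 <- st$xi; xi2[e] <- v
    full <- (latent_loglik(mg, th, xi2) + obs_loglik(mg, th, xi2)) -
            (st$ll_lat + st$ll_obs)
    expect_equal(d, full, tolerance = 1e-9)
  }
  expect_equal(delta_loglik(mg, st, 3, st$xi[3]), 0)
})

test_that("chain-state caches survive an audit after engine updates", {
  set.seed(26)
  scn <- diagnostic_scenario(P = 20)
  sim <- simulate_scenario(scn, seed = 27)
  bm <- build_diagnostic(scn, sim$data)
  tr <- run_chain(bm$model, bm$ids, engine_config(updates = 200, burnin = 100, seed = 28))
  st <- attr(tr, "final_state")
  expect_lt(audit_state(bm$model, st), 1e-9)
})
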